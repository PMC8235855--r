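#' Pedigree construction and the numerator relationship matrix
#'
#' A pedigree is an ordered set of (animal, sire, dam) triplets in which every
#' known parent appears before its offspring. From it the numerator
#' relationship matrix \eqn{A} (expected additive-genetic relatedness) and its
#' sparse inverse are built; \eqn{A} is the kernel of every genetic covariance
#' in the SAD animal models of this package.
#'
#' @name pedigree
NULL

UNKNOWN_PARENT <- NA_character_

#' Create a validated, topologically sorted pedigree
#'
#' @param animal character vector of animal ids (unique).
#' @param sire,dam character vectors of parent ids; `NA`, `""` or `"0"` mean
#'   unknown. Every known parent must itself appear in `animal`.
#' @return An object of class `pedigree`: a data.frame with columns
#'   `animal`, `sire`, `dam`, ordered so parents precede offspring, plus an
#'   `index` attribute mapping id to row.
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- normalise_parent(sire)
  dam <- normalise_parent(dam)
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  known <- c(sire[!is.na(sire)], dam[!is.na(dam)])
  missing_parents <- setdiff(known, animal)
  if (length(missing_parents)) {
    stop("parent id(s) not listed as animals: ",
         paste(missing_parents, collapse = ", "))
  }
  ord <- pedigree_toposort(animal, sire, dam)
  ped <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

normalise_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- UNKNOWN_PARENT
  x
}

# Kahn topological sort over the parent -> offspring DAG; names any cycle.
pedigree_toposort <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), NA_integer_, idx[sire])
  di <- ifelse(is.na(dam), NA_integer_, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(n)
  head <- 1L; tail <- length(queue)
  out[seq_len(tail)] <- queue
  while (head <= tail && tail <= n) {
    v <- out[head]
    head <- head + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) {
        tail <- tail + 1L
        out[tail] <- ch
      }
    }
  }
  out <- out[seq_len(tail)]
  if (length(out) < n) {
    stop("pedigree cycle detected involving: ",
         paste(animal[indeg > 0L], collapse = ", "))
  }
  out
}

#' Read a pedigree from a delimited file
#'
#' Expects three columns `animal,sire,dam` (header optional if the columns are
#' in that order); `0` or empty fields denote unknown parents. Rows may appear
#' in any order; the result is topologically sorted.
#'
#' @param path path to a CSV/TSV file.
#' @param sep field separator; guessed from the extension by default.
#' @return a [pedigree()] object.
#' @export
read_pedigree <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  first <- readLines(path, n = 1L)
  has_header <- grepl("animal", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = sep, header = has_header,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 3L) stop("pedigree file must have 3 columns (animal, sire, dam)")
  pedigree(df[[1L]], df[[2L]], df[[3L]])
}

ped_parent_index <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  list(
    sire = ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire]),
    dam = ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  )
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes the dense \eqn{A} matrix with exact inbreeding:
#' \eqn{A_{ij} = \tfrac12 (A_{j,s(i)} + A_{j,d(i)})} for \eqn{j < i} and
#' \eqn{A_{ii} = 1 + \tfrac12 A_{s(i),d(i)}}; unknown parents contribute 0.
#'
#' @param ped a [pedigree()].
#' @return symmetric matrix with dimnames = animal ids; entries \eqn{A_{ii} =
#'   1 + F_i} on the diagonal.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  par <- ped_parent_index(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- par$sire[i]; d <- par$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

# Mendelian sampling variances d_i (so |A| = prod d_i), from tabular A.
mendelian_variances <- function(ped, A = NULL) {
  if (is.null(A)) A <- build_A(ped)
  par <- ped_parent_index(ped)
  n <- nrow(ped)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- par$sire[i]; dm <- par$dam[i]
    v <- 1
    if (!is.na(s)) v <- v - 0.25 * A[s, s]
    if (!is.na(dm)) v <- v - 0.25 * A[dm, dm]
    d[i] <- v
  }
  d
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' \eqn{1/d_i} to its diagonal, \eqn{-1/(2 d_i)} to animal-parent cells and
#' \eqn{1/(4 d_i)} to parent-parent cells, where \eqn{d_i} is the Mendelian
#' sampling variance computed exactly from the tabular \eqn{A}.
#'
#' @param ped a [pedigree()].
#' @param A optional precomputed [build_A()] result (reused for the
#'   inbreeding coefficients).
#' @return sparse symmetric `Matrix::dsCMatrix` with dimnames = animal ids.
#' @export
build_A_inverse <- function(ped, A = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  d <- mendelian_variances(ped, A)
  par <- ped_parent_index(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (i in seq_len(n)) {
    a <- 1 / d[i]
    parents <- c(par$sire[i], par$dam[i])
    parents <- parents[!is.na(parents)]
    add(i, i, a)
    for (p in parents) {
      add(i, p, -a / 2); add(p, i, -a / 2)
    }
    if (length(parents)) {
      for (p in parents) for (q in parents) add(p, q, a / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' log-determinant of A
#'
#' \eqn{\log|A| = \sum_i \log d_i} with \eqn{d_i} the Mendelian sampling
#' variances; used in the restricted likelihood.
#' @inheritParams build_A_inverse
#' @return scalar
#' @export
logdet_A <- function(ped, A = NULL) sum(log(mendelian_variances(ped, A)))

#' Write A as a sparse triplet CSV plus id map
#'
#' @param A matrix from [build_A()] (dense) or any matrix with dimnames.
#' @param file output CSV path (columns i, j, value; upper triangle including
#'   diagonal); `<file>.ids.csv` receives the id-to-index map.
#' @param zero_tol entries with absolute value below this are omitted.
#' @export
write_A_triplets <- function(A, file, zero_tol = 0) {
  ids <- rownames(A)
  keep <- which(upper.tri(A, diag = TRUE) & abs(A) > zero_tol, arr.ind = TRUE)
  utils::write.csv(data.frame(i = keep[, 1], j = keep[, 2],
                              value = A[keep]),
                   file, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(index = seq_along(ids), animal = ids),
                   paste0(sub("\\.csv$", "", file), ".ids.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}
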