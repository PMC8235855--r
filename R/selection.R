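#' Selection criteria and model-comparison statistics
#'
#' Time-specific estimated breeding values (TEBV) are summarised for
#' selection by projecting each animal's trajectory on the leading
#' eigenvectors of the genetic covariance matrix: SBV1 tracks the average
#' level of the trait over the test period and SBV2 the main slope of its
#' trajectory. Agreement between models is measured by per-week Spearman
#' rank correlations of EBV, k-means clustering of trajectories and Cohen's
#' kappa on the cluster assignments.
#'
#' @name selection_outputs
NULL

#' Eigen-summarised breeding values
#'
#' Eigendecomposition of the genetic covariance matrix with a deterministic
#' sign convention (each eigenvector's entry sum made non-negative), and the
#' projections of each animal's TEBV trajectory on the leading k
#' eigenvectors.
#'
#' @param G symmetric PD genetic covariance matrix (weeks x weeks).
#' @param tebv animals x weeks matrix of breeding values.
#' @param k number of summarised breeding values (default 2).
#' @return list with `sbv` (animals x k), `eigenvalues`, `eigenvectors`,
#'   `variance_explained`.
#' @export
eigen_summary <- function(G, tebv, k = 2L) {
  n <- nrow(G)
  if (k > n) stop("k must not exceed the number of time points")
  if (ncol(tebv) != n) stop("tebv and G dimensions disagree")
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  sgn <- ifelse(colSums(eg$vectors) < 0, -1, 1)
  vec <- sweep(eg$vectors, 2L, sgn, `*`)
  sbv <- tebv %*% vec[, seq_len(k), drop = FALSE]
  colnames(sbv) <- paste0("SBV", seq_len(k))
  list(sbv = sbv, eigenvalues = eg$values,
       eigenvectors = vec,
       variance_explained = eg$values / sum(eg$values))
}

#' Cluster breeding-value trajectories
#'
#' k-means with multiple restarts under a fixed seed; clusters are
#' relabelled by ascending mean trajectory level so labels are deterministic
#' across runs and animal orderings.
#'
#' @param tebv animals x weeks matrix (no missing entries).
#' @param k number of clusters (default 3).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return integer vector of cluster labels (named by animal).
#' @export
cluster_trajectories <- function(tebv, k = 3L, seed = 20210625L, nstart = 25L) {
  if (k < 2L) stop("k must be at least 2")
  if (k > nrow(tebv)) stop("k exceeds the number of animals")
  if (anyNA(tebv)) stop("tebv must not contain missing entries")
  set.seed(seed)
  if (k == nrow(tebv)) {
    # degenerate case: every animal is its own cluster
    labels <- rank(rowMeans(tebv), ties.method = "first")
    names(labels) <- rownames(tebv)
    return(labels)
  }
  km <- stats::kmeans(tebv, centers = k, nstart = nstart, iter.max = 100L)
  ord <- order(rowMeans(km$centers))
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  names(labels) <- rownames(tebv)
  labels
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Cohen's kappa between two clusterings
#'
#' Because cluster labels are arbitrary, labels of `b` are first matched to
#' `a` by the permutation maximising agreement; kappa is then
#' \eqn{(p_o - p_e)/(1 - p_e)} with the expected agreement from the
#' marginals.
#'
#' @param a,b label vectors of equal length.
#' @param match_labels align labels by best permutation first (default).
#' @return numeric kappa.
#' @export
cohens_kappa <- function(a, b, match_labels = TRUE) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  if (length(unique(a)) < 2L && length(unique(b)) < 2L) {
    stop("kappa undefined: a single shared label")
  }
  if (match_labels) {
    lv <- sort(unique(b))
    if (length(lv) <= 8L) {
      best <- -Inf; bbest <- b
      for (pm in all_permutations(lv)) {
        bb <- pm[match(b, lv)]
        ag <- mean(a == bb)
        if (ag > best) { best <- ag; bbest <- bb }
      }
      b <- bbest
    }
  }
  lev <- sort(unique(c(a, b)))
  ta <- factor(a, levels = lev); tb <- factor(b, levels = lev)
  tab <- table(ta, tb) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe < .Machine$double.eps) stop("kappa undefined: degenerate marginals")
  (po - pe) / (1 - pe)
}

#' Per-week Spearman correlations between two EBV matrices
#'
#' @param a,b animals x weeks matrices sharing row names.
#' @param grouping optional named factor (e.g. selection line) to compute
#'   correlations per group.
#' @param conf confidence level of the Fisher-z interval.
#' @return data.frame `group, week, rho, lower, upper, n`.
#' @export
spearman_by_week <- function(a, b, grouping = NULL, conf = 0.95) {
  common <- intersect(rownames(a), rownames(b))
  if (length(common) < 3L) stop("fewer than 3 shared animals")
  a <- a[common, , drop = FALSE]
  b <- b[common, , drop = FALSE]
  groups <- if (is.null(grouping)) {
    list(all = common)
  } else {
    split(common, grouping[common])
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) < 3L) next
    for (j in seq_len(ncol(a))) {
      r <- stats::cor(a[ids, j], b[ids, j], method = "spearman")
      n <- length(ids)
      fz <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
      ci <- tanh(fz + c(-1, 1) * z / sqrt(n - 3))
      out[[length(out) + 1L]] <- data.frame(group = g, week = j, rho = r,
                                            lower = ci[1], upper = ci[2], n = n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-line, per-generation means of summarised breeding values
#'
#' @param sbv animals x components matrix (e.g. from [eigen_summary()]).
#' @param metadata data.frame with columns `animal`, `line`, `generation`
#'   covering all rows of `sbv`.
#' @return data.frame `line, generation, component, mean, se, n`.
#' @export
generation_trend <- function(sbv, metadata) {
  unknown <- setdiff(rownames(sbv), metadata$animal)
  if (length(unknown)) {
    stop("animals missing from metadata: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  md <- metadata[match(rownames(sbv), metadata$animal), ]
  out <- list()
  for (cmp in colnames(sbv)) {
    agg <- stats::aggregate(sbv[, cmp],
                            by = list(line = md$line, generation = md$generation),
                            FUN = function(v) c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
                                                n = length(v)))
    out[[cmp]] <- data.frame(line = agg$line, generation = agg$generation,
                             component = cmp,
                             mean = agg$x[, "mean"], se = agg$x[, "se"],
                             n = agg$x[, "n"])
  }
  res <- do.call(rbind, out)
  empty <- res$n == 0
  if (any(empty)) {
    warning("empty group(s) omitted")
    res <- res[!empty, ]
  }
  rownames(res) <- NULL
  res
}

#' Extract a per-week TEBV matrix for one trait
#'
#' @param tebv animals x trait:week matrix (from [blup_solve()]).
#' @param trait trait name (cells `trait:week`).
#' @return animals x weeks matrix.
#' @export
tebv_matrix <- function(tebv, trait) {
  cols <- grep(paste0("^", trait, ":"), colnames(tebv), value = TRUE)
  m <- tebv[, cols, drop = FALSE]
  colnames(m) <- sub(".*:", "", cols)
  m
}
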