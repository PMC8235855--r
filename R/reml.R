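#' REML estimation of SAD animal models
#'
#' The observation model is \eqn{y = X\beta + Zu + e} with
#' \eqn{u \sim N(0, A \otimes \Sigma_g)} over pedigree animals and
#' \eqn{e \sim N(0, I \otimes \Sigma_e)} over phenotyped animals, where
#' \eqn{\Sigma_g, \Sigma_e} are the joint trait-by-time SAD covariance
#' matrices. Missing cells are dropped from the likelihood, never imputed.
#'
#' Two evaluation paths give identical values: when every phenotyped animal
#' has complete records, the likelihood is computed after rotating animals by
#' the eigenvectors of the phenotyped block of \eqn{A} and simultaneously
#' diagonalising \eqn{\Sigma_g} against \eqn{\Sigma_e}, which reduces each
#' evaluation to scalar operations; otherwise Henderson's mixed-model
#' equations with the sparse inverse of \eqn{A} are used.
#'
#' @name mixed_model
NULL

## ---- design construction ----

#' Build fixed/random design information for a phenotype table
#'
#' Records are put in canonical order (animal within pedigree order, then
#' trait, then week); each trait receives its own fixed-effect block built
#' from `fixed` (use `wk`, the week factor, in the formula; the default is
#' week-specific intercepts per trait).
#'
#' @param pheno data.frame with columns `animal, week, trait, value` plus any
#'   columns referenced by `fixed`.
#' @param grid a [time_grid()].
#' @param traits trait order (regressed trait last).
#' @param fixed one-sided formula evaluated per trait; default `~ 0 + wk`.
#' @param animals optional canonical animal ordering (e.g. pedigree order).
#' @return list with the record table `rec` (canonically ordered), dense `X`,
#'   `y`, `animal_index`, `cell` (trait-by-week cell per record), `animals`,
#'   `q`, and `complete` (logical: all animals have all cells).
#' @export
build_design <- function(pheno, grid, traits, fixed = ~ 0 + wk,
                         animals = NULL) {
  need <- c("animal", "week", "trait", "value")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  vars <- setdiff(all.vars(fixed), c("wk"))
  miss <- setdiff(vars, names(pheno))
  if (length(miss)) stop("fixed formula references unknown column(s): ", paste(miss, collapse = ", "))
  if (anyNA(pheno$value)) stop("phenotype values must not be NA; drop missing records instead")
  rec <- pheno[pheno$trait %in% traits & pheno$week %in% seq_along(grid), , drop = FALSE]
  if (anyDuplicated(rec[c("animal", "week", "trait")])) {
    stop("duplicate (animal, week, trait) records")
  }
  if (is.null(animals)) animals <- sort(unique(rec$animal))
  animals <- animals[animals %in% rec$animal]
  n <- length(grid)
  ti <- match(rec$trait, traits)
  rec$..cell <- (ti - 1L) * n + rec$week
  rec$..animal_i <- match(rec$animal, animals)
  ord <- order(rec$..animal_i, rec$..cell)
  rec <- rec[ord, , drop = FALSE]
  # single-week grids: a one-level factor breaks model.matrix, use a
  # constant regressor instead (the week-specific intercept)
  rec$wk <- if (n > 1L) factor(rec$week, levels = seq_len(n)) else 1
  blocks <- lapply(traits, function(tr) {
    rows <- which(rec$trait == tr)
    mm <- stats::model.matrix(fixed, rec[rows, , drop = FALSE])
    colnames(mm) <- paste0(tr, ".", colnames(mm))
    list(rows = rows, mm = mm)
  })
  p <- sum(vapply(blocks, function(b) ncol(b$mm), integer(1)))
  X <- matrix(0, nrow(rec), p)
  cn <- character(p)
  off <- 0L
  for (b in blocks) {
    cols <- off + seq_len(ncol(b$mm))
    X[b$rows, cols] <- b$mm
    cn[cols] <- colnames(b$mm)
    off <- off + ncol(b$mm)
  }
  colnames(X) <- cn
  # structurally empty columns (e.g. a nested covariate that is identically
  # zero) carry no information: drop them rather than flag rank deficiency
  nz <- colSums(abs(X)) > 0
  if (!all(nz)) {
    X <- X[, nz, drop = FALSE]
    cn <- cn[nz]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- cn[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; confounded column(s): ",
         paste(bad, collapse = ", "))
  }
  complete <- nrow(rec) == length(animals) * length(traits) * n
  list(rec = rec, X = X, y = rec$value, animal_index = rec$..animal_i,
       cell = rec$..cell, animals = animals, q = length(traits) * n,
       n_traits = length(traits), complete = complete)
}

## ---- REML setup ----

#' Prepare a REML evaluation context
#'
#' Precomputes everything that does not depend on the SAD parameters:
#' the design, the eigendecomposition of the phenotyped block of A (complete
#' data) or the sparse inverse of A and incidence structures (missing data).
#'
#' @param pheno phenotype table (long format).
#' @param ped a [pedigree()] covering all phenotyped animals.
#' @param spec a [sad_spec()].
#' @param grid a [time_grid()].
#' @param fixed fixed-effect formula per trait (see [build_design()]).
#' @param A optional precomputed [build_A()] matrix.
#' @param method `"auto"` (eigen path when records are complete), `"eigen"`,
#'   or `"mme"`.
#' @return object of class `reml_setup`.
#' @export
reml_setup <- function(pheno, ped, spec, grid, fixed = ~ 0 + wk, A = NULL,
                       method = c("auto", "eigen", "mme")) {
  method <- match.arg(method)
  stopifnot(inherits(ped, "pedigree"), inherits(spec, "sad_spec"))
  if (is.null(A)) A <- build_A(ped)
  des <- build_design(pheno, grid, spec$traits, fixed = fixed,
                      animals = ped$animal)
  if (method == "auto") method <- if (des$complete) "eigen" else "mme"
  if (method == "eigen" && !des$complete) {
    stop("eigen likelihood path requires complete records; use method = 'mme'")
  }
  N <- length(des$animals)
  q <- des$q
  p <- ncol(des$X)
  out <- list(spec = spec, grid = grid, des = des, method = method,
              ped = ped, N = N, q = q, p = p)
  if (method == "eigen") {
    App <- A[des$animals, des$animals]
    ea <- eigen(App, symmetric = TRUE)
    out$U <- ea$vectors
    out$s <- ea$values
    # records are animal-major, cell-minor; Y[i, k]
    Y <- matrix(des$y, nrow = q)  # q x N
    out$Ytil <- crossprod(out$U, t(Y))  # N x q
    # balanced design: X rows identical across animals within each cell
    X3 <- array(des$X, c(q, N, p))  # cell fastest within animal? records are
    # ordered animal-major so dim must be (q, N, p) with cell fastest: row
    # index = (i-1)q + k -> array(q, N, p)[k, i, l]
    bal <- TRUE
    X0 <- matrix(0, q, p)
    for (l in seq_len(p)) {
      sl <- matrix(X3[, , l], q, N)
      rng <- apply(sl, 1L, function(z) max(z) - min(z))
      if (any(rng > 0)) { bal <- FALSE; break }
      X0[, l] <- sl[, 1L]
    }
    out$balanced <- bal
    if (bal) {
      out$X0 <- X0
      out$cvec <- colSums(out$U)  # U' 1_N
      out$cvec2 <- out$cvec^2
    } else {
      # Xt_flat[(l-1)q + k, i] = sum_j U[j,i] X[row(j,k), l]
      Xf <- matrix(aperm(X3, c(1L, 3L, 2L)), q * p, N)  # (q,p) x N
      out$Xt_flat <- Xf %*% out$U
    }
  } else {
    out$Ainv <- build_A_inverse(ped, A)
    out$logdetA <- logdet_A(ped, A)
    out$ped_pos <- match(des$animals, ped$animal)
    # observation pattern per animal
    obs <- split(des$cell, des$animal_index)
    pat_key <- vapply(obs, function(k) paste(k, collapse = ","), character(1))
    out$patterns <- split(seq_len(N), pat_key)
    out$obs_cells <- obs
    nrec <- nrow(des$rec)
    out$Z <- Matrix::sparseMatrix(
      i = seq_len(nrec),
      j = (out$ped_pos[des$animal_index] - 1L) * q + des$cell,
      x = 1, dims = c(nrec, nrow(ped) * q))
    out$Xs <- Matrix::Matrix(des$X, sparse = TRUE)
  }
  class(out) <- "reml_setup"
  out
}

## ---- likelihood evaluation ----

reml_value <- function(setup, params) {
  ll <- tryCatch(
    if (setup$method == "eigen") reml_value_eigen(setup, params)
    else reml_value_mme(setup, params),
    error = function(e) -Inf)
  if (!is.finite(ll)) -Inf else ll
}

sigma_pair <- function(setup, params) {
  list(Sg = multi_trait_covariance(params, setup$grid, "genetic"),
       Se = multi_trait_covariance(params, setup$grid, "environmental"))
}

reml_value_eigen <- function(setup, params) {
  S <- sigma_pair(setup, params)
  q <- setup$q; N <- setup$N; p <- setup$p
  Lo <- t(chol(S$Se))
  W0 <- forwardsolve(Lo, diag(q))
  K <- W0 %*% S$Sg %*% t(W0)
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  W <- crossprod(ek$vectors, W0)          # q x q whitening + rotation
  lam <- pmax(ek$values, 0)
  d <- outer(setup$s, lam) + 1            # N x q
  if (any(d <= 0)) return(-Inf)
  ldSe <- 2 * sum(log(diag(Lo)))
  logdetV <- N * ldSe + sum(log(d))
  Yw <- setup$Ytil %*% t(W)               # N x q
  if (isTRUE(setup$balanced)) {
    XW <- W %*% setup$X0                  # q x p
    v <- colSums(setup$cvec2 / d)         # q
    XtVX <- crossprod(XW, v * XW)
    tvec <- colSums(setup$cvec * Yw / d)
    Xty <- crossprod(XW, tvec)
    yty <- sum(Yw^2 / d)
  } else {
    Xw <- W %*% matrix(setup$Xt_flat, q, p * N)  # wrong layout guard below
    # Xt_flat is (q*p) x N with (l-1)q+k rows: reshape to q x (p*N)
    arr <- array(setup$Xt_flat, c(q, p, N))
    Xw <- W %*% matrix(arr, q, p * N)
    Xw_long <- matrix(aperm(array(Xw, c(q, p, N)), c(1L, 3L, 2L)), N * q, p)
    wts <- as.vector(t(1 / d))            # cell fastest within animal
    yl <- as.vector(t(Yw))
    XtVX <- crossprod(Xw_long, Xw_long * wts)
    Xty <- crossprod(Xw_long, yl * wts)
    yty <- sum(yl^2 * wts)
  }
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), Xty))
  yPy <- yty - sum(Xty * beta)
  ldXtVX <- 2 * sum(log(diag(ch)))
  -0.5 * (logdetV + ldXtVX + yPy + (N * q - p) * log(2 * pi))
}

reml_value_mme <- function(setup, params) {
  S <- sigma_pair(setup, params)
  q <- setup$q
  n_ped <- nrow(setup$ped)
  Sg_inv <- solve(S$Sg)
  ldSg <- as.numeric(determinant(S$Sg, logarithm = TRUE)$modulus)
  logdetG <- q * setup$logdetA + n_ped * ldSg
  # R inverse, block per animal, grouped by observation pattern
  nrec <- nrow(setup$des$rec)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  logdetR <- 0
  row_of <- split(seq_len(nrec), setup$des$animal_index)
  for (grp in setup$patterns) {
    cells <- setup$obs_cells[[grp[1L]]]
    Ro <- S$Se[cells, cells, drop = FALSE]
    ch <- chol(Ro)
    Rinv <- chol2inv(ch)
    logdetR <- logdetR + 2 * length(grp) * sum(log(diag(ch)))
    m <- length(cells)
    idx <- which(Rinv != 0, arr.ind = TRUE)
    for (a in grp) {
      rows <- row_of[[a]]
      ii <- c(ii, rows[idx[, 1L]])
      jj <- c(jj, rows[idx[, 2L]])
      xx <- c(xx, Rinv[idx])
    }
  }
  Rinv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nrec, nrec))
  Wm <- cbind(setup$Xs, setup$Z)
  WtR <- Matrix::crossprod(Wm, Rinv)
  C <- WtR %*% Wm
  Gkron_inv <- Matrix::kronecker(setup$Ainv, Sg_inv)
  p <- setup$p
  nu <- n_ped * q
  pad <- Matrix::bdiag(Matrix::Matrix(0, p, p), Gkron_inv)
  C <- Matrix::forceSymmetric(C + pad)
  ch <- tryCatch(suppressWarnings(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)),
                 error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetC <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  rhs <- WtR %*% setup$des$y
  sol <- Matrix::solve(ch, rhs)
  yRy <- as.numeric(Matrix::crossprod(setup$des$y, Rinv %*% setup$des$y))
  yPy <- yRy - as.numeric(Matrix::crossprod(rhs, sol))
  -0.5 * (logdetR + logdetG + logdetC + yPy + (nrec - p) * log(2 * pi))
}

#' Restricted log-likelihood of a SAD animal model
#'
#' @param omega named parameter vector (see [params_to_vector()]).
#' @param pheno phenotype table or a prepared [reml_setup()].
#' @param ped pedigree (ignored when `pheno` is a setup).
#' @param spec a [sad_spec()] (ignored when `pheno` is a setup).
#' @param grid a [time_grid()] (ignored when `pheno` is a setup).
#' @param ... passed to [reml_setup()].
#' @return scalar REML log-likelihood (`-Inf` on numerical failure).
#' @export
restricted_loglik <- function(omega, pheno, ped = NULL, spec = NULL,
                              grid = NULL, ...) {
  setup <- if (inherits(pheno, "reml_setup")) pheno
  else reml_setup(pheno, ped, spec, grid, ...)
  params <- vector_to_params(omega, setup$spec)
  reml_value(setup, params)
}

## ---- starting values ----

reml_start <- function(setup) {
  spec <- setup$spec
  des <- setup$des
  # residual variance per trait after removing cell means
  res_var <- vapply(spec$traits, function(tr) {
    rows <- des$rec$trait == tr
    v <- des$y[rows]
    cellm <- stats::ave(v, des$rec$week[rows])
    max(stats::var(v - cellm), 1e-3)
  }, numeric(1))
  omega <- stats::setNames(rep(0, length(param_template(spec))),
                           param_template(spec))
  for (tr in spec$traits) {
    omega[paste0("g.", tr, ".theta.0")] <- 0.3
    omega[paste0("e.", tr, ".theta.0")] <- 0.3
    omega[paste0("g.", tr, ".lvar.0")] <- log(0.35 * res_var[tr])
    omega[paste0("e.", tr, ".lvar.0")] <- log(0.6 * res_var[tr])
  }
  # crude phenotypic regression of the regressed trait on each target as a
  # starting cross coefficient
  reg <- spec_regressed(spec)
  for (comp in c("genetic", "environmental")) {
    cr <- spec[[paste0("cross_", comp)]]
    tag <- if (comp == "genetic") "bg" else "be"
    for (s in names(cr)) {
      b0 <- cross_start(des, s, reg)
      omega[paste0(tag, ".", s, ".0")] <- b0
    }
  }
  omega
}

cross_start <- function(des, s, reg) {
  a <- des$rec[des$rec$trait == s, c("animal", "week", "value")]
  b <- des$rec[des$rec$trait == reg, c("animal", "week", "value")]
  m <- merge(a, b, by = c("animal", "week"))
  if (nrow(m) < 10L) return(0.3)
  xs <- m$value.x - stats::ave(m$value.x, m$week)
  ys <- m$value.y - stats::ave(m$value.y, m$week)
  vv <- stats::var(xs)
  if (vv <= 0) 0.3 else stats::cov(xs, ys) / vv
}

## ---- fitting ----

#' Fit a SAD animal model by REML
#'
#' Maximises the restricted likelihood by quasi-Newton (BFGS with numerical
#' gradients) on the unconstrained coefficient vector (innovation variances
#' enter through their log-polynomials, so positivity is automatic).
#' A subset of parameters can be frozen at given values, supporting the
#' two-stage scheme in which production-trait antedependence and innovation
#' parameters are fixed at their single-trait estimates.
#'
#' @param pheno phenotype table or prepared [reml_setup()].
#' @param ped pedigree (when `pheno` is a table).
#' @param spec a [sad_spec()].
#' @param grid a [time_grid()].
#' @param fixed fixed-effect formula per trait.
#' @param start optional named starting vector (defaults are data-driven).
#' @param frozen named numeric vector of parameters to hold fixed.
#' @param maxit,reltol optimizer control.
#' @param restarts jittered restarts attempted on non-convergence.
#' @param hessian compute the finite-difference information matrix.
#' @param seed seed for restart jitter.
#' @param ... passed to [reml_setup()].
#' @return object of class `sad_fit`.
#' @export
fit_reml <- function(pheno, ped = NULL, spec = NULL, grid = NULL,
                     fixed = ~ 0 + wk, start = NULL, frozen = NULL,
                     maxit = 400L, reltol = 1e-10, restarts = 1L,
                     hessian = TRUE, seed = 1L, ...) {
  setup <- if (inherits(pheno, "reml_setup")) pheno
  else reml_setup(pheno, ped, spec, grid, fixed = fixed, ...)
  spec <- setup$spec
  template <- param_template(spec)
  omega0 <- reml_start(setup)
  if (!is.null(start)) omega0[names(start)] <- start
  if (!is.null(frozen)) {
    bad <- setdiff(names(frozen), template)
    if (length(bad)) stop("frozen parameter(s) not in spec: ", paste(bad, collapse = ", "))
    omega0[names(frozen)] <- frozen
  }
  free <- setdiff(template, names(frozen))
  if (!length(free)) stop("no free parameters to estimate")
  full <- omega0
  negll <- function(x) {
    full[free] <- x
    v <- restricted_loglik(full, setup)
    if (!is.finite(v)) 1e10 else -v
  }
  set.seed(seed)
  best <- NULL
  x0 <- omega0[free]
  for (try in 0:restarts) {
    xs <- if (try == 0L) x0 else x0 + stats::rnorm(length(x0), 0, 0.1 * (1 + abs(x0)))
    opt <- stats::optim(xs, negll, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol,
                                       ndeps = rep(1e-5, length(x0))))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0L) break
  }
  omega_hat <- omega0
  omega_hat[free] <- best$par
  info <- NULL
  if (hessian) {
    info <- tryCatch(
      stats::optimHess(best$par, negll,
                       control = list(ndeps = rep(1e-4, length(free)))),
      error = function(e) NULL)
    if (!is.null(info)) {
      info <- (info + t(info)) / 2
      dimnames(info) <- list(free, free)
    }
  }
  params <- vector_to_params(omega_hat, spec)
  derived <- list(
    Sg = multi_trait_covariance(params, setup$grid, "genetic"),
    Se = multi_trait_covariance(params, setup$grid, "environmental"))
  beta <- reml_beta(setup, params)
  structure(list(spec = spec, grid = setup$grid, params = params,
                 omega = omega_hat, free = free, frozen = frozen,
                 loglik = -best$value, information = info,
                 converged = best$convergence == 0L,
                 counts = best$counts, beta = beta,
                 derived = derived, setup = setup),
            class = "sad_fit")
}

#' @export
print.sad_fit <- function(x, ...) {
  cat("SAD animal model fit (", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  cat("  traits:", paste(x$spec$traits, collapse = ", "), "\n")
  cat("  restricted log-likelihood:", format(x$loglik, digits = 10), "\n")
  cat("  free parameters:", length(x$free), "\n")
  invisible(x)
}

# GLS fixed-effect estimates (and their covariance) at given parameters
reml_beta <- function(setup, params) {
  S <- sigma_pair(setup, params)
  if (setup$method == "eigen") {
    q <- setup$q; N <- setup$N; p <- setup$p
    Lo <- t(chol(S$Se)); W0 <- forwardsolve(Lo, diag(q))
    K <- W0 %*% S$Sg %*% t(W0)
    ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
    W <- crossprod(ek$vectors, W0)
    d <- outer(setup$s, pmax(ek$values, 0)) + 1
    Yw <- setup$Ytil %*% t(W)
    if (isTRUE(setup$balanced)) {
      XW <- W %*% setup$X0
      v <- colSums(setup$cvec2 / d)
      XtVX <- crossprod(XW, v * XW)
      Xty <- crossprod(XW, colSums(setup$cvec * Yw / d))
    } else {
      arr <- array(setup$Xt_flat, c(q, p, N))
      Xw <- W %*% matrix(arr, q, p * N)
      Xw_long <- matrix(aperm(array(Xw, c(q, p, N)), c(1L, 3L, 2L)), N * q, p)
      wts <- as.vector(t(1 / d))
      XtVX <- crossprod(Xw_long, Xw_long * wts)
      Xty <- crossprod(Xw_long, as.vector(t(Yw)) * wts)
    }
    V <- solve(XtVX)
    est <- drop(V %*% Xty)
  } else {
    # via MME: beta block of the solution
    sol <- mme_solution(setup, params)
    est <- sol$beta
    V <- sol$beta_cov
  }
  names(est) <- colnames(setup$des$X)
  dimnames(V) <- list(names(est), names(est))
  list(estimate = est, cov = V)
}

## ---- mixed model equation solve (BLUP) ----

mme_solution <- function(setup, params) {
  stopifnot(setup$method == "mme")
  S <- sigma_pair(setup, params)
  q <- setup$q
  n_ped <- nrow(setup$ped)
  Sg_inv <- solve(S$Sg)
  nrec <- nrow(setup$des$rec)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  row_of <- split(seq_len(nrec), setup$des$animal_index)
  for (grp in setup$patterns) {
    cells <- setup$obs_cells[[grp[1L]]]
    Rinv <- chol2inv(chol(S$Se[cells, cells, drop = FALSE]))
    idx <- which(Rinv != 0, arr.ind = TRUE)
    for (a in grp) {
      rows <- row_of[[a]]
      ii <- c(ii, rows[idx[, 1L]])
      jj <- c(jj, rows[idx[, 2L]])
      xx <- c(xx, Rinv[idx])
    }
  }
  Rinv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nrec, nrec))
  Wm <- cbind(setup$Xs, setup$Z)
  WtR <- Matrix::crossprod(Wm, Rinv)
  C <- WtR %*% Wm
  p <- setup$p
  pad <- Matrix::bdiag(Matrix::Matrix(0, p, p),
                       Matrix::kronecker(setup$Ainv, Sg_inv))
  C <- Matrix::forceSymmetric(C + pad)
  ch <- suppressWarnings(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE))
  sol <- as.numeric(Matrix::solve(ch, WtR %*% setup$des$y))
  beta <- sol[seq_len(p)]
  u <- matrix(sol[-seq_len(p)], nrow = q)  # q x n_ped (animal-major blocks)
  Cinv_beta <- Matrix::solve(ch, Matrix::Diagonal(nrow(C))[, seq_len(p), drop = FALSE])
  list(beta = beta, beta_cov = as.matrix(Cinv_beta[seq_len(p), , drop = FALSE]),
       u = t(u))
}

#' BLUP of time-specific breeding values and residual effects
#'
#' Solves for the best linear unbiased predictions of every pedigree
#' animal's trait-by-week genetic effects at the fitted parameters, plus the
#' environmental effects of phenotyped animals (conditional expectations at
#' unobserved cells).
#'
#' @param fit a [fit_reml()] result.
#' @return list with `tebv` (pedigree animals x trait:week), `e`
#'   (phenotyped animals x trait:week), `beta` (GLS fixed effects).
#' @export
blup_solve <- function(fit) {
  setup <- fit$setup
  params <- fit$params
  q <- setup$q
  labels <- cell_labels(setup$spec$traits, setup$grid)
  if (setup$method == "eigen") {
    S <- sigma_pair(setup, params)
    N <- setup$N; p <- setup$p
    Lo <- t(chol(S$Se)); W0 <- forwardsolve(Lo, diag(q))
    K <- W0 %*% S$Sg %*% t(W0)
    ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
    W <- crossprod(ek$vectors, W0)
    d <- outer(setup$s, pmax(ek$values, 0)) + 1
    beta <- fit$beta$estimate
    # residual of transformed data
    if (isTRUE(setup$balanced)) {
      Rtil <- setup$Ytil - tcrossprod(setup$cvec, drop(setup$X0 %*% beta))
    } else {
      arr <- array(setup$Xt_flat, c(q, p, N))
      fitX <- matrix(matrix(aperm(arr, c(1L, 3L, 2L)), N * q, p) %*% beta,
                     q, N)  # rows cell, col animal
      Rtil <- setup$Ytil - t(fitX)
    }
    Rw <- Rtil %*% t(W)          # N x q
    M <- (Rw / d) %*% W %*% S$Sg # N x q : rows = Sigma_g V_i^{-1} r_i
    U_pheno <- setup$U %*% (setup$s * M)
    ped_ids <- setup$ped$animal
    other <- setdiff(ped_ids, setup$des$animals)
    A <- build_A(setup$ped)
    tebv <- matrix(0, length(ped_ids), q, dimnames = list(ped_ids, labels))
    tebv[setup$des$animals, ] <- U_pheno
    if (length(other)) {
      tebv[other, ] <- A[other, setup$des$animals] %*% setup$U %*% M
    }
    Y <- t(matrix(setup$des$y, nrow = q))
    fitted_fix <- if (isTRUE(setup$balanced)) {
      matrix(rep(drop(setup$X0 %*% beta), N), N, q, byrow = TRUE)
    } else {
      t(matrix(setup$des$X %*% beta, nrow = q))
    }
    e <- Y - fitted_fix - U_pheno
    dimnames(e) <- list(setup$des$animals, labels)
    return(list(tebv = tebv, e = e, beta = fit$beta))
  }
  sol <- mme_solution(setup, params)
  tebv <- sol$u
  dimnames(tebv) <- list(setup$ped$animal, labels)
  # residual effects: observed cells from data, unobserved by conditional
  # expectation given the observed residuals
  S <- sigma_pair(setup, params)
  N <- setup$N
  e <- matrix(NA_real_, N, q, dimnames = list(setup$des$animals, labels))
  yhat <- as.numeric(setup$des$X %*% sol$beta)
  uhat_rec <- tebv[cbind(match(setup$des$rec$animal, setup$ped$animal),
                         setup$des$cell)]
  res <- setup$des$y - yhat - uhat_rec
  for (i in seq_len(N)) {
    rows <- which(setup$des$animal_index == i)
    cells <- setup$des$cell[rows]
    e[i, cells] <- res[rows]
    missing_cells <- setdiff(seq_len(q), cells)
    if (length(missing_cells)) {
      e[i, missing_cells] <- S$Se[missing_cells, cells, drop = FALSE] %*%
        solve(S$Se[cells, cells, drop = FALSE], res[rows])
    }
  }
  list(tebv = tebv, e = e, beta = list(estimate = sol$beta, cov = sol$beta_cov))
}

## ---- model comparison and diagnostics ----

#' Likelihood ratio test between nested SAD fits
#'
#' @param fit_small,fit_big nested [fit_reml()] results on the same data.
#' @param boundary `"naive"` chi-square p-value (default) or `"mixture"`
#'   (50:50 mixture of chi-squares with df and df-1, for a single variance
#'   parameter on its boundary).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(fit_small, fit_big, boundary = c("naive", "mixture")) {
  boundary <- match.arg(boundary)
  df <- length(fit_big$free) - length(fit_small$free)
  if (df < 0) stop("models are not nested (fit_big has fewer free parameters)")
  small_tpl <- param_template(fit_small$spec)
  big_tpl <- param_template(fit_big$spec)
  if (!all(small_tpl %in% big_tpl)) stop("specs are not nested")
  stat <- max(0, 2 * (fit_big$loglik - fit_small$loglik))
  if (df == 0L) {
    if (stat > 1e-6) stop("models are not nested (same size, different likelihood)")
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  p <- if (boundary == "naive") {
    stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    0.5 * stats::pchisq(stat, df, lower.tail = FALSE) +
      0.5 * (if (df > 1) stats::pchisq(stat, df - 1, lower.tail = FALSE) else
        as.numeric(stat == 0))
  }
  list(statistic = stat, df = df, p_value = p)
}

#' Condition number of the information matrix
#'
#' Square root of the ratio of the largest to the smallest eigenvalue of
#' \eqn{I(\hat\omega)}; values above `threshold` flag a practical
#' identifiability concern.
#'
#' @param fit a [fit_reml()] result (or a matrix).
#' @param threshold flag level (default 1000).
#' @return numeric with attributes `flagged` and `warning` (non-PSD case).
#' @export
information_condition_number <- function(fit, threshold = 1000) {
  info <- if (is.matrix(fit)) fit else fit$information
  if (is.null(info)) stop("no information matrix available")
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  warn <- any(ev <= 0)
  if (warn) warning("information matrix is not positive definite")
  cn <- suppressWarnings(sqrt(max(ev) / min(ev)))
  structure(cn, flagged = is.finite(cn) && cn > threshold, warning = warn)
}

## ---- stepwise degree selection ----

bump_spec <- function(spec, trait, component, fun) {
  d <- spec[[component]][[trait]]
  d[[fun]] <- d[[fun]] + 1L
  spec[[component]][[trait]] <- d
  sad_spec(spec$traits, genetic = spec$genetic, environmental = spec$environmental,
           cross_genetic = spec$cross_genetic,
           cross_environmental = spec$cross_environmental,
           scale_time = spec$scale_time)
}

#' Forward stepwise selection of SAD polynomial degrees
#'
#' First selects the antedependence/innovation degrees for each trait with
#' single-trait models, alternating between the antedependence parameter and
#' the innovation variance (for the genetic then the environmental
#' component), accepting an increment when the likelihood ratio test is
#' significant. Then, with production-trait parameters frozen at their
#' single-trait estimates, the degrees of all cross-antedependence functions
#' are increased together while the joint test stays significant.
#'
#' @param pheno phenotype table.
#' @param ped pedigree.
#' @param grid a [time_grid()].
#' @param traits trait order (regressed trait last).
#' @param alpha stepwise significance level.
#' @param max_degree largest polynomial degree attempted per function.
#' @param max_cross_degree largest cross-antedependence degree attempted.
#' @param fixed fixed-effect formula.
#' @param ... passed to [fit_reml()].
#' @return list with `spec` (retained [sad_spec()]), `single_fits`,
#'   `cross_fit` and a decision `trail` data.frame.
#' @export
select_degrees <- function(pheno, ped, grid, traits, alpha = 0.05,
                           max_degree = 2L, max_cross_degree = 2L,
                           fixed = ~ 0 + wk, ...) {
  trail <- list()
  note <- function(...) trail[[length(trail) + 1L]] <<- data.frame(...)
  single <- list()
  for (tr in traits) {
    sub <- pheno[pheno$trait == tr, , drop = FALSE]
    cur_spec <- sad_spec_single(tr, c(theta = 0, lvar = 0), c(theta = 0, lvar = 0))
    cur_fit <- fit_reml(sub, ped, cur_spec, grid, fixed = fixed, ...)
    moves <- expand.grid(component = c("genetic", "environmental"),
                         fun = c("theta", "lvar"), stringsAsFactors = FALSE)
    moves <- moves[order(moves$component == "environmental", moves$fun == "lvar"), ]
    repeat {
      # evaluate every admissible degree increment, accept the most
      # significant one (the alternation order breaks ties)
      best <- NULL
      for (mi in seq_len(nrow(moves))) {
        comp <- moves$component[mi]; fun <- moves$fun[mi]
        if (cur_spec[[comp]][[tr]][[fun]] >= max_degree) next
        cand_spec <- bump_spec(cur_spec, tr, comp, fun)
        cand_fit <- tryCatch(fit_reml(sub, ped, cand_spec, grid, fixed = fixed, ...),
                             error = function(e) NULL)
        if (is.null(cand_fit)) {
          note(trait = tr, step = paste(comp, fun), outcome = "fit failed",
               p = NA_real_)
          next
        }
        test <- lrt(cur_fit, cand_fit)
        sig <- is.finite(test$p_value) && test$p_value < alpha
        note(trait = tr, step = paste(comp, fun),
             outcome = if (sig) "significant" else "rejected", p = test$p_value)
        if (sig && (is.null(best) || test$p_value < best$p)) {
          best <- list(spec = cand_spec, fit = cand_fit, p = test$p_value,
                       step = paste(comp, fun))
        }
      }
      if (is.null(best)) break
      note(trait = tr, step = best$step, outcome = "accepted", p = best$p)
      cur_spec <- best$spec; cur_fit <- best$fit
    }
    single[[tr]] <- list(spec = cur_spec, fit = cur_fit)
  }
  reg <- utils::tail(traits, 1L)
  prod_traits <- utils::head(traits, -1L)
  make_joint <- function(cross_deg) {
    sad_spec(traits,
             genetic = lapply(single, function(s) s$spec$genetic[[1L]])[traits],
             environmental = lapply(single, function(s) s$spec$environmental[[1L]])[traits],
             cross_genetic = stats::setNames(rep(cross_deg, length(prod_traits)), prod_traits),
             cross_environmental = stats::setNames(rep(cross_deg, length(prod_traits)), prod_traits))
  }
  frozen_production <- function(spec) {
    out <- numeric(0)
    for (tr in prod_traits) {
      est <- params_to_vector(single[[tr]]$fit$params)
      out <- c(out, est)
    }
    out
  }
  cur_deg <- 0L
  spec0 <- make_joint(cur_deg)
  frz <- frozen_production(spec0)
  start0 <- params_to_vector(single[[reg]]$fit$params)
  cur_fit <- fit_reml(pheno, ped, spec0, grid, fixed = fixed, frozen = frz,
                      start = start0, ...)
  while (cur_deg < max_cross_degree) {
    cand_spec <- make_joint(cur_deg + 1L)
    cand_fit <- tryCatch(
      fit_reml(pheno, ped, cand_spec, grid, fixed = fixed,
               frozen = frozen_production(cand_spec),
               start = c(start0, params_to_vector(cur_fit$params)[
                 intersect(names(params_to_vector(cur_fit$params)),
                           param_template(cand_spec))]), ...),
      error = function(e) NULL)
    if (is.null(cand_fit)) {
      note(trait = reg, step = paste0("cross degree ", cur_deg + 1L),
           outcome = "fit failed", p = NA_real_)
      break
    }
    test <- lrt(cur_fit, cand_fit)
    accept <- is.finite(test$p_value) && test$p_value < alpha
    note(trait = reg, step = paste0("cross degree ", cur_deg + 1L),
         outcome = if (accept) "accepted" else "rejected", p = test$p_value)
    if (!accept) break
    cur_deg <- cur_deg + 1L
    cur_fit <- cand_fit
  }
  list(spec = cur_fit$spec, single_fits = single, cross_fit = cur_fit,
       trail = do.call(rbind, trail))
}
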