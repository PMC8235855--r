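#' Residual feed intake criteria
#'
#' Two longitudinal RFI criteria are provided. The phenotypic-regression
#' model regresses feed intake on the production traits in the fixed part of
#' a single-response SAD animal model, with week-specific coefficients; the
#' resulting RFI is generally not genetically independent of the production
#' traits. The multi-SAD regression model fits all traits jointly with
#' cross-antedependence of feed intake on the production traits and derives
#' RFI* by adjusting the feed-intake effects with the genetic regression
#' coefficients, which makes RFI* genetically independent of the production
#' traits at every time point.
#'
#' @name rfi_models
NULL

#' Fit the phenotypic-regression RFI model
#'
#' Single-response SAD animal model for feed intake with the production
#' traits as week-nested fixed covariates. Every feed-intake record must
#' have all production covariates at that week: with missing production
#' phenotypes this model is not usable (interpolate first with
#' [interpolate_missing()]).
#'
#' @param pheno long phenotype table holding the regressed trait and all
#'   production traits.
#' @param ped a [pedigree()].
#' @param grid a [time_grid()].
#' @param traits trait order, regressed trait last.
#' @param spec_rfi single-trait [sad_spec()] for the RFI genetic and
#'   environmental structures (default genetic SAD11, environmental SAD12).
#' @param extra_fixed additional fixed-effect terms (character, e.g.
#'   `"batch"`), added per week-nested covariates.
#' @param ... passed to [fit_reml()].
#' @return a `sad_fit` with elements `rfi_G`, `rfi_P` (covariance matrices
#'   of the genetic and environmental RFI components) and `b_weekly` (the
#'   estimated weekly regression coefficients with SEs).
#' @export
fit_phenotypic_regression_model <- function(pheno, ped, grid,
                                            traits = c("ADG", "MBW", "BF", "FI"),
                                            spec_rfi = NULL,
                                            extra_fixed = NULL, ...) {
  reg <- utils::tail(traits, 1L)
  prod_traits <- utils::head(traits, -1L)
  fi <- pheno[pheno$trait == reg, , drop = FALSE]
  wide <- fi
  for (s in prod_traits) {
    ps <- pheno[pheno$trait == s, c("animal", "week", "value")]
    names(ps)[3L] <- s
    wide <- merge(wide, ps, by = c("animal", "week"), all.x = TRUE)
  }
  if (anyNA(wide[prod_traits])) {
    stop("missing production phenotypes at feed-intake records; ",
         "the phenotypic regression model requires complete covariates - ",
         "interpolate them first (see interpolate_missing())")
  }
  if (is.null(spec_rfi)) {
    spec_rfi <- sad_spec_single(reg, genetic = c(theta = 1, lvar = 1),
                                environmental = c(theta = 1, lvar = 2))
  }
  fml <- paste("~ 0 + wk +", paste0("wk:", prod_traits, collapse = " + "))
  if (!is.null(extra_fixed)) fml <- paste(fml, "+", paste(extra_fixed, collapse = " + "))
  fit <- fit_reml(wide, ped, spec_rfi, grid, fixed = stats::as.formula(fml), ...)
  wk <- paste0("RFI:", seq_along(grid))
  fit$rfi_G <- covariance_from_factors_of(fit, reg, "genetic")
  fit$rfi_P <- covariance_from_factors_of(fit, reg, "environmental")
  dimnames(fit$rfi_G) <- dimnames(fit$rfi_P) <- list(wk, wk)
  fit$b_weekly <- weekly_covariate_estimates(fit, prod_traits, length(grid))
  fit$model <- "phenotypic_regression"
  fit
}

covariance_from_factors_of <- function(fit, trait, component) {
  f <- single_trait_factors(fit$params, fit$grid, trait, component)
  covariance_from_factors(f$L, f$D)
}

weekly_covariate_estimates <- function(fit, prod_traits, n) {
  est <- fit$beta$estimate
  se <- sqrt(diag(fit$beta$cov))
  out <- list()
  for (s in prod_traits) {
    idx <- grep(paste0("wk([0-9]+):", s, "$"), names(est))
    if (!length(idx)) next  # covariate dropped (structurally zero)
    wk <- as.integer(sub(".*wk([0-9]+):.*", "\\1", names(est)[idx]))
    out[[s]] <- data.frame(trait = s, week = wk, estimate = unname(est[idx]),
                           se = unname(se[idx]))[order(wk), ]
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Fit the multi-SAD regression RFI model
#'
#' Joint SAD fit of all traits with cross-antedependence of the regressed
#' trait on the production traits in both the genetic and environmental
#' components. Missing production records are handled by the likelihood
#' (cells are dropped, not imputed). With `two_stage = TRUE` (default) each
#' production trait is first fitted alone and its antedependence and
#' innovation-variance parameters are frozen at those estimates in the
#' joint fit, which reduces the joint search space.
#'
#' @param pheno long phenotype table.
#' @param ped a [pedigree()].
#' @param grid a [time_grid()].
#' @param spec a multi-trait [sad_spec()] (default [default_sad_spec()]).
#' @param two_stage freeze production-trait parameters at single-trait
#'   estimates.
#' @param fixed fixed-effect formula.
#' @param ... passed to [fit_reml()].
#' @return a `sad_fit` with element `rfi_star` ([rfi_star_covariances()]
#'   output) and `model = "multi_sad"`.
#' @export
fit_multi_sad_model <- function(pheno, ped, grid, spec = default_sad_spec(),
                                two_stage = TRUE, fixed = ~ 0 + wk, ...) {
  frozen <- NULL
  if (two_stage) {
    prod_traits <- utils::head(spec$traits, -1L)
    frozen <- numeric(0)
    dots <- list(...)
    dots$hessian <- FALSE
    for (tr in prod_traits) {
      sub <- pheno[pheno$trait == tr, , drop = FALSE]
      sspec <- sad_spec_single(tr, genetic = spec$genetic[[tr]],
                               environmental = spec$environmental[[tr]],
                               scale_time = spec$scale_time)
      sfit <- do.call(fit_reml, c(list(sub, ped, sspec, grid, fixed = fixed), dots))
      frozen <- c(frozen, params_to_vector(sfit$params))
    }
  }
  fit <- fit_reml(pheno, ped, spec, grid, fixed = fixed, frozen = frozen, ...)
  fit$rfi_star <- rfi_star_covariances(fit$params, grid)
  fit$model <- "multi_sad"
  fit
}

#' Regression-coefficient trajectories
#'
#' Evaluates the genetic and environmental cross-antedependence polynomials
#' at every week (with delta-method SEs from the information matrix) and
#' extracts the covariance-implied phenotypic coefficients
#' \eqn{b_{p,j} = cov_p(s_j, FI_j) / var_p(s_j)} from \eqn{\Sigma_g +
#' \Sigma_e}.
#'
#' @param fit a multi-SAD `sad_fit`.
#' @return data.frame `trait, week, b_phenotypic, b_genetic, b_environmental,
#'   se_genetic, se_environmental`.
#' @export
regression_trajectories <- function(fit) {
  spec <- fit$spec
  grid <- fit$grid
  n <- length(grid)
  reg <- spec_regressed(spec)
  prod_traits <- names(spec$cross_genetic)
  if (is.null(prod_traits)) stop("fit has no cross-antedependence terms")
  Sg <- fit$derived$Sg
  Sp <- Sg + fit$derived$Se
  tt <- sad_time(spec, grid)
  out <- list()
  for (s in prod_traits) {
    bg <- cross_values(fit$params, s, "genetic", grid)
    be <- cross_values(fit$params, s, "environmental", grid)
    lab_s <- paste0(s, ":", seq_len(n))
    lab_f <- paste0(reg, ":", seq_len(n))
    bp <- diag(Sp[lab_s, lab_f, drop = FALSE]) / diag(Sp[lab_s, lab_s, drop = FALSE])
    seg <- poly_se(fit, paste0("bg.", s, "."), tt)
    see <- poly_se(fit, paste0("be.", s, "."), tt)
    out[[s]] <- data.frame(trait = s, week = seq_len(n), b_phenotypic = bp,
                           b_genetic = bg, b_environmental = be,
                           se_genetic = seg, se_environmental = see)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# delta-method SE of a polynomial evaluated at times tt, for coefficients
# whose omega names start with `prefix`
poly_se <- function(fit, prefix, tt) {
  if (is.null(fit$information)) return(rep(NA_real_, length(tt)))
  free <- rownames(fit$information)
  idx <- grep(paste0("^", gsub("\\.", "\\\\.", prefix), "[0-9]+$"), free)
  if (!length(idx)) return(rep(0, length(tt)))
  Vfull <- tryCatch(solve(fit$information), error = function(e) NULL)
  if (is.null(Vfull)) return(rep(NA_real_, length(tt)))
  degs <- as.integer(sub(paste0("^", gsub("\\.", "\\\\.", prefix)), "", free[idx]))
  Tm <- outer(tt, degs, `^`)
  sqrt(pmax(0, rowSums((Tm %*% Vfull[idx, idx, drop = FALSE]) * Tm)))
}

#' RFI* components by the adjustment recursions
#'
#' Given per-animal trait-by-week genetic and environmental effects
#' (BLUP predictions or simulated truth), applies the forward recursions
#' \deqn{u^*_{j} = u_{FI,j} + \theta_{uFI,j}(u^*_{j-1} - u_{FI,j-1}) -
#'   \sum_s b_{u,s j} u_{s,j}} (no lag term at the first week) and the
#' analogous residual recursion. Following the defining equations the
#' residual adjustment also uses the genetic coefficients \eqn{b_u};
#' `use_be = TRUE` switches it to the environmental coefficients, which
#' yields an RFI independent of production traits at both levels.
#'
#' @param fit a multi-SAD `sad_fit` (or [sad_params()]).
#' @param u,e matrices animals x trait:week cells (as from [blup_solve()]
#'   or [simulate_effects()]).
#' @param use_be use environmental cross coefficients in the residual
#'   adjustment.
#' @return list with matrices `u_rfi`, `e_rfi`, `rfi` (animals x week).
#' @export
compute_rfi_star <- function(fit, u, e, use_be = FALSE) {
  params <- if (inherits(fit, "sad_params")) fit else fit$params
  grid <- if (inherits(fit, "sad_params")) NULL else fit$grid
  spec <- params$spec
  reg <- spec_regressed(spec)
  n <- if (is.null(grid)) sum(startsWith(colnames(u), paste0(reg, ":"))) else length(grid)
  if (is.null(grid)) grid <- time_grid(seq_len(n))
  th_u <- theta_values(params, reg, "genetic", grid)
  th_e <- theta_values(params, reg, "environmental", grid)
  targets <- names(spec$cross_genetic)
  bu <- vapply(targets, function(s) cross_values(params, s, "genetic", grid),
               numeric(n))
  badj <- if (use_be) {
    vapply(targets, function(s) cross_values(params, s, "environmental", grid),
           numeric(n))
  } else bu
  col_of <- function(tr, j) paste0(tr, ":", j)
  recurse <- function(x, th, bmat) {
    N <- nrow(x)
    star <- matrix(0, N, n)
    for (j in seq_len(n)) {
      adj <- rep(0, N)
      for (ti in seq_along(targets)) {
        adj <- adj + bmat[j, ti] * x[, col_of(targets[ti], j)]
      }
      star[, j] <- x[, col_of(reg, j)] - adj +
        if (j > 1L) th[j] * (star[, j - 1L] - x[, col_of(reg, j - 1L)]) else 0
    }
    star
  }
  u_rfi <- recurse(u, th_u, matrix(bu, nrow = n))
  e_rfi <- recurse(e, th_e, matrix(badj, nrow = n))
  wk <- paste0("RFI:", seq_len(n))
  dimnames(u_rfi) <- list(rownames(u), wk)
  dimnames(e_rfi) <- list(rownames(e), wk)
  common <- intersect(rownames(u_rfi), rownames(e_rfi))
  list(u_rfi = u_rfi, e_rfi = e_rfi,
       rfi = u_rfi[common, , drop = FALSE] + e_rfi[common, , drop = FALSE])
}

#' Heritability profile of the RFI criterion
#'
#' Multi-SAD model: \eqn{h^2_j = G^*_{jj} / (G^*_{jj} + P^*_{FI,jj})};
#' phenotypic-regression model: \eqn{G_{jj} / (G_{jj} + P_{jj})}. SEs by the
#' delta method through the information matrix.
#'
#' @param fit a `sad_fit` from [fit_multi_sad_model()] or
#'   [fit_phenotypic_regression_model()].
#' @return data.frame `week, h2, se, model`.
#' @export
heritability_profile <- function(fit) {
  grid <- fit$grid
  n <- length(grid)
  h2_of <- function(omega_free) {
    om <- fit$omega
    om[names(omega_free)] <- omega_free
    pp <- vector_to_params(om, fit$spec)
    if (identical(fit$model, "multi_sad")) {
      rs <- rfi_star_covariances(pp, grid)
      reg <- spec_regressed(fit$spec)
      lab <- paste0(reg, ":", seq_len(n))
      g <- diag(rs$G_star)
      p <- diag(rs$P_star[lab, lab])
    } else {
      reg <- fit$spec$traits[1L]
      g <- diag(covariance_from_factors_of(fit, reg, "genetic"))
      p <- diag(covariance_from_factors_of(fit, reg, "environmental"))
    }
    g / (g + p)
  }
  x0 <- fit$omega[fit$free]
  h2 <- h2_of(x0)
  se <- rep(NA_real_, n)
  if (!is.null(fit$information)) {
    V <- tryCatch(solve(fit$information), error = function(e) NULL)
    if (!is.null(V)) {
      J <- numeric_jacobian(h2_of, x0)
      se <- sqrt(pmax(0, rowSums((J %*% V) * J)))
    }
  }
  data.frame(week = seq_len(n), h2 = h2, se = se,
             model = fit$model %||% "sad")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

numeric_jacobian <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    xi <- x
    step <- h * (1 + abs(x[i]))
    xi[i] <- x[i] + step
    J[, i] <- (f(xi) - f0) / step
  }
  J
}

#' Genetic correlation matrix from a covariance matrix
#'
#' @param G symmetric PD covariance matrix.
#' @return correlation matrix (unit diagonal).
#' @export
genetic_correlation_matrix <- function(G) {
  d <- diag(G)
  if (any(d <= 0)) stop("zero or negative diagonal entry: correlation undefined")
  stats::cov2cor(G)
}

#' Kennedy independence gap
#'
#' \eqn{(1 - h^2_P)\,cov(u_{FI,j}, u_{P,j}) - h^2_P\,cov(e_{FI,j},
#' e_{P,j})}: zero exactly when the phenotypic-regression RFI is genetically
#' independent of production trait P at week j.
#'
#' @param fit a multi-SAD `sad_fit` (or list with `Sg`, `Se` matrices and
#'   `traits`).
#' @param trait production trait name.
#' @param week week index (vectorised).
#' @return numeric vector of gaps.
#' @export
kennedy_gap <- function(fit, trait, week) {
  Sg <- if (inherits(fit, "sad_fit")) fit$derived$Sg else fit$Sg
  Se <- if (inherits(fit, "sad_fit")) fit$derived$Se else fit$Se
  traits <- if (inherits(fit, "sad_fit")) fit$spec$traits else fit$traits
  reg <- utils::tail(traits, 1L)
  vapply(week, function(j) {
    ls <- paste0(trait, ":", j)
    lf <- paste0(reg, ":", j)
    h2 <- Sg[ls, ls] / (Sg[ls, ls] + Se[ls, ls])
    (1 - h2) * Sg[lf, ls] - h2 * Se[lf, ls]
  }, numeric(1))
}
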