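#' Structured antedependence (SAD) covariance functions
#'
#' In a first-order SAD model a random effect at time \eqn{t_j} is a
#' regression on its own value at \eqn{t_{j-1}} plus an innovation:
#' \eqn{u_j = \theta_j u_{j-1} + \varepsilon_j}, \eqn{var(\varepsilon_j) =
#' \sigma^2_j}. Antedependence parameters \eqn{\theta} are polynomials of
#' time; innovation variances are exp(polynomial) so they stay positive. The
#' implied covariance has the factored inverse \eqn{\Sigma^{-1} = L' D^{-1} L}
#' with \eqn{L} unit lower triangular carrying \eqn{-\theta_j} and \eqn{D}
#' the diagonal of innovation variances. The multi-trait extension adds
#' cross-antedependence rows: the regressed trait (feed intake) at time
#' \eqn{t_j} also regresses on the contemporaneous effects of the production
#' traits with time-varying coefficients \eqn{b_{s,j}}.
#'
#' @name sad_covariance
NULL

#' Polynomial parameter function of time
#'
#' @param coefficients numeric vector, intercept first (length = degree + 1).
#' @param link `"identity"` (antedependence and cross coefficients) or
#'   `"exp"` (innovation variances).
#' @return object of class `poly_fun`.
#' @export
poly_fun <- function(coefficients, link = c("identity", "exp")) {
  link <- match.arg(link)
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1L)
  structure(list(coefficients = as.numeric(coefficients), link = link),
            class = "poly_fun")
}

#' Evaluate a polynomial parameter function
#'
#' @param f a [poly_fun()].
#' @param t numeric vector of times.
#' @return numeric vector; strictly positive when the link is `exp`.
#' @export
eval_poly <- function(f, t) {
  stopifnot(inherits(f, "poly_fun"))
  p <- length(f$coefficients)
  val <- drop(outer(t, 0:(p - 1L), `^`) %*% f$coefficients)
  if (f$link == "exp") exp(val) else val
}

#' Measurement time grid
#'
#' @param times strictly increasing numeric vector (week indices by default).
#' @return numeric vector of class `time_grid`.
#' @export
time_grid <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing and non-empty")
  }
  structure(times, class = "time_grid")
}

#' SAD model specification (polynomial degrees)
#'
#' Describes which polynomial degrees are used per trait and per component.
#' The regressed trait (last in `traits`, feed intake in the application)
#' may carry cross-antedependence terms on every earlier trait.
#'
#' @param traits character vector of trait names, the regressed trait last.
#' @param genetic,environmental named lists, one entry per trait, each a
#'   vector `c(theta = <degree>, lvar = <degree>)` giving the degree of the
#'   antedependence polynomial and of the log innovation-variance polynomial
#'   (the SAD "beta gamma" notation: `SAD11` means `theta = 1, lvar = 1`).
#' @param cross_genetic,cross_environmental named numeric vectors of
#'   polynomial degrees for the cross-antedependence coefficients of the
#'   regressed trait on each named production trait; `NULL` for none.
#' @param scale_time if `TRUE`, polynomials are evaluated on the grid mapped
#'   affinely to \[-1, 1\] (numerical conditioning); default uses raw times.
#' @return object of class `sad_spec`.
#' @export
sad_spec <- function(traits,
                     genetic,
                     environmental,
                     cross_genetic = NULL,
                     cross_environmental = NULL,
                     scale_time = FALSE) {
  traits <- as.character(traits)
  stopifnot(length(traits) >= 1L, !anyDuplicated(traits))
  check_side <- function(side, label) {
    if (!setequal(names(side), traits)) {
      stop(label, " must have one entry per trait")
    }
    for (tr in traits) {
      d <- side[[tr]]
      if (!all(c("theta", "lvar") %in% names(d)) || any(d < 0)) {
        stop(label, "$", tr, " must be c(theta = >=0, lvar = >=0)")
      }
    }
  }
  check_side(genetic, "genetic")
  check_side(environmental, "environmental")
  check_cross <- function(cr, label) {
    if (is.null(cr)) return(invisible())
    if (length(traits) < 2L) stop("cross terms require >= 2 traits")
    targets <- names(cr)
    if (!length(targets) || !all(targets %in% utils::head(traits, -1L))) {
      stop(label, " targets must be production traits (all but the last)")
    }
    if (anyDuplicated(targets) || any(cr < 0)) stop("invalid ", label)
  }
  check_cross(cross_genetic, "cross_genetic")
  check_cross(cross_environmental, "cross_environmental")
  structure(list(traits = traits,
                 genetic = lapply(genetic[traits], function(x) x[c("theta", "lvar")]),
                 environmental = lapply(environmental[traits], function(x) x[c("theta", "lvar")]),
                 cross_genetic = cross_genetic,
                 cross_environmental = cross_environmental,
                 scale_time = isTRUE(scale_time)),
            class = "sad_spec")
}

#' Convenience single-trait specification
#' @param trait trait name.
#' @param genetic,environmental `c(theta=, lvar=)` degree pairs.
#' @inheritParams sad_spec
#' @export
sad_spec_single <- function(trait, genetic, environmental, scale_time = FALSE) {
  sad_spec(trait,
           genetic = stats::setNames(list(genetic), trait),
           environmental = stats::setNames(list(environmental), trait),
           scale_time = scale_time)
}

spec_regressed <- function(spec) utils::tail(spec$traits, 1L)

spec_has_cross <- function(spec) {
  !is.null(spec$cross_genetic) || !is.null(spec$cross_environmental)
}

sad_time <- function(spec, times) {
  times <- as.numeric(times)
  if (!isTRUE(spec$scale_time) || length(times) == 1L) return(times)
  r <- range(times)
  2 * (times - r[1]) / (r[2] - r[1]) - 1
}

#' SAD parameter set conforming to a specification
#'
#' @param spec a [sad_spec()].
#' @param genetic,environmental named lists per trait with elements
#'   `theta` (coefficients, length degree+1) and `lvar` (coefficients of the
#'   log innovation variance).
#' @param cross_genetic,cross_environmental named lists of coefficient
#'   vectors for the cross-antedependence polynomials (identity link).
#' @return object of class `sad_params`.
#' @export
sad_params <- function(spec, genetic, environmental,
                       cross_genetic = NULL, cross_environmental = NULL) {
  stopifnot(inherits(spec, "sad_spec"))
  check <- function(side, degs, label) {
    for (tr in spec$traits) {
      th <- side[[tr]]$theta; lv <- side[[tr]]$lvar
      if (length(th) != degs[[tr]][["theta"]] + 1L ||
          length(lv) != degs[[tr]][["lvar"]] + 1L) {
        stop(label, "$", tr, ": coefficient lengths do not match the spec degrees")
      }
    }
  }
  check(genetic, spec$genetic, "genetic")
  check(environmental, spec$environmental, "environmental")
  check_cr <- function(cr, degs, label) {
    if (is.null(degs)) {
      if (!is.null(cr) && length(cr)) stop(label, " given but spec has none")
      return(invisible())
    }
    for (tr in names(degs)) {
      if (length(cr[[tr]]) != degs[[tr]] + 1L) {
        stop(label, "$", tr, ": coefficient length does not match spec degree")
      }
    }
  }
  check_cr(cross_genetic, spec$cross_genetic, "cross_genetic")
  check_cr(cross_environmental, spec$cross_environmental, "cross_environmental")
  structure(list(spec = spec, genetic = genetic, environmental = environmental,
                 cross_genetic = cross_genetic,
                 cross_environmental = cross_environmental),
            class = "sad_params")
}

param_side <- function(params, component) {
  switch(component, genetic = params$genetic, environmental = params$environmental,
         stop("component must be 'genetic' or 'environmental'"))
}

cross_side <- function(params, component) {
  switch(component, genetic = params$cross_genetic,
         environmental = params$cross_environmental)
}

theta_values <- function(params, trait, component, grid) {
  tt <- sad_time(params$spec, grid)
  eval_poly(poly_fun(param_side(params, component)[[trait]]$theta), tt)
}

innovation_variances <- function(params, trait, component, grid) {
  tt <- sad_time(params$spec, grid)
  eval_poly(poly_fun(param_side(params, component)[[trait]]$lvar, link = "exp"), tt)
}

cross_values <- function(params, target, component, grid) {
  cr <- cross_side(params, component)
  if (is.null(cr) || is.null(cr[[target]])) return(rep(0, length(grid)))
  eval_poly(poly_fun(cr[[target]]), sad_time(params$spec, grid))
}

#' Single-trait SAD factors L and D
#'
#' \eqn{L} is unit lower triangular with \eqn{-\theta_j} on the first
#' subdiagonal (row \eqn{j = 2..n}); \eqn{D} is the diagonal of innovation
#' variances. The first time point has no antedependence term, so its
#' innovation variance is the full variance there.
#'
#' @param params a [sad_params()].
#' @param grid a [time_grid()].
#' @param trait trait name.
#' @param component `"genetic"` or `"environmental"`.
#' @return list with matrices `L` and `D`.
#' @export
single_trait_factors <- function(params, grid, trait,
                                 component = c("genetic", "environmental")) {
  component <- match.arg(component)
  n <- length(grid)
  th <- theta_values(params, trait, component, grid)
  v <- innovation_variances(params, trait, component, grid)
  L <- diag(n)
  if (n > 1L) L[cbind(2:n, 1:(n - 1L))] <- -th[2:n]
  list(L = L, D = diag(v, n))
}

#' Covariance matrix from SAD factors
#'
#' Returns \eqn{\Sigma = L^{-1} D L^{-T}}, i.e. the matrix whose inverse is
#' \eqn{L' D^{-1} L}, computed by triangular solves.
#'
#' @param L unit lower triangular matrix.
#' @param D diagonal matrix (or vector of its diagonal) with positive entries.
#' @return symmetric positive definite matrix.
#' @export
covariance_from_factors <- function(L, D) {
  d <- if (is.matrix(D)) diag(D) else as.numeric(D)
  if (any(d <= 0)) stop("innovation variances must be strictly positive")
  Linv <- backsolve(L, diag(nrow(L)), upper.tri = FALSE)
  Sigma <- Linv %*% (d * t(Linv))
  (Sigma + t(Sigma)) / 2
}

cell_labels <- function(traits, grid) {
  as.vector(vapply(traits, function(tr) paste0(tr, ":", seq_along(grid)),
                   character(length(grid))))
}

#' Joint multi-trait SAD factors
#'
#' Builds the unit-lower-triangular regression operator and innovation
#' diagonal of the stacked trait-by-time random effects (trait-major order,
#' regressed trait last). Production traits carry only within-trait
#' antedependence and are mutually independent; the regressed trait's rows
#' additionally regress on the contemporaneous production-trait effects.
#'
#' @inheritParams single_trait_factors
#' @return list with `L`, `D` ((Tn) x (Tn)) and `labels`.
#' @export
joint_factors <- function(params, grid, component = c("genetic", "environmental")) {
  component <- match.arg(component)
  spec <- params$spec
  n <- length(grid)
  traits <- spec$traits
  Tt <- length(traits)
  N <- Tt * n
  L <- diag(N)
  d <- numeric(N)
  block <- function(tr) (match(tr, traits) - 1L) * n
  for (tr in traits) {
    off <- block(tr)
    th <- theta_values(params, tr, component, grid)
    d[off + seq_len(n)] <- innovation_variances(params, tr, component, grid)
    if (n > 1L) L[cbind(off + 2:n, off + 1:(n - 1L))] <- -th[2:n]
  }
  reg <- spec_regressed(spec)
  cr_deg <- switch(component, genetic = spec$cross_genetic,
                   environmental = spec$cross_environmental)
  if (!is.null(cr_deg)) {
    offFI <- block(reg)
    for (s in names(cr_deg)) {
      b <- cross_values(params, s, component, grid)
      L[cbind(offFI + seq_len(n), block(s) + seq_len(n))] <- -b
    }
  }
  list(L = L, D = diag(d, N), labels = cell_labels(traits, grid))
}

#' Joint multi-trait SAD covariance matrix
#'
#' Covariance of the stacked trait-by-time random effects implied by the SAD
#' recursions (within-trait antedependence plus cross-antedependence of the
#' regressed trait), in trait-major order.
#'
#' @inheritParams single_trait_factors
#' @return symmetric PD matrix with `trait:week` dimnames.
#' @export
multi_trait_covariance <- function(params, grid,
                                   component = c("genetic", "environmental")) {
  component <- match.arg(component)
  f <- joint_factors(params, grid, component)
  Sigma <- covariance_from_factors(f$L, f$D)
  dimnames(Sigma) <- list(f$labels, f$labels)
  Sigma
}

#' Regression operator B mapping joint environmental effects to RFI* space
#'
#' \eqn{B} is block lower triangular with identity diagonal blocks; the
#' regressed-trait row blocks \eqn{b_{s/FI}} have entries (row \eqn{j},
#' column \eqn{m \le j}) equal to
#' \eqn{-(\prod_{k=m+1}^{j} \theta_{eFI,k}) \, b_{u,s m}} (empty product = 1
#' on the diagonal), which is the unrolled form of the e* adjustment
#' recursion. By default the genetic cross coefficients \eqn{b_u} are used,
#' exactly as in the defining recursions; `use_be = TRUE` substitutes the
#' environmental coefficients.
#'
#' @inheritParams single_trait_factors
#' @param use_be use environmental cross coefficients instead of genetic.
#' @return (Tn) x (Tn) matrix with `trait:week` dimnames.
#' @export
build_B <- function(params, grid, use_be = FALSE) {
  spec <- params$spec
  n <- length(grid)
  traits <- spec$traits
  reg <- spec_regressed(spec)
  N <- length(traits) * n
  B <- diag(N)
  labels <- cell_labels(traits, grid)
  dimnames(B) <- list(labels, labels)
  cr_deg <- if (use_be) spec$cross_environmental else spec$cross_genetic
  if (is.null(cr_deg)) return(B)
  th_e <- theta_values(params, reg, "environmental", grid)
  # cumulative products of theta_eFI over k = m+1 .. j
  cp <- cumprod(c(1, th_e[-1L]))  # cp[j] = prod_{k<=j} theta_k (theta_1 unused)
  offFI <- (match(reg, traits) - 1L) * n
  for (s in names(cr_deg)) {
    b <- cross_values(params, s, if (use_be) "environmental" else "genetic", grid)
    offs <- (match(s, traits) - 1L) * n
    for (j in seq_len(n)) {
      m <- seq_len(j)
      B[offFI + j, offs + m] <- -(cp[j] / cp[m]) * b[m]
    }
  }
  B
}

#' Covariance matrices of the multi-SAD residual feed intake criterion
#'
#' The genetic covariance \eqn{G^*} of RFI* is the SAD covariance built from
#' the regressed trait's genetic antedependence parameters and genetic
#' innovation variances only (cross-antedependence excluded): substituting
#' the feed-intake recursion into the RFI* recursion leaves a pure
#' first-order antedependence process driven by the feed-intake genetic
#' innovations, so RFI* is genetically independent of the production traits
#' at all time points. The environmental covariance of RFI* and production
#' traits is \eqn{P^* = B P_T B'} with \eqn{P_T} the joint environmental
#' covariance.
#'
#' @inheritParams build_B
#' @return list with `G_star` (n x n), `P_T`, `B`, `P_star` ((Tn) x (Tn)),
#'   the factors `L_star`, `D_star`, and the trait/grid layout.
#' @export
rfi_star_covariances <- function(params, grid, use_be = FALSE) {
  spec <- params$spec
  reg <- spec_regressed(spec)
  f <- single_trait_factors(params, grid, reg, "genetic")
  G_star <- covariance_from_factors(f$L, f$D)
  wk <- paste0("RFI:", seq_along(grid))
  dimnames(G_star) <- list(wk, wk)
  P_T <- multi_trait_covariance(params, grid, "environmental")
  B <- build_B(params, grid, use_be = use_be)
  P_star <- B %*% P_T %*% t(B)
  P_star <- (P_star + t(P_star)) / 2
  dimnames(P_star) <- dimnames(P_T)
  list(G_star = G_star, P_T = P_T, B = B, P_star = P_star,
       L_star = f$L, D_star = f$D, traits = spec$traits, grid = as.numeric(grid))
}

## ---- parameter vector (omega) flattening ----

param_template <- function(spec) {
  nm <- character(0)
  for (comp in c("genetic", "environmental")) {
    tag <- if (comp == "genetic") "g" else "e"
    for (tr in spec$traits) {
      degs <- spec[[comp]][[tr]]
      nm <- c(nm,
              paste0(tag, ".", tr, ".theta.", 0:degs[["theta"]]),
              paste0(tag, ".", tr, ".lvar.", 0:degs[["lvar"]]))
    }
  }
  for (comp in c("genetic", "environmental")) {
    cr <- spec[[paste0("cross_", comp)]]
    tag <- if (comp == "genetic") "bg" else "be"
    for (s in names(cr)) nm <- c(nm, paste0(tag, ".", s, ".", 0:cr[[s]]))
  }
  nm
}

#' Flatten SAD parameters into a named vector
#' @param params a [sad_params()].
#' @return named numeric vector (the REML parameter vector omega).
#' @export
params_to_vector <- function(params) {
  spec <- params$spec
  out <- numeric(0)
  for (comp in c("genetic", "environmental")) {
    tag <- if (comp == "genetic") "g" else "e"
    side <- param_side(params, comp)
    for (tr in spec$traits) {
      th <- side[[tr]]$theta; lv <- side[[tr]]$lvar
      v <- c(th, lv)
      names(v) <- c(paste0(tag, ".", tr, ".theta.", seq_along(th) - 1L),
                    paste0(tag, ".", tr, ".lvar.", seq_along(lv) - 1L))
      out <- c(out, v)
    }
  }
  for (comp in c("genetic", "environmental")) {
    cr <- cross_side(params, comp)
    tag <- if (comp == "genetic") "bg" else "be"
    for (s in names(cr)) {
      v <- cr[[s]]
      names(v) <- paste0(tag, ".", s, ".", seq_along(v) - 1L)
      out <- c(out, v)
    }
  }
  out[param_template(spec)]
}

#' Rebuild SAD parameters from a named vector
#' @param omega named vector as produced by [params_to_vector()].
#' @param spec the matching [sad_spec()].
#' @return a [sad_params()].
#' @export
vector_to_params <- function(omega, spec) {
  nm <- param_template(spec)
  if (!all(nm %in% names(omega))) stop("omega does not match the spec layout")
  omega <- omega[nm]
  side <- function(tag, comp) {
    out <- list()
    for (tr in spec$traits) {
      degs <- spec[[comp]][[tr]]
      out[[tr]] <- list(
        theta = unname(omega[paste0(tag, ".", tr, ".theta.", 0:degs[["theta"]])]),
        lvar = unname(omega[paste0(tag, ".", tr, ".lvar.", 0:degs[["lvar"]])]))
    }
    out
  }
  cross <- function(tag, degs) {
    if (is.null(degs)) return(NULL)
    out <- list()
    for (s in names(degs)) out[[s]] <- unname(omega[paste0(tag, ".", s, ".", 0:degs[[s]])])
    out
  }
  sad_params(spec,
             genetic = side("g", "genetic"),
             environmental = side("e", "environmental"),
             cross_genetic = cross("bg", spec$cross_genetic),
             cross_environmental = cross("be", spec$cross_environmental))
}
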