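kennedy_params <- function(lambda = 1 / 3, b = 0.8, theta = 0) {
  # proportional genetic/environmental structures: the independence
  # condition holds identically at every week
  sp <- sad_spec(c("ADG", "FI"),
                 genetic = list(ADG = c(theta = 0, lvar = 0), FI = c(theta = 0, lvar = 0)),
                 environmental = list(ADG = c(theta = 0, lvar = 0), FI = c(theta = 0, lvar = 0)),
                 cross_genetic = c(ADG = 0), cross_environmental = c(ADG = 0))
  sad_params(sp,
             genetic = list(ADG = list(theta = theta, lvar = log(lambda * 90)),
                            FI = list(theta = theta, lvar = log(lambda * 300))),
             environmental = list(ADG = list(theta = theta, lvar = log(90)),
                                  FI = list(theta = theta, lvar = log(300))),
             cross_genetic = list(ADG = b),
             cross_environmental = list(ADG = b))
}

test_that("phenotypic regression model demands complete production covariates", {
  grid <- time_grid(1:3)
  cfg <- sim_config(n_founders = 12, generations = 1,
                    offspring_per_generation = 20, n_sires = 4, n_dams = 6,
                    grid = grid, seed = 2)
  sim <- simulate_dataset(cfg, complete = TRUE)
  ph <- sim$pheno
  drop_row <- which(ph$trait == "MBW")[1]
  ph2 <- ph[-drop_row, ]
  expect_error(fit_phenotypic_regression_model(ph2, sim$ped, grid),
               "interpolate")
})

test_that("zero production covariates reduce the model to a plain SAD fit", {
  grid <- time_grid(1:3)
  cfg <- sim_config(n_founders = 14, generations = 1,
                    offspring_per_generation = 30, n_sires = 4, n_dams = 7,
                    grid = grid, seed = 4)
  sim <- simulate_dataset(cfg, complete = TRUE)
  ph <- sim$pheno
  ph$value[ph$trait != "FI"] <- 0
  spec1 <- sad_spec_single("FI", c(theta = 0, lvar = 0), c(theta = 0, lvar = 0))
  fitP <- fit_phenotypic_regression_model(ph, sim$ped, grid, spec_rfi = spec1,
                                          hessian = FALSE)
  fit0 <- fit_reml(ph[ph$trait == "FI", ], sim$ped, spec1, grid, hessian = FALSE)
  expect_equal(fitP$loglik, fit0$loglik, tolerance = 1e-6)
})

test_that("weekly regression coefficients recover a pure covariate effect", {
  # FI generated as exactly b * ADG + noise, no genetic part in FI
  set.seed(12)
  grid <- time_grid(1:4)
  # related animals (half-sib families) so genetic variance is identifiable
  nf <- 30
  ped <- simulate_pedigree(sim_config(n_founders = 40, generations = 1,
                                      offspring_per_generation = 210,
                                      n_sires = 12, n_dams = 20, seed = 7))
  keep <- ped$animal[attr(ped, "generation") == 1]
  n <- length(keep)
  adg <- matrix(rnorm(n * 4, 0, 3), n, 4)
  b_true <- 1.2
  fi <- 100 + b_true * adg + matrix(rnorm(n * 4, 0, 1), n, 4)
  ph <- rbind(
    data.frame(animal = rep(keep, each = 4), week = rep(1:4, n),
               trait = "ADG", value = as.vector(t(adg)) + 50),
    data.frame(animal = rep(keep, each = 4), week = rep(1:4, n),
               trait = "FI", value = as.vector(t(fi))))
  fit <- fit_phenotypic_regression_model(ph, ped, grid, traits = c("ADG", "FI"),
                                         spec_rfi = sad_spec_single(
                                           "FI", c(theta = 0, lvar = 0),
                                           c(theta = 0, lvar = 0)),
                                         hessian = FALSE)
  expect_true(all(abs(fit$b_weekly$estimate - b_true) < 3 * fit$b_weekly$se))
  # genetic variance pushed to the boundary (far below the residual variance)
  g1 <- fit$rfi_G[1, 1]; p1 <- fit$rfi_P[1, 1]
  expect_lt(g1, 0.25 * p1)
})

test_that("regression trajectories evaluate the fitted polynomials with SEs", {
  grid <- time_grid(1:10)
  pp <- default_sad_params()
  fit <- structure(list(spec = pp$spec, grid = grid, params = pp,
                        omega = params_to_vector(pp),
                        free = names(params_to_vector(pp)),
                        information = diag(length(params_to_vector(pp))),
                        derived = list(
                          Sg = multi_trait_covariance(pp, grid, "genetic"),
                          Se = multi_trait_covariance(pp, grid, "environmental")),
                        model = "multi_sad"),
                   class = "sad_fit")
  tr <- regression_trajectories(fit)
  adg <- tr[tr$trait == "ADG", ]
  expect_equal(adg$b_genetic[1], 1.13)    # 1.19 - 0.06 * 1
  expect_equal(adg$b_genetic[10], 0.59)   # 1.19 - 0.06 * 10
  expect_true(all(is.finite(adg$se_genetic)))
  # zero cross coefficients give identically zero trajectories
  pp0 <- pp
  pp0$cross_genetic <- lapply(pp0$cross_genetic, function(x) x * 0)
  pp0$cross_environmental <- lapply(pp0$cross_environmental, function(x) x * 0)
  fit0 <- fit; fit0$params <- pp0; fit0$information <- NULL
  tr0 <- regression_trajectories(fit0)
  expect_true(all(tr0$b_genetic == 0) && all(tr0$b_environmental == 0))
  # with no antedependence in the regressed trait the covariance-implied
  # genetic ratio equals the polynomial exactly
  ppf <- pp
  ppf$genetic$FI$theta <- c(0, 0)
  Sgf <- multi_trait_covariance(ppf, grid, "genetic")
  ratio <- vapply(1:10, function(j) {
    Sgf[paste0("ADG:", j), paste0("FI:", j)] / Sgf[paste0("ADG:", j), paste0("ADG:", j)]
  }, numeric(1))
  expect_equal(ratio, longsad:::cross_values(ppf, "ADG", "genetic", grid),
               tolerance = 1e-10)
})

test_that("RFI* recursion base case and degenerate reductions hold", {
  grid <- time_grid(1:3)
  set.seed(3)
  pp <- random_multisad_params()
  labels <- longsad:::cell_labels(pp$spec$traits, grid)
  u <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(paste0("an", 1:5), labels))
  st <- compute_rfi_star(pp, u, u * 0)
  bu <- sapply(c("ADG", "MBW", "BF"),
               function(s) longsad:::cross_values(pp, s, "genetic", grid)[1])
  manual1 <- u[, "FI:1"] - bu["ADG"] * u[, "ADG:1"] - bu["MBW"] * u[, "MBW:1"] -
    bu["BF"] * u[, "BF:1"]
  expect_equal(unname(st$u_rfi[, 1]), unname(manual1))
  # all cross terms zero: u*_RFI is exactly u_FI
  pp0 <- pp
  pp0$cross_genetic <- lapply(pp0$cross_genetic, function(x) x * 0)
  st0 <- compute_rfi_star(pp0, u, u * 0)
  expect_equal(unname(st0$u_rfi), unname(u[, paste0("FI:", 1:3)]))
  # linearity in the input effects
  st2 <- compute_rfi_star(pp, 2 * u, u * 0)
  expect_equal(st2$u_rfi, 2 * st$u_rfi, tolerance = 1e-12)
  # rfi = u + e decomposition is exact
  e <- matrix(rnorm(5 * 12), 5, 12, dimnames = dimnames(u))
  st3 <- compute_rfi_star(pp, u, e)
  expect_equal(st3$rfi, st3$u_rfi + st3$e_rfi)
})

test_that("the implied linear operator of RFI* reproduces G*", {
  grid <- time_grid(1:4)
  set.seed(6)
  pp <- random_multisad_params()
  labels <- longsad:::cell_labels(pp$spec$traits, grid)
  q <- length(labels)
  # extract the linear map by feeding unit vectors through the recursion
  Mop <- matrix(0, 4, q)
  for (k in seq_len(q)) {
    uk <- matrix(0, 1, q, dimnames = list("a", labels))
    uk[1, k] <- 1
    Mop[, k] <- compute_rfi_star(pp, uk, uk * 0)$u_rfi[1, ]
  }
  Sg <- multi_trait_covariance(pp, grid, "genetic")
  G_implied <- Mop %*% Sg %*% t(Mop)
  rs <- rfi_star_covariances(pp, grid)
  expect_equal(G_implied, unname(rs$G_star), tolerance = 1e-8)
  # and the implied covariance with production effects is exactly zero
  cross_block <- Mop %*% Sg[, 1:12]
  expect_lt(max(abs(cross_block)), 1e-8)
})

test_that("heritability profiles follow the variance ratios", {
  grid <- time_grid(1:10)
  pp <- default_sad_params()
  fit <- structure(list(spec = pp$spec, grid = grid, params = pp,
                        omega = params_to_vector(pp),
                        free = names(params_to_vector(pp)),
                        information = NULL,
                        derived = list(
                          Sg = multi_trait_covariance(pp, grid, "genetic"),
                          Se = multi_trait_covariance(pp, grid, "environmental")),
                        model = "multi_sad"),
                   class = "sad_fit")
  h2 <- heritability_profile(fit)
  rs <- rfi_star_covariances(pp, grid)
  fi <- paste0("FI:", 1:10)
  expect_equal(h2$h2, unname(diag(rs$G_star) /
                               (diag(rs$G_star) + diag(rs$P_star[fi, fi]))))
  expect_true(all(h2$h2 > 0 & h2$h2 < 1))
  # equal variances give one half
  expect_equal(unname(0.5), 4 / (4 + 4) * 1)
})

test_that("genetic correlation matrix normalises and validates", {
  expect_equal(genetic_correlation_matrix(diag(c(2, 3))), diag(2))
  G <- matrix(c(1, 0.5, 0.5, 4), 2)
  expect_equal(genetic_correlation_matrix(G)[1, 2], 0.25)
  expect_error(genetic_correlation_matrix(matrix(c(0, 0, 0, 1), 2)),
               "undefined")
  set.seed(1)
  L <- matrix(rnorm(16), 4)
  R <- genetic_correlation_matrix(crossprod(L) + diag(4))
  expect_true(all(R >= -1 & R <= 1))
  expect_equal(diag(R), rep(1, 4))
})

test_that("the independence gap is zero under proportional structures", {
  grid <- time_grid(1:10)
  pp <- kennedy_params(theta = 0.5)
  fake <- list(Sg = multi_trait_covariance(pp, grid, "genetic"),
               Se = multi_trait_covariance(pp, grid, "environmental"),
               traits = c("ADG", "FI"))
  expect_lt(max(abs(kennedy_gap(fake, "ADG", 1:10))), 1e-10)
  # hand-computed asymmetric case: h2 = 0.25, cov_u = cov_e
  sp <- kennedy_params()$spec
  pp2 <- sad_params(sp,
                    genetic = list(ADG = list(theta = 0, lvar = log(1)),
                                   FI = list(theta = 0, lvar = 0)),
                    environmental = list(ADG = list(theta = 0, lvar = log(3)),
                                         FI = list(theta = 0, lvar = 0)),
                    cross_genetic = list(ADG = 1),
                    cross_environmental = list(ADG = 1 / 3))
  fake2 <- list(Sg = multi_trait_covariance(pp2, grid, "genetic"),
                Se = multi_trait_covariance(pp2, grid, "environmental"),
                traits = c("ADG", "FI"))
  # cov_u = 1, cov_e = 1, h2 = 0.25 -> gap = 0.75 - 0.25 = 0.5
  expect_equal(kennedy_gap(fake2, "ADG", 1), 0.5)
})

test_that("multi-SAD fit tolerates missing production records", {
  grid <- time_grid(1:4)
  sp <- sad_spec(c("ADG", "FI"),
                 genetic = list(ADG = c(theta = 0, lvar = 0), FI = c(theta = 1, lvar = 0)),
                 environmental = list(ADG = c(theta = 0, lvar = 0), FI = c(theta = 0, lvar = 0)),
                 cross_genetic = c(ADG = 0), cross_environmental = c(ADG = 0))
  pp <- sad_params(sp,
                   genetic = list(ADG = list(theta = 0.4, lvar = log(20)),
                                  FI = list(theta = c(0.2, 0.05), lvar = log(40))),
                   environmental = list(ADG = list(theta = 0.3, lvar = log(40)),
                                        FI = list(theta = 0.3, lvar = log(80))),
                   cross_genetic = list(ADG = 0.9),
                   cross_environmental = list(ADG = 0.6))
  cfg <- sim_config(n_founders = 40, generations = 2,
                    offspring_per_generation = 100, grid = grid, params = pp,
                    means = rbind(ADG = rep(80, 4), FI = rep(200, 4)),
                    missingness = rbind(ADG = rep(0.3, 4), FI = rep(0, 4)),
                    seed = 13)
  sim <- simulate_dataset(cfg)
  expect_lt(nrow(sim$pheno), nrow(sim$pheno_complete))
  fit <- fit_multi_sad_model(sim$pheno, sim$ped, grid, spec = sp,
                             two_stage = FALSE, hessian = TRUE, maxit = 300,
                             start = params_to_vector(pp) + 0.1)
  expect_true(fit$converged)
  se <- sqrt(diag(solve(fit$information)))
  dev <- abs(fit$omega[fit$free] - params_to_vector(pp)[fit$free]) / se
  expect_lt(max(dev), 4)
})
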