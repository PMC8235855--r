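two_trait_spec <- function() {
  sad_spec(c("P", "FI"),
           genetic = list(P = c(theta = 0, lvar = 0), FI = c(theta = 1, lvar = 0)),
           environmental = list(P = c(theta = 0, lvar = 1), FI = c(theta = 0, lvar = 0)),
           cross_genetic = c(P = 1), cross_environmental = c(P = 0))
}

random_omega <- function(spec) {
  nm <- longsad:::param_template(spec)
  stats::setNames(stats::runif(length(nm), -0.5, 0.5), nm)
}

test_that("design construction builds trait blocks and catches rank problems", {
  ped <- pedigree(c("a", "b"), c(NA, NA), c(NA, NA))
  grid <- time_grid(1:2)
  ph <- toy_pheno(ped, grid, "FI")
  d <- build_design(ph, grid, "FI", fixed = ~1)
  expect_equal(dim(d$X), c(4L, 1L))
  expect_true(all(d$X == 1))
  # week factor, treatment coding: intercept + 2 contrast columns
  grid3 <- time_grid(1:3)
  ph3 <- toy_pheno(ped, grid3, "FI")
  d3 <- build_design(ph3, grid3, "FI", fixed = ~wk)
  expect_equal(ncol(d3$X), 3L)
  # confounded factors named in the error
  ph3$pen <- "p1"
  ph3$batch <- ifelse(ph3$animal == "a", "b1", "b2")
  ph3$pen <- ph3$batch
  expect_error(build_design(ph3, grid3, "FI", fixed = ~ 0 + wk + batch + pen),
               "pen|batch")
  expect_error(build_design(ph3, grid3, "FI", fixed = ~ 0 + wk + ghost),
               "ghost")
  ph_na <- ph3; ph_na$value[1] <- NA
  expect_error(build_design(ph_na, grid3, "FI", fixed = ~wk), "NA")
})

test_that("restricted likelihood matches a dense first-principles criterion", {
  set.seed(7)
  ped <- pedigree(c("a", "b", "c", "d", "e"), c(NA, NA, "a", "a", NA),
                  c(NA, NA, "b", "b", NA))
  grid <- time_grid(1:2)
  sp <- two_trait_spec()
  ph <- toy_pheno(ped, grid, c("P", "FI"), means = 10)
  setupE <- reml_setup(ph, ped, sp, grid, method = "eigen")
  setupM <- reml_setup(ph, ped, sp, grid, method = "mme")
  for (i in 1:25) {
    om <- random_omega(sp)
    ld <- dense_reml_oracle(om, ph, ped, sp, grid)
    expect_equal(restricted_loglik(om, setupE), ld, tolerance = 1e-8)
    expect_equal(restricted_loglik(om, setupM), ld, tolerance = 1e-8)
  }
})

test_that("restricted likelihood handles missing cells by marginalisation", {
  set.seed(8)
  ped <- pedigree(c("a", "b", "c", "d", "e"), c(NA, NA, "a", "a", NA),
                  c(NA, NA, "b", "b", NA))
  grid <- time_grid(1:2)
  sp <- two_trait_spec()
  ph <- toy_pheno(ped, grid, c("P", "FI"), means = 10)
  ph <- ph[-c(2, 7, 13, 19), ]
  setup <- reml_setup(ph, ped, sp, grid, method = "mme")
  for (i in 1:10) {
    om <- random_omega(sp)
    expect_equal(restricted_loglik(om, setup),
                 dense_reml_oracle(om, ph, ped, sp, grid), tolerance = 1e-8)
  }
  expect_error(reml_setup(ph, ped, sp, grid, method = "eigen"), "complete")
})

test_that("REML value is invariant to translation in the fixed-effect span and to contrast coding", {
  set.seed(9)
  ped <- pedigree(letters[1:6], rep(NA, 6), rep(NA, 6))
  grid <- time_grid(1:3)
  sp <- sad_spec_single("FI", c(theta = 1, lvar = 1), c(theta = 0, lvar = 0))
  ph <- toy_pheno(ped, grid, "FI")
  om <- random_omega(sp)
  l0 <- restricted_loglik(om, ph, ped, sp, grid)
  ph2 <- ph
  ph2$value <- ph2$value + 5  # constant lies in the span of the week means
  expect_equal(restricted_loglik(om, ph2, ped, sp, grid), l0, tolerance = 1e-8)
  l_treat <- restricted_loglik(om, ph, ped, sp, grid, fixed = ~wk)
  expect_equal(l_treat, l0, tolerance = 1e-8)
})

test_that("iid degenerate case recovers the closed-form location-model REML", {
  # single trait, single week: V = (s_g + s_e) I for unrelated animals
  set.seed(10)
  n <- 12
  ped <- pedigree(sprintf("a%02d", 1:n), rep(NA, n), rep(NA, n))
  grid <- time_grid(1)
  sp <- sad_spec_single("FI", c(theta = 0, lvar = 0), c(theta = 0, lvar = 0))
  ph <- toy_pheno(ped, grid, "FI", means = 3, noise_sd = 2)
  om <- c(g.FI.theta.0 = 0.3, g.FI.lvar.0 = log(1.5),
          e.FI.theta.0 = -0.2, e.FI.lvar.0 = log(2.5))
  s2 <- 1.5 + 2.5
  y <- ph$value
  closed <- -0.5 * ((n - 1) * log(2 * pi * s2) + log(n) +
                      sum((y - mean(y))^2) / s2)
  expect_equal(restricted_loglik(om, ph, ped, sp, grid), closed,
               tolerance = 1e-8)
})

test_that("REML recovers generating parameters and the optimum is a maximum", {
  grid <- time_grid(1:10)
  sp <- sad_spec_single("FI", c(theta = 0, lvar = 0), c(theta = 0, lvar = 0))
  truth <- sad_params(sp, genetic = list(FI = list(theta = 0.5, lvar = 0)),
                      environmental = list(FI = list(theta = 0.3, lvar = log(2))))
  cfg <- sim_config(n_founders = 60, generations = 2,
                    offspring_per_generation = 150, grid = grid, params = truth,
                    means = matrix(100, 1, 10, dimnames = list("FI", NULL)),
                    missingness = matrix(0, 1, 10, dimnames = list("FI", NULL)),
                    seed = 11)
  sim <- simulate_dataset(cfg, complete = TRUE)
  fit <- fit_reml(sim$pheno, sim$ped, sp, grid)
  expect_true(fit$converged)
  se <- sqrt(diag(solve(fit$information)))
  expect_true(all(abs(fit$omega - params_to_vector(truth)) < 4 * se))
  # restarting from the truth cannot beat the found maximum by more than noise
  fit2 <- fit_reml(sim$pheno, sim$ped, sp, grid,
                   start = params_to_vector(truth), hessian = FALSE)
  expect_gte(fit$loglik + 1e-4, fit2$loglik - 1e-4)
  # freezing parameters pins them exactly
  frz <- c(g.FI.theta.0 = 0.5)
  fit3 <- fit_reml(sim$pheno, sim$ped, sp, grid, frozen = frz, hessian = FALSE)
  expect_equal(unname(fit3$omega["g.FI.theta.0"]), 0.5)
  expect_false("g.FI.theta.0" %in% fit3$free)
  expect_error(fit_reml(sim$pheno, sim$ped, sp, grid,
                        frozen = c(nonsense.par = 1)), "frozen")
})

test_that("likelihood ratio test behaves on identical and nested fits", {
  grid <- time_grid(1:4)
  sp0 <- sad_spec_single("FI", c(theta = 0, lvar = 0), c(theta = 0, lvar = 0))
  sp1 <- sad_spec_single("FI", c(theta = 1, lvar = 0), c(theta = 0, lvar = 0))
  cfg <- sim_config(n_founders = 30, generations = 1,
                    offspring_per_generation = 60, n_sires = 10, n_dams = 15,
                    grid = grid,
                    params = sad_params(sp0,
                                        genetic = list(FI = list(theta = 0.4, lvar = 0)),
                                        environmental = list(FI = list(theta = 0.2, lvar = 0))),
                    means = matrix(0, 1, 4, dimnames = list("FI", NULL)),
                    missingness = matrix(0, 1, 4, dimnames = list("FI", NULL)),
                    seed = 5)
  sim <- simulate_dataset(cfg, complete = TRUE)
  f0 <- fit_reml(sim$pheno, sim$ped, sp0, grid, hessian = FALSE)
  # identical fits: zero statistic, p = 1
  t0 <- lrt(f0, f0)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  f1 <- fit_reml(sim$pheno, sim$ped, sp1, grid, hessian = FALSE)
  t1 <- lrt(f0, f1)
  expect_equal(t1$df, 1L)
  expect_gte(t1$statistic, 0)
  expect_true(t1$p_value >= 0 && t1$p_value <= 1)
  # reversed order is rejected
  expect_error(lrt(f1, f0), "not nested")
  # boundary mixture halves the naive p-value for df = 1
  tm <- lrt(f0, f1, boundary = "mixture")
  expect_equal(tm$p_value, 0.5 * t1$p_value + 0.5 * (t1$statistic == 0))
})

test_that("BLUP shrinks to zero without genetic variance and averages parents", {
  grid <- time_grid(1:2)
  sp <- sad_spec_single("FI", c(theta = 0, lvar = 0), c(theta = 0, lvar = 0))
  ped <- pedigree(c("s", "d", "o", "x", "y"), c(NA, NA, "s", NA, NA),
                  c(NA, NA, "d", NA, NA))
  ph <- toy_pheno(ped, grid, "FI", means = 5, seed = 3)
  ph <- ph[ph$animal != "o", ]  # offspring unphenotyped
  # near-zero genetic variance: all TEBV collapse to ~0
  frz_all <- c(g.FI.theta.0 = 0, g.FI.lvar.0 = -18, e.FI.theta.0 = 0.2)
  fit0 <- fit_reml(ph, ped, sp, grid, frozen = frz_all, hessian = FALSE,
                   method = "mme")
  bl0 <- blup_solve(fit0)
  expect_lt(max(abs(bl0$tebv)), 1e-4)
  # moderate genetic variance: unphenotyped offspring of two phenotyped
  # parents (no descendants) gets the parent-average TEBV
  frz <- c(g.FI.theta.0 = 0.3, g.FI.lvar.0 = 0, e.FI.theta.0 = 0.2)
  fit <- fit_reml(ph, ped, sp, grid, frozen = frz, hessian = FALSE,
                  method = "mme")
  bl <- blup_solve(fit)
  expect_equal(bl$tebv["o", ], (bl$tebv["s", ] + bl$tebv["d", ]) / 2,
               tolerance = 1e-6)
  # residual effects reproduce the data decomposition at observed cells
  yfit <- fit$beta$estimate
  rec <- ph[ph$animal == "s" & ph$week == 1, ]
  expect_equal(unname(bl$e["s", "FI:1"]),
               rec$value - unname(yfit["FI.wk1"]) - unname(bl$tebv["s", "FI:1"]),
               tolerance = 1e-8)
})

test_that("eigen-path and MME BLUPs agree on complete data", {
  grid <- time_grid(1:3)
  sp <- sad_spec_single("FI", c(theta = 1, lvar = 0), c(theta = 0, lvar = 1))
  cfg <- sim_config(n_founders = 16, generations = 1,
                    offspring_per_generation = 30, n_sires = 5, n_dams = 8,
                    grid = grid,
                    params = sad_params(sp,
                                        genetic = list(FI = list(theta = c(0.1, 0.1), lvar = 0)),
                                        environmental = list(FI = list(theta = 0.3, lvar = c(0.5, 0.1)))),
                    means = matrix(50, 1, 3, dimnames = list("FI", NULL)),
                    missingness = matrix(0, 1, 3, dimnames = list("FI", NULL)),
                    seed = 6)
  sim <- simulate_dataset(cfg, complete = TRUE)
  fitE <- fit_reml(sim$pheno, sim$ped, sp, grid, method = "eigen", hessian = FALSE)
  fitM <- fitE
  fitM$setup <- reml_setup(sim$pheno, sim$ped, sp, grid, method = "mme")
  blE <- blup_solve(fitE)
  blM <- blup_solve(fitM)
  expect_equal(blE$tebv, blM$tebv[rownames(blE$tebv), ], tolerance = 1e-6)
  expect_equal(blE$e, blM$e[rownames(blE$e), ], tolerance = 1e-6)
})

test_that("information condition number is the eigenvalue ratio square root", {
  expect_equal(as.numeric(information_condition_number(diag(3))), 1)
  expect_equal(as.numeric(information_condition_number(diag(c(4, 1)))), 2)
  set.seed(2)
  L <- matrix(rnorm(25), 5)
  M <- crossprod(L) + diag(5)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(as.numeric(information_condition_number(M)),
               sqrt(max(ev) / min(ev)))
  expect_true(attr(information_condition_number(diag(c(1e8, 1))), "flagged"))
  expect_warning(information_condition_number(diag(c(1, -1))), "positive")
})

test_that("degree selection with zero search depth returns the base model", {
  grid <- time_grid(1:3)
  cfg <- sim_config(n_founders = 16, generations = 1,
                    offspring_per_generation = 40, n_sires = 5, n_dams = 8,
                    grid = grid, seed = 8)
  sim <- simulate_dataset(cfg, complete = TRUE)
  sel <- select_degrees(sim$pheno, sim$ped, grid,
                        traits = c("ADG", "MBW", "BF", "FI"),
                        max_degree = 0L, max_cross_degree = 0L, hessian = FALSE)
  for (tr in c("ADG", "MBW", "BF", "FI")) {
    expect_equal(unname(sel$spec$genetic[[tr]]), c(0, 0))
    expect_equal(unname(sel$spec$environmental[[tr]]), c(0, 0))
  }
  expect_true(all(sel$spec$cross_genetic == 0))
})
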