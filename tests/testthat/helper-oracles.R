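# Shared fixtures and independent oracles used across test files.
# The oracles deliberately avoid the package's covariance/likelihood code
# paths: recursions are simulated with plain loops, the dense REML criterion
# is computed from first principles on full matrices.

trio_pedigree <- function() {
  pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
}

random_pedigree <- function(n, seed) {
  set.seed(seed)
  n_founders <- max(4L, n %/% 4L)
  animal <- sprintf("a%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    sire[i] <- animal[sample(i - 1L, 1L)]
    repeat {
      d <- animal[sample(i - 1L, 1L)]
      if (d != sire[i]) break
    }
    dam[i] <- d
  }
  pedigree(animal, sire, dam)
}

# random multi-trait SAD parameter set on the standard 4-trait spec
random_multisad_params <- function() {
  sp <- default_sad_spec()
  ru <- function(k, lo, hi) stats::runif(k, lo, hi)
  sad_params(sp,
    genetic = list(ADG = list(theta = ru(1, -.5, .9), lvar = ru(1, -.5, .5)),
                   MBW = list(theta = ru(1, -.5, .9), lvar = ru(1, -.5, .5)),
                   BF = list(theta = ru(1, -.5, .9), lvar = ru(1, -.5, .5)),
                   FI = list(theta = ru(2, -.3, .3), lvar = ru(2, -.3, .3))),
    environmental = list(ADG = list(theta = ru(1, -.5, .9), lvar = ru(1, -.5, .5)),
                         MBW = list(theta = ru(1, -.5, .9), lvar = ru(2, -.3, .3)),
                         BF = list(theta = ru(1, -.5, .9), lvar = ru(2, -.3, .3)),
                         FI = list(theta = ru(2, -.3, .3), lvar = ru(3, -.2, .2))),
    cross_genetic = list(ADG = ru(2, -.3, .6), MBW = ru(2, -.3, .6),
                         BF = ru(2, -.3, .6)),
    cross_environmental = list(ADG = ru(2, -.3, .6), MBW = ru(2, -.3, .6),
                               BF = ru(2, -.3, .6)))
}

# simulate the defining recursions directly (independent of joint_factors):
# returns M x (4n) matrix in trait-major column order with labels
simulate_recursions <- function(pp, grid, component, M) {
  n <- length(grid)
  traits <- pp$spec$traits
  reg <- traits[length(traits)]
  prod_traits <- traits[-length(traits)]
  th <- sapply(traits, function(tr) longsad:::theta_values(pp, tr, component, grid))
  sg <- sapply(traits, function(tr) longsad:::innovation_variances(pp, tr, component, grid))
  b <- sapply(prod_traits, function(s) longsad:::cross_values(pp, s, component, grid))
  th <- matrix(th, n); sg <- matrix(sg, n); b <- matrix(b, n)
  colnames(th) <- colnames(sg) <- traits; colnames(b) <- prod_traits
  out <- array(0, c(M, n, length(traits)), dimnames = list(NULL, NULL, traits))
  for (tr in prod_traits) {
    for (j in seq_len(n)) {
      prev <- if (j > 1) th[j, tr] * out[, j - 1, tr] else 0
      out[, j, tr] <- prev + stats::rnorm(M, 0, sqrt(sg[j, tr]))
    }
  }
  for (j in seq_len(n)) {
    prev <- if (j > 1) th[j, reg] * out[, j - 1, reg] else 0
    cross <- 0
    for (s in prod_traits) cross <- cross + b[j, s] * out[, j, s]
    out[, j, reg] <- prev + cross + stats::rnorm(M, 0, sqrt(sg[j, reg]))
  }
  m <- matrix(out, M, length(traits) * n)
  colnames(m) <- longsad:::cell_labels(traits, grid)
  m
}

# three-sigma Monte-Carlo band for a sample covariance entry
cov_mc_se <- function(Sigma, M) {
  sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / M)
}

# dense first-principles REML criterion: projection form on the full V
dense_reml_oracle <- function(omega, pheno, ped, spec, grid, A = NULL) {
  if (is.null(A)) A <- build_A(ped)
  pp <- vector_to_params(omega, spec)
  Sg <- multi_trait_covariance(pp, grid, "genetic")
  Se <- multi_trait_covariance(pp, grid, "environmental")
  traits <- spec$traits
  n <- length(grid)
  q <- length(traits) * n
  animals <- ped$animal[ped$animal %in% pheno$animal]
  N <- length(animals)
  d <- pheno
  d$cell <- (match(d$trait, traits) - 1L) * n + d$week
  d$ai <- match(d$animal, animals)
  d <- d[order(d$ai, d$cell), ]
  rows <- (d$ai - 1L) * q + d$cell
  V <- (kronecker(A[animals, animals], Sg) + kronecker(diag(N), Se))[rows, rows]
  X <- matrix(0, length(rows), q)
  X[cbind(seq_along(rows), d$cell)] <- 1
  X <- X[, colSums(X) > 0, drop = FALSE]
  y <- d$value
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  Pm <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  p <- ncol(X)
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% Pm %*% y + (length(rows) - p) * log(2 * pi)))
}

# long phenotype table for all animals of a pedigree from explicit effects
toy_pheno <- function(ped, grid, traits, means = 0, noise_sd = 1, seed = 1) {
  set.seed(seed)
  g <- expand.grid(animal = ped$animal, week = seq_along(grid), trait = traits,
                   stringsAsFactors = FALSE)
  g$value <- means + stats::rnorm(nrow(g), sd = noise_sd)
  g
}
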