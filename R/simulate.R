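#' Synthetic data generator for a longitudinal feed-efficiency design
#'
#' Emulates the study design the package targets: a multi-generation pig
#' pedigree, four traits (average daily gain ADG, metabolic body weight MBW,
#' backfat BF, feed intake FI) recorded over 10 weekly time points, generated
#' from multi-trait SAD recursions with cross-antedependence of FI on the
#' production traits, week-specific means, and trait-by-week missingness.
#' Units follow the field convention that keeps trait variances comparable:
#' ADG and FI in 10x g/d, MBW in 10x kg^0.6, BF in 0.1x mm.
#'
#' @name simulate
NULL

#' Default SAD specification (retained model forms)
#'
#' ADG: genetic SAD00 / environmental SAD00; MBW and BF: genetic SAD00 /
#' environmental SAD01; FI: genetic SAD11 / environmental SAD12; all
#' cross-antedependence coefficient functions of degree 1 for both the
#' genetic and environmental parts.
#' @return a [sad_spec()].
#' @export
default_sad_spec <- function() {
  sad_spec(
    traits = c("ADG", "MBW", "BF", "FI"),
    genetic = list(ADG = c(theta = 0, lvar = 0),
                   MBW = c(theta = 0, lvar = 0),
                   BF = c(theta = 0, lvar = 0),
                   FI = c(theta = 1, lvar = 1)),
    environmental = list(ADG = c(theta = 0, lvar = 0),
                         MBW = c(theta = 0, lvar = 1),
                         BF = c(theta = 0, lvar = 1),
                         FI = c(theta = 1, lvar = 2)),
    cross_genetic = c(ADG = 1, MBW = 1, BF = 1),
    cross_environmental = c(ADG = 1, MBW = 1, BF = 1)
  )
}

#' Default SAD truth parameters
#'
#' Cross-antedependence trajectories use the reported week-1 values and
#' slopes (e.g. genetic ADG coefficient 1.13 at week 1 with slope -0.06).
#' Antedependence and innovation-variance coefficients were calibrated so
#' that the implied phenotypic SDs per week, trait heritability
#' trajectories, and the stable moderate heritability of the multi-SAD RFI
#' criterion match the study population (see the methods vignette).
#' @return a [sad_params()].
#' @export
default_sad_params <- function() {
  sad_params(
    default_sad_spec(),
    genetic = list(
      ADG = list(theta = 0.73, lvar = 4.143),
      MBW = list(theta = 0.851, lvar = 2.833),
      BF = list(theta = 0.933, lvar = 3.296),
      FI = list(theta = c(0.1494, 0.0713), lvar = c(5.4513, -0.1834))
    ),
    environmental = list(
      ADG = list(theta = 0.57, lvar = 4.890),
      MBW = list(theta = 0.40, lvar = c(4.231, -0.0716)),
      BF = list(theta = 0.60, lvar = c(4.247, 0.043)),
      FI = list(theta = c(0.45, 0.02), lvar = c(7.1532, -0.2642, 0.0135))
    ),
    cross_genetic = list(ADG = c(1.19, -0.06),
                         MBW = c(1.65, -0.17),
                         BF = c(0.18, 0)),
    cross_environmental = list(ADG = c(0.919, 0.001),
                               MBW = c(0.52, -0.04),
                               BF = c(0.214, 0.006))
  )
}

#' Weekly trait means and missingness rates of the emulated population
#'
#' Week-specific phenotypic means (the default fixed effects) and
#' trait-by-week missing-record proportions matching the descriptive
#' statistics of the emulated dataset; FI is essentially complete.
#' @return list with matrices `means` and `missingness` (trait x week).
#' @export
default_trait_tables <- function() {
  wk <- paste0("w", 1:10)
  means <- rbind(
    ADG = c(74, 77, 77, 81, 84, 86, 89, 91, 81, 87),
    MBW = c(90, 96, 106, 112, 118, 124, 133, 138, 145, 150),
    BF = c(75, 76, 107, 107, 104, 103, 128, 122, 126, 123),
    FI = c(168, 181, 193, 202, 213, 221, 229, 234, 242, 245)
  )
  missingness <- rbind(
    ADG = c(12, 59, 55, 61, 8, 60, 53, 55, 14, 74),
    MBW = c(52, 59, 8, 58, 53, 52, 0.5, 13, 32, 35),
    BF = c(87, 95, 46, 92, 89, 87, 37, 86, 82, 77),
    FI = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 6)
  ) / 100
  colnames(means) <- colnames(missingness) <- wk
  list(means = means, missingness = missingness)
}

#' Simulation configuration
#'
#' @param n_founders founder animals (generation 0, unrelated).
#' @param generations number of offspring generations.
#' @param offspring_per_generation litter output per generation.
#' @param n_sires,n_dams breeding animals sampled per generation.
#' @param grid measurement [time_grid()] (weeks 1..10 by default).
#' @param params truth [sad_params()].
#' @param means trait-by-week fixed-effect mean matrix.
#' @param missingness trait-by-week missing-record proportion matrix.
#' @param phenotyped_generations how many of the last generations carry
#'   records.
#' @param batch list(n, sd) for an optional additive Gaussian batch effect,
#'   or NULL.
#' @param seed integer seed driving all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 80,
                       generations = 3,
                       offspring_per_generation = 320,
                       n_sires = 20, n_dams = 40,
                       grid = time_grid(1:10),
                       params = default_sad_params(),
                       means = default_trait_tables()$means,
                       missingness = default_trait_tables()$missingness,
                       phenotyped_generations = 2,
                       batch = NULL,
                       seed = 1L) {
  stopifnot(all(missingness >= 0 & missingness <= 1))
  structure(list(n_founders = n_founders, generations = generations,
                 offspring_per_generation = offspring_per_generation,
                 n_sires = n_sires, n_dams = n_dams,
                 grid = grid, params = params, means = means,
                 missingness = missingness,
                 phenotyped_generations = phenotyped_generations,
                 batch = batch, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a discrete-generation pedigree
#'
#' Random mating without selfing: each offspring draws a sire among the
#' males and a dam among the females selected from the previous generation.
#'
#' @param cfg a [sim_config()] (only the pedigree-shape fields are used).
#' @param seed overrides `cfg$seed` when given.
#' @return a [pedigree()] with attributes `generation` (integer per animal)
#'   and `sex` (`"M"`/`"F"`).
#' @export
simulate_pedigree <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  ids <- sprintf("G0_%04d", seq_len(cfg$n_founders))
  sex <- sample(rep_len(c("M", "F"), cfg$n_founders))
  gen <- rep(0L, cfg$n_founders)
  sire <- dam <- rep(NA_character_, cfg$n_founders)
  prev_ids <- ids; prev_sex <- sex
  for (g in seq_len(cfg$generations)) {
    males <- prev_ids[prev_sex == "M"]
    females <- prev_ids[prev_sex == "F"]
    sires <- sample(males, min(cfg$n_sires, length(males)))
    dams <- sample(females, min(cfg$n_dams, length(females)))
    n <- cfg$offspring_per_generation
    new_ids <- sprintf("G%d_%04d", g, seq_len(n))
    new_sex <- sample(rep_len(c("M", "F"), n))
    ids <- c(ids, new_ids)
    sex <- c(sex, new_sex)
    gen <- c(gen, rep(g, n))
    sire <- c(sire, sample(sires, n, replace = TRUE))
    dam <- c(dam, sample(dams, n, replace = TRUE))
    prev_ids <- new_ids; prev_sex <- new_sex
  }
  ped <- pedigree(ids, sire, dam)
  m <- match(ped$animal, ids)
  attr(ped, "generation") <- gen[m]
  attr(ped, "sex") <- sex[m]
  ped
}

#' Simulate genetic and environmental trait-by-week effects
#'
#' Genetic effects are drawn with covariance \eqn{A \otimes \Sigma_g}
#' (Kronecker factorisation of the pedigree and SAD covariances);
#' environmental effects are iid per animal with \eqn{\Sigma_e}. With
#' `method = "recursion"` the defining SAD recursions are applied to
#' innovations instead (distributionally identical).
#'
#' @param ped a [pedigree()].
#' @param params a [sad_params()].
#' @param grid a [time_grid()].
#' @param seed integer.
#' @param A optional precomputed relationship matrix.
#' @param method `"factor"` or `"recursion"`.
#' @return list with matrices `u` and `e` (animals x trait:week cells).
#' @export
simulate_effects <- function(ped, params, grid, seed = 1L, A = NULL,
                             method = c("factor", "recursion")) {
  method <- match.arg(method)
  set.seed(seed)
  if (is.null(A)) A <- build_A(ped)
  n_ped <- nrow(ped)
  labels <- cell_labels(params$spec$traits, grid)
  q <- length(labels)
  # left-multiplication by the lower Cholesky factor of A, keeping sparse
  # relationship matrices sparse
  mixA <- if (inherits(A, "Matrix")) {
    La <- methods::as(Matrix::t(Matrix::chol(A)), "CsparseMatrix")
    function(Z) as.matrix(La %*% Z)
  } else {
    La <- t(chol(A))
    function(Z) La %*% Z
  }
  if (method == "factor") {
    Sg <- multi_trait_covariance(params, grid, "genetic")
    Se <- multi_trait_covariance(params, grid, "environmental")
    u <- mixA(matrix(stats::rnorm(n_ped * q), n_ped, q)) %*% chol(Sg)
    e <- matrix(stats::rnorm(n_ped * q), n_ped, q) %*% chol(Se)
  } else {
    fg <- joint_factors(params, grid, "genetic")
    fe <- joint_factors(params, grid, "environmental")
    sg <- sqrt(diag(fg$D)); se <- sqrt(diag(fe$D))
    Eg <- mixA(matrix(stats::rnorm(n_ped * q), n_ped, q)) %*% diag(sg)
    Ee <- matrix(stats::rnorm(n_ped * q), n_ped, q) %*% diag(se)
    u <- t(forwardsolve(fg$L, t(Eg)))
    e <- t(forwardsolve(fe$L, t(Ee)))
  }
  dimnames(u) <- dimnames(e) <- list(ped$animal, labels)
  list(u = u, e = e)
}

#' Assemble a long-format phenotype table from simulated effects
#'
#' value = week mean + optional batch effect + genetic + environmental
#' effect, for the phenotyped animals of the configured last generations.
#'
#' @param effects output of [simulate_effects()].
#' @param cfg a [sim_config()].
#' @param ped the pedigree the effects were simulated on.
#' @param latent_bw also emit a latent body-weight track (kg, weekly ages)
#'   consistent with the simulated MBW, for exercising trait derivation and
#'   interpolation.
#' @return data.frame `animal, week, trait, value` (+ `batch` if configured);
#'   with `latent_bw`, attribute `bw` holds a data.frame
#'   `animal, week, age_days, bw`.
#' @export
assemble_phenotypes <- function(effects, cfg, ped, latent_bw = FALSE) {
  gen <- attr(ped, "generation")
  keep_gen <- sort(unique(gen), decreasing = TRUE)[seq_len(min(cfg$phenotyped_generations, length(unique(gen))))]
  animals <- ped$animal[gen %in% keep_gen]
  traits <- cfg$params$spec$traits
  n <- length(cfg$grid)
  tot <- effects$u[animals, , drop = FALSE] + effects$e[animals, , drop = FALSE]
  out <- do.call(rbind, lapply(traits, function(tr) {
    cols <- paste0(tr, ":", seq_len(n))
    data.frame(animal = rep(animals, each = n),
               week = rep(seq_len(n), length(animals)),
               trait = tr,
               value = as.vector(t(tot[, cols, drop = FALSE])) +
                 rep(cfg$means[tr, seq_len(n)], length(animals)),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cfg$batch)) {
    set.seed(cfg$seed + 77L)
    bl <- sample(seq_len(cfg$batch$n), length(animals), replace = TRUE)
    eff <- stats::rnorm(cfg$batch$n, 0, cfg$batch$sd)
    out$batch <- factor(bl[match(out$animal, animals)])
    out$value <- out$value + eff[bl[match(out$animal, animals)]]
  }
  rownames(out) <- NULL
  if (latent_bw) {
    mbw <- out[out$trait == "MBW", ]
    bw <- data.frame(animal = mbw$animal, week = mbw$week,
                     age_days = 90 + 7 * (mbw$week - 1),
                     bw = (mbw$value / 10)^(1 / 0.6))
    attr(out, "bw") <- bw
  }
  out
}

#' Derive ADG and MBW from a body-weight series
#'
#' ADG at week j is the gain over the surrounding 4-week window,
#' \eqn{(BW_{j+2} - BW_{j-2}) / (age_{j+2} - age_{j-2})} (missing if either
#' flanking weight is unavailable); MBW is \eqn{BW^{0.6}}. Inputs are in kg
#' and days; outputs use the package units (ADG 10x g/d, MBW 10x kg^0.6).
#'
#' @param bw data.frame with columns `animal, week, age_days, bw` (kg).
#' @return data.frame `animal, week, trait, value` for traits ADG and MBW.
#' @export
derive_traits <- function(bw) {
  stopifnot(all(c("animal", "week", "age_days", "bw") %in% names(bw)))
  split_bw <- split(bw, bw$animal)
  out <- lapply(split_bw, function(d) {
    d <- d[order(d$week), ]
    if (any(diff(d$age_days) <= 0)) stop("ages must be strictly increasing for animal ", d$animal[1])
    wk <- d$week
    adg <- vapply(wk, function(j) {
      lo <- match(j - 2, wk); hi <- match(j + 2, wk)
      if (is.na(lo) || is.na(hi) || is.na(d$bw[lo]) || is.na(d$bw[hi])) return(NA_real_)
      # kg/day -> g/day -> 10x g/d units
      100 * (d$bw[hi] - d$bw[lo]) / (d$age_days[hi] - d$age_days[lo])
    }, numeric(1))
    mbw <- 10 * d$bw^0.6
    rbind(data.frame(animal = d$animal, week = wk, trait = "ADG", value = adg),
          data.frame(animal = d$animal, week = wk, trait = "MBW", value = mbw))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[!is.na(res$value) | res$trait == "ADG", ]
}

#' Delete records completely at random at trait-by-week rates
#'
#' @param pheno long phenotype data.frame (`animal, week, trait, value`).
#' @param rates trait x week matrix of deletion probabilities.
#' @param seed integer.
#' @return the table with sampled rows removed.
#' @export
apply_missingness <- function(pheno, rates, seed = 1L) {
  set.seed(seed)
  p <- rates[cbind(match(pheno$trait, rownames(rates)), pheno$week)]
  p[is.na(p)] <- 0
  drop <- stats::runif(nrow(pheno)) < p
  out <- pheno[!drop, ]
  rownames(out) <- NULL
  out
}

#' Linear interpolation of missing longitudinal records
#'
#' Completes a trait's weekly series per animal by linear interpolation on
#' the week index between flanking observations; ends are extrapolated with
#' the nearest segment's slope. Animals with fewer than two observations are
#' left incomplete.
#'
#' @param pheno long phenotype data.frame.
#' @param traits traits to complete (default all present).
#' @param weeks full week index to complete to (default observed range).
#' @return completed table with logical column `interpolated`.
#' @export
interpolate_missing <- function(pheno, traits = unique(pheno$trait),
                                weeks = NULL) {
  if (is.null(weeks)) weeks <- seq(min(pheno$week), max(pheno$week))
  keep <- pheno[!(pheno$trait %in% traits), , drop = FALSE]
  if (nrow(keep)) keep$interpolated <- FALSE
  done <- lapply(traits, function(tr) {
    d <- pheno[pheno$trait == tr, , drop = FALSE]
    pieces <- lapply(split(d, d$animal), function(a) {
      a <- a[order(a$week), ]
      obs_w <- a$week; obs_v <- a$value
      if (length(obs_w) < 2L) {
        a$interpolated <- FALSE
        return(a)
      }
      miss <- setdiff(weeks, obs_w)
      if (!length(miss)) {
        a$interpolated <- FALSE
        return(a)
      }
      pred <- vapply(miss, function(w) {
        if (w < obs_w[1]) {
          s <- (obs_v[2] - obs_v[1]) / (obs_w[2] - obs_w[1])
          obs_v[1] + s * (w - obs_w[1])
        } else if (w > obs_w[length(obs_w)]) {
          k <- length(obs_w)
          s <- (obs_v[k] - obs_v[k - 1]) / (obs_w[k] - obs_w[k - 1])
          obs_v[k] + s * (w - obs_w[k])
        } else {
          stats::approx(obs_w, obs_v, xout = w)$y
        }
      }, numeric(1))
      extra <- a[rep(1L, length(miss)), , drop = FALSE]
      extra$week <- miss
      extra$value <- pred
      a$interpolated <- FALSE
      extra$interpolated <- TRUE
      rbind(a, extra)
    })
    do.call(rbind, pieces)
  })
  out <- rbind(keep, do.call(rbind, done))
  out <- out[order(out$trait, out$animal, out$week), ]
  rownames(out) <- NULL
  out
}

#' One-call dataset simulation
#'
#' Pedigree, effects, phenotypes and missingness in one step.
#'
#' @param cfg a [sim_config()].
#' @param complete skip the missingness step.
#' @return list with `ped`, `A`, `effects`, `pheno` (and `pheno_complete`).
#' @export
simulate_dataset <- function(cfg, complete = FALSE) {
  ped <- simulate_pedigree(cfg)
  A <- build_A(ped)
  eff <- simulate_effects(ped, cfg$params, cfg$grid, seed = cfg$seed + 1L, A = A)
  pheno <- assemble_phenotypes(eff, cfg, ped)
  out <- list(ped = ped, A = A, effects = eff, pheno_complete = pheno)
  out$pheno <- if (complete) pheno else
    apply_missingness(pheno, cfg$missingness, seed = cfg$seed + 2L)
  out
}
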