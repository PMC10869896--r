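#' Configuration for the synthetic transect study generator
#'
#' The defaults emulate the structure of the plateau-lizard field study the
#' package's analysis chain is designed for: 11 transects, capture groups
#' of 40 juveniles, 30 males and 41 females, group-separated functional
#' trait centroids, a strong positive correlation (0.958) between surface
#' ground and soil temperature, a strong negative correlation (-0.907)
#' between bare-soil and clumping-grass coverage, and Poisson counts driven
#' by a log-linear predictor of standardized microhabitat variables.
#'
#' @param n_transects number of transects (default 11, minimum 2).
#' @param group_sizes named integer vector of individuals per group
#'   (default `c(juvenile = 40, male = 30, female = 41)`).
#' @param trait_centroid_shift separation of the group trait centroids in
#'   within-group SD units along designated group contrasts (default 2;
#'   0 gives exchangeable groups, the null case).
#' @param env_corr_temp latent correlation between surface ground and soil
#'   temperature (default 0.958).
#' @param env_corr_cover latent (logit-scale) correlation between bare-soil
#'   and clumping-grass coverage (default -0.907).
#' @param glm_coefficients named list (one element per group) of named
#'   coefficient vectors on z-scored environment variables, used for the
#'   count model and the transect allocation of individuals.
#' @param seed optional integer seed; each generator derives its own child
#'   seed from it, so the pieces are reproducible independently.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_transects = 11,
                              group_sizes = c(juvenile = 40, male = 30, female = 41),
                              trait_centroid_shift = 2,
                              env_corr_temp = 0.958,
                              env_corr_cover = -0.907,
                              glm_coefficients = default_glm_coefficients(),
                              seed = NULL) {
  if (n_transects < 2) stop("n_transects must be at least 2")
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be a named vector")
  }
  if (any(group_sizes <= 0) || any(group_sizes != round(group_sizes))) {
    stop("group sizes must be positive integers")
  }
  if (trait_centroid_shift < 0) stop("trait_centroid_shift must be nonnegative")
  if (abs(env_corr_temp) > 1 || abs(env_corr_cover) > 1) {
    stop("correlations must lie in [-1, 1]")
  }
  structure(
    list(
      n_transects = as.integer(n_transects),
      group_sizes = group_sizes,
      trait_centroid_shift = trait_centroid_shift,
      env_corr_temp = env_corr_temp,
      env_corr_cover = env_corr_cover,
      glm_coefficients = glm_coefficients,
      seed = seed
    ),
    class = "simulation_config"
  )
}

#' Default habitat-preference coefficients of the generator
#'
#' Signs follow the qualitative preferences the analysis chain is meant to
#' recover: juveniles favour warm, rocky, dry microhabitats; males and
#' females avoid high illuminance; males additionally avoid dense clumping
#' grass.  Coefficients act on z-scored environment variables in a
#' log-link count model.
#' @return named list of named numeric vectors.
#' @export
default_glm_coefficients <- function() {
  list(
    juvenile = c(ST = 0.8, RC = 0.5, SH = -0.8, AT = -0.5, AH = -0.5),
    male = c(Illu = -0.6, CGC = -0.6),
    female = c(Illu = -0.6, AT = 0.3)
  )
}

# latent trait model shared by the generator: means, within-group SDs and
# group contrast directions for the 8 free latent traits (LR = RFL / RHL
# is determined by the limb traits and therefore not free).
latent_trait_model <- function() {
  nm <- c("Mass", "EP", "MS", "HS", "RFL", "RHL", "RTL", "RAW")
  base <- c(Mass = 0.80, EP = 0.55, MS = 0.72, HS = 9.0,
            RFL = 0.43, RHL = 0.63, RTL = 0.75, RAW = 0.26)
  sds <- c(Mass = 0.08, EP = 0.04, MS = 0.04, HS = 0.55,
           RFL = 0.030, RHL = 0.040, RTL = 0.060, RAW = 0.025)
  # within-group correlation: four trait "factors" (size, limbs, head,
  # rear body), so the pooled correlation matrix reliably has four axes
  # with eigenvalues above 1 and the remainder clearly below 1 -- the
  # eigenvalue structure real lizard trait sets show
  cr <- diag(8)
  dimnames(cr) <- list(nm, nm)
  blk <- function(a, b, r) cr[a, b] <<- cr[b, a] <<- r
  blk("Mass", "HS", 0.65)  # size factor: heavy lizards have big heads
  blk("Mass", "RAW", 0.45) # ... and wide abdomens
  blk("HS", "RAW", 0.40)
  blk("EP", "MS", 0.50)    # head-shape factor
  blk("RFL", "RHL", 0.50)  # limb factor (the derived LR ratio adds a
  blk("RFL", "RTL", 0.35)  # second, contrast-like limb axis by itself)
  blk("RHL", "RTL", 0.35)
  # unit-norm contrast directions per group (in SD units)
  dirs <- rbind(
    juvenile = c(Mass = -1.0, EP = 0.6, MS = 0.2, HS = -1.0,
                 RFL = 0.6, RHL = 0.7, RTL = 0.6, RAW = -0.5),
    male = c(Mass = -0.25, EP = -0.1, MS = 0.3, HS = 0.1,
             RFL = 0.3, RHL = 0.1, RTL = 0.45, RAW = -0.7),
    female = c(Mass = 0.8, EP = -0.35, MS = -0.25, HS = 0.75,
               RFL = -0.4, RHL = -0.45, RTL = -0.5, RAW = 0.6)
  )
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(names = nm, base = base, sds = sds, corr = cr, dirs = dirs)
}

#' Generate synthetic individual morphometric records
#'
#' Individuals are simulated on the latent functional-trait scale --
#' group-specific multivariate-normal trait vectors whose centroids are
#' displaced by `trait_centroid_shift` within-group SDs along designated
#' group contrasts -- and then back-transformed through the trait formulas
#' to raw morphometrics.  Snout-vent length is drawn per group with
#' juveniles below 40 mm (the stage-defining threshold) and adults above
#' it, and each individual is assigned uniformly at random to a transect.
#'
#' With `trait_centroid_shift = 0`, the three groups' trait distributions
#' are exchangeable: the null case for group-difference tests.
#'
#' @param config a [simulation_config()].
#' @return data frame of individuals with columns `id`, `transect`,
#'   `group` and the raw measurements in [MORPHO_VARS].
#' @export
generate_individuals <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(child_seed(config$seed, "individuals"))
  mod <- latent_trait_model()
  svl_pars <- list(
    juvenile = c(mean = 34, sd = 2.5, lo = 24, hi = 39.9),
    male = c(mean = 57, sd = 3.5, lo = 41, hi = 75),
    female = c(mean = 59, sd = 3.5, lo = 41, hi = 78)
  )
  chol_cr <- chol(mod$corr)
  rows <- list()
  for (g in names(config$group_sizes)) {
    ng <- config$group_sizes[[g]]
    dir_g <- if (g %in% rownames(mod$dirs)) mod$dirs[g, ] else 0 * mod$base
    mu <- mod$base + config$trait_centroid_shift / 2 * dir_g * mod$sds
    z <- matrix(rnorm(ng * 8), ng, 8) %*% chol_cr
    lat <- sweep(sweep(z, 2, mod$sds, "*"), 2, mu, "+")
    colnames(lat) <- mod$names
    # keep latent traits physically meaningful
    lat <- pmax(lat, rep(0.05 * mod$base, each = ng))
    sp <- svl_pars[[if (g %in% names(svl_pars)) g else "female"]]
    svl <- pmin(pmax(rnorm(ng, sp["mean"], sp["sd"]), sp["lo"]), sp["hi"])
    # invert the trait formulas: traits are exactly the latent draws, so
    # group trait distributions are exchangeable when the shift is 0
    hs <- lat[, "HS"]
    hw <- 1.02 * hs
    hh <- 0.75 * hs
    hl <- hs / (1.02 * 0.75)
    rows[[g]] <- data.frame(
      group = g,
      M = pmax(10^lat[, "Mass"] - 1, 0),
      IO = lat[, "EP"] * hw,
      MW = lat[, "MS"] * hw,
      HL = hl, HH = hh, HW = hw,
      FLL = lat[, "RFL"] * svl,
      HLL = lat[, "RHL"] * svl,
      TAL = lat[, "RTL"] * svl,
      AMW = lat[, "RAW"] * svl,
      SVL = svl,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$id <- sprintf("ind%03d", seq_len(nrow(out)))
  out$transect <- sprintf("T%02d", sample.int(config$n_transects, nrow(out),
                                              replace = TRUE))
  rownames(out) <- NULL
  out[, c("id", "transect", "group", MORPHO_VARS)]
}

#' Generate synthetic transect microhabitat environments
#'
#' Environment variables are drawn from a latent multivariate Gaussian
#' whose correlation matrix embeds `env_corr_temp` between surface ground
#' and soil temperature and `env_corr_cover` between the (logit-scale)
#' bare-soil and clumping-grass coverages; all other pairs are
#' uncorrelated.  Coverages are simulated on the logit scale and mapped to
#' percent so they respect the `[0, 100]` bounds while preserving their
#' negative association; aspect is treated as a plain linear variable
#' clamped to `[0, 360)`.
#'
#' @param config a [simulation_config()].
#' @param n_transects optional override of `config$n_transects` (useful
#'   for Monte-Carlo checks of the realized correlations).
#' @return data frame with `transect` and the variables in [ENV_VARS].
#' @export
generate_environments <- function(config, n_transects = config$n_transects) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(child_seed(config$seed, "environments"))
  n <- as.integer(n_transects)
  vars <- ENV_VARS
  p <- length(vars)
  cr <- diag(p)
  dimnames(cr) <- list(vars, vars)
  cr["SGT", "ST"] <- cr["ST", "SGT"] <- config$env_corr_temp
  cr["BSC", "CGC"] <- cr["CGC", "BSC"] <- config$env_corr_cover
  ch <- tryCatch(chol(cr), error = function(e) {
    stop("requested correlation matrix is not positive definite")
  })
  mu <- c(AT = 12, AH = 40, SGT = 22, ST = 16, SH = 15, slope = 10,
          aspect = 180, Illu = 60000, RC = 25,
          BSC = qlogis(0.40), CGC = qlogis(0.35))
  sdv <- c(AT = 3, AH = 10, SGT = 6, ST = 4, SH = 6, slope = 5,
           aspect = 80, Illu = 20000, RC = 10, BSC = 0.5, CGC = 0.5)
  z <- matrix(rnorm(n * p), n, p) %*% ch
  x <- sweep(sweep(z, 2, sdv[vars], "*"), 2, mu[vars], "+")
  colnames(x) <- vars
  env <- as.data.frame(x)
  env$BSC <- 100 * plogis(env$BSC)
  env$CGC <- 100 * plogis(env$CGC)
  env$AH <- pmin(pmax(env$AH, 0), 100)
  env$SH <- pmin(pmax(env$SH, 0), 100)
  env$RC <- pmin(pmax(env$RC, 0), 100)
  env$Illu <- pmax(env$Illu, 0)
  env$slope <- pmax(env$slope, 0)
  env$aspect <- pmin(pmax(env$aspect, 0), 359.99)
  cbind(data.frame(transect = sprintf("T%02d", seq_len(n))), env)
}

#' Generate per-transect counts from a log-linear count model
#'
#' Counts are drawn from the requested family with a log link on z-scored
#' environment variables: `E(count) = exp(intercept + sum_j beta_j z_j)`.
#'
#' @param env data frame of transects (see [generate_environments()]).
#' @param coefficients named numeric vector of effects on z-scored
#'   predictors; an `"(Intercept)"` entry, if present, sets the log of the
#'   baseline mean (default `log(5)`).
#' @param family `"poisson"` or `"negbin"`.
#' @param seed optional integer seed.
#' @param theta negative binomial shape (ignored for Poisson).
#' @return integer vector of counts, one per row of `env`.
#' @export
generate_counts <- function(env, coefficients, family = c("poisson", "negbin"),
                            seed = NULL, theta = 2) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  lp <- count_linpred(env, coefficients)
  mu <- exp(lp)
  n <- length(mu)
  if (family == "poisson") rpois(n, mu) else rnbinom(n, size = theta, mu = mu)
}

count_linpred <- function(env, coefficients) {
  env <- as.data.frame(env)
  b0 <- if ("(Intercept)" %in% names(coefficients)) {
    coefficients[["(Intercept)"]]
  } else {
    log(5)
  }
  beta <- coefficients[setdiff(names(coefficients), "(Intercept)")]
  unknown <- setdiff(names(beta), names(env))
  if (length(unknown)) {
    stop("unknown predictor name(s): ", paste(unknown, collapse = ", "))
  }
  lp <- rep(b0, nrow(env))
  for (v in names(beta)) {
    x <- env[[v]]
    s <- sd(x)
    z <- if (s > 0) (x - mean(x)) / s else 0 * x
    lp <- lp + beta[[v]] * z
  }
  lp
}

#' Generate a coherent synthetic dataset for the whole pipeline
#'
#' Draws transect environments, then allocates each group's individuals to
#' transects with probabilities proportional to the group's expected
#' habitat-model counts (`exp` of the log-linear predictor), which is the
#' Poisson count model conditioned on the group total.  The per-transect
#' capture counts in the transect table therefore agree exactly with the
#' individual table.
#'
#' @param config a [simulation_config()].
#' @return list with `individuals` (see [generate_individuals()]) and
#'   `transects` (environments plus `n_juvenile`, `n_male`, `n_female`
#'   count columns).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  env <- generate_environments(config)
  ind <- generate_individuals(config)
  if (!is.null(config$seed)) set.seed(child_seed(config$seed, "allocation"))
  for (g in names(config$group_sizes)) {
    cf <- config$glm_coefficients[[g]]
    pr <- if (is.null(cf)) rep(1, nrow(env)) else exp(count_linpred(env, cf))
    idx <- which(ind$group == g)
    ind$transect[idx] <- sample(env$transect, length(idx), replace = TRUE,
                                prob = pr / sum(pr))
  }
  for (g in names(config$group_sizes)) {
    env[[paste0("n_", g)]] <- tabulate(
      match(ind$transect[ind$group == g], env$transect), nbins = nrow(env)
    )
  }
  list(individuals = ind, transects = env)
}

# deterministic per-stage child seed derived from a global seed
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
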