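#' Ground-truth parameters for the synthetic field-experiment generator
#'
#' Defines every generating parameter of [generate_experiment()]. Effect
#' coefficients are expressed on the standardized-predictor scale (per SD of
#' the realized predictor), which is the scale the inference module reports,
#' so an unbiased fit should recover them directly. The default effect sizes
#' are the field estimates: brood production falls by 0.36 mg/worker/week per
#' SD of conspecific worker biomass and 0.29 per SD of heterospecific
#' biomass with a -0.29 interaction; worker survival carries a -0.29
#' logit-scale effect of the squared standardized conspecific colony density,
#' a +0.10 heterospecific main effect and a +0.30 interaction; and the
#' per-worker-weight growth rate Gw carries standardized slopes -0.06
#' (conspecific colony density) and -0.013 (heterospecific biomass).
#'
#' @param survival_intercept logit-scale baseline survival (default
#'   `qlogis(0.85)`: about 85% of marked workers recaptured after one week).
#' @param survival_beta_cd2 logit effect of squared standardized conspecific
#'   colony density.
#' @param survival_beta_het logit effect of standardized heterospecific
#'   biomass.
#' @param survival_beta_cd2_x_het logit-scale interaction of the two.
#' @param colony_random_sd SD of colony-level logit intercepts (>= 0).
#' @param brood_intercept baseline brood production, mg/worker/week.
#' @param brood_beta_con,brood_beta_het,brood_beta_int brood effects,
#'   mg/worker/week per SD of conspecific biomass, heterospecific biomass,
#'   and their product.
#' @param brood_noise_sd per-worker brood noise, mg/week (>= 0). Workers
#'   contribute brood independently, so a colony of W1 workers has
#'   per-worker noise SD `brood_noise_sd / sqrt(W1)` -- the
#'   variance structure the W1-weighted brood regression assumes.
#' @param month_random_sd SD of monthly brood/growth shocks, mg/worker/week.
#' @param n_months number of month blocks colonies are spread over.
#' @param growth_intercept baseline Gw, per week.
#' @param growth_alpha_con,growth_alpha_het Gw effects per SD of conspecific
#'   colony density and heterospecific biomass.
#' @param growth_noise_sd residual SD of Gw, per week.
#' @param mean_adult_weight mean adult fresh weight M, mg (> 0).
#' @param emergence_rate expected newly emerged workers per mg of cocoons per
#'   week.
#' @param density_model list controlling the field distributions:
#'   `nest_mean` (Poisson mean of persistent conspecific nest counts),
#'   `wet_weights` (mean wet weight per individual, mg, for the focal
#'   species and the six designated heterospecific species),
#'   `count_means` (mean pitfall catch per species), and `count_size`
#'   (negative-binomial size; small values give the right-skewed catches
#'   typical of trap data). Per-species biomass is catch times wet weight,
#'   exactly as the pipeline computes it from the trap tables.
#' @return validated list of class `true_parameters`.
#' @export
true_parameters <- function(survival_intercept = qlogis(0.85),
                            survival_beta_cd2 = -0.29,
                            survival_beta_het = 0.10,
                            survival_beta_cd2_x_het = 0.30,
                            colony_random_sd = 0.5,
                            brood_intercept = 1.0,
                            brood_beta_con = -0.36,
                            brood_beta_het = -0.29,
                            brood_beta_int = -0.29,
                            brood_noise_sd = 0.5,
                            month_random_sd = 0.2,
                            n_months = 3,
                            growth_intercept = 0.10,
                            growth_alpha_con = -0.06,
                            growth_alpha_het = -0.013,
                            growth_noise_sd = 0.05,
                            mean_adult_weight = 10,
                            emergence_rate = 0.05,
                            density_model = list()) {
  dm <- utils::modifyList(list(
    nest_mean = 2,
    wet_weights = c(Diacamma_cf_indicum      = 10.0,
                    Anoplolepis_gracilipes   = 2.5,
                    Tetramorium_bicarinatum  = 1.2,
                    Pheidole_parva           = 0.4,
                    Monomorium_chinense      = 0.2,
                    Nylanderia_ryukyuensis   = 0.5,
                    Ochetellus_glaber        = 0.6),
    count_means = c(Diacamma_cf_indicum      = 30,
                    Anoplolepis_gracilipes   = 48,
                    Tetramorium_bicarinatum  = 50,
                    Pheidole_parva           = 100,
                    Monomorium_chinense      = 125,
                    Nylanderia_ryukyuensis   = 60,
                    Ochetellus_glaber        = 33),
    count_size = 4
  ), density_model)
  truth <- list(
    survival_intercept = survival_intercept,
    survival_beta_cd2 = survival_beta_cd2,
    survival_beta_het = survival_beta_het,
    survival_beta_cd2_x_het = survival_beta_cd2_x_het,
    colony_random_sd = colony_random_sd,
    brood_intercept = brood_intercept,
    brood_beta_con = brood_beta_con,
    brood_beta_het = brood_beta_het,
    brood_beta_int = brood_beta_int,
    brood_noise_sd = brood_noise_sd,
    month_random_sd = month_random_sd,
    n_months = n_months,
    growth_intercept = growth_intercept,
    growth_alpha_con = growth_alpha_con,
    growth_alpha_het = growth_alpha_het,
    growth_noise_sd = growth_noise_sd,
    mean_adult_weight = mean_adult_weight,
    emergence_rate = emergence_rate,
    density_model = dm
  )
  validate_truth(truth)
  structure(truth, class = "true_parameters")
}

validate_truth <- function(truth) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid TrueParameters: field '", field, "' ", why)
  }
  chk(is.numeric(truth$colony_random_sd) && truth$colony_random_sd >= 0,
      "colony_random_sd", "must be >= 0")
  chk(is.numeric(truth$brood_noise_sd) && truth$brood_noise_sd >= 0,
      "brood_noise_sd", "must be >= 0")
  chk(is.numeric(truth$month_random_sd) && truth$month_random_sd >= 0,
      "month_random_sd", "must be >= 0")
  chk(is.numeric(truth$growth_noise_sd) && truth$growth_noise_sd >= 0,
      "growth_noise_sd", "must be >= 0")
  chk(is.numeric(truth$mean_adult_weight) && truth$mean_adult_weight > 0,
      "mean_adult_weight", "must be > 0")
  chk(is.numeric(truth$emergence_rate) && truth$emergence_rate >= 0,
      "emergence_rate", "must be >= 0")
  chk(truth$n_months >= 1, "n_months", "must be >= 1")
  dm <- truth$density_model
  chk(dm$nest_mean >= 0, "density_model$nest_mean", "must be >= 0")
  chk(all(dm$wet_weights > 0), "density_model$wet_weights", "must all be > 0")
  chk(all(dm$count_means >= 0), "density_model$count_means", "must be >= 0")
  chk(identical(sort(names(dm$wet_weights)), sort(names(dm$count_means))),
      "density_model$count_means", "must name the same species as wet_weights")
  chk(dm$count_size > 0, "density_model$count_size", "must be > 0")
  invisible(truth)
}

#' Generate a synthetic colony release-recapture experiment
#'
#' Emulates the field design: each synthetic colony (30-300 workers) is
#' released for one week at a point with its own local ant community, and the
#' recapture census is generated from three response channels with known
#' ground truth.
#'
#' \enumerate{
#'   \item \emph{Local densities.} Persistent conspecific nest counts are
#'     Poisson; the conspecific worker-biomass proxy and the six
#'     heterospecific species biomasses are right-skewed gamma draws.
#'     Predictors are then z-scored on the realized sample (the same
#'     standardization the inference module applies), so the generating
#'     coefficients live on exactly the scale a fit reports.
#'   \item \emph{Survival.} Each of the W1 workers survives as an independent
#'     Bernoulli draw whose logit is the survival linear predictor (squared
#'     standardized conspecific colony density, heterospecific biomass,
#'     interaction) plus a colony-level random intercept; W2 is the number of
#'     survivors (drawn as a single binomial, which is distributionally
#'     identical because workers of a colony share one probability).
#'   \item \emph{Brood and growth.} B2 - B1 = W1 * (brood linear predictor +
#'     month shock + colony noise), floored so B2 >= 0. Cocoons are tracked
#'     separately: B1/B2 exclude pre-existing cocoons, B3 = B1 + cocoons,
#'     and worker emergence from cocoon mass yields W3 >= W2. B4 is then set
#'     so that the per-worker-weight growth rate Gw follows its linear model
#'     in the standardized densities, floored at zero. Floored colonies are
#'     flagged in `flags` so tests can exclude them.
#' }
#'
#' Regeneration with the same seed and parameters is bit-for-bit identical.
#'
#' @param n_colonies number of colonies (>= 1).
#' @param truth a [true_parameters()] object.
#' @param seed integer seed.
#' @return list of class `synthetic_experiment`: `censuses` (a
#'   `colony_census` table), `densities` (local-density table with per-species
#'   biomass columns), `truth`, `seed`, `flags` (per-colony clamping flags)
#'   and `design` (the realized standardized predictors used in generation).
#' @export
generate_experiment <- function(n_colonies, truth = true_parameters(), seed = 1) {
  if (!is.numeric(n_colonies) || n_colonies < 1)
    stop("n_colonies must be a positive integer")
  n_colonies <- as.integer(n_colonies)
  validate_truth(truth)
  set.seed(as.integer(seed))
  dm <- truth$density_model

  colony_id <- sprintf("c%03d", seq_len(n_colonies))
  month_labels <- paste0("month", seq_len(truth$n_months))
  month <- month_labels[1 + (seq_len(n_colonies) - 1) %% truth$n_months]
  month_effect <- rnorm(truth$n_months, 0, truth$month_random_sd)

  W1 <- sample(30:300, n_colonies, replace = TRUE)
  nest_count <- rpois(n_colonies, dm$nest_mean)
  species <- names(dm$wet_weights)
  focal <- species[1]
  counts <- vapply(species, function(sp)
    stats::rnbinom(n_colonies, size = dm$count_size, mu = dm$count_means[[sp]]),
    numeric(n_colonies))
  counts <- matrix(counts, nrow = n_colonies, dimnames = list(NULL, species))
  biomass <- sweep(counts, 2, dm$wet_weights[species], `*`)
  con_biomass <- biomass[, focal]
  het_species <- biomass[, setdiff(species, focal), drop = FALSE]
  het_total <- rowSums(het_species)

  # realized standardized predictors (identical to what inference recomputes)
  z_or_zero <- function(x) {
    if (length(x) >= 2 && stats::sd(x) > 0) as.numeric(standardize(x))
    else rep(0, length(x))
  }
  z_cd <- z_or_zero(nest_count)
  z_cb <- z_or_zero(con_biomass)
  z_het <- z_or_zero(het_total)

  # survival channel
  u_colony <- rnorm(n_colonies, 0, truth$colony_random_sd)
  logit_s <- truth$survival_intercept +
    truth$survival_beta_cd2 * z_cd^2 +
    truth$survival_beta_het * z_het +
    truth$survival_beta_cd2_x_het * z_cd^2 * z_het +
    u_colony
  p_surv <- plogis(logit_s)
  W2 <- rbinom(n_colonies, W1, p_surv)

  # brood channel (per-worker, mg/week)
  b1_per_worker <- rgamma(n_colonies, shape = 12, scale = 0.5)  # ~6 mg/worker
  cocoon_per_worker <- rgamma(n_colonies, shape = 2, scale = 0.5) # ~1 mg/worker
  B1 <- W1 * b1_per_worker
  C1 <- W1 * cocoon_per_worker
  B3 <- B1 + C1
  P_true <- truth$brood_intercept +
    truth$brood_beta_con * z_cb +
    truth$brood_beta_het * z_het +
    truth$brood_beta_int * z_cb * z_het +
    month_effect[match(month, month_labels)] +
    rnorm(n_colonies, 0, truth$brood_noise_sd / sqrt(W1))
  B2 <- B1 + W1 * P_true
  clamped_brood <- B2 < 0
  B2[clamped_brood] <- 0

  # emergence from the cocoon compartment, then the growth channel fixes B4
  emerged <- rpois(n_colonies, truth$emergence_rate * C1)
  W3 <- W2 + emerged
  M <- truth$mean_adult_weight
  Gw_true <- truth$growth_intercept +
    truth$growth_alpha_con * z_cd +
    truth$growth_alpha_het * z_het +
    rnorm(n_colonies, 0, truth$growth_noise_sd)
  B4 <- B3 + M * W1 * Gw_true - M * (W3 - W1)
  clamped_growth <- B4 < 0
  B4[clamped_growth] <- 0

  censuses <- as_colony_census(data.frame(
    colony_id = colony_id, month = month,
    W1 = W1, W2 = W2, W3 = W3,
    B1 = B1, B2 = B2, B3 = B3, B4 = B4, M = M))
  densities <- data.frame(
    colony_id = colony_id,
    conspecific_nest_count = nest_count,
    conspecific_worker_biomass = con_biomass,
    het_species,
    heterospecific_total_biomass = het_total,
    check.names = FALSE)
  structure(list(
    censuses = censuses,
    densities = densities,
    pitfall_counts = data.frame(colony_id = colony_id, counts,
                                check.names = FALSE),
    truth = truth,
    seed = as.integer(seed),
    flags = data.frame(colony_id = colony_id,
                       clamped_brood = clamped_brood,
                       clamped_growth = clamped_growth),
    design = data.frame(colony_id = colony_id, z_cd = z_cd, z_cb = z_cb,
                        z_het = z_het)
  ), class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("Synthetic field experiment: %d colonies (seed %d)\n",
              nrow(x$censuses), x$seed))
  cat(sprintf("  clamped colonies: %d brood, %d growth\n",
              sum(x$flags$clamped_brood), sum(x$flags$clamped_growth)))
  invisible(x)
}

#' Map generating coefficients onto the standardized-predictor scale
#'
#' Returns the coefficient values an unbiased fit of the correctly specified
#' models should recover from `experiment`, given the realized sample
#' means/SDs of the predictors. Because the generator applies its effects to
#' predictors z-scored on the realized sample -- the same standardization the
#' inference module performs -- the mapping is the identity; this function
#' recomputes the standardization from the generated tables, verifies the
#' stored design matches (guarding against a mismatched experiment/truth
#' pair), and returns the coefficients.
#'
#' @param truth the [true_parameters()] the experiment was generated from.
#' @param experiment the matching [generate_experiment()] result.
#' @return named numeric vector of standardized-scale coefficients.
#' @export
truth_to_standardized <- function(truth, experiment) {
  if (!inherits(experiment, "synthetic_experiment"))
    stop("experiment must come from generate_experiment()")
  if (!identical(unclass(truth), unclass(experiment$truth)))
    stop("truth does not match the parameters stored in the experiment")
  d <- experiment$densities
  z <- function(x) if (stats::sd(x) > 0) as.numeric(standardize(x)) else rep(0, length(x))
  recomputed <- data.frame(z_cd = z(d$conspecific_nest_count),
                           z_cb = z(d$conspecific_worker_biomass),
                           z_het = z(d$heterospecific_total_biomass))
  if (max(abs(as.matrix(recomputed) -
              as.matrix(experiment$design[, c("z_cd", "z_cb", "z_het")]))) > 1e-8)
    stop("experiment densities do not reproduce the stored standardized design")
  c(survival_beta_cd2       = truth$survival_beta_cd2,
    survival_beta_het       = truth$survival_beta_het,
    survival_beta_cd2_x_het = truth$survival_beta_cd2_x_het,
    brood_beta_con          = truth$brood_beta_con,
    brood_beta_het          = truth$brood_beta_het,
    brood_beta_int          = truth$brood_beta_int,
    growth_alpha_con        = truth$growth_alpha_con,
    growth_alpha_het        = truth$growth_alpha_het)
}
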