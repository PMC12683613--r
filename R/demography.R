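#' Validate a table of colony censuses
#'
#' A colony census records the composition of one marked, released colony
#' before release and at recapture one week later: `W1` marked workers before
#' release, `W2` marked workers recaptured, `W3` total workers at recapture
#' (including workers that emerged after release), brood fresh weights in mg
#' (`B1` eggs+larvae before release, `B2` eggs+larvae+newly pupated cocoons at
#' recapture, `B3` = `B1` plus cocoons, `B4` = `B2` plus all cocoons), and `M`
#' the mean fresh weight of an adult worker (mg).
#'
#' Rows violating the census invariants (`W1 >= 1`, `0 <= W2 <= W1`,
#' `W3 >= W2`, non-negative weights, `B3 >= B1`, `M > 0`) are rejected with
#' row-level diagnostics rather than silently dropped.
#'
#' @param x data.frame with columns `colony_id`, `month`, `W1`, `W2`, `W3`,
#'   `B1`, `B2`, `B3`, `B4`, `M`.
#' @return `x`, with class `colony_census` prepended.
#' @export
as_colony_census <- function(x) {
  needed <- c("colony_id", "month", "W1", "W2", "W3", "B1", "B2", "B3", "B4", "M")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    stop("census table is missing columns: ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)
  probs <- census_problems(x)
  if (length(probs))
    stop("invalid census rows:\n", paste(probs, collapse = "\n"))
  class(x) <- c("colony_census", class(x))
  x
}

# one message per offending row, naming the violated invariant
census_problems <- function(x) {
  msgs <- character(0)
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) msgs <<- c(msgs, sprintf("  row %d: %s", i, what))
  }
  bad(x$W1 < 1, "W1 < 1 (colony must hold at least one marked worker)")
  bad(x$W2 < 0 | x$W2 > x$W1, "W2 outside [0, W1] (marked workers cannot be gained)")
  bad(x$W3 < x$W2, "W3 < W2 (total workers cannot be fewer than marked survivors)")
  for (col in c("B1", "B2", "B3", "B4"))
    bad(x[[col]] < 0, paste0(col, " negative (brood weights are fresh weights in mg)"))
  bad(x$B3 < x$B1, "B3 < B1 (cocoon-inclusive weight below cocoon-free weight)")
  bad(x$M <= 0, "M <= 0 (mean adult fresh weight must be positive)")
  msgs
}

#' Per-worker demographic rates from a colony census
#'
#' The four estimators of one-week colony performance:
#' \describe{
#'   \item{`per_worker_survival()`}{S = W2 / W1, the recapture probability of
#'     a marked worker.}
#'   \item{`brood_production()`}{P = (B2 - B1) / W1, mg of cocoon-free brood
#'     gained per worker (newly pupated cocoons counted in B2 because they
#'     reflect larval growth); may be negative.}
#'   \item{`net_colony_growth()`}{G = \[(M W3 + B4) - (M W1 + B3)\] / W1, the
#'     change in total colony fresh weight (adults valued at M mg each, all
#'     brood included) per initial worker.}
#'   \item{`per_worker_weight_growth()`}{Gw = G / M, the same change expressed
#'     per unit of initial adult biomass; this dimensionless weekly rate is
#'     the response used for the Lotka-Volterra fit.}
#' }
#'
#' @param census one census row (list/data.frame with the `colony_census`
#'   fields) or a whole census table; all estimators are vectorised.
#' @return numeric vector of rates, one per census row.
#' @examples
#' cen <- data.frame(colony_id = "c1", month = "Oct", W1 = 80, W2 = 60,
#'                   W3 = 62, B1 = 50, B2 = 65, B3 = 70, B4 = 90, M = 10)
#' per_worker_survival(cen)      # 0.75
#' brood_production(cen)         # 0.1875 mg / worker
#' net_colony_growth(cen)
#' per_worker_weight_growth(cen)
#' @export
per_worker_survival <- function(census) {
  if (any(census$W1 < 1)) stop("W1 must be >= 1")
  if (any(census$W2 > census$W1 | census$W2 < 0))
    stop("census inconsistency: W2 must lie in [0, W1]; marked workers cannot be gained")
  census$W2 / census$W1
}

#' @rdname per_worker_survival
#' @export
brood_production <- function(census) {
  if (any(census$W1 < 1)) stop("W1 must be >= 1")
  (census$B2 - census$B1) / census$W1
}

#' @rdname per_worker_survival
#' @export
net_colony_growth <- function(census) {
  if (any(census$W1 < 1)) stop("W1 must be >= 1")
  if (any(census$M <= 0)) stop("M must be positive")
  ((census$M * census$W3 + census$B4) - (census$M * census$W1 + census$B3)) / census$W1
}

#' @rdname per_worker_survival
#' @export
per_worker_weight_growth <- function(census) {
  net_colony_growth(census) / census$M
}

#' Pitfall-trap biomass proxy
#'
#' Local population density of a species is proxied by biomass: the total
#' number of individuals caught over the pitfall array times the species'
#' mean wet weight per individual (measured separately).
#'
#' @param count non-negative integer count of trapped individuals.
#' @param mean_wet_weight mean wet weight per individual, mg (> 0).
#' @return biomass in mg.
#' @export
pitfall_biomass <- function(count, mean_wet_weight) {
  if (any(count < 0)) stop("trap counts cannot be negative")
  if (any(mean_wet_weight <= 0)) stop("mean wet weight must be positive")
  count * mean_wet_weight
}

#' Persistent conspecific nest count
#'
#' Counts the nests present within the survey radius on every observation day
#' (default window 7 days): only nests present throughout the window are
#' scored, i.e. nest density at recapture. A nest absent on any single day is
#' excluded.
#'
#' @param daily_observations list with one element per day, each a character
#'   (or other atomic) vector of nest identifiers seen that day.
#' @param window_days expected number of observation days; if supplied and
#'   different from `length(daily_observations)` an error is raised.
#' @return integer count of nests present on all days.
#' @examples
#' persistent_nest_count(rep(list(c("a", "b", "c")), 7))  # 3
#' @export
persistent_nest_count <- function(daily_observations, window_days = NULL) {
  if (!is.list(daily_observations) || length(daily_observations) == 0)
    stop("need at least one day of nest observations")
  if (!is.null(window_days) && length(daily_observations) != window_days)
    stop("expected ", window_days, " days of observations, got ",
         length(daily_observations))
  persistent <- Reduce(intersect, daily_observations)
  length(persistent)
}

#' Build the tidy per-colony rates table
#'
#' Joins a census table with the matching local-density table and computes
#' the four demographic rates per colony. This table is the input to
#' [fit_density_dependence()] and [fit_lv()].
#'
#' @param censuses census table (see [as_colony_census()]).
#' @param densities data.frame with one row per colony: `colony_id`,
#'   `conspecific_nest_count` (persistent nests within the survey radius),
#'   `conspecific_worker_biomass` (mg, pitfall proxy) and
#'   `heterospecific_total_biomass` (mg, summed over the designated
#'   heterospecific species).
#' @return data.frame with one row per colony: identifiers, W1, month, the
#'   rates `S`, `P`, `G`, `Gw`, and the three density covariates.
#' @export
colony_rates <- function(censuses, densities) {
  censuses <- as_colony_census(censuses)
  need <- c("colony_id", "conspecific_nest_count", "conspecific_worker_biomass",
            "heterospecific_total_biomass")
  miss <- setdiff(need, names(densities))
  if (length(miss))
    stop("density table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(censuses$colony_id %in% densities$colony_id))
    stop("no local-density record for colonies: ",
         paste(setdiff(censuses$colony_id, densities$colony_id), collapse = ", "))
  d <- densities[match(censuses$colony_id, densities$colony_id), , drop = FALSE]
  data.frame(
    colony_id = censuses$colony_id,
    month     = censuses$month,
    W1        = censuses$W1,
    W2        = censuses$W2,
    S         = per_worker_survival(censuses),
    P         = brood_production(censuses),
    G         = net_colony_growth(censuses),
    Gw        = per_worker_weight_growth(censuses),
    conspecific_nest_count       = d$conspecific_nest_count,
    conspecific_worker_biomass   = d$conspecific_worker_biomass,
    heterospecific_total_biomass = d$heterospecific_total_biomass,
    row.names = NULL
  )
}
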