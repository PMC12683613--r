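# CSV schemas shared by the pipeline and the synthetic generator.
#
#   censuses.csv : colony_id,month,W1,W2,W3,B1_mg,B2_mg,B3_mg,B4_mg,M_mg
#   pitfall.csv  : colony_id,species,count
#   weights.csv  : species,mean_wet_weight_mg
#   nests.csv    : colony_id,day,nest_id   (daily nest-map observations)
#
# Weights are serialized with 2 decimal places (the microbalance reads to
# +/- 0.01 mg), so CSV round trips are lossless at that precision.

#' Read and validate a colony-census CSV
#'
#' Expects the header `colony_id,month,W1,W2,W3,B1_mg,B2_mg,B3_mg,B4_mg,M_mg`.
#' All rows are validated against the census invariants; every offending row
#' is reported (with its row number) in a single error.
#'
#' @param path CSV path.
#' @return a `colony_census` data.frame (weight columns renamed to
#'   `B1`..`B4`, `M`).
#' @export
read_censuses <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("colony_id", "month", "W1", "W2", "W3",
              "B1_mg", "B2_mg", "B3_mg", "B4_mg", "M_mg")
  miss <- setdiff(needed, names(x))
  if (length(miss))
    stop("census file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  for (col in c("W1", "W2", "W3", "B1_mg", "B2_mg", "B3_mg", "B4_mg", "M_mg"))
    if (!is.numeric(x[[col]]))
      stop("census column ", col, " is not numeric")
  names(x) <- sub("_mg$", "", names(x))
  as_colony_census(x)
}

#' @rdname read_censuses
#' @param censuses a `colony_census` table to write.
#' @export
write_censuses <- function(censuses, path) {
  out <- as.data.frame(censuses)
  for (col in c("B1", "B2", "B3", "B4", "M")) out[[col]] <- round(out[[col]], 2)
  names(out) <- sub("^(B[1-4]|M)$", "\\1_mg", names(out))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read pitfall-trap tables into local biomass densities
#'
#' Combines a per-colony species-count table (`colony_id,species,count`) with
#' a species wet-weight table (`species,mean_wet_weight_mg`) into per-colony
#' biomasses. The focal species' biomass becomes the conspecific
#' worker-biomass proxy; the total over the designated heterospecific species
#' (default: every non-focal species in the weights table) becomes the
#' heterospecific density. Species trapped but absent from the weights table
#' are an error naming the species; row order is immaterial.
#'
#' @param path pitfall counts CSV.
#' @param weights_path species wet-weight CSV.
#' @param focal_species species name treated as conspecific.
#' @param het_species character vector of heterospecific species to sum
#'   (default: all non-focal species in the weights table).
#' @return data.frame: `colony_id`, `conspecific_worker_biomass`, one biomass
#'   column per heterospecific species, `heterospecific_total_biomass` (mg).
#' @export
read_pitfall <- function(path, weights_path,
                         focal_species = "Diacamma_cf_indicum",
                         het_species = NULL) {
  counts <- read.csv(path, stringsAsFactors = FALSE)
  weights <- read.csv(weights_path, stringsAsFactors = FALSE)
  if (!all(c("colony_id", "species", "count") %in% names(counts)))
    stop("pitfall file needs columns colony_id, species, count")
  if (!all(c("species", "mean_wet_weight_mg") %in% names(weights)))
    stop("weights file needs columns species, mean_wet_weight_mg")
  unknown <- setdiff(unique(counts$species), weights$species)
  if (length(unknown))
    stop("species missing from the weights table: ",
         paste(unknown, collapse = ", "))
  if (is.null(het_species))
    het_species <- setdiff(weights$species, focal_species)
  w <- setNames(weights$mean_wet_weight_mg, weights$species)
  counts$biomass <- pitfall_biomass(counts$count, w[counts$species])
  ids <- unique(counts$colony_id)
  species <- c(focal_species, het_species)
  bm <- matrix(0, length(ids), length(species),
               dimnames = list(ids, species))
  agg <- stats::aggregate(biomass ~ colony_id + species, counts, sum)
  keep <- agg$species %in% species
  bm[cbind(match(agg$colony_id[keep], ids), match(agg$species[keep], species))] <-
    agg$biomass[keep]
  out <- data.frame(colony_id = ids,
                    conspecific_worker_biomass = bm[, focal_species],
                    bm[, het_species, drop = FALSE],
                    heterospecific_total_biomass =
                      rowSums(bm[, het_species, drop = FALSE]),
                    check.names = FALSE, row.names = NULL)
  out
}

#' Read daily nest-map observations into persistent nest counts
#'
#' Expects rows `colony_id,day,nest_id`. For each colony the persistent count
#' is the number of nest identifiers present on every observation day
#' ([persistent_nest_count()]).
#'
#' @param path nests CSV.
#' @param window_days number of observation days (default 7); each colony
#'   must have been surveyed on days `1..window_days` (a nest absent from a
#'   day is simply missing a row; a day with no nests at all needs no rows).
#' @param colony_ids optional vector of colonies that must appear in the
#'   output (those with no rows get a count of 0).
#' @return data.frame `colony_id`, `conspecific_nest_count`.
#' @export
read_nest_observations <- function(path, window_days = 7, colony_ids = NULL) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("colony_id", "day", "nest_id") %in% names(x)))
    stop("nest file needs columns colony_id, day, nest_id")
  ids <- union(colony_ids, unique(x$colony_id))
  n <- vapply(ids, function(id) {
    rows <- x[x$colony_id == id, , drop = FALSE]
    daily <- lapply(seq_len(window_days), function(d)
      rows$nest_id[rows$day == d])
    persistent_nest_count(daily)
  }, integer(1))
  data.frame(colony_id = ids, conspecific_nest_count = n, row.names = NULL)
}

#' Write a synthetic experiment to a directory of CSVs
#'
#' Emits `censuses.csv`, `pitfall.csv`, `weights.csv`, `nests.csv` (nests
#' present on all `window_days` days, so the persistent count round-trips),
#' and a `truth.json` sidecar holding the generating parameters and seed.
#'
#' @param experiment a [generate_experiment()] result.
#' @param dir output directory (created if needed).
#' @param window_days observation window used for the nest file.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir, window_days = 7) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_censuses(experiment$censuses, file.path(dir, "censuses.csv"))

  pc <- experiment$pitfall_counts
  species <- setdiff(names(pc), "colony_id")
  long <- data.frame(
    colony_id = rep(pc$colony_id, times = length(species)),
    species = rep(species, each = nrow(pc)),
    count = as.integer(unlist(pc[species])))
  write.csv(long, file.path(dir, "pitfall.csv"), row.names = FALSE, quote = FALSE)

  w <- experiment$truth$density_model$wet_weights
  write.csv(data.frame(species = names(w),
                       mean_wet_weight_mg = sprintf("%.2f", w)),
            file.path(dir, "weights.csv"), row.names = FALSE, quote = FALSE)

  d <- experiment$densities
  nests <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    k <- d$conspecific_nest_count[i]
    if (k == 0) return(NULL)
    expand.grid(colony_id = d$colony_id[i], day = seq_len(window_days),
                nest_id = sprintf("%s_n%d", d$colony_id[i], seq_len(k)),
                stringsAsFactors = FALSE)
  }))
  if (is.null(nests))
    nests <- data.frame(colony_id = character(0), day = integer(0),
                        nest_id = character(0))
  write.csv(nests, file.path(dir, "nests.csv"), row.names = FALSE, quote = FALSE)

  truth <- experiment$truth
  sidecar <- c(unclass(truth)[setdiff(names(truth), "density_model")],
               list(density_model = truth$density_model,
                    seed = experiment$seed))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an experiment directory back into a rates table
#'
#' Loads the census, pitfall, weight and nest files written by
#' [write_experiment()] (or assembled by hand in the same schemas) and
#' returns the tidy per-colony rates table.
#'
#' @param dir directory holding the CSVs.
#' @param window_days nest observation window.
#' @param focal_species conspecific species name in the pitfall tables.
#' @return a [colony_rates()] table.
#' @export
read_experiment_rates <- function(dir, window_days = 7,
                                  focal_species = "Diacamma_cf_indicum") {
  censuses <- read_censuses(file.path(dir, "censuses.csv"))
  pit <- read_pitfall(file.path(dir, "pitfall.csv"),
                      file.path(dir, "weights.csv"),
                      focal_species = focal_species)
  nests <- read_nest_observations(file.path(dir, "nests.csv"),
                                  window_days = window_days,
                                  colony_ids = censuses$colony_id)
  dens <- merge(nests, pit, by = "colony_id", all.x = TRUE)
  dens[is.na(dens)] <- 0
  colony_rates(censuses, dens)
}
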