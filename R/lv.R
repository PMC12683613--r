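#' Estimate Lotka-Volterra competition coefficients from colony growth
#'
#' Fits the two-species Lotka-Volterra competition model
#' \deqn{(1/N_i) dN_i/dt = r_i (1 - \alpha_{ii} N_i - \alpha_{ij} N_j)}
#' to field data by ordinary least squares: the per-worker-weight net colony
#' growth Gw (a dimensionless weekly rate, the empirical analogue of the
#' per-capita biomass growth rate) is regressed on the standardized
#' conspecific density (persistent nest count within the survey radius, or
#' the pitfall worker-biomass proxy) and the standardized heterospecific
#' biomass.
#'
#' The standardized slopes are the reported competition coefficients (sign
#' convention: negative = suppressive), and their ratio measures the relative
#' strength of intra- vs interspecific competition. On the raw predictor
#' scale the model maps the intercept to the intrinsic rate
#' \eqn{r_i} (growth extrapolated to zero density) and each raw slope
#' \eqn{b_k} to \eqn{-r_i \alpha_{ik}}, so
#' \eqn{\alpha_{ik} = -b_k / r_i}; the raw-scale coefficients are reported
#' whenever \eqn{r_i > 0}.
#'
#' @param rates per-colony rates table from [colony_rates()] (needs `Gw`,
#'   `conspecific_nest_count`, `conspecific_worker_biomass`,
#'   `heterospecific_total_biomass`; at least 3 colonies).
#' @param conspecific_metric `"colony_count"` (nest-map data; default) or
#'   `"worker_biomass"` (pitfall data).
#' @return object of class `lv_fit` with components `coefficients`
#'   (standardized: intercept, alpha_ii, alpha_ij), `se`, `ratio`
#'   (alpha_ii / alpha_ij on the standardized scale), `r_intrinsic` and
#'   `alpha_raw` (raw-scale mapping, `NA` when the intercept extrapolation
#'   is non-positive), the underlying `dd_fit`, and the predictor
#'   centers/scales. Supports `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `simulate` and `plot`.
#' @examples
#' truth <- true_parameters()
#' ex <- generate_experiment(60, truth, seed = 1)
#' rates <- colony_rates(ex$censuses, ex$densities)
#' fit <- fit_lv(rates)
#' fit
#' coef(fit)
#' @export
fit_lv <- function(rates, conspecific_metric = c("colony_count", "worker_biomass")) {
  conspecific_metric <- match.arg(conspecific_metric)
  if (nrow(rates) < 3)
    stop("need at least 3 colonies to estimate competition coefficients")
  x1_raw <- switch(conspecific_metric,
                   colony_count = rates$conspecific_nest_count,
                   worker_biomass = rates$conspecific_worker_biomass)
  x2_raw <- rates$heterospecific_total_biomass
  z1 <- standardize(x1_raw)
  z2 <- standardize(x2_raw)
  X <- cbind(conspecific = as.numeric(z1), heterospecific = as.numeric(z2))
  fit <- fit_ols(X, rates$Gw)

  b <- fit$coefficients
  ratio <- if (b[["heterospecific"]] != 0)
    b[["conspecific"]] / b[["heterospecific"]] else NA_real_

  # raw-scale mapping: Gw = r (1 - a_ii N_i - a_ij N_j)
  s1 <- attr(z1, "scale"); m1 <- attr(z1, "center")
  s2 <- attr(z2, "scale"); m2 <- attr(z2, "center")
  b1_raw <- b[["conspecific"]] / s1
  b2_raw <- b[["heterospecific"]] / s2
  r_i <- b[["(Intercept)"]] - b1_raw * m1 - b2_raw * m2
  alpha_raw <- if (is.finite(r_i) && r_i > 0)
    c(alpha_ii = -b1_raw / r_i, alpha_ij = -b2_raw / r_i)
  else c(alpha_ii = NA_real_, alpha_ij = NA_real_)

  structure(list(
    coefficients = c(`(Intercept)` = b[["(Intercept)"]],
                     alpha_ii = b[["conspecific"]],
                     alpha_ij = b[["heterospecific"]]),
    se = setNames(fit$se, c("(Intercept)", "alpha_ii", "alpha_ij")),
    ratio = ratio,
    scale = "standardized",
    conspecific_metric = conspecific_metric,
    r_intrinsic = r_i,
    alpha_raw = alpha_raw,
    centers = c(conspecific = m1, heterospecific = m2),
    scales = c(conspecific = s1, heterospecific = s2),
    fit = fit,
    n = nrow(rates),
    model = data.frame(Gw = rates$Gw, conspecific = x1_raw,
                       heterospecific = x2_raw)
  ), class = "lv_fit")
}

#' @export
print.lv_fit <- function(x, ...) {
  cat("Lotka-Volterra competition-coefficient fit\n")
  cat(sprintf("  conspecific metric: %s; n = %d colonies\n",
              x$conspecific_metric, x$n))
  cat("  standardized coefficients (negative = suppressive):\n")
  cat(sprintf("    intra (alpha_ii): %8.4f   inter (alpha_ij): %8.4f\n",
              x$coefficients[["alpha_ii"]], x$coefficients[["alpha_ij"]]))
  cat(sprintf("    ratio alpha_ii / alpha_ij: %.2f\n", x$ratio))
  if (is.finite(x$r_intrinsic) && x$r_intrinsic > 0)
    cat(sprintf("  raw scale: r = %.4f /week, alpha_ii = %.3g, alpha_ij = %.3g\n",
                x$r_intrinsic, x$alpha_raw[["alpha_ii"]], x$alpha_raw[["alpha_ij"]]))
  invisible(x)
}

#' @export
coef.lv_fit <- function(object, ...) object$coefficients

#' @export
summary.lv_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  tval <- est / se
  df <- object$n - 3
  tab <- data.frame(estimate = est, se = se, t = tval,
                    p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
  out <- list(coefficients = tab, ratio = object$ratio,
              r_intrinsic = object$r_intrinsic, alpha_raw = object$alpha_raw,
              sigma = object$fit$sigma, n = object$n,
              conspecific_metric = object$conspecific_metric)
  class(out) <- "summary.lv_fit"
  out
}

#' @export
print.summary.lv_fit <- function(x, ...) {
  cat("Lotka-Volterra competition-coefficient fit (", x$conspecific_metric,
      ", n = ", x$n, ")\n\n", sep = "")
  print(round(x$coefficients, 5))
  cat(sprintf("\nresidual sd: %.4f;  ratio alpha_ii/alpha_ij: %.2f\n",
              x$sigma, x$ratio))
  invisible(x)
}

#' @export
predict.lv_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$model
  z1 <- (newdata$conspecific - object$centers[["conspecific"]]) /
    object$scales[["conspecific"]]
  z2 <- (newdata$heterospecific - object$centers[["heterospecific"]]) /
    object$scales[["heterospecific"]]
  b <- object$coefficients
  b[["(Intercept)"]] + b[["alpha_ii"]] * z1 + b[["alpha_ij"]] * z2
}

#' @export
residuals.lv_fit <- function(object, ...) object$fit$residuals

#' @export
simulate.lv_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  out <- replicate(nsim, rnorm(length(mu), mu, object$fit$sigma),
                   simplify = FALSE)
  as.data.frame(setNames(out, paste0("sim_", seq_len(nsim))))
}

#' Partial competition plots for an `lv_fit`
#'
#' Two base-graphics panels: Gw against each raw density with the fitted
#' partial regression line (other predictor held at its mean).
#'
#' @param x an `lv_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lv_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (v in c("conspecific", "heterospecific")) {
    other <- setdiff(c("conspecific", "heterospecific"), v)
    graphics::plot(x$model[[v]], x$model$Gw,
                   xlab = paste(v, if (v == "conspecific" &&
                                       x$conspecific_metric == "colony_count")
                                "nest count" else "biomass (mg)"),
                   ylab = "net growth per worker weight (Gw, /week)", ...)
    xs <- seq(min(x$model[[v]]), max(x$model[[v]]), length.out = 50)
    nd <- data.frame(xs, mean(x$model[[other]]))
    names(nd) <- c(v, other)
    graphics::lines(xs, predict(x, nd), col = "steelblue", lwd = 2)
  }
  invisible(x)
}
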