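#' Standardize a predictor to mean 0, SD 1
#'
#' z-scores with the n-1 denominator. All explanatory variables entering the
#' density-dependence and Lotka-Volterra fits are standardized; squared and
#' interaction columns are built from the standardized columns afterwards.
#'
#' @param x numeric vector, length >= 2, with positive variance.
#' @return z-scored vector with attributes `center` and `scale` so the
#'   transform can be inverted (`z * scale + center`).
#' @export
standardize <- function(x) {
  if (!is.numeric(x)) stop("standardize() needs a numeric vector")
  if (length(x) < 2) stop("need at least two observations to standardize")
  if (anyNA(x)) stop("standardize() does not accept missing values")
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop("cannot standardize a zero-variance (constant) vector")
  m <- mean(x)
  z <- (x - m) / s
  attr(z, "center") <- m
  attr(z, "scale") <- s
  z
}

# Design-matrix builder shared by the fixed-effect fitters and the stepwise
# selector. Term labels are column names of `data`; "A:B" denotes the
# elementwise product of columns A and B. A squared term must be supplied as
# its own column (e.g. a z^2 column), so it is atomic for marginality.
build_design <- function(data, terms) {
  if (!length(terms)) return(matrix(numeric(0), nrow(data), 0))
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(data))
    if (length(miss))
      stop("unknown predictor column(s): ", paste(miss, collapse = ", "))
    Reduce(`*`, lapply(parts, function(p) as.numeric(data[[p]])))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

new_dd_fit <- function(coefficients, se, loglik, npar, n, family,
                       converged = TRUE, extra = list()) {
  out <- c(list(
    coefficients = coefficients,
    se = se,
    loglik = loglik,
    npar = npar,
    aic = -2 * loglik + 2 * npar,
    n = n,
    family = family,
    converged = converged
  ), extra)
  class(out) <- "dd_fit"
  out
}

#' Ordinary / weighted least squares with Gaussian likelihood bookkeeping
#'
#' A small self-contained WLS fitter used by the stepwise selector and the
#' Lotka-Volterra estimator. An intercept is always added. The log-likelihood
#' and AIC follow the usual Gaussian ML convention (error variance counted as
#' one parameter), so AICs are directly comparable with [stats::lm()] fits.
#'
#' @param x matrix or data.frame of predictor columns (no intercept column).
#' @param y numeric response.
#' @param weights optional positive case weights (e.g. colony size W1 when
#'   the response is a per-worker rate).
#' @return a `dd_fit` list: `coefficients`, `se`, `loglik`, `aic`, `n`,
#'   `converged`, plus `fitted`, `residuals`, `sigma`.
#' @export
fit_ols <- function(x, y, weights = NULL) {
  X <- cbind(`(Intercept)` = 1, as.matrix(x))
  n <- length(y)
  if (nrow(X) != n) stop("predictor and response lengths differ")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w <= 0)) stop("weights must be positive")
  sw <- sqrt(w)
  qx <- qr(X * sw)
  p <- ncol(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y * sw)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(w * res^2)
  sigma2_ml <- rss / n
  # matches logLik() of a weighted lm fit
  ll <- -0.5 * n * (log(2 * pi) + log(sigma2_ml) + 1) + 0.5 * sum(log(w))
  sigma2_hat <- rss / (n - p)
  XtWX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtWX_inv) * sigma2_hat)
  names(se) <- names(beta)
  new_dd_fit(beta, se, ll, npar = p + 1, n = n, family = "gaussian",
             extra = list(fitted = fitted, residuals = res,
                          sigma = sqrt(sigma2_hat)))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Binomial GLM fitter used for the worker-survival analyses, where each
#' marked worker is an independent Bernoulli trial. Outcomes can be given
#' per individual (`y` in 0/1, `trials = 1`) or aggregated per colony
#' (`y` = successes, `trials` = trials), which yields the identical
#' likelihood because the covariates are colony-level. When `cluster` labels
#' are supplied a colony-level random intercept is added and the fit is
#' delegated to [lme4::glmer()] (declared plumbing; the fixed-effect IRLS
#' machinery itself is implemented here).
#'
#' Complete separation is detected (diverging linear predictor) and flagged
#' via `converged = FALSE` rather than silently returned.
#'
#' @param x predictor matrix/data.frame (no intercept column).
#' @param y successes (0/1 if `trials` is 1).
#' @param trials number of Bernoulli trials per row (default 1).
#' @param cluster optional grouping labels for a random intercept.
#' @return a `dd_fit` list as in [fit_ols()]; `npar` includes the random
#'   intercept variance when `cluster` is used.
#' @export
fit_logistic <- function(x, y, trials = NULL, cluster = NULL) {
  n <- length(y)
  m <- if (is.null(trials)) rep(1, n) else as.numeric(trials)
  if (any(y < 0) || any(y > m)) stop("successes must lie in [0, trials]")
  X <- cbind(`(Intercept)` = 1, as.matrix(x))
  if (all(y == 0) || all(y == m)) {
    # one outcome class: the MLE is at infinity -- flag, don't iterate
    beta <- setNames(c(if (all(y == 0)) -30 else 30, rep(0, ncol(X) - 1)),
                     colnames(X))
    return(new_dd_fit(beta, rep(Inf, ncol(X)), loglik = 0, npar = ncol(X),
                      n = n, family = "binomial", converged = FALSE,
                      extra = list(fitted = plogis(drop(X %*% beta)),
                                   separated = TRUE)))
  }
  if (!is.null(cluster)) return(fit_logistic_glmer(x, y, m, cluster))

  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  for (iter in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    wirls <- pmax(m * mu * (1 - mu), 1e-12)
    z <- eta + (y - m * mu) / wirls
    qx <- qr(X * sqrt(wirls))
    if (qx$rank < p) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
      stop("design matrix is rank deficient; offending column(s): ",
           paste(bad, collapse = ", "))
    }
    beta_new <- qr.coef(qx, z * sqrt(wirls))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  separated <- max(abs(eta)) > 30
  if (separated) converged <- FALSE
  ll <- sum(dbinom(round(y), round(m), mu, log = TRUE))
  wirls <- pmax(m * mu * (1 - mu), 1e-12)
  cov <- chol2inv(chol(crossprod(X * sqrt(wirls))))
  se <- sqrt(diag(cov))
  names(se) <- names(beta) <- colnames(X)
  new_dd_fit(beta, se, ll, npar = p, n = n, family = "binomial",
             converged = converged,
             extra = list(fitted = mu, separated = separated))
}

fit_logistic_glmer <- function(x, y, m, cluster) {
  df <- as.data.frame(as.matrix(x))
  orig <- colnames(df)
  colnames(df) <- paste0("x", seq_along(df))
  df$.succ <- y
  df$.fail <- m - y
  df$.grp <- factor(cluster)
  rhs <- if (ncol(x)) paste(colnames(df)[seq_len(ncol(x))], collapse = " + ") else "1"
  form <- stats::as.formula(paste0("cbind(.succ, .fail) ~ ", rhs, " + (1 | .grp)"))
  fit <- lme4::glmer(form, data = df, family = stats::binomial())
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(fe) <- names(se) <- c("(Intercept)", orig)
  ll <- as.numeric(stats::logLik(fit))
  npar <- attr(stats::logLik(fit), "df")
  conv <- length(fit@optinfo$conv$lme4) == 0
  new_dd_fit(fe, se, ll, npar = npar, n = length(y), family = "binomial",
             converged = conv, extra = list(engine = "glmer", model = fit))
}

#' @export
print.dd_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d, logLik = %.3f, AIC = %.3f%s)\n",
              x$family, x$n, x$loglik, x$aic,
              if (x$converged) "" else ", NOT converged"))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 5))
  invisible(x)
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values via chi2 = -2 sum(log p) on 2k degrees of
#' freedom; used to combine the per-species heterospecific density tests.
#'
#' @param p_values numeric vector with all values in (0, 1].
#' @return list with `chi2`, `df`, `p_value`.
#' @examples
#' fishers_method(c(0.018, 0.028))  # chi2 ~ 15.19 on 4 df
#' @export
fishers_method <- function(p_values) {
  if (!length(p_values)) stop("need at least one p-value")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("all p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE))
}
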