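# Downward stepwise AIC selection with a marginality rule.
#
# Terms are column labels; "A:B" is the product of columns A and B. A term is
# droppable only if it is not a component of another remaining term, so a main
# effect cannot leave while one of its interactions stays. A squared predictor
# is carried as its own column (z^2), so it may be retained without its linear
# term -- the selection behaviour the survival analysis requires.

term_components <- function(tm) strsplit(tm, ":", fixed = TRUE)[[1]]

droppable_terms <- function(terms) {
  Filter(function(tm) {
    !any(vapply(setdiff(terms, tm), function(other) {
      tm %in% term_components(other) && length(term_components(other)) >
        length(term_components(tm))
    }, logical(1)))
  }, terms)
}

# One candidate fit in the stepwise path. Fixed-effect models use the
# in-package fitters; a random intercept delegates to lme4 (ML, not REML, so
# AICs are comparable across fixed-effect structures).
fit_terms <- function(data, response, terms, family, weights = NULL,
                      trials = NULL, random = NULL) {
  X <- build_design(data, terms)
  if (is.null(random)) {
    if (family == "gaussian") fit_ols(X, response, weights = weights)
    else fit_logistic(X, response, trials = trials)
  } else {
    if (family == "binomial")
      fit_logistic(X, response, trials = trials, cluster = data[[random]])
    else
      fit_lmer_terms(X, response, weights, data[[random]], terms)
  }
}

fit_lmer_terms <- function(X, y, weights, grp, terms) {
  df <- as.data.frame(X)
  colnames(df) <- if (ncol(X)) paste0("x", seq_len(ncol(X))) else character(0)
  df$.y <- y
  df$.grp <- factor(grp)
  df$.w <- if (is.null(weights)) rep(1, length(y)) else weights
  rhs <- if (ncol(X)) paste(colnames(df)[seq_len(ncol(X))], collapse = " + ") else "1"
  form <- stats::as.formula(paste0(".y ~ ", rhs, " + (1 | .grp)"))
  fit <- suppressMessages(lme4::lmer(form, data = df, weights = .w, REML = FALSE))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(fe) <- names(se) <- c("(Intercept)", terms)
  ll <- as.numeric(stats::logLik(fit))
  npar <- attr(stats::logLik(fit), "df")
  new_dd_fit(fe, se, ll, npar = npar, n = length(y), family = "gaussian",
             converged = TRUE, extra = list(engine = "lmer", model = fit))
}

#' Downward stepwise model selection by AIC
#'
#' Starting from the full model, repeatedly drops the single term whose
#' removal lowers AIC the most, respecting marginality (a main effect is not
#' dropped while an interaction containing it remains; a squared term,
#' supplied as its own column, may outlive its linear term). Selection stops
#' when no single removal lowers the AIC. Exact ties (|dAIC| < 1e-9) are
#' broken by dropping the later term in the declared ordering. Candidate fits
#' that fail to converge are skipped and logged.
#'
#' @param data data.frame holding the (already standardized) predictor
#'   columns.
#' @param response numeric response (successes if binomial).
#' @param terms character vector of term labels (columns, or "A:B" products),
#'   in the declared order used for tie-breaking.
#' @param family "gaussian" or "binomial".
#' @param weights optional case weights (gaussian only).
#' @param trials binomial trials per row.
#' @param random optional name of a grouping column; adds a random intercept
#'   via lme4.
#' @return list of class `stepwise_fit`: `terms` (selected), `fit` (the
#'   selected `dd_fit`), and `path`, a data.frame logging every step
#'   (dropped term, AIC before/after, skipped non-convergent candidates).
#' @export
stepwise_aic <- function(data, response, terms, family = c("gaussian", "binomial"),
                         weights = NULL, trials = NULL, random = NULL) {
  family <- match.arg(family)
  current_terms <- terms
  current <- fit_terms(data, response, current_terms, family, weights, trials, random)
  if (!current$converged) stop("full model did not converge")
  path <- data.frame(step = 0L, action = "start",
                     model = paste(current_terms, collapse = " + "),
                     aic = current$aic, stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    cand <- droppable_terms(current_terms)
    if (!length(cand)) break
    fits <- lapply(cand, function(tm)
      tryCatch(fit_terms(data, response, setdiff(current_terms, tm),
                         family, weights, trials, random),
               error = function(e) NULL))
    ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
    if (any(!ok)) {
      for (tm in cand[!ok])
        path <- rbind(path, data.frame(step = step, action = "skip_nonconverged",
                                       model = paste0("- ", tm), aic = NA_real_))
    }
    cand <- cand[ok]; fits <- fits[ok]
    if (!length(cand)) break
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    best_aic <- min(aics)
    if (best_aic >= current$aic) break
    tied <- which(aics - best_aic < 1e-9)
    # drop the later term in the declared ordering among ties
    pick <- tied[which.max(match(cand[tied], terms))]
    step <- step + 1L
    current_terms <- setdiff(current_terms, cand[pick])
    current <- fits[[pick]]
    path <- rbind(path, data.frame(step = step,
                                   action = paste0("drop ", cand[pick]),
                                   model = if (length(current_terms))
                                     paste(current_terms, collapse = " + ") else "1",
                                   aic = current$aic))
  }
  structure(list(terms = current_terms, fit = current, path = path),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Downward stepwise AIC selection\n")
  cat("Selected terms:", if (length(x$terms)) paste(x$terms, collapse = " + ")
      else "(intercept only)", "\n")
  cat(sprintf("AIC path: %s\n",
              paste(sprintf("%.2f", x$path$aic[!is.na(x$path$aic)]), collapse = " -> ")))
  print(x$fit)
  invisible(x)
}
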