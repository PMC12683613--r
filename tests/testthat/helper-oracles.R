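# Independent oracles and small fixture builders used across the suite.

# random valid colony census table
random_censuses <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W1 <- sample(30:300, n, replace = TRUE)
  W2 <- rbinom(n, W1, runif(n, 0.3, 1))
  W3 <- W2 + rpois(n, 10)
  B1 <- runif(n, 0, 500)
  C1 <- runif(n, 0, 300)
  data.frame(colony_id = sprintf("r%03d", seq_len(n)),
             month = sample(c("m1", "m2", "m3"), n, replace = TRUE),
             W1 = W1, W2 = W2, W3 = W3,
             B1 = B1, B2 = pmax(B1 + rnorm(n, 0, 100), 0),
             B3 = B1 + C1, B4 = runif(n, 0, 900),
             M = runif(n, 5, 15))
}

# weighted least squares by explicit normal equations
ols_oracle <- function(X, y, w = rep(1, length(y))) {
  Xi <- cbind(1, as.matrix(X))
  solve(t(Xi) %*% (w * Xi), t(Xi) %*% (w * y))[, 1]
}

# binomial log-likelihood on a 2-parameter (intercept + slope) model
logistic_ll <- function(beta, x, y, m = rep(1, length(y))) {
  mu <- plogis(beta[1] + beta[2] * x)
  sum(dbinom(y, m, mu, log = TRUE))
}

# brute-force downward stepwise enumerator following the same rule set as
# stepwise_aic(): drop the admissible term whose removal lowers AIC most,
# ties broken by dropping the later term in the declared order
stepwise_oracle <- function(data, y, terms, family, weights = NULL,
                            trials = NULL) {
  comp <- function(tm) strsplit(tm, ":", fixed = TRUE)[[1]]
  admissible <- function(ts) {
    Filter(function(tm) !any(vapply(setdiff(ts, tm), function(o)
      tm %in% comp(o) && length(comp(o)) > length(comp(tm)), logical(1))), ts)
  }
  fit_aic <- function(ts) {
    X <- antcomp:::build_design(data, ts)
    f <- if (family == "gaussian") fit_ols(X, y, weights = weights)
    else fit_logistic(X, y, trials = trials)
    unname(f$aic)
  }
  current <- terms
  cur_aic <- fit_aic(current)
  repeat {
    cand <- admissible(current)
    if (!length(cand)) break
    aics <- vapply(cand, function(tm) fit_aic(setdiff(current, tm)), numeric(1))
    best <- min(aics)
    if (best >= cur_aic) break
    tied <- which(aics - best < 1e-9)
    pick <- tied[which.max(match(cand[tied], terms))]
    current <- setdiff(current, cand[pick])
    cur_aic <- unname(aics[pick])
  }
  list(terms = current, aic = cur_aic)
}
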