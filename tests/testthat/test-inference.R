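test_that("standardize gives z-scores with the n-1 denominator and inverts", {
  expect_equal(as.numeric(standardize(c(1, 2, 3))), c(-1, 0, 1))
  expect_error(standardize(rep(2, 5)), "zero-variance")
  expect_error(standardize(1), "two observations")
  set.seed(1)
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(as.numeric(z) * attr(z, "scale") + attr(z, "center"), x,
               tolerance = 1e-12)
})

test_that("least squares matches the normal-equations oracle and lm", {
  set.seed(21)
  # noise-free planted coefficients are recovered exactly
  z1 <- rnorm(40); z2 <- rnorm(40)
  y <- 0.1 - 0.06 * z1 - 0.013 * z2
  f <- fit_ols(cbind(z1 = z1, z2 = z2), y)
  expect_equal(unname(f$coefficients), c(0.1, -0.06, -0.013), tolerance = 1e-12)

  f0 <- fit_ols(matrix(numeric(0), 40, 0), y)
  expect_equal(unname(f0$coefficients), mean(y))

  for (i in 1:20) {
    n <- sample(8:20, 1); p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    w <- if (i %% 2) runif(n, 0.5, 3) else NULL
    f <- fit_ols(X, y, weights = w)
    expect_equal(unname(f$coefficients),
                 unname(ols_oracle(X, y, if (is.null(w)) rep(1, n) else w)),
                 tolerance = 1e-10)
    lmfit <- if (is.null(w)) lm(y ~ X) else lm(y ~ X, weights = w)
    expect_equal(f$loglik, as.numeric(logLik(lmfit)), tolerance = 1e-8)
    expect_equal(unname(f$se), unname(coef(summary(lmfit))[, 2]),
                 tolerance = 1e-8)
    expect_equal(f$aic, -2 * f$loglik + 2 * f$npar)
  }
  expect_error(fit_ols(cbind(a = 1:5, b = 2 * (1:5)), rnorm(5)),
               "rank deficient")
})

test_that("logistic IRLS attains the grid-oracle likelihood and matches glm", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(20:50, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 - 0.8 * x))
    if (length(unique(y)) < 2) next
    f <- fit_logistic(cbind(x = x), y)
    expect_true(f$converged)
    g <- glm(y ~ x, family = binomial())
    expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
    # the IRLS optimum dominates every point of a fine grid
    grid <- expand.grid(b0 = seq(-4, 4, 0.05), b1 = seq(-4, 4, 0.05))
    grid_best <- max(mapply(function(b0, b1) logistic_ll(c(b0, b1), x, y),
                            grid$b0, grid$b1))
    expect_gte(f$loglik, grid_best - 1e-6)
  }
})

test_that("aggregated binomial counts give the same fit as worker-level rows", {
  set.seed(8)
  n <- 30
  x <- rnorm(n)
  m <- sample(20:60, n, replace = TRUE)
  y <- rbinom(n, m, plogis(0.5 - 0.6 * x))
  agg <- fit_logistic(cbind(x = x), y, trials = m)
  longx <- rep(x, m)
  longy <- unlist(mapply(function(k, mm) rep(1:0, c(k, mm - k)), y, m))
  lng <- fit_logistic(cbind(x = longx), longy)
  expect_equal(agg$coefficients, lng$coefficients, tolerance = 1e-8)
  expect_equal(agg$se, lng$se, tolerance = 1e-8)
})

test_that("degenerate and null logistic problems behave as declared", {
  # one-class outcome: flagged, not silently returned
  f <- fit_logistic(cbind(x = rnorm(20)), rep(1, 20))
  expect_false(f$converged)
  expect_true(f$separated)
  # complete separation is flagged
  x <- c(rep(-2, 10), rep(2, 10))
  y <- c(rep(0, 10), rep(1, 10))
  fs <- fit_logistic(cbind(x = x), y)
  expect_false(fs$converged)
  # zero-effect predictor: slope within 3 SE of zero at n = 1000
  set.seed(55)
  x <- rnorm(1000)
  y <- rbinom(1000, 1, 0.5)
  fz <- fit_logistic(cbind(x = x), y)
  expect_lt(abs(fz$coefficients[["x"]]), 3 * fz$se[["x"]])
})

test_that("Fisher's method is -2 sum log p on 2k degrees of freedom", {
  one <- fishers_method(1)
  expect_equal(one$chi2, 0)
  expect_equal(one$df, 2L)
  f <- fishers_method(c(0.018, 0.028))
  expect_equal(f$chi2, -2 * (log(0.018) + log(0.028)))
  expect_equal(f$chi2, 15.18587, tolerance = 1e-5)
  expect_equal(f$df, 4L)
  expect_equal(f$p_value, pchisq(f$chi2, 4, lower.tail = FALSE))
  # additivity over identical p-values
  expect_equal(fishers_method(rep(0.2, 5))$chi2, 5 * fishers_method(0.2)$chi2)
  expect_error(fishers_method(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("downward stepwise AIC keeps real signals and drops noise", {
  set.seed(77)
  n <- 1000
  d <- data.frame(A = rnorm(n), B = rnorm(n))
  y <- 2 + 1.5 * d$A + rnorm(n)
  sw <- stepwise_aic(d, y, c("A", "B"), family = "gaussian")
  expect_identical(sw$terms, "A")
  # a full model that is already the AIC minimum is a fixed point
  y2 <- 1 + d$A - d$B + 0.8 * d$A * d$B + rnorm(n, 0, 0.5)
  sw2 <- stepwise_aic(d, y2, c("A", "B", "A:B"), family = "gaussian")
  expect_identical(sw2$terms, c("A", "B", "A:B"))
})

test_that("marginality protects main effects but not the linear-under-square", {
  # the admissible-drop rule itself: a main effect is shielded by its
  # interactions, but a squared column does not shield its linear term
  droppable <- antcomp:::droppable_terms
  expect_setequal(droppable(c("A", "A2", "B", "A2:B")), c("A", "A2:B"))
  expect_setequal(droppable(c("A", "B", "A:B")), "A:B")
  expect_setequal(droppable(c("A2", "B", "A2:B")), "A2:B")

  set.seed(78)
  n <- 600
  d <- data.frame(A = rnorm(n), B = rnorm(n))
  d$A2 <- d$A^2
  # noise constructed orthogonal to the null term A, so its removal lowers
  # AIC deterministically while the planted signals stay
  e <- rnorm(n)
  e <- residuals(lm(e ~ A + A2 + B + A:B + A2:B, data = d))
  y <- 1 - 0.8 * d$A2 + 0.5 * d$B + 0.6 * d$A2 * d$B + e
  sw <- stepwise_aic(d, y, c("A", "A2", "B", "A:B", "A2:B"),
                     family = "gaussian")
  expect_true(all(c("A2", "B", "A2:B") %in% sw$terms))
  expect_false("A" %in% sw$terms)   # the square survives without its linear term
  # B could never have been dropped while A2:B was present
  expect_true(is.na(match("drop B", sw$path$action)))
})

test_that("stepwise agrees with a brute-force enumerator on small term sets", {
  set.seed(90)
  for (i in 1:8) {
    n <- 120
    d <- data.frame(A = rnorm(n), B = rnorm(n), C = rnorm(n))
    beta <- round(runif(4, -1, 1) * rbinom(4, 1, 0.6), 2)
    y <- beta[1] * d$A + beta[2] * d$B + beta[3] * d$C +
      beta[4] * d$A * d$B + rnorm(n)
    terms <- c("A", "B", "C", "A:B")
    sw <- stepwise_aic(d, y, terms, family = "gaussian")
    oracle <- stepwise_oracle(d, y, terms, family = "gaussian")
    expect_identical(sort(sw$terms), sort(oracle$terms))
    expect_equal(sw$fit$aic, oracle$aic, tolerance = 1e-9)
    # deterministic given the data
    expect_identical(sw$terms,
                     stepwise_aic(d, y, terms, family = "gaussian")$terms)
  }
  # binomial route too
  set.seed(91)
  n <- 400
  d <- data.frame(A = rnorm(n), B = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.2 + 1.2 * d$A))
  sw <- stepwise_aic(d, y, c("A", "B"), family = "binomial")
  oracle <- stepwise_oracle(d, y, c("A", "B"), family = "binomial")
  expect_identical(sort(sw$terms), sort(oracle$terms))
})

test_that("density-dependence wrapper selects the generating structure", {
  truth <- true_parameters()
  ex <- generate_experiment(400, truth, seed = 61)
  rates <- colony_rates(ex$censuses, ex$densities)
  fit <- fit_density_dependence(rates, "brood")
  expect_true(all(c("conspecific_biomass", "heterospecific_biomass",
                    "conspecific_biomass:heterospecific_biomass") %in% fit$terms))
  s <- summary(fit)
  expect_true(all(c("estimate", "chi2", "p") %in% names(s)))
  lv <- fit_density_dependence(rates, "growth_per_weight")
  expect_true("conspecific_density" %in% lv$terms)
})
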