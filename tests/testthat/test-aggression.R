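base_scenario <- function(...) {
  args <- utils::modifyList(list(p0 = 1, lam = 1, V = 100, r_b = 0.75,
                                 mu = 0.5, q = 1, v_w = 10), list(...))
  do.call(aggression_scenario, args)
}

test_that("theft probability declines from p0 with distance", {
  sc <- base_scenario(p0 = 0.8, lam = 0.5)
  expect_equal(theft_probability(0, sc), 0.8)
  expect_lt(theft_probability(50, sc), 1e-8)
  flat <- base_scenario(p0 = 0.8, lam = 0)
  expect_equal(theft_probability(c(0, 1, 10), flat), rep(0.8, 3))
  d <- seq(0, 10, 0.5)
  expect_true(all(diff(theft_probability(d, sc)) <= 0))
  lg <- base_scenario(p0 = 0.8, decay = "logistic")
  expect_equal(theft_probability(0, lg), 0.8)
  expect_true(all(diff(theft_probability(d, lg)) <= 0))
  expect_error(theft_probability(-1, sc), "non-negative")
})

test_that("net gain matches the outcome-tree enumeration", {
  # independent oracle: enumerate death x repel x theft branches explicitly
  oracle_gain <- function(d, sc) {
    p <- sc$p0 * exp(-sc$lam * d)
    fight <- 0
    for (death in 0:1) for (repel in 0:1) for (theft in 0:1) {
      prob <- (if (death) sc$mu else 1 - sc$mu) *
        (if (repel) sc$q else 1 - sc$q) *
        (if (theft) p else 1 - p)
      loss <- (if (death) sc$v_w else 0) +
        (if (!repel && theft) sc$r_b * sc$V else 0)
      fight <- fight - prob * loss
    }
    avoid <- -(p * sc$r_b * sc$V)
    fight - avoid
  }
  set.seed(14)
  for (i in 1:50) {
    sc <- base_scenario(p0 = runif(1), lam = runif(1, 0, 2),
                        V = runif(1, 0, 200), r_b = runif(1),
                        mu = runif(1), q = runif(1, 0.05, 1),
                        v_w = runif(1, 0, 50))
    d <- runif(1, 0, 6)
    expect_equal(net_fight_gain(d, sc), oracle_gain(d, sc), tolerance = 1e-12)
  }
  # costless defense always pays while theft is possible
  expect_gt(net_fight_gain(3, base_scenario(mu = 0)), 0)
  # nothing to steal: never fight
  expect_lte(net_fight_gain(0, base_scenario(p0 = 0)), 0)
})

test_that("threshold distance has the closed form and matches bisection", {
  sc <- base_scenario()
  expect_equal(threshold_distance(sc), log(15), tolerance = 1e-12)
  expect_equal(threshold_distance(sc), 2.708, tolerance = 1e-3)
  # bisection on the gain function agrees
  root <- uniroot(function(d) net_fight_gain(d, sc), c(0, 50), tol = 1e-10)$root
  expect_equal(threshold_distance(sc), root, tolerance = 1e-6)
  # fighting never pays when the cost dominates even at the entrance
  expect_equal(threshold_distance(base_scenario(mu = 1, v_w = 200)), 0)
  # distance-independent positive gain: always fight
  expect_equal(threshold_distance(base_scenario(lam = 0)), Inf)
  # logistic decay: numeric root still matches independent bisection
  lg <- base_scenario(decay = "logistic", lam = 2)
  root_lg <- uniroot(function(d) net_fight_gain(d, lg), c(0, 50),
                     tol = 1e-10)$root
  expect_equal(threshold_distance(lg), root_lg, tolerance = 1e-6)
})

test_that("the decision is a step in distance: fight near, avoid far", {
  set.seed(27)
  for (i in 1:30) {
    sc <- base_scenario(p0 = runif(1, 0.2, 1), lam = runif(1, 0.2, 2),
                        V = runif(1, 10, 200), r_b = runif(1, 0.25, 1),
                        mu = runif(1, 0.05, 0.9), q = runif(1, 0.2, 1),
                        v_w = runif(1, 1, 40))
    ds <- threshold_distance(sc)
    grid <- seq(0, 8, 0.05)
    dec <- decide(grid, sc)
    expect_identical(dec$fight, grid < ds)
  }
  # near-nest confrontations with high stakes provoke fighting
  expect_true(decide(0.2, base_scenario())$fight)
  # far from the nest the theft risk vanishes and avoidance wins
  expect_false(decide(20, base_scenario())$fight)
  # exactly at the threshold the tie resolves to avoid
  sc <- base_scenario()
  expect_false(decide(threshold_distance(sc), sc)$fight)
})

test_that("heterospecific encounters (nothing stealable) never provoke fighting", {
  sc <- base_scenario(V = 0)
  prof <- aggression_profile(sc, seq(0, 5, 0.5))
  expect_false(any(prof$fight))
  expect_equal(threshold_distance(sc), 0)
})

test_that("the threshold moves the right way with stakes, relatedness and risk", {
  num_dstar <- function(...) threshold_distance(base_scenario(...))
  V <- seq(50, 200, 25)
  expect_true(all(diff(vapply(V, function(v) num_dstar(V = v), numeric(1))) > 0))
  rb <- seq(0.3, 1, 0.1)
  expect_true(all(diff(vapply(rb, function(r) num_dstar(r_b = r), numeric(1))) > 0))
  mu <- seq(0.1, 0.9, 0.1)
  expect_true(all(diff(vapply(mu, function(m) num_dstar(mu = m), numeric(1))) < 0))
  vw <- seq(2, 40, 4)
  expect_true(all(diff(vapply(vw, function(v) num_dstar(v_w = v), numeric(1))) < 0))
})

test_that("scenario validation names the offending field", {
  expect_error(aggression_scenario(1.2, 1, 10, 0.5, 0.5, 1, 1), "p0")
  expect_error(aggression_scenario(0.5, -1, 10, 0.5, 0.5, 1, 1), "lam")
  expect_error(aggression_scenario(0.5, 1, 10, 0.5, 0.5, 0, 1), "q")
})
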