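#' Inclusive-fitness scenario for territorial aggression
#'
#' Parameterizes the decision a worker faces on encountering a conspecific
#' alien at distance `d` from its own nest: fight (risking its own death) or
#' avoid (risking theft of brood and nest). The expected inclusive-fitness
#' gain of fighting over avoiding is
#' \deqn{\Delta(d) = p(d) \, q \, r_b \, V - \mu \, v_w}
#' where `p(d)` is the probability that an unopposed alien encountered at
#' distance `d` steals or usurps the colony's resources, `q` the probability
#' that fighting repels it, `r_b` the worker's relatedness to the brood, `V`
#' the colony-productivity value of the defended resources, `mu` the
#' probability the worker dies fighting, and `v_w` the residual value of the
#' worker's own future work. Because `p(d)` declines with distance, the
#' optimal behaviour is threshold-like: fight near the nest, avoid beyond a
#' critical distance.
#'
#' Heterospecific encounters are represented by setting the stealable value
#' `V` to zero (other species cannot use the brood or nest), which makes
#' avoidance optimal at every distance.
#'
#' @param p0 theft/usurpation probability at the nest entrance (d = 0), in
#'   \[0, 1\].
#' @param lam spatial decay rate of the theft probability, per metre (>= 0).
#' @param V value of the defended resources (brood + nest), colony
#'   productivity units (>= 0).
#' @param r_b worker's relatedness to the brood, in \[0, 1\].
#' @param mu probability the worker dies if it fights, in \[0, 1\].
#' @param q probability a fight repels the alien, in (0, 1\].
#' @param v_w residual value of the worker itself, same units as V (>= 0).
#' @param decay `"exponential"` (default): `p(d) = p0 exp(-lam d)`; or
#'   `"logistic"`: `p(d) = p0 plogis(-lam (d - d_mid))`, a sigmoid
#'   alternative with midpoint `d_mid`.
#' @param d_mid midpoint of the logistic decay (metres).
#' @return validated list of class `aggression_scenario`.
#' @examples
#' sc <- aggression_scenario(p0 = 1, lam = 1, V = 100, r_b = 0.75,
#'                           mu = 0.5, q = 1, v_w = 10)
#' threshold_distance(sc)   # log(15) ~ 2.71 m
#' decide(1, sc)$fight      # TRUE near the nest
#' @export
aggression_scenario <- function(p0, lam, V, r_b, mu, q, v_w,
                                decay = c("exponential", "logistic"),
                                d_mid = 2) {
  decay <- match.arg(decay)
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid scenario: ", msg)
  chk(p0 >= 0 && p0 <= 1, "p0 must lie in [0, 1]")
  chk(lam >= 0, "lam must be >= 0")
  chk(V >= 0 && v_w >= 0, "V and v_w must be >= 0")
  chk(r_b >= 0 && r_b <= 1, "r_b must lie in [0, 1]")
  chk(mu >= 0 && mu <= 1, "mu must lie in [0, 1]")
  chk(q > 0 && q <= 1, "q must lie in (0, 1]")
  structure(list(p0 = p0, lam = lam, V = V, r_b = r_b, mu = mu, q = q,
                 v_w = v_w, decay = decay, d_mid = d_mid),
            class = "aggression_scenario")
}

#' Theft probability at distance d
#'
#' Monotone non-increasing in distance; equals `p0` at the nest entrance.
#'
#' @param d distance from the nest, metres (>= 0); vectorised.
#' @param scenario an [aggression_scenario()].
#' @return probability in \[0, 1\].
#' @export
theft_probability <- function(d, scenario) {
  if (any(d < 0)) stop("distance must be non-negative")
  switch(scenario$decay,
         exponential = scenario$p0 * exp(-scenario$lam * d),
         logistic = scenario$p0 * plogis(-scenario$lam * (d - scenario$d_mid)) /
           plogis(scenario$lam * scenario$d_mid))
}

#' Net inclusive-fitness gain of fighting at distance d
#'
#' `p(d) q r_b V - mu v_w`: the expected resource loss prevented by fighting
#' minus the expected cost of the worker's own death.
#'
#' @inheritParams theft_probability
#' @return net gain in inclusive-fitness units; vectorised over `d`.
#' @export
net_fight_gain <- function(d, scenario) {
  theft_probability(d, scenario) * scenario$q * scenario$r_b * scenario$V -
    scenario$mu * scenario$v_w
}

#' Threshold distance for aggression
#'
#' The distance below which fighting pays. With exponential decay the closed
#' form is \eqn{d^* = (1/\lambda) \log(p_0 q r_b V / (\mu v_w))}, clamped to
#' `[0, Inf)`: `0` when fighting never pays (even at the nest entrance) and
#' `Inf` when it always pays. With `lam = 0` the gain is
#' distance-independent, so `d*` is 0 or `Inf` by its sign; ties (gain
#' exactly zero) resolve to avoid. The logistic decay mode is solved by
#' bisection.
#'
#' @param scenario an [aggression_scenario()].
#' @return threshold distance in metres (possibly 0 or `Inf`).
#' @export
threshold_distance <- function(scenario) {
  gain0 <- net_fight_gain(0, scenario)
  if (gain0 <= 0) return(0)           # never fight, even at the entrance
  A <- scenario$p0 * scenario$q * scenario$r_b * scenario$V
  B <- scenario$mu * scenario$v_w
  if (scenario$lam == 0 || B <= 0) return(Inf)  # gain never decays to zero
  if (scenario$decay == "exponential") return(log(A / B) / scenario$lam)
  # logistic decay: gain is strictly decreasing; bracket then bisect
  hi <- scenario$d_mid + 1
  while (net_fight_gain(hi, scenario) > 0 && hi < 1e6) hi <- hi * 2
  if (net_fight_gain(hi, scenario) > 0) return(Inf)
  uniroot(function(d) net_fight_gain(d, scenario), c(0, hi),
          tol = 1e-10)$root
}

#' Fight-or-avoid decision at distance d
#'
#' Fight iff the net inclusive-fitness gain is strictly positive (ties go to
#' avoid, the risk-free default; gains within 1e-12 of the fight cost are
#' treated as ties so the boundary distance itself resolves to avoid despite
#' floating-point round-off). The decision as a function of distance is a
#' step: fight for all `d < d_star`, avoid for all `d > d_star`.
#'
#' @inheritParams theft_probability
#' @return list of class `aggression_decision`: `fight`, `net_gain`,
#'   `d_star`.
#' @export
decide <- function(d, scenario) {
  gain <- net_fight_gain(d, scenario)
  tie_tol <- 1e-12 * max(1, scenario$mu * scenario$v_w)
  structure(list(fight = gain > tie_tol, net_gain = gain,
                 d_star = threshold_distance(scenario)),
            class = "aggression_decision")
}

#' @export
print.aggression_decision <- function(x, ...) {
  cat(sprintf("decision: %s (net gain %.4g; threshold d* = %.4g m)\n",
              paste(ifelse(x$fight, "FIGHT", "avoid"), collapse = ", "),
              x$net_gain[1], x$d_star))
  invisible(x)
}

#' Decision profile over a distance grid
#'
#' @param scenario an [aggression_scenario()].
#' @param d_grid distances (metres).
#' @return data.frame: `d`, `p_theft`, `net_gain`, `fight`.
#' @export
aggression_profile <- function(scenario, d_grid = seq(0, 6, by = 0.1)) {
  data.frame(d = d_grid,
             p_theft = theft_probability(d_grid, scenario),
             net_gain = net_fight_gain(d_grid, scenario),
             fight = net_fight_gain(d_grid, scenario) > 0)
}
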