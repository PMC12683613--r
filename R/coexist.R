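#' Consumer-resource competition system with interference mortality
#'
#' A chemostat community of consumers competing for one shared resource R:
#' \deqn{dR/dt = D (S - R) - \sum_i c_i f_i(R) N_i}
#' \deqn{dN_i/dt = N_i [ g_i f_i(R) - m_i - \delta_i N_i^{\theta_i} ]}
#' with Monod uptake \eqn{f_i(R) = R / (K_i + R)} (or linear,
#' \eqn{f_i(R) = R}). The \eqn{\delta_i N_i^{\theta_i}} term is conspecific
#' density-dependent excess mortality from interference competition
#' (territorial fighting); \eqn{\delta_i = 0} recovers classical exploitative
#' competition, where the species with the lowest R* excludes all others.
#' Giving the dominant (lowest-R*) species a sufficiently large \eqn{\delta}
#' stabilizes coexistence.
#'
#' @param D resource dilution/turnover rate (per week).
#' @param S_supply supplied resource concentration.
#' @param species data.frame with one row per consumer and columns `g`
#'   (maximal conversion growth rate, per week), `K` (half-saturation), `m`
#'   (baseline mortality, per week), `c` (consumption scale), `delta`
#'   (excess-mortality strength, per week per consumer), and optionally
#'   `theta` (excess-mortality exponent >= 1, default 1).
#' @param uptake `"monod"` (default) or `"linear"`.
#' @return validated list of class `cr_system`.
#' @examples
#' sys <- cr_system(D = 1, S_supply = 2,
#'                  species = data.frame(g = c(2, 1.6), K = 1, m = 0.5,
#'                                       c = c(2, 1.6), delta = c(0.2, 0)))
#' rstar(sys)
#' @export
cr_system <- function(D, S_supply, species, uptake = c("monod", "linear")) {
  uptake <- match.arg(uptake)
  if (!is.data.frame(species) || !all(c("g", "K", "m", "c", "delta") %in% names(species)))
    stop("species must be a data.frame with columns g, K, m, c, delta")
  if (is.null(species$theta)) species$theta <- 1
  if (D < 0 || S_supply < 0) stop("D and S_supply must be non-negative")
  with(species, {
    if (any(c(g, K, m, c, delta) < 0)) stop("all species rates must be non-negative")
    if (any(theta < 1)) stop("theta must be >= 1")
  })
  structure(list(D = D, S_supply = S_supply, species = species,
                 uptake = uptake, n_species = nrow(species)),
            class = "cr_system")
}

#' @export
print.cr_system <- function(x, ...) {
  cat(sprintf("Consumer-resource system (%s uptake): D = %g, S = %g\n",
              x$uptake, x$D, x$S_supply))
  sp <- x$species
  sp$rstar <- vapply(seq_len(nrow(sp)), function(i)
    tryCatch(rstar(x, i), error = function(e) NA_real_), numeric(1))
  print(sp)
  invisible(x)
}

uptake_f <- function(system, R, i) {
  if (system$uptake == "monod") R / (system$species$K[i] + R) else R
}

#' Per-capita growth rate of consumer i
#'
#' \eqn{g_i f_i(R) - m_i - \delta_i N_i^{\theta_i}}.
#'
#' @param system a [cr_system()].
#' @param i species index.
#' @param R resource level (>= 0).
#' @param N_i density of species i (>= 0).
#' @return per-capita growth rate (per week).
#' @export
per_capita_growth <- function(system, i, R, N_i) {
  if (any(R < 0) || any(N_i < 0)) stop("R and N_i must be non-negative")
  sp <- system$species
  sp$g[i] * uptake_f(system, R, i) - sp$m[i] - sp$delta[i] * N_i^sp$theta[i]
}

#' Minimum resource requirement R*
#'
#' The resource level at which per-capita growth is zero in the absence of
#' interference: Monod uptake gives \eqn{R^* = m K / (g - m)}, linear uptake
#' \eqn{R^* = m / g}. The species with the lowest R* wins pure exploitative
#' competition.
#'
#' @param system a [cr_system()].
#' @param i species index (default: all species).
#' @return R* value(s). A species with `g <= m` is nonviable even at
#'   saturating resource; this is signalled as an error naming the species.
#' @export
rstar <- function(system, i = seq_len(system$n_species)) {
  sp <- system$species
  nonviable <- sp$g[i] <= sp$m[i] & sp$m[i] > 0
  if (any(nonviable))
    stop("species ", paste(i[nonviable], collapse = ", "),
         " nonviable: g <= m, growth is negative at any resource level")
  if (system$uptake == "monod") sp$m[i] * sp$K[i] / (sp$g[i] - sp$m[i])
  else sp$m[i] / sp$g[i]
}

cr_rhs <- function(system) {
  sp <- system$species
  function(t, state, parms) {
    R <- max(state[1], 0)
    N <- pmax(state[-1], 0)
    f <- vapply(seq_len(system$n_species), function(i) uptake_f(system, R, i),
                numeric(1))
    dR <- system$D * (system$S_supply - R) - sum(sp$c * f * N)
    dN <- N * (sp$g * f - sp$m - sp$delta * N^sp$theta)
    list(c(dR, dN))
  }
}

#' Integrate the consumer-resource dynamics
#'
#' Stiff-capable adaptive integration via [deSolve::lsoda()]. Densities that
#' go (numerically) negative are clipped to zero when below `atol`; larger
#' negativity is treated as a solver failure and reported with the failing
#' time.
#'
#' @param system a [cr_system()].
#' @param R0 initial resource level.
#' @param N0 vector of initial consumer densities.
#' @param t_end end time (weeks).
#' @param n_steps number of output points.
#' @param rtol,atol solver tolerances.
#' @return data.frame of class `cr_trajectory`: `t`, `R`, `N1`, `N2`, ...
#' @export
simulate_cr <- function(system, R0, N0, t_end = 1000, n_steps = 400,
                        rtol = 1e-8, atol = 1e-10) {
  if (R0 < 0 || any(N0 < 0)) stop("initial state must be non-negative")
  if (length(N0) != system$n_species)
    stop("N0 must have one entry per species")
  times <- seq(0, t_end, length.out = n_steps + 1)
  sol <- deSolve::lsoda(c(R = R0, setNames(N0, paste0("N", seq_along(N0)))),
                        times, cr_rhs(system), parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed at t = ", max(sol[, "time"]))
  out <- as.data.frame(sol)
  names(out)[1] <- "t"
  vals <- as.matrix(out[, -1, drop = FALSE])
  if (min(vals) < -100 * atol)
    stop("solver produced substantially negative densities (min ", min(vals),
         ") at t = ", out$t[which(vals < -100 * atol, arr.ind = TRUE)[1, 1]])
  out[, -1][vals < 0] <- 0
  class(out) <- c("cr_trajectory", class(out))
  out
}

#' @export
plot.cr_trajectory <- function(x, log = "", ...) {
  cols <- setdiff(names(x), "t")
  graphics::matplot(x$t, as.matrix(x[cols]), type = "l", lty = 1,
                    xlab = "time (weeks)", ylab = "density", log = log, ...)
  graphics::legend("topright", legend = cols, col = seq_along(cols), lty = 1,
                   bty = "n")
  invisible(x)
}

# numerical Jacobian of the full RHS at a state (R, N)
cr_jacobian <- function(system, state) {
  rhs <- cr_rhs(system)
  pracma::jacobian(function(s) unlist(rhs(0, s, NULL)), state)
}

#' Interior two-species equilibrium under interference on species 1
#'
#' For a two-species system in which species 1 (the dominant, lower-R*
#' competitor) suffers excess mortality `delta > 0` and species 2 does not,
#' the candidate coexistence equilibrium is: resource pinned at species 2's
#' break-even level \eqn{\hat R = R^*_2}; species 1 held at
#' \eqn{\hat N_1 = [(g_1 f_1(\hat R) - m_1)/\delta_1]^{1/\theta_1}} where its
#' own interference cancels its resource surplus; and species 2 absorbing the
#' leftover resource flux,
#' \eqn{\hat N_2 = [D (S - \hat R) - c_1 f_1(\hat R) \hat N_1] /
#' (c_2 f_2(\hat R))}. The equilibrium is feasible iff both densities are
#' positive; infeasibility is flagged, not errored.
#'
#' @param system a two-species [cr_system()] with `delta[1] > 0` and
#'   `delta[2] == 0`.
#' @return list: `R`, `N` (length 2), `feasible`, `eigenvalues` (of the
#'   numerical Jacobian at the state, when feasible) and `stable`.
#' @export
interior_equilibrium <- function(system) {
  if (system$n_species != 2)
    stop("interior_equilibrium() is defined for exactly two species")
  sp <- system$species
  if (sp$delta[1] <= 0 || sp$delta[2] != 0)
    stop("requires delta > 0 for species 1 and delta = 0 for species 2")
  Rhat <- rstar(system, 2)
  f1 <- uptake_f(system, Rhat, 1)
  surplus1 <- sp$g[1] * f1 - sp$m[1]
  if (surplus1 <= 0)
    return(list(R = Rhat, N = c(0, NA), feasible = FALSE,
                eigenvalues = NULL, stable = NA))
  N1 <- (surplus1 / sp$delta[1])^(1 / sp$theta[1])
  f2 <- uptake_f(system, Rhat, 2)
  N2 <- (system$D * (system$S_supply - Rhat) - sp$c[1] * f1 * N1) /
    (sp$c[2] * f2)
  feasible <- is.finite(N2) && N2 > 0 && N1 > 0
  eig <- NULL
  stable <- NA
  if (feasible) {
    eig <- eigen(cr_jacobian(system, c(Rhat, N1, N2)), only.values = TRUE)$values
    stable <- max(Re(eig)) < -1e-8
  }
  list(R = Rhat, N = c(N1, N2), feasible = feasible,
       eigenvalues = eig, stable = stable)
}

#' Critical interference strength for coexistence
#'
#' Sweeps the excess-mortality strength delta of the dominant species and
#' returns the smallest value at which the interior equilibrium is feasible
#' and locally stable (all Jacobian eigenvalues with real part below
#' -1e-8). For `theta = 1` the feasibility boundary has the closed form
#' \deqn{\delta_{crit} = c_1 f_1(R^*_2) (g_1 f_1(R^*_2) - m_1) /
#'   [D (S - R^*_2)]}
#' which is returned alongside the bisection estimate.
#'
#' @param system a two-species [cr_system()] template (delta of species 1 is
#'   the swept parameter; species 2 must have delta = 0).
#' @param delta_range search interval for the bisection.
#' @param tol bisection tolerance on delta.
#' @return list: `delta_crit` (bisection on feasibility + stability),
#'   `delta_crit_closed_form` (`NA` unless theta = 1), `range_ok`.
#' @export
coexistence_threshold <- function(system, delta_range = c(1e-6, 10),
                                  tol = 1e-8) {
  if (system$n_species != 2) stop("needs exactly two species")
  sp <- system$species
  if (sp$delta[2] != 0) stop("species 2 must have delta = 0")
  rs <- rstar(system)
  if (rs[1] >= rs[2])
    stop("species 1 must be the dominant competitor (lower R*)")
  closed <- NA_real_
  if (sp$theta[1] == 1) {
    Rhat <- rs[2]
    f1 <- uptake_f(system, Rhat, 1)
    closed <- sp$c[1] * f1 * (sp$g[1] * f1 - sp$m[1]) /
      (system$D * (system$S_supply - Rhat))
  }
  ok <- function(delta) {
    sys2 <- system
    sys2$species$delta[1] <- delta
    eq <- interior_equilibrium(sys2)
    isTRUE(eq$feasible) && isTRUE(eq$stable)
  }
  lo <- delta_range[1]; hi <- delta_range[2]
  if (ok(lo)) return(list(delta_crit = lo, delta_crit_closed_form = closed,
                          range_ok = TRUE))
  if (!ok(hi)) return(list(delta_crit = NA_real_,
                           delta_crit_closed_form = closed, range_ok = FALSE))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  list(delta_crit = hi, delta_crit_closed_form = closed, range_ok = TRUE)
}

#' Classify the long-run outcome of a consumer-resource community
#'
#' Integrates the system, applies an extinction threshold (default 1e-6 of
#' each species' initial density), checks that the surviving subcommunity has
#' settled (RHS residual below `resid_tol`), and inspects the Jacobian
#' eigenvalues restricted to the resource + surviving species.
#'
#' Labels: `"collapse"` (no survivors), `"exclusion"` (one survivor; `winner`
#' gives its index), `"stable_coexistence"` (>= 2 survivors, all eigenvalue
#' real parts < -1e-8), or `"non_hyperbolic"` (survivors on a neutral
#' manifold: leading eigenvalue real part within tolerance of zero, as for
#' two identical species). If the trajectory has not converged the label is
#' withheld (`NA`) and diagnostics are returned.
#'
#' @param system a [cr_system()].
#' @param R0,N0 initial state.
#' @param t_end integration horizon (weeks).
#' @param extinction_frac extinction threshold as a fraction of initial
#'   density.
#' @param resid_tol maximum RHS residual accepted as "settled".
#' @return list of class `cr_outcome`: `label`, `winner`, `converged`,
#'   `equilibrium` (final state), `eigenvalues`, `residual`.
#' @export
classify_outcome <- function(system, R0, N0, t_end = 2000,
                             extinction_frac = 1e-6, resid_tol = 1e-6) {
  traj <- simulate_cr(system, R0, N0, t_end = t_end)
  fin <- as.numeric(traj[nrow(traj), -1])
  R <- fin[1]; N <- fin[-1]
  thresh <- extinction_frac * pmax(N0, .Machine$double.eps)
  alive <- which(N > thresh)
  state <- c(R, ifelse(seq_along(N) %in% alive, N, 0))
  resid <- max(abs(unlist(cr_rhs(system)(0, state, NULL))[c(1, 1 + alive)]))
  keep <- c(1, 1 + alive)
  eig <- if (length(alive))
    eigen(cr_jacobian(system, state)[keep, keep, drop = FALSE],
          only.values = TRUE)$values else NULL
  converged <- resid < resid_tol
  label <- if (!converged) NA_character_
  else if (length(alive) == 0) "collapse"
  else if (length(alive) == 1) "exclusion"
  else if (max(Re(eig)) < -1e-8) "stable_coexistence"
  else "non_hyperbolic"
  structure(list(label = label,
                 winner = if (identical(label, "exclusion")) alive else NA_integer_,
                 converged = converged,
                 equilibrium = c(R = R, setNames(N, paste0("N", seq_along(N)))),
                 eigenvalues = eig, residual = resid),
            class = "cr_outcome")
}

#' @export
print.cr_outcome <- function(x, ...) {
  cat("Community outcome:",
      if (is.na(x$label)) "not converged (label withheld)" else x$label)
  if (identical(x$label, "exclusion")) cat(" (winner: species", x$winner, ")")
  cat("\n  final state:", paste(sprintf("%s = %.5g", names(x$equilibrium),
                                        x$equilibrium), collapse = ", "), "\n")
  cat(sprintf("  RHS residual: %.3g; leading eigenvalue Re: %s\n", x$residual,
              if (is.null(x$eigenvalues)) "-" else
                sprintf("%.3g", max(Re(x$eigenvalues)))))
  invisible(x)
}
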