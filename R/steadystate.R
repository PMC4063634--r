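# Analytic steady-state cell distributions for the closed 1D chamber.
#
# The zero-flux steady state of the two-direction run-and-tumble process is
#   P_s(x) \propto v(x)^{-1} exp(-(1/2) \int^x dz(x')/v(x') dx')
# where dz = z_+ - z_- is the tumbling-rate difference between right- and
# left-moving cells, itself set by the activity difference da carried by the
# two sub-populations through their methylation memory.

# infer the signalling mode from the active environment profiles
infer_mode <- function(env) {
  has_L <- !is.null(env$ligand); has_ph <- !is.null(env$ph)
  has_T <- !is.null(env$temp)
  if (has_ph && !has_L && !has_T) return("ph")
  if (has_T && has_L) return("mixed")
  if (has_T) return("thermo")
  if (has_L) return("chemo")
  "none"
}

# locally adapted state along x: temperature, adapted activity, methylation,
# and the spatial derivative of the total free energy at fixed internal state
adapted_state <- function(env, rp, x, mode = infer_mode(env)) {
  T <- temperature_at(env, x, rp$T0)
  a0 <- adapted_activity(T, rp)
  f0 <- log(1 / a0 - 1)
  aT <- alpha_T(T, rp)
  fs <- rep(0, length(x))
  dfdx <- rep(0, length(x))
  if (mode %in% c("chemo", "mixed")) {
    L <- signal_at(env, x, "ligand")
    fs <- fs + rp$N * ligand_log_ratio(L, rp)
    dfdx <- dfdx + rp$N * (1 / (rp$KI + L) - 1 / (rp$KA + L)) *
      signal_slope_at(env, x, "ligand")
  }
  if (mode == "ph") {
    pH <- signal_at(env, x, "ph")
    fs <- fs + rp$N * ph_signal_term(pH, rp)
    dfdx <- dfdx + rp$N * ph_signal_slope(pH, rp) * signal_slope_at(env, x, "ph")
  }
  if (mode %in% c("thermo", "mixed")) {
    m_ss <- rp$m0 + (fs - f0) / (rp$N * aT)
    dfdx <- dfdx + rp$N * rp$dalpha_dT * (rp$m0 - m_ss) *
      signal_slope_at(env, x, "temperature")
  } else {
    m_ss <- rp$m0 + (fs - f0) / (rp$N * aT)
  }
  list(T = T, a0 = a0, f0 = f0, m_ss = m_ss, dfdx = dfdx)
}

#' Effective population sensitivity
#'
#' The dimensionless gain translating a free-energy gradient into the
#' logarithmic slope of the steady-state cell distribution. It factorizes
#' into a receptor gain `N*a0*(1-a0)`, a motor gain `H*(1-B0)/a0` (with `B0`
#' the adapted CW bias), and a damping factor
#' `z_motor / (z_motor + 2*D_r + 1/tau_m)` accounting for the loss of
#' directional persistence to rotational diffusion and, weakly, to the finite
#' adaptation rate.
#'
#' @param rp a [receptor_params()] object.
#' @param mp a [motor_params()] object.
#' @param T temperature (degC) at which the adapted operating point is
#'   evaluated; vectorized.
#' @return An object of class `sensitivity_summary`: a list with `chi` and
#'   its factors `receptor_gain`, `motor_gain`, `damping`.
#' @export
sensitivity_chi <- function(rp, mp, T = rp$T0) {
  a0 <- adapted_activity(T, rp)
  B0 <- cw_bias(a0, mp, T)
  z_motor <- B0 / mp$tau_tumble
  receptor_gain <- rp$N * a0 * (1 - a0)
  motor_gain <- mp$H * (1 - B0) / a0
  damping <- z_motor / (z_motor + 2 * mp$D_r + 1 / rp$tau_m)
  structure(list(chi = receptor_gain * motor_gain * damping,
                 receptor_gain = receptor_gain, motor_gain = motor_gain,
                 damping = damping),
            class = "sensitivity_summary")
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat("Effective population sensitivity\n")
  cat(sprintf("  chi           : %.4g\n", x$chi[1]))
  cat(sprintf("  receptor gain : %.4g\n", x$receptor_gain[1]))
  cat(sprintf("  motor gain    : %.4g\n", x$motor_gain[1]))
  cat(sprintf("  damping       : %.4g\n", x$damping[1]))
  invisible(x)
}

#' Activity difference between right- and left-moving cells
#'
#' In the adiabatic regime (adaptation much slower than runs) the two
#' direction populations carry slightly different methylation memories,
#' giving `da(x) = -2 v a0 (1-a0) F'(x) / (z_eff + 1/tau_m)` where `F'` is
#' the spatial derivative of the total free energy at the locally adapted
#' state. Its sign makes runs up an attractant gradient longer.
#'
#' @param x positions (um).
#' @param env an [environment_1d()].
#' @param rp,mp receptor and motor parameters.
#' @return `da = a_+ - a_-` at each position.
#' @export
activity_difference <- function(x, env, rp, mp) {
  st <- adapted_state(env, rp, x)
  v <- speed_at(env, x, rp$T0)
  z_eff <- tumbling_rate(st$a0, mp, st$T)
  -2 * v * st$a0 * (1 - st$a0) * st$dfdx / (z_eff + 1 / rp$tau_m)
}

#' Tumbling-rate difference between right- and left-moving cells
#'
#' `dz(x) = (dz_motor/da at a0) * da(x)`; same sign as the activity
#' difference since the motor response is monotone.
#'
#' @inheritParams activity_difference
#' @return `dz = z_+ - z_-` in 1/s.
#' @export
tumbling_rate_difference <- function(x, env, rp, mp) {
  st <- adapted_state(env, rp, x)
  motor_rate_slope(st$a0, mp, st$T) * activity_difference(x, env, rp, mp)
}

new_density_profile <- function(df, check = TRUE) {
  if (check) {
    if (any(df$density < 0)) stop("density must be non-negative")
    Z <- trapz(df$x, df$density)
    if (abs(Z - 1) > 1e-8) stop("density not normalized: integral = ", Z)
  }
  class(df) <- c("density_profile", "data.frame")
  df
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Steady-state density profile: %d grid points on [%g, %g]\n",
              nrow(x), min(x$x), max(x$x)))
  peak <- x$x[which.max(x$density)]
  cat(sprintf("  peak at x = %g; density range [%.3g, %.3g] per um\n",
              peak, min(x$density), max(x$density)))
  invisible(x)
}

#' General steady-state cell distribution
#'
#' Evaluates the closed-form zero-flux steady state
#' `P_s(x) = W^-1 v(x)^-1 exp(-(1/2) int dz/v dx')` for any combination of
#' chemical, pH, and thermal profiles, using the locally adapted internal
#' state. The exponent is accumulated by cumulative trapezoid in the log
#' domain and the profile normalized to unit integral.
#'
#' @param env an [environment_1d()].
#' @param rp,mp receptor and motor parameters.
#' @param grid optional positions overriding the environment grid.
#' @param mode signalling mode; inferred from the active profiles by default.
#' @return A `density_profile` data.frame with columns `x`, the active
#'   signal(s), `density`, `activity` (adapted activity along the channel),
#'   `methylation` (adapted methylation), and `potential`
#'   (`-log density`, shifted to minimum 0).
#' @export
steady_state_density <- function(env, rp, mp, grid = NULL,
                                 mode = infer_mode(env)) {
  x <- if (is.null(grid)) env$grid else grid
  st <- adapted_state(env, rp, x, mode)
  v <- speed_at(env, x, rp$T0)
  # accumulate the exponent on a 4x-refined grid (profiles are closed-form,
  # so refinement costs nothing and keeps the trapezoid error negligible)
  xf <- refine_grid(x, 4L)
  dzf <- tumbling_rate_difference(xf, env, rp, mp)
  vf <- speed_at(env, xf, rp$T0)
  Ef <- -0.5 * cumtrapz(xf, dzf / vf)
  logd <- Ef[seq(1, length(xf), by = 4L)] - log(v)
  dens <- normalize_log_density(x, logd)
  df <- data.frame(x = x)
  if (!is.null(env$ligand)) df$ligand <- signal_at(env, x, "ligand")
  if (!is.null(env$ph)) df$ph <- signal_at(env, x, "ph")
  if (!is.null(env$temp)) df$temperature <- signal_at(env, x, "temperature")
  df$density <- dens
  df$activity <- st$a0
  df$methylation <- st$m_ss
  df$potential <- -log(dens) - min(-log(dens))
  new_density_profile(df)
}

#' Closed-form chemotaxis distribution
#'
#' For a single attractant at constant swimming speed the steady state is
#' `P_s(x) \propto [(1 + L(x)/KI) / (1 + L(x)/KA)]^chi`, with `chi` the
#' effective population sensitivity.
#'
#' @param env an [environment_1d()] with a ligand profile.
#' @param chi effective sensitivity (a number or a `sensitivity_summary`).
#' @param rp a [receptor_params()] object.
#' @param grid optional positions overriding the environment grid.
#' @return A `density_profile` data.frame.
#' @export
chemotaxis_closed_form <- function(env, chi, rp, grid = NULL) {
  if (inherits(chi, "sensitivity_summary")) chi <- chi$chi
  x <- if (is.null(grid)) env$grid else grid
  L <- signal_at(env, x, "ligand")
  logd <- chi * ligand_log_ratio(L, rp)
  dens <- normalize_log_density(x, logd)
  st <- adapted_state(env, rp, x, "chemo")
  new_density_profile(data.frame(
    x = x, ligand = L, density = dens, activity = st$a0,
    methylation = st$m_ss,
    potential = -log(dens) - min(-log(dens))))
}

#' Fit the effective sensitivity to a density profile
#'
#' Least-squares fit of log-density against the log of the chemotaxis kernel
#' `log((1 + L/KI)/(1 + L/KA))`; the slope estimates `chi`. Bins with zero
#' density (possible in simulated histograms) are dropped.
#'
#' The closed form describes the chamber bulk; within roughly one
#' persistence length of a reflecting wall the just-reflected cells carry
#' direction-mismatched methylation memory and the profile flattens. For
#' simulated histograms, `trim` excludes that boundary layer from the fit.
#'
#' @param profile a `density_profile` (analytic or simulated histogram).
#' @param env the environment supplying the ligand profile.
#' @param rp a [receptor_params()] object (for `KI`, `KA`).
#' @param trim length (um) excluded at each end of the domain.
#' @return A list with `chi`, `r_squared`, and `residual_se`.
#' @export
fit_chi <- function(profile, env, rp, trim = 0) {
  keep <- profile$density > 0 &
    profile$x >= env$x_min + trim & profile$x <= env$x_max - trim
  kernel <- ligand_log_ratio(signal_at(env, profile$x[keep], "ligand"), rp)
  if (stats::sd(kernel) < 1e-12)
    stop("degenerate (constant) chemotaxis kernel; cannot fit chi")
  fit <- stats::lm(log(profile$density[keep]) ~ kernel)
  s <- suppressWarnings(summary(fit))  # a perfect fit is a legitimate input
  list(chi = unname(stats::coef(fit)[2]), r_squared = s$r.squared,
       residual_se = s$sigma)
}

#' Effective potential of a density profile
#'
#' `U(x) = -log P_s(x)`, shifted so that `min U = 0`. Minima of `U` mark
#' accumulation points.
#'
#' @param profile a `density_profile`.
#' @return Numeric vector of potential values along the grid.
#' @export
effective_potential <- function(profile) {
  if (any(profile$density <= 0))
    stop("effective potential undefined where density is zero")
  U <- -log(profile$density)
  U - min(U)
}

#' Preferred accumulation point
#'
#' Finds the interior zero of the drift integrand (the derivative of the
#' steady-state exponent), i.e. the point where the push-pull balance of the
#' sensory response changes sign. With constant speed this is the density
#' maximum. If the drift does not change sign inside the domain the cells
#' accumulate at a boundary, which is reported with `interior = FALSE`.
#'
#' @param env an [environment_1d()].
#' @param rp,mp receptor and motor parameters.
#' @param mode signalling mode; inferred by default.
#' @return A list with `x_star`, `signal` (the pH or temperature there),
#'   `interior`, and `roots` (all interior sign changes found).
#' @export
preferred_point <- function(env, rp, mp, mode = infer_mode(env)) {
  h <- (env$x_max - env$x_min) * 1e-7
  drift <- function(x) {
    st <- adapted_state(env, rp, x, mode)
    chi <- sensitivity_chi(rp, mp, st$T)$chi
    # d(log P)/dx: sensing exponent derivative minus the local speed term
    xp <- pmin(x + h, env$x_max); xm <- pmax(x - h, env$x_min)
    dlogv <- (log(speed_at(env, xp, rp$T0)) - log(speed_at(env, xm, rp$T0))) /
      (xp - xm)
    (chi / rp$N) * st$dfdx - dlogv
  }
  x <- env$grid
  s <- drift(x)
  sgn <- sign(s)
  roots <- numeric(0); is_max <- logical(0)
  # a node where the drift vanishes exactly is itself a root
  for (i in which(sgn == 0)) {
    if (i > 1 && i < length(x) && sgn[i - 1] != 0 && sgn[i + 1] != 0 &&
        sgn[i - 1] != sgn[i + 1]) {
      roots <- c(roots, x[i])
      is_max <- c(is_max, sgn[i - 1] > 0)
    }
  }
  idx <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  for (i in idx) {
    roots <- c(roots, stats::uniroot(drift, c(x[i], x[i + 1]),
                                     tol = 1e-10)$root)
    is_max <- c(is_max, sgn[i] > 0)
  }
  ord <- order(roots)
  roots <- roots[ord]; is_max <- is_max[ord]
  sig_kind <- switch(mode, ph = "ph", thermo = "temperature",
                     mixed = "temperature", "ligand")
  if (length(roots[is_max]) == 0) {
    x_star <- if (s[1] < 0) x[1] else x[length(x)]
    return(list(x_star = x_star,
                signal = signal_at(env, x_star, sig_kind),
                interior = FALSE, roots = roots))
  }
  if (sum(is_max) > 1)
    warning("multiple interior accumulation points; reporting the first")
  x_star <- roots[is_max][1]
  list(x_star = x_star, signal = signal_at(env, x_star, sig_kind),
       interior = TRUE, roots = roots)
}

#' Tunability of the preferred pH
#'
#' Computes the preferred pH for a set of Tar/Tsr abundance ratios and
#' regresses it on `log10(ratio)`. The magnitude of the slope is the
#' tunability coefficient `eta`: how many pH units the preferred point moves
#' per decade of receptor-ratio change.
#'
#' @param ratios Tar/Tsr abundance ratios (>= 4 values spanning at least one
#'   decade).
#' @param env an [environment_1d()] with a pH profile.
#' @param rp receptor parameters; the pH regime (pK values) is taken from
#'   here while `f_a`, `f_s` are swept.
#' @param mp motor parameters.
#' @return A list with `eta`, `r_squared`, `intercept`, and the scan `table`
#'   (ratio, f_a, pH*).
#' @export
ph_tunability <- function(ratios, env, rp, mp) {
  if (length(ratios) < 4 || diff(range(log10(ratios))) < 1)
    stop("need >= 4 ratios spanning at least one decade")
  rows <- lapply(ratios, function(r) {
    f_a <- r / (1 + r)
    rp_i <- rp
    rp_i$ph$f_a <- f_a; rp_i$ph$f_s <- 1 - f_a
    pp <- preferred_point(env, rp_i, mp, mode = "ph")
    if (!pp$interior) {
      warning("preferred pH hits the boundary at ratio ", signif(r, 3),
              "; point excluded")
      return(NULL)
    }
    data.frame(ratio = r, f_a = f_a, ph_star = pp$signal)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3)
    stop("too few interior preferred points for a tunability fit")
  fit <- stats::lm(ph_star ~ log10(ratio), data = tab)
  s <- summary(fit)
  list(eta = unname(abs(stats::coef(fit)[2])),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared, table = tab)
}

#' Dispersion of a population on the signal axis
#'
#' Standard deviation of the stationary cell distribution measured in signal
#' units (e.g. pH or degC), i.e. the density-weighted second moment of the
#' signal value over the chamber.
#'
#' @param profile a `density_profile` containing the signal column.
#' @param signal_axis column name: `"ph"`, `"temperature"`, `"ligand"`, or
#'   `"x"`.
#' @return Standard deviation in signal units.
#' @export
dispersion <- function(profile, signal_axis = "ph") {
  if (!signal_axis %in% names(profile))
    stop("profile has no column '", signal_axis, "'")
  s <- profile[[signal_axis]]
  mu <- trapz(profile$x, s * profile$density)
  sqrt(trapz(profile$x, (s - mu)^2 * profile$density))
}

#' Steady state in a linear temperature gradient
#'
#' The general solver evaluated with the thermal free energy. The result also
#' carries (as attribute `"leading_order"`) the near-critical Gaussian
#' approximation obtained by keeping the leading order of the sensory
#' exponent around the critical temperature, for diagnostic comparison.
#'
#' @inheritParams steady_state_density
#' @return A `density_profile`; `attr(., "leading_order")` holds the
#'   approximate density and `attr(., "T_c")` the critical temperature.
#' @export
thermo_density <- function(env, rp, mp, grid = NULL) {
  prof <- steady_state_density(env, rp, mp, grid, mode = "thermo")
  T_c <- critical_temperature(rp)
  Tg <- prof$temperature
  chi_c <- sensitivity_chi(rp, mp, T_c)$chi
  dF0 <- -rp$da0_dT / (adapted_activity(T_c, rp) * (1 - adapted_activity(T_c, rp)))
  curv <- (chi_c / rp$N) * (rp$dalpha_dT / alpha_T(T_c, rp)) * abs(dF0)
  v <- speed_at(env, prof$x, rp$T0)
  lo <- normalize_log_density(prof$x, -0.5 * curv * (Tg - T_c)^2 - log(v))
  attr(prof, "leading_order") <- data.frame(x = prof$x, density = lo)
  attr(prof, "T_c") <- T_c
  prof
}

#' Steady state under combined thermal and chemical gradients
#'
#' Tar-only cells in a temperature gradient with a superimposed attractant
#' profile. The exponent contains the chemotactic drift term plus the
#' chemo-thermal interference term arising from the ligand dependence of the
#' adapted methylation level; with no ligand it reduces exactly to
#' [thermo_density()].
#'
#' @inheritParams steady_state_density
#' @return A `density_profile`.
#' @export
combined_density <- function(env, rp, mp, grid = NULL) {
  steady_state_density(env, rp, mp, grid, mode = "mixed")
}
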