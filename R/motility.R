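#' Flagellar-motor parameters
#'
#' @param H motor Hill coefficient: ultrasensitivity of the clockwise (CW)
#'   bias to kinase activity (dimensionless, > 0).
#' @param K_ref activity at half-maximal CW bias at the reference temperature,
#'   in (0, 1).
#' @param kappa fractional slope of the motor switching threshold with
#'   temperature (1/degC): `K(T) = K_ref * (1 + kappa * (T - T0))`. The
#'   observed increase of K with temperature compensates the increase of the
#'   adapted kinase activity, keeping the motor in its sensitive range.
#' @param tau_tumble tumble duration (s, > 0); sets the tumble-rate
#'   normalization `z_motor = CW_bias / tau_tumble`.
#' @param D_r rotational diffusion rate (1/s, >= 0). In the one-dimensional
#'   projection it contributes a direction-decorrelation rate of `2 * D_r`.
#' @param T0 reference temperature (degC) for `K(T)`.
#' @return An object of class `motor_params`.
#' @export
motor_params <- function(H = 10, K_ref = 0.605, kappa = 0, tau_tumble = 0.1,
                         D_r = 0.062, T0 = 25) {
  stopifnot(H > 0, K_ref > 0, K_ref < 1, tau_tumble > 0, D_r >= 0)
  structure(list(H = H, K_ref = K_ref, kappa = kappa,
                 tau_tumble = tau_tumble, D_r = D_r, T0 = T0),
            class = "motor_params")
}

#' Motor switching threshold at a given temperature
#'
#' `K(T) = K_ref * (1 + kappa * (T - T0))`, the activity at which the CW bias
#' is one half.
#'
#' @param T temperature (degC); may be a vector.
#' @param mp a [motor_params()] object.
#' @return Threshold activity in (0, 1).
#' @export
motor_K <- function(T, mp) {
  K <- mp$K_ref * (1 + mp$kappa * (T - mp$T0))
  if (any(K <= 0 | K >= 1))
    stop("motor threshold K(T) leaves (0, 1) on the requested range")
  K
}

#' Clockwise bias of the flagellar motor
#'
#' Hill response of the CW bias to kinase activity:
#' `B(a) = a^H / (a^H + K(T)^H)`, equal to 1/2 at `a = K(T)`.
#'
#' @param a kinase activity in (0, 1); may be a vector.
#' @param mp a [motor_params()] object.
#' @param T temperature (degC).
#' @return CW bias in (0, 1), strictly increasing in `a`.
#' @export
cw_bias <- function(a, mp, T = mp$T0) {
  if (any(a <= 0 | a >= 1)) stop("activity must lie strictly in (0, 1)")
  K <- motor_K(T, mp)
  aH <- a^mp$H
  aH / (aH + K^mp$H)
}

#' Effective tumbling (direction-decorrelation) rate
#'
#' `z_eff = z_motor + z_rot` where `z_motor = cw_bias(a) / tau_tumble` is the
#' rate of entering the tumbling state and `z_rot = 2 * D_r` is the
#' decorrelation rate contributed by rotational diffusion in the 1D
#' projection. Strictly increasing in `a`.
#'
#' @inheritParams cw_bias
#' @param components if `TRUE`, return a list with `z_motor`, `z_rot`, and
#'   `z_eff` instead of the scalar total.
#' @return Rate in 1/s.
#' @export
tumbling_rate <- function(a, mp, T = mp$T0, components = FALSE) {
  z_motor <- cw_bias(a, mp, T) / mp$tau_tumble
  z_rot <- 2 * mp$D_r
  if (components)
    list(z_motor = z_motor, z_rot = z_rot, z_eff = z_motor + z_rot)
  else z_motor + z_rot
}

# dz_motor/da at activity a (1/s per unit activity)
motor_rate_slope <- function(a, mp, T = mp$T0) {
  B <- cw_bias(a, mp, T)
  mp$H * B * (1 - B) / (a * mp$tau_tumble)
}

#' Swimming-speed profile
#'
#' @param kind one of `"constant"`, `"linear_in_T"`, `"quadratic_in_T"`,
#'   `"custom"`.
#' @param v0 reference speed (um/s, > 0). For `linear_in_T` this is the speed
#'   at `T_ref`; for `quadratic_in_T` the peak speed at `T_peak`.
#' @param dv_dT slope for the linear form (um/s/degC).
#' @param T_ref reference temperature for the linear form (degC).
#' @param T_peak temperature of maximal speed for the quadratic form (degC).
#' @param curvature positive coefficient `c` of the quadratic form
#'   `v = v0 - c * (T - T_peak)^2` (um/s/degC^2).
#' @param table two-column data.frame (`x` or `T`, `v`) for `"custom"`;
#'   linearly interpolated. The first column name decides whether the profile
#'   is indexed by position or temperature.
#' @return An object of class `speed_profile`.
#' @export
speed_profile <- function(kind = c("constant", "linear_in_T", "quadratic_in_T",
                                   "custom"),
                          v0 = 20, dv_dT = 0, T_ref = 25,
                          T_peak = NULL, curvature = 0, table = NULL) {
  kind <- match.arg(kind)
  stopifnot(v0 > 0)
  if (kind == "quadratic_in_T" && is.null(T_peak))
    stop("quadratic_in_T requires T_peak")
  if (kind == "custom") {
    if (is.null(table) || ncol(table) != 2)
      stop("custom speed profile requires a two-column table")
    if (any(table[[2]] <= 0)) stop("custom speed values must be positive")
  }
  structure(list(kind = kind, v0 = v0, dv_dT = dv_dT, T_ref = T_ref,
                 T_peak = T_peak, curvature = curvature, table = table),
            class = "speed_profile")
}

#' Evaluate a speed profile
#'
#' @param sp a [speed_profile()].
#' @param x position (for `"custom"` profiles indexed by position).
#' @param T temperature (for the temperature-dependent forms).
#' @return Speed in um/s (strictly positive; an error otherwise).
#' @export
speed <- function(sp, x = NULL, T = NULL) {
  v <- switch(sp$kind,
    constant = rep(sp$v0, max(length(x), length(T), 1)),
    linear_in_T = {
      if (is.null(T)) stop("linear_in_T profile needs a temperature")
      sp$v0 + sp$dv_dT * (T - sp$T_ref)
    },
    quadratic_in_T = {
      if (is.null(T)) stop("quadratic_in_T profile needs a temperature")
      sp$v0 - sp$curvature * (T - sp$T_peak)^2
    },
    custom = {
      key <- if (names(sp$table)[1] == "T") T else x
      if (is.null(key)) stop("custom profile index not supplied")
      stats::approx(sp$table[[1]], sp$table[[2]], xout = key, rule = 2)$y
    })
  if (any(v <= 0)) stop("speed profile is non-positive at a query point")
  v
}
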