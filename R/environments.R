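#' One-dimensional closed-chamber environment
#'
#' A finite interval with zero-flux (reflecting) boundaries carrying up to
#' three signal profiles (chemoattractant, pH, temperature) and a swimming
#' speed profile. Profiles are closed-form (`linear`, `exponential`) or
#' tabulated (`custom`, linearly interpolated).
#'
#' @param x_min,x_max domain endpoints (um), `x_min < x_max`.
#' @param n_grid number of grid points (>= 64).
#' @param ligand,ph,temp profile descriptors: `NULL` (inactive) or a list
#'   with `kind = "linear"` (`from`, `to`: endpoint values),
#'   `kind = "exponential"` (`value0`, `rate`: `S(x) = value0*exp(rate*x)`,
#'   ligand only), or `kind = "custom"` (`x`, `value` vectors).
#' @param speed a [speed_profile()].
#' @return An object of class `environment_1d` with a cell-centered
#'   evaluation grid in `$grid`.
#' @export
environment_1d <- function(x_min = 0, x_max = 400, n_grid = 513,
                           ligand = NULL, ph = NULL, temp = NULL,
                           speed = speed_profile("constant")) {
  stopifnot(x_min < x_max, n_grid >= 64)
  for (pr in list(ligand, ph, temp)) {
    if (!is.null(pr) && !pr$kind %in% c("linear", "exponential", "custom"))
      stop("unknown profile kind: ", pr$kind)
  }
  if (!is.null(ligand)) {
    lv <- profile_values(ligand, c(x_min, x_max), x_min, x_max)
    if (any(lv < 0)) stop("ligand profile must be non-negative")
  }
  env <- structure(list(x_min = x_min, x_max = x_max,
                        grid = seq(x_min, x_max, length.out = n_grid),
                        ligand = ligand, ph = ph, temp = temp,
                        speed = speed, boundary = "zero-flux"),
                   class = "environment_1d")
  # fail early if the speed profile is not positive on the whole domain
  invisible(speed_at(env, env$grid))
  env
}

profile_values <- function(pr, x, x_min, x_max) {
  switch(pr$kind,
    linear = pr$from + (pr$to - pr$from) * (x - x_min) / (x_max - x_min),
    exponential = pr$value0 * exp(pr$rate * (x - x_min)),
    custom = stats::approx(pr$x, pr$value, xout = x, rule = 1)$y)
}

profile_slopes <- function(pr, x, x_min, x_max) {
  switch(pr$kind,
    linear = rep((pr$to - pr$from) / (x_max - x_min), length(x)),
    exponential = pr$rate * profile_values(pr, x, x_min, x_max),
    custom = {
      h <- (x_max - x_min) * 1e-6
      xp <- pmin(x + h, x_max); xm <- pmax(x - h, x_min)
      (stats::approx(pr$x, pr$value, xout = xp, rule = 2)$y -
       stats::approx(pr$x, pr$value, xout = xm, rule = 2)$y) / (xp - xm)
    })
}

#' Evaluate a signal profile
#'
#' @param env an [environment_1d()].
#' @param x positions inside the domain.
#' @param kind one of `"ligand"`, `"ph"`, `"temperature"`.
#' @return Signal values at `x`.
#' @export
signal_at <- function(env, x, kind = c("ligand", "ph", "temperature")) {
  kind <- match.arg(kind)
  if (any(x < env$x_min | x > env$x_max)) stop("position outside the domain")
  pr <- switch(kind, ligand = env$ligand, ph = env$ph, temperature = env$temp)
  if (is.null(pr)) stop("no ", kind, " profile in this environment")
  profile_values(pr, x, env$x_min, env$x_max)
}

signal_slope_at <- function(env, x, kind) {
  pr <- switch(kind, ligand = env$ligand, ph = env$ph, temperature = env$temp)
  if (is.null(pr)) return(rep(0, length(x)))
  profile_slopes(pr, x, env$x_min, env$x_max)
}

# temperature at x, defaulting to the reference temperature when no thermal
# profile is active
temperature_at <- function(env, x, T_default) {
  if (is.null(env$temp)) rep(T_default, length(x))
  else profile_values(env$temp, x, env$x_min, env$x_max)
}

speed_at <- function(env, x, T_default = 25) {
  sp <- env$speed
  if (sp$kind %in% c("linear_in_T", "quadratic_in_T") ||
      (sp$kind == "custom" && names(sp$table)[1] == "T")) {
    speed(sp, T = temperature_at(env, x, T_default))
  } else {
    speed(sp, x = x)
  }
}

#' Build a single linear-gradient environment
#'
#' @param kind which signal carries the gradient: `"ligand"`, `"ph"`, or
#'   `"temperature"`.
#' @param value_at_min,value_at_max endpoint signal values.
#' @param x_min,x_max domain endpoints (um).
#' @param ... further arguments to [environment_1d()] (e.g. `speed`,
#'   `n_grid`).
#' @return An [environment_1d()] whose `steepness` attribute reports
#'   `(value_at_max - value_at_min) / (x_max - x_min)`.
#' @export
make_linear_gradient <- function(kind = c("ligand", "ph", "temperature"),
                                 value_at_min, value_at_max,
                                 x_min = 0, x_max = 400, ...) {
  kind <- match.arg(kind)
  if (kind == "ligand" && (value_at_min < 0 || value_at_max < 0))
    stop("ligand endpoint values must be >= 0")
  pr <- list(kind = "linear", from = value_at_min, to = value_at_max)
  args <- list(x_min = x_min, x_max = x_max, ...)
  args[[switch(kind, ligand = "ligand", ph = "ph", temperature = "temp")]] <- pr
  env <- do.call(environment_1d, args)
  attr(env, "steepness") <- (value_at_max - value_at_min) / (x_max - x_min)
  env
}

#' Scenario fixtures
#'
#' Ready-made scenario configurations (environment plus receptor and motor
#' parameters) for the four scenario families. All channels are closed
#' (zero-flux); lengths, gradients and parameter defaults are package
#' choices documented in the methods vignette.
#'
#' * `fixture_chemotaxis()`: linear attractant gradient in a 400 um channel,
#'   constant speed.
#' * `fixture_ph()`: linear pH gradient (5.8 to 8.2) in an 800 um channel,
#'   constant speed; `regime` selects the Tar/Tsr dissociation-constant
#'   regime and `f_a` the Tar fraction.
#' * `fixture_thermo()`: linear temperature gradient (20 to 30 degC) in a
#'   500 um channel; speed constant or temperature-dependent.
#' * `fixture_combined()`: the thermotaxis fixture plus an opposing
#'   attractant gradient (`grad_L` in uM/cm, concentration fixed at the
#'   channel midpoint), Tar-only cells.
#'
#' @param L_min,L_max attractant endpoint concentrations (uM).
#' @param length channel length (um).
#' @param n_grid grid resolution.
#' @return A list with elements `env`, `receptor`, `motor`, and `scenario`.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_chemotaxis <- function(L_min = 0, L_max = 1, length = 400,
                               n_grid = 513) {
  list(scenario = "chemo",
       env = make_linear_gradient("ligand", L_min, L_max, 0, length,
                                  n_grid = n_grid),
       receptor = receptor_params(),
       motor = motor_params())
}

#' @rdname fixtures
#' @param ph_min,ph_max pH endpoint values.
#' @param regime shipped pH regime name, see [ph_regime()].
#' @param f_a Tar fraction.
#' @export
fixture_ph <- function(ph_min = 5.8, ph_max = 8.2, length = 800,
                       regime = "balanced", f_a = 0.5, n_grid = 513) {
  list(scenario = "ph",
       env = make_linear_gradient("ph", ph_min, ph_max, 0, length,
                                  n_grid = n_grid),
       receptor = receptor_params(ph = ph_regime(regime, f_a = f_a)),
       motor = motor_params())
}

#' @rdname fixtures
#' @param T1,T2 temperature endpoints (degC).
#' @param speed a [speed_profile()]; the default is constant.
#' @param kappa motor-threshold temperature slope (1/degC).
#' @export
fixture_thermo <- function(T1 = 20, T2 = 30, length = 500,
                           speed = speed_profile("constant"),
                           kappa = 0, n_grid = 513) {
  list(scenario = "thermo",
       env = make_linear_gradient("temperature", T1, T2, 0, length,
                                  n_grid = n_grid, speed = speed),
       receptor = receptor_params(),
       motor = motor_params(kappa = kappa))
}

#' @rdname fixtures
#' @param grad_L opposing attractant gradient magnitude (uM/cm); the ligand
#'   decreases left to right while temperature increases.
#' @param L_mid attractant concentration at the channel midpoint (uM).
#' @export
fixture_combined <- function(grad_L = 3, L_mid = 0.2, T1 = 20, T2 = 30,
                             length = 500, n_grid = 513,
                             speed = speed_profile("constant")) {
  dL <- grad_L * 1e-4 * length / 2        # uM/cm -> uM over half-channel
  L_from <- L_mid + dL; L_to <- L_mid - dL
  if (L_to < 0) stop("opposing gradient drives the ligand negative; reduce ",
                     "grad_L or raise L_mid")
  env <- environment_1d(0, length, n_grid = n_grid,
                        ligand = list(kind = "linear", from = L_from, to = L_to),
                        temp = list(kind = "linear", from = T1, to = T2),
                        speed = speed)
  list(scenario = "mixed", env = env,
       receptor = receptor_params(), motor = motor_params())
}
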