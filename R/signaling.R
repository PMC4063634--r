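#' Receptor-cluster parameters
#'
#' Bundles every parameter of the Monod-Wyman-Changeux (MWC) receptor-cluster
#' model and its methylation adaptation dynamics: cooperativity, methylation
#' energetics, ligand dissociation constants, per-receptor-type pH dissociation
#' constants, and the linear temperature dependences of the methylation
#' free-energy coefficient and of the adapted activity.
#'
#' The free-energy convention used throughout the package: the total
#' free-energy difference `f` between the active and inactive conformations
#' carries the cooperativity factor `N` internally, so the cluster activity is
#' `a = 1/(1 + exp(f))` with `f = N * (alpha(T)*(m0 - m) + f_signal)`.
#'
#' @param N receptor cooperativity (dimensionless, > 0).
#' @param alpha0 free-energy change per added methyl group at the reference
#'   temperature (kT per methyl, > 0).
#' @param m0 reference methylation level (dimensionless).
#' @param a0_ref adapted activity at the reference temperature, in (0, 1).
#' @param tau_m adaptation timescale in seconds: the linearized relaxation
#'   time of the activity after a small stimulus step.
#' @param KI,KA dissociation constants of the inactive and active receptor
#'   conformations for the chemoattractant (same concentration units as the
#'   ligand profile; `KI < KA` for an attractant).
#' @param ph named list with entries `pKI_tar`, `pKA_tar`, `pKI_tsr`,
#'   `pKA_tsr` (pH-scale dissociation constants) and receptor fractions
#'   `f_a` (Tar) and `f_s` (Tsr), `f_a + f_s = 1`. Tar responds to a pH
#'   decrease as to an attractant (`pKI_tar > pKA_tar`), Tsr oppositely
#'   (`pKI_tsr < pKA_tsr`). See [ph_regime()] for shipped parameter regimes.
#' @param dalpha_dT slope of the methylation free-energy coefficient with
#'   temperature (kT/degC/methyl). Its sign must equal the sign of `da0_dT`
#'   for cells to accumulate at the critical temperature rather than flee it.
#' @param da0_dT slope of the adapted activity with temperature (1/degC).
#' @param T0 reference temperature (degC).
#' @param m_c critical methylation level at which the thermal response of the
#'   receptor inverts. Under the linear `alpha(T)` form this equals `m0`.
#'
#' @return An object of class `receptor_params`.
#' @seealso [motor_params()], [activity()], [adapted_methylation()]
#' @export
receptor_params <- function(N = 6, alpha0 = 2, m0 = 1, a0_ref = 0.5,
                            tau_m = 10, KI = 18, KA = 3000,
                            ph = ph_regime("balanced"),
                            dalpha_dT = 0.2, da0_dT = 0.01, T0 = 25,
                            m_c = m0) {
  stopifnot(is.numeric(N), N > 0, alpha0 > 0, tau_m > 0)
  if (!(a0_ref > 0 && a0_ref < 1))
    stop("a0_ref must lie strictly in (0, 1)")
  if (!(KI < KA))
    stop("attractant convention requires KI < KA")
  ph <- validate_ph_params(ph)
  p <- list(N = N, alpha0 = alpha0, m0 = m0, a0_ref = a0_ref, tau_m = tau_m,
            KI = KI, KA = KA, ph = ph, dalpha_dT = dalpha_dT,
            da0_dT = da0_dT, T0 = T0, m_c = m_c)
  class(p) <- "receptor_params"
  p
}

validate_ph_params <- function(ph) {
  need <- c("pKI_tar", "pKA_tar", "pKI_tsr", "pKA_tsr", "f_a", "f_s")
  if (!all(need %in% names(ph)))
    stop("ph parameters must contain: ", paste(need, collapse = ", "))
  if (abs(ph$f_a + ph$f_s - 1) > 1e-12)
    stop("receptor fractions must satisfy f_a + f_s = 1")
  if (ph$f_a < 0 || ph$f_a > 1)
    stop("receptor fractions must lie in [0, 1]")
  if (ph$f_a > 0 && !(ph$pKI_tar > ph$pKA_tar))
    stop("Tar pH constants must satisfy pKI_tar > pKA_tar ",
         "(attractant response to a pH decrease)")
  if (ph$f_s > 0 && !(ph$pKI_tsr < ph$pKA_tsr))
    stop("Tsr pH constants must satisfy pKI_tsr < pKA_tsr ",
         "(attractant response to a pH increase)")
  ph
}

#' Shipped pH dissociation-constant regimes
#'
#' Three representative parameter regimes for the Tar/Tsr pH response,
#' distinguished by the tunability coefficient `eta` of the preferred pH with
#' respect to the Tar/Tsr ratio (see [ph_tunability()]):
#'
#' * `"subdued"`: both receptors sense through far exponential tails of their
#'   titration terms; `eta` is about 1/2 and the population accumulates
#'   loosely.
#' * `"balanced"` (default): Tar in its exponential tail against a softly
#'   saturating Tsr term; `eta` is about 1 and the stationary distribution is
#'   the sharpest of the three regimes (highest accuracy).
#' * `"tunable"`: all four pK values close to the preferred pH; `eta` is
#'   about 2 (highly tunable preferred point, broader distribution).
#'
#' @param name one of `"subdued"`, `"balanced"`, `"tunable"`.
#' @param f_a Tar fraction of the receptor cluster; Tsr fraction is `1 - f_a`.
#' @return Named list of pH parameters suitable for [receptor_params()].
#' @export
ph_regime <- function(name = c("balanced", "subdued", "tunable"), f_a = 0.5) {
  name <- match.arg(name)
  pk <- switch(name,
    subdued  = c(pKI_tar = 9.5, pKA_tar = 8.5, pKI_tsr = 4.5, pKA_tsr = 5.5),
    balanced = c(pKI_tar = 8.6, pKA_tar = 7.1, pKI_tsr = 5.5, pKA_tsr = 7.0),
    tunable  = c(pKI_tar = 7.8, pKA_tar = 6.9, pKI_tsr = 6.2, pKA_tsr = 7.1))
  c(as.list(pk), list(f_a = f_a, f_s = 1 - f_a))
}

#' A point value of the external signals
#'
#' @param ligand chemoattractant concentration (>= 0), or `NA` if inactive.
#' @param pH pH value, or `NA` if inactive.
#' @param T temperature in degC, or `NA` if inactive.
#' @return A named list of class `signal_point`.
#' @export
signal_point <- function(ligand = NA_real_, pH = NA_real_, T = NA_real_) {
  if (!is.na(ligand) && ligand < 0) stop("ligand concentration must be >= 0")
  structure(list(ligand = ligand, pH = pH, T = T), class = "signal_point")
}

#' MWC receptor-cluster activity
#'
#' Two-state activity `a = 1/(1 + exp(f))` where `f` is the total free-energy
#' difference (in kT) between the active and inactive conformations of the
#' cluster, already including the cooperativity factor `N`.
#'
#' @param f_total total free-energy difference (kT); may be a vector.
#' @return Activity in (0, 1), strictly decreasing in `f_total`.
#' @examples
#' activity(0)       # 0.5
#' activity(log(3))  # 0.25
#' @export
activity <- function(f_total) {
  if (!all(is.finite(f_total))) stop("f_total must be finite")
  1 / (1 + exp(f_total))
}

# alpha(T), adapted activity a0(T), and F0(T) = log(1/a0 - 1): internal
alpha_T <- function(T, p) p$alpha0 + p$dalpha_dT * (T - p$T0)

#' Adapted activity at a given temperature
#'
#' The adapted (post-adaptation) activity drifts linearly with temperature,
#' `a0(T) = a0_ref + da0_dT * (T - T0)`, reflecting the observed increase of
#' the adapted CheY-P level with temperature. Values outside (0, 1) indicate
#' a misconfigured temperature range and raise an error.
#'
#' @param T temperature (degC); may be a vector.
#' @param p a [receptor_params()] object.
#' @return Adapted activity in (0, 1).
#' @export
adapted_activity <- function(T, p) {
  a0 <- p$a0_ref + p$da0_dT * (T - p$T0)
  if (any(a0 <= 0 | a0 >= 1))
    stop("adapted activity leaves (0, 1) on the requested temperature range; ",
         "adjust da0_dT or the range")
  a0
}

adapted_f0 <- function(T, p) log(1 / adapted_activity(T, p) - 1)

# log((1 + 10^(pH - pKI)) / (1 + 10^(pH - pKA))): shared MWC titration term
ph_log_ratio <- function(pH, pKI, pKA) {
  log1p(10^(pH - pKI)) - log1p(10^(pH - pKA))
}

ligand_log_ratio <- function(L, p) {
  log1p(L / p$KI) - log1p(L / p$KA)
}

#' Free energy for a chemoattractant signal
#'
#' `f = N * (alpha0 * (m0 - m) + log((1 + L/KI)/(1 + L/KA)))` (kT).
#' For an attractant (`KI < KA`) the ligand term increases with `L`, lowering
#' activity through [activity()]; the methylation term decreases with `m`.
#'
#' @param m methylation level; may be a vector.
#' @param L ligand concentration (>= 0).
#' @param p a [receptor_params()] object.
#' @return Free-energy difference in kT.
#' @export
free_energy_chemo <- function(m, L, p) {
  if (any(L < 0)) stop("ligand concentration must be >= 0")
  p$N * (p$alpha0 * (p$m0 - m) + ligand_log_ratio(L, p))
}

#' Free energy for a pH signal (mixed Tar/Tsr cluster)
#'
#' `f = N * (alpha0 * (m0 - m) + f_a * g_tar(pH) + f_s * g_tsr(pH))` where
#' each `g` is an MWC titration term `log((1 + 10^(pH-pKI))/(1 + 10^(pH-pKA)))`
#' on the pH scale. With `pKI_tar > pKA_tar` the Tar term decreases with pH
#' (a pH drop acts on Tar like an attractant, so Tar-only populations drift to
#' low pH); the Tsr ordering is opposite. Their balance sets the preferred pH
#' of wild-type cells.
#'
#' @inheritParams free_energy_chemo
#' @param pH pH value.
#' @return Free-energy difference in kT.
#' @export
free_energy_ph <- function(m, pH, p) {
  ph <- validate_ph_params(p$ph)
  g <- ph_signal_term(pH, p)
  p$N * (p$alpha0 * (p$m0 - m) + g)
}

ph_signal_term <- function(pH, p) {
  ph <- p$ph
  ph$f_a * ph_log_ratio(pH, ph$pKI_tar, ph$pKA_tar) +
    ph$f_s * ph_log_ratio(pH, ph$pKI_tsr, ph$pKA_tsr)
}

# d/dpH of ph_signal_term
ph_signal_slope <- function(pH, p) {
  ph <- p$ph
  dg <- function(pH, pKI, pKA) {
    uI <- 10^(pH - pKI); uA <- 10^(pH - pKA)
    log(10) * (uI / (1 + uI) - uA / (1 + uA))
  }
  ph$f_a * dg(pH, ph$pKI_tar, ph$pKA_tar) +
    ph$f_s * dg(pH, ph$pKI_tsr, ph$pKA_tsr)
}

#' Free energy for a thermal signal (Tar thermosensing)
#'
#' `f = N * alpha(T) * (m0 - m)` with `alpha(T) = alpha0 + dalpha_dT*(T - T0)`.
#' At fixed methylation the response to a temperature change,
#' `df/dT = N * dalpha_dT * (m0 - m)`, changes sign as `m` crosses `m0`;
#' under this linear form the critical methylation level is `m_c = m0`.
#'
#' @inheritParams free_energy_chemo
#' @param T temperature (degC).
#' @return Free-energy difference in kT.
#' @export
free_energy_thermo <- function(m, T, p) {
  p$N * alpha_T(T, p) * (p$m0 - m)
}

#' Free energy under combined thermal and chemical signals
#'
#' The thermal free energy plus the ligand titration term:
#' `free_energy_thermo(m, T, p) + N * log((1 + L/KI)/(1 + L/KA))`.
#' This is the Tar-only configuration used for navigation under opposing
#' chemical and thermal gradients.
#'
#' @inheritParams free_energy_thermo
#' @param L ligand concentration (>= 0).
#' @return Free-energy difference in kT.
#' @export
free_energy_mixed <- function(m, T, L, p) {
  if (any(L < 0)) stop("ligand concentration must be >= 0")
  free_energy_thermo(m, T, p) + p$N * ligand_log_ratio(L, p)
}

# N * f_signal(s) for a mode, without the methylation term
signal_free_energy <- function(s, p, mode) {
  switch(mode,
    chemo  = p$N * ligand_log_ratio(s$ligand, p),
    ph     = p$N * ph_signal_term(s$pH, p),
    thermo = 0,
    mixed  = p$N * ligand_log_ratio(s$ligand, p),
    stop("unknown mode: ", mode))
}

#' Adapted methylation level for a given signal
#'
#' Solves the adaptation condition `activity(f(m_ss, s)) = a0(T)` for the
#' steady-state methylation level. For the linear methylation free energy the
#' solution is closed-form,
#' `m_ss = m0 + (N*f_signal(s) - log(1/a0 - 1)) / (N*alpha(T))`;
#' a numerical root is also computed and both are required to agree to 1e-10.
#'
#' @param s a [signal_point()].
#' @param p a [receptor_params()] object.
#' @param mode one of `"chemo"`, `"ph"`, `"thermo"`, `"mixed"`.
#' @param bounds methylation bracket for the numerical root.
#' @param check if `TRUE` (default), cross-check the closed form against a
#'   numerical root solve.
#' @return Steady-state methylation level.
#' @export
adapted_methylation <- function(s, p, mode = c("chemo", "ph", "thermo", "mixed"),
                                bounds = c(-6, 10), check = TRUE) {
  mode <- match.arg(mode)
  T <- if (is.na(s$T)) p$T0 else s$T
  aT <- alpha_T(T, p)
  if (aT <= 0) stop("alpha(T) must be positive on the working range")
  f0 <- adapted_f0(T, p)
  fs <- signal_free_energy(s, p, mode)
  m_closed <- p$m0 + (fs - f0) / (p$N * aT)
  if (check) {
    h <- function(m) p$N * aT * (p$m0 - m) + fs - f0
    if (h(bounds[1]) * h(bounds[2]) > 0)
      stop("no adapted methylation root inside the configured bounds")
    m_num <- stats::uniroot(h, bounds, tol = 1e-13)$root
    if (abs(m_num - m_closed) > 1e-10)
      stop("closed-form and numerical adapted methylation disagree")
  }
  m_closed
}

#' Methylation rate
#'
#' Linear-in-activity adaptation kinetics `dm/dt = k_m * (a0 - a)` with the
#' rate constant `k_m = 1 / (tau_m * N * alpha(T) * a0 * (1 - a0))` chosen so
#' that the linearized relaxation time of the activity equals `tau_m`.
#'
#' @param a current activity, in (0, 1).
#' @param a0 adapted activity, in (0, 1).
#' @param p a [receptor_params()] object.
#' @param T temperature (degC); defaults to the reference temperature.
#' @return `dm/dt` in 1/s. Zero iff `a == a0`; positive when `a < a0`
#'   (added methyl raises activity back toward the set point).
#' @export
methylation_rate <- function(a, a0, p, T = p$T0) {
  stopifnot(all(a > 0 & a < 1), all(a0 > 0 & a0 < 1))
  k_m <- 1 / (p$tau_m * p$N * alpha_T(T, p) * a0 * (1 - a0))
  k_m * (a0 - a)
}

#' Critical temperature of the thermal-response inversion
#'
#' The temperature at which the adapted methylation level crosses the
#' critical level `m_c`, i.e. where the receptor switches from warm sensing
#' (`m_ss < m_c`) to cold sensing (`m_ss > m_c`). Determined entirely by the
#' receptor kinetics; motor parameters play no role.
#'
#' @param p a [receptor_params()] object.
#' @param range temperature search interval (degC); by default the widest
#'   interval on which both `alpha(T) > 0` and `a0(T)` stays in (0, 1).
#' @return Critical temperature (degC).
#' @export
critical_temperature <- function(p, range = valid_temperature_range(p)) {
  h <- function(T) {
    adapted_methylation(signal_point(T = T), p, "thermo", check = FALSE) - p$m_c
  }
  lo <- h(range[1]); hi <- h(range[2])
  if (abs(lo) < 1e-14 && abs(hi) < 1e-14)
    stop("degenerate configuration: adapted methylation equals m_c at all ",
         "temperatures; no critical temperature is defined")
  if (lo * hi > 0)
    stop("adapted methylation does not cross m_c on the given range")
  stats::uniroot(h, range, tol = 1e-12)$root
}

#' Temperature range on which the receptor model is well-posed
#'
#' The widest interval (shrunk by a small margin) on which the methylation
#' free-energy coefficient `alpha(T)` stays positive and the adapted activity
#' `a0(T)` stays strictly inside (0, 1).
#'
#' @param p a [receptor_params()] object.
#' @param margin fractional margin trimmed from each end.
#' @return Length-2 numeric vector (degC).
#' @export
valid_temperature_range <- function(p, margin = 0.02) {
  lo <- -Inf; hi <- Inf
  if (p$dalpha_dT > 0) lo <- max(lo, p$T0 - p$alpha0 / p$dalpha_dT)
  if (p$dalpha_dT < 0) hi <- min(hi, p$T0 + p$alpha0 / abs(p$dalpha_dT))
  if (p$da0_dT > 0) {
    lo <- max(lo, p$T0 - p$a0_ref / p$da0_dT)
    hi <- min(hi, p$T0 + (1 - p$a0_ref) / p$da0_dT)
  }
  if (p$da0_dT < 0) {
    lo <- max(lo, p$T0 - (1 - p$a0_ref) / abs(p$da0_dT))
    hi <- min(hi, p$T0 + p$a0_ref / abs(p$da0_dT))
  }
  lo <- max(lo, p$T0 - 100); hi <- min(hi, p$T0 + 100)
  pad <- margin * (hi - lo)
  c(lo + pad, hi - pad)
}

#' Activity relaxation after a stimulus step
#'
#' Integrates the methylation dynamics `dm/dt = k_m (a0 - a)` at a fixed
#' post-step signal and returns the activity trajectory, for inspecting
#' perfect adaptation and the relaxation timescale.
#'
#' @param s post-step [signal_point()].
#' @param p a [receptor_params()] object.
#' @param mode signalling mode, as in [adapted_methylation()].
#' @param m_init initial methylation level (e.g. the pre-step adapted level).
#' @param t_end,dt integration horizon and output step (s).
#' @return A data.frame with columns `time`, `m`, `a`.
#' @export
adapt_trajectory <- function(s, p, mode = "chemo", m_init, t_end = 10 * p$tau_m,
                             dt = p$tau_m / 200) {
  mode <- match.arg(mode, c("chemo", "ph", "thermo", "mixed"))
  T <- if (is.na(s$T)) p$T0 else s$T
  a0 <- adapted_activity(T, p)
  fs <- signal_free_energy(s, p, mode)
  deriv <- function(t, y, parms) {
    a <- activity(p$N * alpha_T(T, p) * (p$m0 - y[1]) + fs)
    list(methylation_rate(a, a0, p, T))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = c(m = m_init), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  m <- sol[, "m"]
  data.frame(time = sol[, "time"], m = m,
             a = activity(p$N * alpha_T(T, p) * (p$m0 - m) + fs))
}
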