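# Stochastic agent-based run-and-tumble simulator: the independent check on
# every analytic steady-state result.

#' Simulation configuration
#'
#' @param n_cells number of cells (>= 1000 recommended for production runs).
#' @param dt time step (s); must satisfy `dt * z_max < 0.05` where `z_max`
#'   is the largest attainable direction-change rate (checked against the
#'   motor parameters at run time).
#' @param t_end simulation horizon (s).
#' @param t_burnin discarded initial window (s); must be at least
#'   `10 * tau_m` so the sampled window is adapted and stationary.
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @param n_bins number of histogram bins.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 10000, dt = 0.004, t_end = 450,
                       t_burnin = 200, seed = NULL, n_bins = 64) {
  stopifnot(n_cells >= 1, dt > 0, t_end > t_burnin, t_burnin >= 0,
            n_bins >= 8)
  structure(list(n_cells = as.integer(n_cells), dt = dt, t_end = t_end,
                 t_burnin = t_burnin, seed = seed,
                 n_bins = as.integer(n_bins)),
            class = "sim_config")
}

# Precompute uniform lookup tables of the local model coefficients:
# F0 = log(1/a0 - 1), G = N*f_signal(x) and its derivative Gp, the thermal
# drive coefficient AoA = (dalpha/dT) T'(x) / alpha(T(x)), the adaptation
# rate km2 = 1/(tau_m a0 (1-a0)) in free-energy units, A = N*alpha(T(x))
# (for methylation bookkeeping), v(x), and K(T(x))^H.
abm_lookup <- function(env, rp, mp, mode = infer_mode(env), n_lut = 1025) {
  xg <- seq(env$x_min, env$x_max, length.out = n_lut)
  T <- temperature_at(env, xg, rp$T0)
  a0 <- adapted_activity(T, rp)
  aT <- alpha_T(T, rp)
  fs <- rep(0, n_lut)
  fsp <- rep(0, n_lut)
  if (mode %in% c("chemo", "mixed")) {
    L <- signal_at(env, xg, "ligand")
    fs <- fs + rp$N * ligand_log_ratio(L, rp)
    fsp <- fsp + rp$N * (1 / (rp$KI + L) - 1 / (rp$KA + L)) *
      signal_slope_at(env, xg, "ligand")
  }
  if (mode == "ph") {
    pH <- signal_at(env, xg, "ph")
    fs <- fs + rp$N * ph_signal_term(pH, rp)
    fsp <- fsp + rp$N * ph_signal_slope(pH, rp) *
      signal_slope_at(env, xg, "ph")
  }
  AoA <- if (mode %in% c("thermo", "mixed"))
    rp$dalpha_dT * signal_slope_at(env, xg, "temperature") / aT
  else rep(0, n_lut)
  list(x = xg,
       F0 = log(1 / a0 - 1),
       G = fs, Gp = fsp, AoA = AoA,
       a0 = a0,
       km2 = 1 / (rp$tau_m * a0 * (1 - a0)),
       A = rp$N * aT,
       v = speed_at(env, xg, rp$T0),
       KH = motor_K(T, mp)^mp$H)
}

validate_dt <- function(cfg, mp, rp) {
  z_max <- 1 / mp$tau_tumble + 2 * mp$D_r
  if (cfg$dt * z_max >= 0.05)
    stop("time step too large: dt * z_max = ", signif(cfg$dt * z_max, 3),
         " must be < 0.05")
  if (cfg$t_burnin < 10 * rp$tau_m)
    stop("t_burnin must be at least 10 * tau_m = ", 10 * rp$tau_m, " s")
  invisible(TRUE)
}

#' Advance an agent population by a number of steps
#'
#' Low-level access to the simulator kernel: per step each cell (1) relaxes
#' its methylation toward the locally adapted level, (2) recomputes its
#' activity, (3) tumbles with probability `z_motor * dt` (new direction
#' uniform on -1/+1) and reverses with probability `D_r * dt` (rotational
#' diffusion), and (4) moves by `dir * v * dt` with reflecting boundaries.
#'
#' @param state list with numeric `x`, integer `dir` (+1/-1), numeric `m`.
#' @param env,rp,mp environment, receptor, and motor parameters.
#' @param dt time step (s).
#' @param n_steps number of steps to take.
#' @return Updated state list (with `a` recomputed).
#' @export
abm_step <- function(state, env, rp, mp, dt, n_steps = 1) {
  lu <- abm_lookup(env, rp, mp)
  at <- function(tab, x) approx(lu$x, tab, xout = x, rule = 2)$y
  # convert methylation to the deviation free energy g = f - F0
  g0 <- at(lu$A, state$x) * (rp$m0 - state$m) + at(lu$G, state$x) -
    at(lu$F0, state$x)
  res <- sim_kernel(as.numeric(state$x), as.integer(state$dir),
                    as.numeric(g0),
                    nsteps = as.integer(n_steps), burn_steps = n_steps,
                    dt = dt, xmin = env$x_min, xmax = env$x_max,
                    F0g = lu$F0, Gg = lu$G, Gpg = lu$Gp, AoAg = lu$AoA,
                    a0g = lu$a0, km2g = lu$km2, Ag = lu$A,
                    vg = lu$v, KHg = lu$KH,
                    m0 = rp$m0, H = mp$H, tau_t = mp$tau_tumble,
                    Dr = mp$D_r, nbins = 8L)
  f <- at(lu$F0, res$x) + res$g
  m <- rp$m0 - (f - at(lu$G, res$x)) / at(lu$A, res$x)
  list(x = res$x, dir = res$dir, m = m, a = activity(f))
}

#' Simulate a cell population to steady state
#'
#' Runs the agent-based run-and-tumble model and returns the time-and-
#' ensemble-averaged position histogram (after burn-in) together with
#' per-direction summaries that allow direct tests of the analytic activity
#' and tumbling-rate differences.
#'
#' Cells start uniformly distributed with uniform directions and locally
#' adapted methylation. Stationarity is checked by comparing the histograms
#' of the two halves of the sampling window; a warning is raised if their
#' difference exceeds twice the window-internal noise level (estimated from
#' the difference between the last two quarters).
#'
#' @param env,rp,mp environment, receptor, and motor parameters.
#' @param cfg a [sim_config()].
#' @return A list of class `abm_result` with elements `profile` (a
#'   `density_profile` histogram with measured mean activity/methylation),
#'   `summary` (per-bin, per-direction mean activity and tumbling rates),
#'   and `config`.
#' @export
simulate_population <- function(env, rp, mp, cfg = sim_config()) {
  validate_dt(cfg, mp, rp)
  mode <- infer_mode(env)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lu <- abm_lookup(env, rp, mp, mode)
  n <- cfg$n_cells
  x0 <- stats::runif(n, env$x_min, env$x_max)
  dir0 <- sample(c(-1L, 1L), n, replace = TRUE)
  nsteps <- round(cfg$t_end / cfg$dt)
  burn <- round(cfg$t_burnin / cfg$dt)
  res <- sim_kernel(x0, dir0, rep(0, n),   # g = 0: locally adapted start
                    nsteps = as.integer(nsteps), burn_steps = as.integer(burn),
                    dt = cfg$dt, xmin = env$x_min, xmax = env$x_max,
                    F0g = lu$F0, Gg = lu$G, Gpg = lu$Gp, AoAg = lu$AoA,
                    a0g = lu$a0, km2g = lu$km2, Ag = lu$A,
                    vg = lu$v, KHg = lu$KH,
                    m0 = rp$m0, H = mp$H, tau_t = mp$tau_tumble,
                    Dr = mp$D_r, nbins = cfg$n_bins)

  bw <- (env$x_max - env$x_min) / cfg$n_bins
  centers <- env$x_min + (seq_len(cfg$n_bins) - 0.5) * bw
  total <- sum(res$occ)
  dens <- res$occ / (total * bw)

  # stationarity: systematic drift between the two halves of the sampling
  # window must not exceed (twice) the window-internal noise, which is
  # estimated self-consistently from the difference of the last two quarters
  # (bin occupancies are time-correlated, so Poisson noise would be too
  # optimistic)
  q <- res$occ_q
  p12 <- (q[1, ] + q[2, ]) / sum(q[1, ] + q[2, ])
  p34 <- (q[3, ] + q[4, ]) / sum(q[3, ] + q[4, ])
  p3 <- q[3, ] / sum(q[3, ]); p4 <- q[4, ] / sum(q[4, ])
  drift <- max(abs(p12 - p34))
  noise <- max(max(abs(p4 - p3)), 1e-3 / cfg$n_bins)
  stationary <- drift < 2 * noise
  if (!stationary)
    warning("stationarity check failed: histogram still drifting after burn-in")

  occ_dir <- res$occ_dir
  dt <- cfg$dt
  summary <- data.frame(
    x = centers,
    density = dens,
    a_minus = res$a_sum[1, ] / pmax(occ_dir[1, ], 1),
    a_plus = res$a_sum[2, ] / pmax(occ_dir[2, ], 1),
    z_minus = res$tumbles[1, ] / (pmax(occ_dir[1, ], 1) * dt),
    z_plus = res$tumbles[2, ] / (pmax(occ_dir[2, ], 1) * dt))

  df <- data.frame(x = centers)
  if (!is.null(env$ligand)) df$ligand <- signal_at(env, centers, "ligand")
  if (!is.null(env$ph)) df$ph <- signal_at(env, centers, "ph")
  if (!is.null(env$temp)) df$temperature <- signal_at(env, centers, "temperature")
  df$density <- dens
  df$activity <- (res$a_sum[1, ] + res$a_sum[2, ]) / pmax(res$occ, 1)
  df$methylation <- (res$m_sum[1, ] + res$m_sum[2, ]) / pmax(res$occ, 1)
  df$potential <- ifelse(dens > 0, -log(pmax(dens, .Machine$double.xmin)), NA)
  df$potential <- df$potential - min(df$potential, na.rm = TRUE)
  profile <- new_density_profile(df, check = FALSE)

  structure(list(profile = profile, summary = summary, config = cfg,
                 stationary = stationary,
                 final = list(x = res$x, dir = res$dir, g = res$g,
                              m = rp$m0 -
                                (approx(lu$x, lu$F0, xout = res$x)$y + res$g -
                                 approx(lu$x, lu$G, xout = res$x)$y) /
                                approx(lu$x, lu$A, xout = res$x)$y)),
            class = "abm_result")
}

#' Compare two density profiles on a shared grid
#'
#' @param hist a `density_profile` (e.g. a simulated histogram).
#' @param analytic a `density_profile` evaluated on the same grid.
#' @return A list with `kl` (Kullback-Leibler divergence of `hist` from
#'   `analytic`, in nats), `sup_rel` (sup-norm of the relative density
#'   difference), and `emd` (earth-mover distance, in grid units).
#' @export
compare_profiles <- function(hist, analytic) {
  if (nrow(hist) != nrow(analytic) ||
      max(abs(hist$x - analytic$x)) > 1e-8 * diff(range(analytic$x)))
    stop("profiles must share the same grid")
  w <- c(diff(hist$x), utils::tail(diff(hist$x), 1))
  p <- hist$density * w; p <- p / sum(p)
  q <- analytic$density * w; q <- q / sum(q)
  if (any(q <= 0 & p > 0)) stop("analytic profile has empty support bins")
  nz <- p > 0
  kl <- sum(p[nz] * log(p[nz] / q[nz]))
  sup_rel <- max(abs(p - q) / q)
  emd <- sum(abs(cumsum(p - q)) * w)
  list(kl = kl, sup_rel = sup_rel, emd = emd)
}
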