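#' Parameters of the switched FES-actuated ankle model
#'
#' The ankle is modeled as a single rotational degree of freedom driven by two
#' antagonist muscle groups under functional electrical stimulation (FES): the
#' plantarflexors (gastrocnemius, active during stance) and the dorsiflexors
#' (tibialis anterior, active during swing).  The dynamics switch between a
#' stance and a swing configuration,
#' \deqn{J_\zeta \ddot\theta = \tau_{muscle} + (1-\sigma)\,\tau_{ext}
#'       - f(\theta,\dot\theta),}
#' where \eqn{\sigma \in \{0,1\}} flags stance (0) versus swing (1),
#' \eqn{f(\theta,\dot\theta) = b\dot\theta + k(\theta-\theta_0)
#' + m g l \sin\theta} collects the musculoskeletal viscous, elastic and
#' gravitational torques, and \eqn{\tau_{ext} = r(\theta) F_{GRF}(t)} is the
#' stance-only external torque from the ground reaction force (GRF) acting at
#' moment arm \eqn{r(\theta) = r_0 \cos\theta}.
#'
#' Muscle recruitment maps stimulation current to torque through a
#' piecewise-linear saturating curve: zero below `recruit_threshold`, linear
#' up to `recruit_saturation`, constant at `recruit_max_torque` beyond.  The
#' sign convention is dorsiflexion positive, so plantarflexor torque is
#' negative.
#'
#' Default values describe a foot segment at slow treadmill walking speeds:
#' inertias of 0.02 / 0.01 kg m^2 for the loaded (stance) and free (swing)
#' configurations, passive stiffness 3 N m/rad, viscous damping 0.1 N m s/rad,
#' a gravitational torque coefficient of 0.8 N m, recruitment from 8 mA
#' (motor threshold) to 45 mA (saturation) with 3 N m maximal torque per
#' muscle group, and a modest effective GRF torque (300 N peak force on a
#' 1 mm effective arm) reflecting the near-ankle center of pressure at very
#' slow speeds.
#'
#' @param inertia_stance,inertia_swing foot/shank inertia about the ankle in
#'   stance and swing (kg m^2).
#' @param viscous_coeff passive viscous coefficient (N m s/rad).
#' @param elastic_coeff passive elastic stiffness (N m/rad).
#' @param elastic_rest_angle rest angle of the passive elastic torque (rad).
#' @param gravity_torque_coeff lumped gravitational coefficient m g l (N m).
#' @param recruit_threshold,recruit_saturation,recruit_max_torque recruitment
#'   curve per muscle: named numeric vectors with elements `pf` and `df`
#'   (mA, mA, N m); scalars are recycled to both muscles.
#' @param grf_peak_force peak vertical ground reaction force (N).
#' @param grf_moment_arm_coeff effective GRF moment-arm coefficient (m);
#'   the arm is \eqn{r(\theta) = r_0\cos\theta}.
#' @param cycle_duration gait cycle duration (s).
#' @param stance_fraction fraction of the cycle spent in stance, in (0, 1).
#' @return an object of class `ankle_params`.
#' @export
ankle_params <- function(inertia_stance = 0.02,
                         inertia_swing = 0.01,
                         viscous_coeff = 0.1,
                         elastic_coeff = 3,
                         elastic_rest_angle = 0,
                         gravity_torque_coeff = 0.8,
                         recruit_threshold = c(pf = 8, df = 8),
                         recruit_saturation = c(pf = 45, df = 45),
                         recruit_max_torque = c(pf = 3, df = 3),
                         grf_peak_force = 300,
                         grf_moment_arm_coeff = 0.001,
                         cycle_duration = 1,
                         stance_fraction = 0.6) {
  both <- function(x, what) {
    if (length(x) == 1L) x <- c(pf = unname(x), df = unname(x))
    if (is.null(names(x)) && length(x) == 2L) names(x) <- c("pf", "df")
    if (!setequal(names(x), c("pf", "df")))
      stop_input("%s must be named with 'pf' and 'df'", what)
    x[c("pf", "df")]
  }
  p <- list(
    inertia_stance = inertia_stance, inertia_swing = inertia_swing,
    viscous_coeff = viscous_coeff, elastic_coeff = elastic_coeff,
    elastic_rest_angle = elastic_rest_angle,
    gravity_torque_coeff = gravity_torque_coeff,
    recruit_threshold = both(recruit_threshold, "recruit_threshold"),
    recruit_saturation = both(recruit_saturation, "recruit_saturation"),
    recruit_max_torque = both(recruit_max_torque, "recruit_max_torque"),
    grf_peak_force = grf_peak_force,
    grf_moment_arm_coeff = grf_moment_arm_coeff,
    cycle_duration = cycle_duration, stance_fraction = stance_fraction
  )
  class(p) <- "ankle_params"
  validate_ankle_params(p)
}

validate_ankle_params <- function(p) {
  pos <- c("inertia_stance", "inertia_swing", "viscous_coeff",
           "elastic_coeff", "grf_peak_force", "cycle_duration")
  for (f in pos)
    if (!is.finite(p[[f]]) || p[[f]] <= 0)
      stop_input("'%s' must be strictly positive", f)
  if (any(p$recruit_max_torque <= 0))
    stop_input("'recruit_max_torque' must be strictly positive")
  if (any(p$recruit_threshold < 0))
    stop_input("'recruit_threshold' must be nonnegative")
  if (any(p$recruit_threshold >= p$recruit_saturation))
    stop_input("recruit_threshold must be below recruit_saturation per muscle")
  if (!is.finite(p$stance_fraction) ||
      p$stance_fraction <= 0 || p$stance_fraction >= 1)
    stop_input("'stance_fraction' must lie strictly between 0 and 1")
  if (p$gravity_torque_coeff < 0)
    stop_input("'gravity_torque_coeff' must be nonnegative")
  if (p$grf_moment_arm_coeff < 0)
    stop_input("'grf_moment_arm_coeff' must be nonnegative")
  p
}

#' @export
print.ankle_params <- function(x, ...) {
  cat("Switched FES ankle model parameters\n")
  cat(sprintf("  inertia (stance/swing): %.4g / %.4g kg m^2\n",
              x$inertia_stance, x$inertia_swing))
  cat(sprintf("  passive: b = %.3g N m s/rad, k = %.3g N m/rad, rest = %.3g rad, mgl = %.3g N m\n",
              x$viscous_coeff, x$elastic_coeff, x$elastic_rest_angle,
              x$gravity_torque_coeff))
  cat(sprintf("  recruitment pf: %g-%g mA -> %g N m | df: %g-%g mA -> %g N m\n",
              x$recruit_threshold["pf"], x$recruit_saturation["pf"],
              x$recruit_max_torque["pf"], x$recruit_threshold["df"],
              x$recruit_saturation["df"], x$recruit_max_torque["df"]))
  cat(sprintf("  GRF: peak %g N, arm coeff %g m; cycle %g s, stance fraction %g\n",
              x$grf_peak_force, x$grf_moment_arm_coeff, x$cycle_duration,
              x$stance_fraction))
  invisible(x)
}

#' FES recruitment torque of one muscle group
#'
#' Piecewise-linear saturating recruitment: no torque below the motor
#' threshold, linear growth up to saturation, constant beyond.  Dorsiflexion
#' is positive, so the plantarflexor returns nonpositive torque.
#'
#' @param u stimulation current (mA), nonnegative; vectorized.
#' @param muscle `"pf"` (plantarflexor) or `"df"` (dorsiflexor).
#' @param params an [ankle_params()] object.
#' @return torque in N m, same length as `u`.
#' @export
muscle_torque <- function(u, muscle = c("pf", "df"), params) {
  muscle <- match.arg(muscle)
  if (any(!is.finite(u)) || any(u < 0))
    stop_input("stimulation current must be finite and nonnegative")
  th <- params$recruit_threshold[[muscle]]
  sat <- params$recruit_saturation[[muscle]]
  tmax <- params$recruit_max_torque[[muscle]]
  frac <- pmin(pmax((u - th) / (sat - th), 0), 1)
  tau <- tmax * frac
  if (muscle == "pf") -tau else tau
}

#' Ground reaction force template over stance
#'
#' A half-sine bump supported on the stance interval: zero at heel strike and
#' toe off, peaking at `grf_peak_force` mid-stance.  Outside the stance
#' interval the force is zero.
#'
#' @param t_in_stance time since stance onset (s); vectorized.
#' @param params an [ankle_params()] object.
#' @return vertical GRF in N.
#' @export
grf_force <- function(t_in_stance, params) {
  t_st <- params$stance_fraction * params$cycle_duration
  inside <- is.finite(t_in_stance) & t_in_stance >= 0 & t_in_stance <= t_st
  f <- numeric(length(t_in_stance))
  f[inside] <- params$grf_peak_force * sin(pi * t_in_stance[inside] / t_st)
  pmax(f, 0)
}

# GRF torque about the ankle at angle theta, time t since stance onset.
grf_torque <- function(theta, t_in_stance, params) {
  params$grf_moment_arm_coeff * cos(theta) * grf_force(t_in_stance, params)
}

#' Right-hand side of the switched ankle dynamics
#'
#' Returns \eqn{(\dot\theta, \ddot\theta)} of the phase-\eqn{\sigma} dynamics.
#' Both muscle channels contribute torque; during a phase the inactive
#' muscle's current is typically zero.  The GRF torque acts only in stance
#' (`sigma = 0`).
#'
#' @param theta,theta_dot ankle angle (rad) and velocity (rad/s).
#' @param u_pf,u_df plantarflexor / dorsiflexor currents (mA).
#' @param sigma gait phase flag: 0 stance, 1 swing.
#' @param t_in_phase time since the current phase began (s); used by the GRF
#'   template in stance.
#' @param params an [ankle_params()] object.
#' @return numeric vector `c(theta_dot, theta_ddot)`.
#' @export
ankle_rhs <- function(theta, theta_dot, u_pf, u_df, sigma, t_in_phase, params) {
  assert_finite(c(theta, theta_dot, u_pf, u_df, t_in_phase), "ankle_rhs inputs")
  if (!sigma %in% c(0, 1)) stop_input("sigma must be 0 (stance) or 1 (swing)")
  tau_m <- muscle_torque(u_pf, "pf", params) + muscle_torque(u_df, "df", params)
  tau_ext <- if (sigma == 0) grf_torque(theta, t_in_phase, params) else 0
  f_pass <- params$viscous_coeff * theta_dot +
    params$elastic_coeff * (theta - params$elastic_rest_angle) +
    params$gravity_torque_coeff * sin(theta)
  J <- if (sigma == 0) params$inertia_stance else params$inertia_swing
  c(theta_dot, (tau_m + tau_ext - f_pass) / J)
}

# Phase flag and time-in-phase for a time point, from the cycle schedule.
phase_of_time <- function(t, params) {
  t_c <- t %% params$cycle_duration
  # guard against floating-point wrap (t_c == cycle_duration)
  t_c[t_c >= params$cycle_duration] <- 0
  t_st <- params$stance_fraction * params$cycle_duration
  sigma <- ifelse(t_c < t_st, 0L, 1L)
  t_in_phase <- ifelse(sigma == 0L, t_c, t_c - t_st)
  list(sigma = sigma, t_in_phase = t_in_phase)
}

#' Simulate the switched nonlinear ankle plant
#'
#' Fixed-step classical fourth-order Runge-Kutta integration at the sampling
#' rate with zero-order-hold inputs.  The gait phase switches on the sample
#' grid according to the cycle schedule (`cycle_duration`,
#' `stance_fraction`); the GRF template time advances continuously through
#' the Runge-Kutta stages.
#'
#' @param x0 initial state `c(theta, theta_dot)` (rad, rad/s).
#' @param u_pf,u_df input current sequences (mA), one value per sample.
#' @param params an [ankle_params()] object.
#' @param sample_rate sampling frequency (Hz).
#' @param n_cycles number of gait cycles; the input sequences must span
#'   `n_cycles * cycle_duration * sample_rate` samples.
#' @param substeps integration substeps per sample (default 1; useful for
#'   step-halving convergence checks).
#' @return an `ankle_trajectory` data frame with columns `time`, `theta`,
#'   `theta_dot`, `u_pf`, `u_df`, `grf`, `sigma` (SI units, radians).
#' @export
simulate_ankle <- function(x0, u_pf, u_df, params, sample_rate = 200,
                           n_cycles = 1, substeps = 1L) {
  n <- round(n_cycles * params$cycle_duration * sample_rate)
  if (length(u_pf) != n || length(u_df) != n)
    stop_input("input sequences must have %d samples (got %d, %d)",
               n, length(u_pf), length(u_df))
  assert_finite(x0, "x0")
  if (length(x0) != 2L) stop_input("x0 must be c(theta, theta_dot)")
  dt <- 1 / sample_rate
  time <- (seq_len(n) - 1L) * dt
  ph <- phase_of_time(time, params)
  theta <- numeric(n); theta_dot <- numeric(n)
  theta[1] <- x0[1]; theta_dot[1] <- x0[2]
  h <- dt / substeps
  for (k in seq_len(n - 1L)) {
    th <- theta[k]; om <- theta_dot[k]
    sg <- ph$sigma[k]; tp <- ph$t_in_phase[k]
    for (s in seq_len(substeps)) {
      t0 <- tp + (s - 1L) * h
      k1 <- ankle_rhs(th, om, u_pf[k], u_df[k], sg, t0, params)
      k2 <- ankle_rhs(th + h / 2 * k1[1], om + h / 2 * k1[2],
                      u_pf[k], u_df[k], sg, t0 + h / 2, params)
      k3 <- ankle_rhs(th + h / 2 * k2[1], om + h / 2 * k2[2],
                      u_pf[k], u_df[k], sg, t0 + h / 2, params)
      k4 <- ankle_rhs(th + h * k3[1], om + h * k3[2],
                      u_pf[k], u_df[k], sg, t0 + h, params)
      th <- th + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      om <- om + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    }
    theta[k + 1L] <- th
    theta_dot[k + 1L] <- om
  }
  grf <- ifelse(ph$sigma == 0L, grf_force(ph$t_in_phase, params), 0)
  new_trajectory(time, theta, theta_dot, u_pf, u_df, grf, ph$sigma)
}

#' Construct and validate a trajectory record
#'
#' The universal interchange record: a uniformly sampled time series of ankle
#' state, FES inputs, GRF, and phase flag.
#'
#' @param time time grid (s), strictly increasing with constant step.
#' @param theta,theta_dot ankle angle (rad) and velocity (rad/s).
#' @param u_pf,u_df nonnegative stimulation currents (mA).
#' @param grf nonnegative vertical ground reaction force (N).
#' @param sigma phase flags in \{0, 1\}; must equal the GRF thresholding rule.
#' @param grf_tolerance force threshold used for the consistency check (N).
#' @return an `ankle_trajectory` data frame.
#' @export
new_trajectory <- function(time, theta, theta_dot, u_pf, u_df, grf, sigma,
                           grf_tolerance = 1e-9) {
  n <- length(time)
  lens <- lengths(list(theta, theta_dot, u_pf, u_df, grf, sigma))
  if (any(lens != n)) stop_input("all trajectory channels must share length %d", n)
  if (n >= 2L) {
    dts <- diff(time)
    if (any(dts <= 0)) stop_input("time must be strictly increasing")
    if (diff(range(dts)) > 1e-9 * max(dts))
      stop_input("time grid must be uniform")
  }
  if (any(u_pf < 0) || any(u_df < 0))
    stop_input("stimulation currents must be nonnegative")
  if (any(grf < 0)) stop_input("grf must be nonnegative")
  if (!all(sigma %in% c(0, 1))) stop_input("sigma must be 0/1")
  # indicator rule: force above tolerance implies stance (equivalently, no
  # force during swing); stance samples at the template boundaries
  # (heel strike, toe off) may carry zero force
  if (any(grf > grf_tolerance & sigma == 1))
    stop_input("sigma is inconsistent with the GRF indicator rule")
  structure(
    data.frame(time = time, theta = theta, theta_dot = theta_dot,
               u_pf = u_pf, u_df = u_df, grf = grf, sigma = as.integer(sigma)),
    class = c("ankle_trajectory", "data.frame")
  )
}

#' Gait-phase indicator from the ground reaction force
#'
#' Thresholds the GRF: stance (`sigma = 0`) where the force exceeds the
#' tolerance, swing (`sigma = 1`) elsewhere.
#'
#' @param grf_series nonnegative GRF samples (N).
#' @param tolerance force threshold (N).
#' @return integer vector of phase flags.
#' @export
phase_indicator <- function(grf_series, tolerance = 1) {
  if (any(grf_series < 0)) stop_input("grf must be nonnegative")
  ifelse(grf_series > tolerance, 0L, 1L)
}

# Passive mechanical energy (kinetic + elastic + gravitational potential)
# of the phase-sigma configuration; used by energy-dissipation checks.
mechanical_energy <- function(theta, theta_dot, sigma, params) {
  J <- ifelse(sigma == 0, params$inertia_stance, params$inertia_swing)
  0.5 * J * theta_dot^2 +
    0.5 * params$elastic_coeff * (theta - params$elastic_rest_angle)^2 +
    params$gravity_torque_coeff * (1 - cos(theta))
}

#' Read and write trajectory files
#'
#' Columnar text interchange: a CSV with header
#' `time,theta,theta_dot,u_pf,u_df,grf,sigma`.  Angles and angular velocities
#' in the file are degrees and degrees per second; they are converted to
#' radians on read.
#'
#' @param traj an `ankle_trajectory`.
#' @param path file path.
#' @return `read_trajectory()` returns an `ankle_trajectory`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- data.frame(
    time = traj$time,
    theta = rad2deg(traj$theta),
    theta_dot = rad2deg(traj$theta_dot),
    u_pf = traj$u_pf, u_df = traj$u_df,
    grf = traj$grf, sigma = traj$sigma
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time", "theta", "theta_dot", "u_pf", "u_df", "grf", "sigma")
  if (!all(need %in% names(d)))
    stop_input("trajectory file must have columns %s", paste(need, collapse = ","))
  new_trajectory(d$time, deg2rad(d$theta), deg2rad(d$theta_dot),
                 d$u_pf, d$u_df, d$grf, d$sigma)
}

#' Read and write ankle parameter files
#'
#' Flat key-value YAML mirroring the [ankle_params()] fields; per-muscle
#' fields are two-element maps with keys `pf` and `df`.
#'
#' @param params an [ankle_params()] object.
#' @param path file path.
#' @return `read_ankle_params()` returns an `ankle_params` object.
#' @export
write_ankle_params <- function(params, path) {
  x <- unclass(params)
  x$recruit_threshold <- as.list(x$recruit_threshold)
  x$recruit_saturation <- as.list(x$recruit_saturation)
  x$recruit_max_torque <- as.list(x$recruit_max_torque)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_ankle_params
#' @export
read_ankle_params <- function(path) {
  x <- yaml::read_yaml(path)
  x$recruit_threshold <- unlist(x$recruit_threshold)
  x$recruit_saturation <- unlist(x$recruit_saturation)
  x$recruit_max_torque <- unlist(x$recruit_max_torque)
  do.call(ankle_params, x)
}

#' Attach a reference trajectory to a simulated trajectory
#'
#' Stores the reference as an attribute so downstream identification can form
#' the augmented (error, reference) state.  The grids must match.
#'
#' @param traj an `ankle_trajectory`.
#' @param ref a `reference_trajectory` (see [make_reference()]).
#' @return `traj` with a `"reference"` attribute.
#' @export
attach_reference <- function(traj, ref) {
  if (nrow(ref) != nrow(traj) ||
      max(abs(ref$time - traj$time)) > 1e-9)
    stop_input("reference and trajectory must share the same time grid")
  attr(traj, "reference") <- ref
  traj
}
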