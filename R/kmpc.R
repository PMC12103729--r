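#' Solve the discrete-time algebraic Riccati equation
#'
#' Fixed-point iteration of the Riccati recursion
#' \deqn{S \leftarrow A'SA - A'SB (R + B'SB)^{-1} B'SA + Q}
#' from `S = Q`, symmetrizing at every step, until the iterates stagnate.
#' Requires a stabilizable pair `(A, B)`; the converged solution is the
#' terminal weighting matrix of the receding-horizon problem and also
#' defines the stabilizing LQR terminal policy.
#'
#' @param A,B system matrices (`n x n`, `n x m`).
#' @param Q state weight, positive semidefinite (`n x n`).
#' @param R input weight, positive definite (`m x m` or scalar).
#' @param tol relative stagnation tolerance.
#' @param max_iter iteration cap.
#' @return symmetric PSD matrix `S` with attributes `"residual"` (Riccati
#'   residual Frobenius norm) and `"iterations"`.
#' @export
solve_dare <- function(A, B, Q, R, tol = 1e-13, max_iter = 10000L) {
  A <- as.matrix(A); B <- as.matrix(B)
  Q <- symmetrize(as.matrix(Q)); R <- as.matrix(R)
  S <- Q
  for (it in seq_len(max_iter)) {
    BtS <- crossprod(B, S)
    Snew <- symmetrize(
      crossprod(A, S %*% A) -
        crossprod(A, t(BtS)) %*% solve(R + BtS %*% B, BtS %*% A) + Q
    )
    delta <- frob(Snew - S) / max(frob(Snew), 1e-300)
    S <- Snew
    if (!all(is.finite(S)))
      stop_input("DARE iteration diverged: is (A, B) stabilizable?")
    if (delta < tol) break
  }
  res <- riccati_residual(A, B, Q, R, S)
  if (res > 1e-8 * max(frob(S), 1))
    stop_input("DARE did not converge (residual %.3g): is (A, B) stabilizable?",
               res)
  attr(S, "residual") <- res
  attr(S, "iterations") <- it
  S
}

# Frobenius norm of the Riccati fixed-point defect.
riccati_residual <- function(A, B, Q, R, S) {
  BtS <- crossprod(as.matrix(B), S)
  frob(S - (crossprod(A, S %*% A) -
              crossprod(A, t(BtS)) %*%
                solve(as.matrix(R) + BtS %*% as.matrix(B), BtS %*% A) + Q))
}

#' LQR feedback gain from a DARE solution
#'
#' `u = -K e` with `K = (R + B'SB)^{-1} B'SA`; the stabilizing terminal
#' policy associated with the terminal cost `S`.
#'
#' @inheritParams solve_dare
#' @param S DARE solution.
#' @return gain matrix `K` (`m x n`).
#' @export
lqr_gain <- function(A, B, S, R) {
  B <- as.matrix(B)
  BtS <- crossprod(B, S)
  solve(as.matrix(R) + BtS %*% B, BtS %*% as.matrix(A))
}

#' Largest terminal-set level consistent with the input bounds
#'
#' The terminal set is the sublevel set `e'Se <= eps`.  The LQR terminal
#' policy `u = -Ke` is input-feasible on the whole set iff
#' `max |Ke| = sqrt(eps * K S^{-1} K')` stays within the available input
#' half-width, giving the closed form
#' `eps_max = halfwidth^2 / (K S^{-1} K')` (scalar input).
#'
#' @param K LQR gain (`1 x n`).
#' @param S DARE solution.
#' @param u_halfwidth half-width of the admissible input interval around the
#'   phase equilibrium input (mA).
#' @return largest admissible `eps`.
#' @export
calibrate_terminal_epsilon <- function(K, S, u_halfwidth) {
  g <- drop(K %*% solve(S, t(K)))
  if (g <= 0) return(Inf)
  u_halfwidth^2 / g
}

#' Terminal-set membership test
#'
#' @param z_T terminal (error) state.
#' @param S terminal weighting matrix (PSD).
#' @param epsilon terminal-set level.
#' @return `TRUE` iff `z' S z <= epsilon`.
#' @export
terminal_check <- function(z_T, S, epsilon) {
  drop(crossprod(z_T, S %*% z_T)) <= epsilon
}

#' Phase-switched MPC problem definition
#'
#' Weights, horizon and constraint sets of the receding-horizon problem.
#' Defaults follow the experimental controller configuration: 200 Hz
#' sampling with a 0.1 s prediction horizon (20 steps), stimulation bounds
#' 10-25 mA (plantarflexor) and 10-20 mA (dorsiflexor), and a +/-20 degree
#' clearance band on the ankle angle.  The numerical weights `Q`, `R`,
#' `terminal_epsilon` are free parameters chosen so that degree-scale
#' tracking errors dominate milliamp-scale inputs; all are exposed here.
#' State and terminal-set constraints are enforced as quadratic penalties
#' (soft), the input box is hard.
#'
#' @param horizon_steps prediction horizon in samples.
#' @param Q 2x2 positive-definite weight on (angle error, velocity error).
#' @param R positive scalar weight on the stimulation current.
#' @param u_min,u_max stimulation bounds per muscle (mA), named `pf`/`df`.
#' @param angle_bounds,velocity_bounds soft state box on the realized angle
#'   (rad) and velocity (rad/s).
#' @param terminal_epsilon terminal-set level.
#' @param sample_rate controller rate (Hz).
#' @param state_penalty_weight,terminal_penalty_weight soft-constraint
#'   weights.
#' @param max_iter,tol projected-gradient iteration cap and tolerance.
#' @return an `mpc_problem` object.
#' @export
mpc_problem <- function(horizon_steps = 20L,
                        Q = diag(c(100, 1)),
                        R = 0.01,
                        u_min = c(pf = 10, df = 10),
                        u_max = c(pf = 25, df = 20),
                        angle_bounds = deg2rad(c(-20, 20)),
                        velocity_bounds = c(-10, 10),
                        terminal_epsilon = 1,
                        sample_rate = 200,
                        state_penalty_weight = 1000,
                        terminal_penalty_weight = 1000,
                        max_iter = 200L,
                        tol = 1e-8) {
  if (horizon_steps < 1) stop_input("horizon_steps must be >= 1")
  ev <- eigen(symmetrize(as.matrix(Q)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) stop_input("Q must be positive semidefinite")
  if (R <= 0) stop_input("R must be positive")
  nm <- c("pf", "df")
  if (length(u_min) == 1L) u_min <- c(pf = unname(u_min), df = unname(u_min))
  if (length(u_max) == 1L) u_max <- c(pf = unname(u_max), df = unname(u_max))
  u_min <- u_min[nm]; u_max <- u_max[nm]
  if (any(is.na(u_min)) || any(is.na(u_max)))
    stop_input("u_min/u_max must be named with 'pf' and 'df'")
  if (any(u_min < 0) || any(u_min >= u_max))
    stop_input("need 0 <= u_min < u_max per muscle")
  if (terminal_epsilon <= 0) stop_input("terminal_epsilon must be positive")
  structure(list(
    horizon_steps = as.integer(horizon_steps), Q = as.matrix(Q), R = R,
    u_min = u_min, u_max = u_max,
    angle_bounds = angle_bounds, velocity_bounds = velocity_bounds,
    terminal_epsilon = terminal_epsilon, sample_rate = sample_rate,
    state_penalty_weight = state_penalty_weight,
    terminal_penalty_weight = terminal_penalty_weight,
    max_iter = as.integer(max_iter), tol = tol
  ), class = "mpc_problem")
}

#' Gait-phase flags over the prediction horizon
#'
#' Per-step stance/swing flags from the cycle schedule, switching at the
#' scheduled transition when it falls inside the horizon.
#'
#' @param sigma_now measured phase flag at the current step (consistency
#'   check against the schedule).
#' @param phase_clock time since the start of the current gait cycle (s).
#' @param timing list with `cycle_duration` and `stance_fraction`.
#' @param horizon_steps number of steps.
#' @param sample_rate sampling rate (Hz).
#' @return integer vector of length `horizon_steps`.
#' @export
build_horizon_schedule <- function(sigma_now, phase_clock, timing,
                                   horizon_steps, sample_rate) {
  t <- phase_clock + (seq_len(horizon_steps) - 1L) / sample_rate
  t_c <- t %% timing$cycle_duration
  t_c[t_c >= timing$cycle_duration] <- 0
  sigma <- ifelse(t_c < timing$stance_fraction * timing$cycle_duration, 0L, 1L)
  if (length(sigma) > 0L && sigma[1L] != sigma_now)
    warning("measured phase flag disagrees with the cycle schedule")
  sigma
}

# Projected-gradient (spectral/Barzilai-Borwein) solver for the condensed
# input-only problem
#   min_u  sum_{j=1..N-1} e_j'Qe_j + sum_j R u_j^2 + e_N'Se_N + penalties
#   s.t.   e_{j+1} = A_j e_j + B_j u_j + d_j,  lo_j <= u_j <= hi_j
# The terminal state carries only the terminal weight S, so with S solving
# the DARE the unconstrained problem is the stationary infinite-horizon
# regulator (receding-horizon consistency).
# Gradients are computed by the adjoint recursion; soft state-box and
# terminal-set penalties enter the stage gradients.  `pen` is NULL or
# list(angle_bounds, velocity_bounds, xd_angle, xd_velocity, w_state,
# w_terminal, S_term, epsilon) with xd_* the known reference channels at
# steps 1..N used to reconstitute absolute angle/velocity from the error.
mpc_core <- function(A_seq, B_seq, d_seq, e0, Q, R, S, lo, hi,
                     pen = NULL, u0 = NULL, max_iter = 200L, tol = 1e-8) {
  N <- length(A_seq)
  ne <- length(e0)
  clip <- function(u) pmin(pmax(u, lo), hi)
  u <- clip(u0 %||% (lo + hi) / 2)

  rollout <- function(u) {
    E <- matrix(0, ne, N + 1L)
    E[, 1L] <- e0
    for (j in seq_len(N))
      E[, j + 1L] <- A_seq[[j]] %*% E[, j] + B_seq[[j]] * u[j] + d_seq[[j]]
    E
  }
  box_pen <- function(v, b) {                 # value and derivative of
    h <- pmax(0, abs(v) - max(abs(b)))        # symmetric soft box
    list(val = h^2, grad = 2 * h * sign(v))
  }
  cost_grad <- function(u) {
    E <- rollout(u)
    Jq <- 0
    lam_next <- numeric(ne)
    g <- numeric(N)
    stage <- vector("list", N)
    for (j in seq_len(N)) {
      ej <- E[, j + 1L]
      if (j < N) {
        sg <- 2 * (Q %*% ej)
        Jq <- Jq + drop(crossprod(ej, Q %*% ej))
      } else {
        sg <- numeric(ne)
      }
      if (!is.null(pen)) {
        a <- ej[1L] + pen$xd_angle[j]
        v <- ej[2L] + pen$xd_velocity[j]
        pa <- box_pen(a, pen$angle_bounds)
        pv <- box_pen(v, pen$velocity_bounds)
        Jq <- Jq + pen$w_state * (pa$val + pv$val)
        sg[1L] <- sg[1L] + pen$w_state * pa$grad
        sg[2L] <- sg[2L] + pen$w_state * pv$grad
      }
      stage[[j]] <- sg
    }
    eN <- E[, N + 1L]
    Jq <- Jq + drop(crossprod(eN, S %*% eN)) + R * sum(u^2)
    stage[[N]] <- stage[[N]] + 2 * (S %*% eN)
    if (!is.null(pen)) {
      q <- drop(crossprod(eN, pen$S_term %*% eN))
      ex <- max(0, q - pen$epsilon)
      Jq <- Jq + pen$w_terminal * ex^2
      stage[[N]] <- stage[[N]] + 4 * pen$w_terminal * ex * (pen$S_term %*% eN)
    }
    for (j in rev(seq_len(N))) {
      lam <- drop(stage[[j]]) + if (j < N) drop(crossprod(A_seq[[j + 1L]], lam_next)) else numeric(ne)
      g[j] <- 2 * R * u[j] + drop(crossprod(B_seq[[j]], lam))
      lam_next <- lam
    }
    list(J = Jq, g = g)
  }

  cg <- cost_grad(u)
  fhist <- rep(cg$J, 10L)
  alpha <- 1 / max(2 * R, 1e-8)
  status <- "max_iter"
  it_used <- max_iter
  for (it in seq_len(max_iter)) {
    # optimality: projected-gradient stationarity
    pg <- u - clip(u - cg$g)
    if (max(abs(pg)) <= tol * (1 + max(abs(u)))) {
      status <- "converged"; it_used <- it - 1L
      break
    }
    fmax <- max(fhist)
    step <- alpha
    repeat {
      u_new <- clip(u - step * cg$g)
      du <- u_new - u
      if (all(du == 0)) break
      cg_new <- cost_grad(u_new)
      if (cg_new$J <= fmax + 1e-4 * sum(cg$g * du)) break
      step <- step / 2
      if (step < 1e-16) break
    }
    u_new <- clip(u - step * cg$g)
    du <- u_new - u
    if (all(du == 0)) { status <- "converged"; it_used <- it; break }
    cg_new <- cost_grad(u_new)
    dg <- cg_new$g - cg$g
    bb <- sum(du * dg)
    alpha <- if (bb > 0) min(max(sum(du * du) / bb, 1e-10), 1e10) else 1
    u <- u_new
    cg <- cg_new
    fhist <- c(fhist[-1L], cg$J)
  }
  E <- rollout(u)
  list(u = u, E = E, cost = cost_grad(u)$J, status = status,
       iterations = it_used)
}

# Split a reduced phase model into error-dynamics pieces for the layout.
phase_error_model <- function(model, phase) {
  ph <- model$phases[[phase]]
  lay <- model$layout
  if (lay$kind == "aug4") {
    list(A = ph$A_tilde[lay$err_idx, lay$err_idx, drop = FALSE],
         A_ref = ph$A_tilde[lay$err_idx, lay$ref_idx, drop = FALSE],
         B = ph$B_tilde[lay$err_idx, , drop = FALSE])
  } else {
    list(A = ph$A_tilde, A_ref = NULL, B = ph$B_tilde)
  }
}

# Terminal ingredients (DARE weight and LQR gain) for both phases.
terminal_ingredients <- function(model, prob) {
  out <- list()
  for (phase in c("P", "D")) {
    em <- phase_error_model(model, phase)
    S <- solve_dare(em$A, em$B, prob$Q, prob$R)
    K <- lqr_gain(em$A, em$B, S, prob$R)
    out[[phase]] <- list(S = S, K = K)
  }
  out
}

#' Stabilizing LQR terminal policy for one phase
#'
#' Returns the gain of the terminal control law `u = -K e` associated with
#' the phase's DARE terminal cost; applied inputs are clipped to the
#' admissible stimulation interval.
#'
#' @param model a `koopman_model`.
#' @param S DARE solution for the phase's error dynamics (see
#'   [solve_dare()]); computed from the model when `NULL`.
#' @param prob an [mpc_problem()].
#' @param phase `"P"` or `"D"`.
#' @return the gain matrix `K` (`1 x 2`).
#' @export
lqr_terminal_policy <- function(model, S = NULL, prob, phase = c("P", "D")) {
  phase <- match.arg(phase)
  em <- phase_error_model(model, phase)
  if (is.null(S)) S <- solve_dare(em$A, em$B, prob$Q, prob$R)
  lqr_gain(em$A, em$B, S, prob$R)
}

#' Solve one phase-switched MPC instance
#'
#' Minimizes the running tracking/effort cost plus the DARE terminal cost
#' over the horizon, subject to the switched linear predictor dynamics, the
#' hard stimulation box, and soft state-box and terminal-set penalties.
#' One muscle is decision-active per step, selected by the phase flag
#' (stance: plantarflexor, swing: dorsiflexor); the reference coordinates
#' are treated as known exogenous signals over the horizon.
#'
#' @param model a fitted `koopman_model` (4-dimensional augmented layout or
#'   plain 2-dimensional layout).
#' @param z0 current augmented state (layout order), or current
#'   `(theta, theta_dot)` for the 2-dimensional layout.
#' @param ref_window reference over the horizon: `2 x (N+1)` matrix with
#'   rows `(theta_d, theta_dot_d)` (or a `reference_trajectory` slice with
#'   `N+1` rows).
#' @param sigma_horizon phase flags for the `N` horizon steps.
#' @param prob an [mpc_problem()].
#' @param terminal optional precomputed [terminal_ingredients] (per-phase
#'   `S`, `K`); computed on the fly when `NULL`.
#' @param u_init optional warm-start input sequence.
#' @return an `mpc_solution`: list with `u_opt`, `z_pred`
#'   (`state_dim x (N+1)`), `cost`, `sigma`, `solver_status`, `iterations`.
#' @export
solve_mpc <- function(model, z0, ref_window, sigma_horizon, prob,
                      terminal = NULL, u_init = NULL) {
  N <- prob$horizon_steps
  if (length(sigma_horizon) != N)
    stop_input("sigma_horizon must have %d entries", N)
  if (!all(sigma_horizon %in% c(0, 1)))
    stop_input("phase flags must be 0/1")
  if (is.data.frame(ref_window))
    ref_window <- rbind(ref_window$theta_d, ref_window$theta_dot_d)
  if (ncol(ref_window) != N + 1L)
    stop_input("ref_window must cover N+1 = %d samples", N + 1L)
  lay <- model$layout
  if (is.null(terminal)) terminal <- terminal_ingredients(model, prob)
  phases <- ifelse(sigma_horizon == 0, "P", "D")
  ems <- list(P = phase_error_model(model, "P"),
              D = phase_error_model(model, "D"))
  A_seq <- vector("list", N); B_seq <- vector("list", N)
  d_seq <- vector("list", N)
  for (j in seq_len(N)) {
    em <- ems[[phases[j]]]
    A_seq[[j]] <- em$A
    B_seq[[j]] <- em$B
    d_seq[[j]] <- if (lay$kind == "aug4") {
      drop(em$A_ref %*% ref_window[, j])
    } else {
      drop(em$A %*% ref_window[, j]) - ref_window[, j + 1L]
    }
  }
  e0 <- if (lay$kind == "aug4") z0[lay$err_idx] else z0 - ref_window[, 1L]
  musc <- ifelse(sigma_horizon == 0, "pf", "df")
  lo <- unname(prob$u_min[musc]); hi <- unname(prob$u_max[musc])
  S_term <- terminal[[phases[N]]]$S
  pen <- list(angle_bounds = prob$angle_bounds,
              velocity_bounds = prob$velocity_bounds,
              xd_angle = ref_window[1L, -1L],
              xd_velocity = ref_window[2L, -1L],
              w_state = prob$state_penalty_weight,
              w_terminal = prob$terminal_penalty_weight,
              S_term = S_term, epsilon = prob$terminal_epsilon)
  sol <- mpc_core(A_seq, B_seq, d_seq, e0, prob$Q, prob$R, S_term,
                  lo, hi, pen = pen, u0 = u_init,
                  max_iter = prob$max_iter, tol = prob$tol)
  z_pred <- matrix(NA_real_, lay$state_dim, N + 1L)
  if (lay$kind == "aug4") {
    z_pred[lay$err_idx, ] <- sol$E
    z_pred[lay$ref_idx, ] <- ref_window
  } else {
    z_pred <- sol$E + ref_window
  }
  structure(list(u_opt = sol$u, z_pred = z_pred, cost = sol$cost,
                 sigma = sigma_horizon, solver_status = sol$status,
                 iterations = sol$iterations),
            class = "mpc_solution")
}

#' Closed-loop FES control of the nonlinear ankle plant
#'
#' Receding-horizon loop against the switched nonlinear simulator: at every
#' sample the plant state is measured, the gait phase is detected from the
#' plant's GRF channel (thresholding), the phase schedule over the horizon
#' is built from the cycle clock, the MPC instance is solved (warm-started
#' with the shifted previous solution), and the first input is applied to
#' the phase's muscle for one sampling interval.  If the solver errors
#' mid-run the previous input is held and the event is logged.
#'
#' @param model a fitted `koopman_model`.
#' @param params plant [ankle_params()]; its cycle timing drives the phase
#'   schedule.
#' @param ref a `reference_trajectory` covering the run (it is held at its
#'   final sample if the horizon peeks beyond its end).
#' @param prob an [mpc_problem()].
#' @param duration run length (s).
#' @param x0 initial plant state `c(theta, theta_dot)` (rad, rad/s).
#' @return list with `trajectory` (realized `ankle_trajectory`), `log`
#'   (per-step data frame: time, sigma, applied input, solver status, cost,
#'   iterations), and `reference`.
#' @export
closed_loop <- function(model, params, ref, prob, duration,
                        x0 = c(0, 0)) {
  dt <- 1 / prob$sample_rate
  n <- round(duration * prob$sample_rate)
  N <- prob$horizon_steps
  timing <- list(cycle_duration = params$cycle_duration,
                 stance_fraction = params$stance_fraction)
  terminal <- terminal_ingredients(model, prob)
  lay <- model$layout
  time <- (seq_len(n) - 1L) * dt
  ph <- phase_of_time(time, params)
  ref_at <- function(k) {       # clamp past the end of the reference
    k <- pmin(pmax(k, 1L), nrow(ref))
    rbind(ref$theta_d[k], ref$theta_dot_d[k])
  }
  theta <- numeric(n); theta_dot <- numeric(n)
  u_pf <- numeric(n); u_df <- numeric(n)
  theta[1] <- x0[1]; theta_dot[1] <- x0[2]
  log <- data.frame(time = time, sigma = ph$sigma, u_applied = NA_real_,
                    solver_status = NA_character_, cost = NA_real_,
                    iterations = NA_integer_)
  u_prev_seq <- NULL
  u_prev_applied <- 0
  for (k in seq_len(n)) {
    grf_k <- if (ph$sigma[k] == 0L) grf_force(ph$t_in_phase[k], params) else 0
    sigma_meas <- ph$sigma[k]    # schedule-based (GRF is zero at the exact
                                 # stance boundaries of the template)
    sig_h <- suppressWarnings(build_horizon_schedule(
      sigma_meas, time[k] %% params$cycle_duration, timing, N,
      prob$sample_rate))
    rw <- ref_at(k:(k + N))
    z0 <- if (lay$kind == "aug4") {
      c(theta[k] - rw[1, 1], rw[1, 1], theta_dot[k] - rw[2, 1], rw[2, 1])
    } else {
      c(theta[k], theta_dot[k])
    }
    sol <- tryCatch(
      solve_mpc(model, z0, rw, sig_h, prob, terminal = terminal,
                u_init = u_prev_seq),
      error = function(e) NULL
    )
    if (is.null(sol)) {
      u_k <- u_prev_applied
      log$solver_status[k] <- "error"
    } else {
      u_k <- sol$u_opt[1]
      u_prev_seq <- c(sol$u_opt[-1], sol$u_opt[length(sol$u_opt)])
      log$solver_status[k] <- sol$solver_status
      log$cost[k] <- sol$cost
      log$iterations[k] <- sol$iterations
    }
    u_prev_applied <- u_k
    log$u_applied[k] <- u_k
    if (sigma_meas == 0L) u_pf[k] <- u_k else u_df[k] <- u_k
    if (k < n) {
      st <- rk4_plant_step(theta[k], theta_dot[k], u_pf[k], u_df[k],
                           ph$sigma[k], ph$t_in_phase[k], dt, params)
      theta[k + 1L] <- st[1]; theta_dot[k + 1L] <- st[2]
    }
  }
  grf <- ifelse(ph$sigma == 0L, grf_force(ph$t_in_phase, params), 0)
  traj <- new_trajectory(time, theta, theta_dot, u_pf, u_df, grf, ph$sigma)
  list(trajectory = traj, log = log, reference = ref)
}

# One RK4 step of the plant with frozen phase flag and ZOH input.
rk4_plant_step <- function(th, om, u_pf, u_df, sigma, t_in_phase, h, params) {
  k1 <- ankle_rhs(th, om, u_pf, u_df, sigma, t_in_phase, params)
  k2 <- ankle_rhs(th + h / 2 * k1[1], om + h / 2 * k1[2], u_pf, u_df, sigma,
                  t_in_phase + h / 2, params)
  k3 <- ankle_rhs(th + h / 2 * k2[1], om + h / 2 * k2[2], u_pf, u_df, sigma,
                  t_in_phase + h / 2, params)
  k4 <- ankle_rhs(th + h * k3[1], om + h * k3[2], u_pf, u_df, sigma,
                  t_in_phase + h, params)
  c(th + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]),
    om + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]))
}
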