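test_that("DARE solution satisfies its fixed point and stabilizes the loop", {
  # A = 0: substituting into the recursion gives S = Q immediately
  Q <- diag(c(2, 3))
  S <- solve_dare(matrix(0, 2, 2), matrix(c(1, 0), 2), Q, 1)
  expect_equal(unclass(S), Q, ignore_attr = TRUE)
  # scalar case against an independent fixed-point iteration
  a <- 0.5; b <- 1; q <- 1; r <- 1
  s <- 0
  for (i in 1:200) s <- a^2 * s - a^2 * s^2 * b^2 / (r + b^2 * s) + q
  S1 <- solve_dare(a, b, q, r)
  expect_equal(as.numeric(S1), s, tolerance = 1e-10)
  # random stabilizable 3x3 pairs: residual and closed-loop contraction
  set.seed(31)
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3)
    A <- A / max(Mod(eigen(A)$values)) * runif(1, 0.3, 0.95)
    B <- matrix(rnorm(3), 3)
    Qr <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    R <- runif(1, 0.1, 2)
    S <- solve_dare(A, B, Qr, R)
    expect_lte(attr(S, "residual"), 1e-8 * koopmanfes:::frob(S))
    K <- lqr_gain(A, B, S, R)
    expect_lt(max(Mod(eigen(A - B %*% K)$values)), 1)
  }
})

test_that("LQR gain has its closed forms", {
  # B = 0 on a stable A: zero gain
  A <- diag(c(0.5, 0.3)); B <- matrix(0, 2, 1); Q <- diag(2)
  S <- solve_dare(A, B, Q, 1)
  expect_equal(lqr_gain(A, B, S, 1), matrix(0, 1, 2))
  # scalar algebra
  a <- 0.8; b <- 0.5; q <- 2; r <- 0.1
  S <- solve_dare(a, b, q, r)
  s <- as.numeric(S)
  expect_equal(as.numeric(lqr_gain(a, b, S, r)), b * s * a / (r + b^2 * s))
})

test_that("horizon schedule reproduces the cycle timing", {
  timing <- list(cycle_duration = 1, stance_fraction = 0.6)
  # horizon entirely inside swing
  expect_equal(build_horizon_schedule(1, 0.7, timing, 20, 200), rep(1L, 20))
  # transition 3 steps in: clock at t_st - 3 dt
  sig <- build_horizon_schedule(0, 0.6 - 3 / 200, timing, 20, 200)
  expect_equal(sig, c(rep(0L, 3), rep(1L, 17)))
  # brute-force per-step membership oracle across random clocks
  set.seed(6)
  for (i in 1:20) {
    clock <- runif(1, 0, 1)
    sig <- suppressWarnings(
      build_horizon_schedule(0, clock, timing, 40, 200))
    t <- clock + (0:39) / 200
    brute <- ifelse(t %% 1 < 0.6, 0L, 1L)
    expect_identical(sig, brute)
  }
  expect_warning(build_horizon_schedule(1, 0.1, timing, 5, 200), "disagrees")
})

test_that("terminal-set membership is the quadratic-form test", {
  expect_true(terminal_check(c(0, 0), diag(2), 0.5))
  expect_true(terminal_check(1, matrix(2), 2))       # boundary
  expect_false(terminal_check(1.01, matrix(2), 2))
  set.seed(8)
  S <- crossprod(matrix(rnorm(4), 2))
  for (i in 1:10) {
    z <- rnorm(2)
    expect_identical(terminal_check(z, S, 1.3),
                     drop(t(z) %*% S %*% z) <= 1.3)
  }
})

test_that("terminal epsilon calibration bounds the LQR action on the set", {
  m <- toy_linear_model()
  prob <- mpc_problem()
  em <- koopmanfes:::phase_error_model(m, "D")
  S <- solve_dare(em$A, em$B, prob$Q, prob$R)
  K <- lqr_terminal_policy(m, S, prob, "D")
  eps <- calibrate_terminal_epsilon(K, S, u_halfwidth = 5)
  # max |K e| over the ellipse equals the closed form; sample the boundary
  set.seed(12)
  worst <- max(replicate(500, {
    v <- rnorm(2); v <- v / sqrt(drop(t(v) %*% S %*% v)) * sqrt(eps)
    abs(drop(K %*% v))
  }))
  expect_lte(worst, 5 + 1e-8)
  expect_gt(worst, 4.5)   # the bound is tight, not vacuous
})

test_that("unconstrained MPC matches the dense KKT oracle", {
  m <- toy_linear_model()
  Q <- diag(c(100, 1)); R <- 0.01; N <- 12
  em <- koopmanfes:::phase_error_model(m, "D")
  S <- solve_dare(em$A, em$B, Q, R)
  set.seed(17)
  for (i in 1:5) {
    e0 <- c(runif(1, -0.3, 0.3), runif(1, -1, 1))
    sol <- koopmanfes:::mpc_core(rep(list(em$A), N), rep(list(em$B), N),
                                 rep(list(c(0, 0)), N), e0, Q, R, S,
                                 rep(-1e7, N), rep(1e7, N),
                                 max_iter = 500, tol = 1e-12)
    qp <- dense_qp(em$A, em$B, Q, R, S, e0, N)
    u_star <- drop(solve(qp$H, -qp$f))
    expect_equal(sol$u, u_star, tolerance = 1e-6)
    expect_equal(sol$status, "converged")
  }
  # the user-facing switched solve agrees with the core on a bounded
  # instance (the lower stimulation bound active early in the horizon)
  prob <- mpc_problem(horizon_steps = N, u_min = 0, u_max = 40,
                      state_penalty_weight = 0, terminal_penalty_weight = 0,
                      max_iter = 500, tol = 1e-12)
  sol1 <- solve_mpc(m, c(0.2, 0), matrix(0, 2, N + 1), rep(1L, N), prob)
  sol2 <- koopmanfes:::mpc_core(rep(list(em$A), N), rep(list(em$B), N),
                                rep(list(c(0, 0)), N), c(0.2, 0), Q, R, S,
                                rep(0, N), rep(40, N),
                                max_iter = 500, tol = 1e-12)
  expect_equal(sol1$u_opt, sol2$u, tolerance = 1e-8)
})

test_that("on-reference equilibrium needs no input and costs nothing", {
  m <- toy_linear_model()
  prob <- mpc_problem(horizon_steps = 10, u_min = 0, u_max = 30)
  sol <- solve_mpc(m, c(0, 0), matrix(0, 2, 11), rep(1L, 10), prob)
  expect_equal(sol$u_opt, rep(0, 10), tolerance = 1e-8)
  expect_lt(sol$cost, 1e-12)
  expect_equal(sol$solver_status, "converged")
})

test_that("input box binds and tightening it never lowers the cost", {
  m <- toy_linear_model()
  em <- koopmanfes:::phase_error_model(m, "D")
  z0 <- c(-0.4, 0)   # needs a large positive dorsiflexor push
  costs <- c()
  for (umax in c(40, 20, 10, 5)) {
    prob <- mpc_problem(horizon_steps = 10, u_min = 0,
                        u_max = c(pf = umax, df = umax),
                        state_penalty_weight = 0,
                        terminal_penalty_weight = 0, max_iter = 500)
    sol <- solve_mpc(m, z0, matrix(0, 2, 11), rep(1L, 10), prob)
    expect_true(all(sol$u_opt <= umax + 1e-12 & sol$u_opt >= -1e-12))
    costs <- c(costs, sol$cost)
  }
  expect_true(all(diff(costs) >= -1e-8))      # tighter box, larger cost
  expect_gt(max(abs(costs[4] - costs[1])), 0) # the box actually binds
})

test_that("receding horizon is consistent with the DARE terminal cost", {
  m <- toy_linear_model()
  Q <- diag(c(100, 1)); R <- 0.01; N <- 8
  em <- koopmanfes:::phase_error_model(m, "D")
  S <- solve_dare(em$A, em$B, Q, R)
  run <- function(e0) koopmanfes:::mpc_core(
    rep(list(em$A), N), rep(list(em$B), N), rep(list(c(0, 0)), N),
    e0, Q, R, S, rep(-1e7, N), rep(1e7, N), max_iter = 500, tol = 1e-12)
  e0 <- c(0.2, -0.5)
  sol1 <- run(e0)
  e1 <- drop(em$A %*% e0 + em$B %*% sol1$u[1])
  sol2 <- run(e1)
  # with the infinite-horizon terminal cost the re-solve reproduces the
  # shifted tail of the previous solution (principle of optimality)
  expect_equal(sol2$u[1:(N - 1)], sol1$u[2:N], tolerance = 1e-5)
})

test_that("value function decreases under the terminal LQR policy", {
  m <- toy_linear_model()
  prob <- mpc_problem()
  for (phase in c("P", "D")) {
    em <- koopmanfes:::phase_error_model(m, phase)
    S <- solve_dare(em$A, em$B, prob$Q, prob$R)
    K <- lqr_terminal_policy(m, S, prob, phase)
    u_half <- (prob$u_max[[if (phase == "P") "pf" else "df"]] -
                 prob$u_min[[if (phase == "P") "pf" else "df"]]) / 2
    eps <- calibrate_terminal_epsilon(K, S, u_half)
    e <- c(1, 0.5)
    e <- e / sqrt(drop(t(e) %*% S %*% e)) * sqrt(0.95 * eps)
    V <- drop(t(e) %*% S %*% e)
    for (k in 1:200) {
      u <- drop(-K %*% e)
      expect_lte(abs(u), u_half + 1e-9)   # policy feasible on the set
      l <- drop(t(e) %*% prob$Q %*% e) + prob$R * u^2
      e <- drop(em$A %*% e + em$B %*% u)
      V1 <- drop(t(e) %*% S %*% e)
      expect_lte(V1, V - l + 1e-8 * (1 + V))
      V <- V1
    }
  }
})

test_that("nominal closed loop on the model itself drives the error to zero", {
  m <- toy_linear_model()
  Q <- diag(c(100, 1)); R <- 0.01; N <- 10
  em <- koopmanfes:::phase_error_model(m, "D")
  S <- solve_dare(em$A, em$B, Q, R)
  e <- c(0.3, 0)
  norms <- sqrt(sum(e^2))
  u_init <- NULL
  for (k in 1:200) {
    sol <- koopmanfes:::mpc_core(rep(list(em$A), N), rep(list(em$B), N),
                                 rep(list(c(0, 0)), N), e, Q, R, S,
                                 rep(-1e7, N), rep(1e7, N),
                                 u0 = u_init, max_iter = 500, tol = 1e-10)
    u_init <- c(sol$u[-1], sol$u[N])
    e <- drop(em$A %*% e + em$B %*% sol$u[1])
    norms <- c(norms, sqrt(sum(e^2)))
  }
  expect_lt(norms[201], 1e-4)
  # geometric decay: contracts by at least half every 50 steps
  expect_lt(norms[101], norms[51] / 2)
  expect_lt(norms[151], norms[101] / 2)
})

test_that("solver refinement does not change the applied input", {
  m <- toy_linear_model()
  z0 <- c(-0.25, 0.4)
  p1 <- mpc_problem(horizon_steps = 10, max_iter = 200)
  p2 <- mpc_problem(horizon_steps = 10, max_iter = 400)
  s1 <- solve_mpc(m, z0, matrix(0, 2, 11), rep(1L, 10), p1)
  s2 <- solve_mpc(m, z0, matrix(0, 2, 11), rep(1L, 10), p2)
  expect_equal(s1$u_opt[1], s2$u_opt[1], tolerance = 1e-6)
})

test_that("problem validation rejects inconsistent configurations", {
  expect_error(mpc_problem(horizon_steps = 0), "horizon")
  expect_error(mpc_problem(R = 0), "positive")
  expect_error(mpc_problem(u_min = c(pf = 30, df = 10),
                           u_max = c(pf = 25, df = 20)), "u_min")
  expect_error(mpc_problem(Q = matrix(c(1, 2, 2, -3), 2)), "semidefinite")
  # default timing: 20 steps at 200 Hz is the 0.1 s horizon
  prob <- mpc_problem()
  expect_equal(prob$horizon_steps / prob$sample_rate, 0.1)
})

test_that("closed loop on the nonlinear plant respects the stimulation box", {
  m <- control_model()
  prob <- mpc_problem(horizon_steps = 10, max_iter = 60)
  p <- test_params()
  p$cycle_duration <- 2
  timing <- list(cycle_duration = 2, stance_fraction = p$stance_fraction,
                 sample_rate = 200)
  ref <- make_reference("gait_setpoints", timing = timing, duration = 2.2)
  run <- closed_loop(m, p, ref, prob, duration = 1, x0 = c(0, 0))
  expect_equal(nrow(run$trajectory), 200)
  u <- run$log$u_applied
  musc <- ifelse(run$log$sigma == 0, "pf", "df")
  expect_true(all(u >= prob$u_min[musc] - 1e-9))
  expect_true(all(u <= prob$u_max[musc] + 1e-9))
  expect_true(all(run$log$solver_status %in% c("converged", "max_iter")))
  # applied inputs land on the phase-active muscle channel
  expect_true(all(run$trajectory$u_df[run$trajectory$sigma == 0] == 0))
  expect_true(all(run$trajectory$u_pf[run$trajectory$sigma == 1] == 0))
})
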