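# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default plant used throughout the tests.
test_params <- function(...) ankle_params(...)

# Ramp-excited identification dataset (the printed training protocol).
ramp_dataset <- function(n_cycles = 30, seed = 42) {
  cached(sprintf("ramp_%d_%d", n_cycles, seed),
         generate_dataset(datagen_config(n_cycles = n_cycles, seed = seed),
                          test_params()))
}

# Randomized-level dataset used to identify the controller model.
control_dataset <- function(n_cycles = 30, seed = 43) {
  cached(sprintf("ctrl_%d_%d", n_cycles, seed),
         generate_dataset(datagen_config(n_cycles = n_cycles, seed = seed,
                                         u_mode = "random"),
                          test_params()))
}

# Controller model in absolute joint coordinates (2-dim custom dictionary).
control_model <- function() {
  cached("control_model", suppressWarnings(
    fit_koopman(control_dataset(), make_dictionary("custom", 1, 2))))
}

quiet_fit <- function(...) suppressWarnings(fit_koopman(...))

# Snapshot set generated by a known linear system z+ = A z + B u under the
# `state` dictionary; the primary oracle for exactness of the EDMD fit.
linear_system_snapshots <- function(n = 3, M = 400, seed = 1,
                                    radius = 0.8) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  A <- A / max(Mod(eigen(A)$values)) * radius
  B <- matrix(rnorm(n), n)
  Z <- matrix(0, n, M)
  U <- runif(M - 1, -1, 1)
  Z[, 1] <- rnorm(n)
  for (k in seq_len(M - 1)) Z[, k + 1] <- A %*% Z[, k] + B * U[k]
  dict <- make_dictionary("state", 1, n)
  snaps <- snapshots_from_matrix(Z, U, dict)
  list(A = A, B = B, Z = Z, U = U, dict = dict, snaps = snaps)
}

# Build a snapshot_set directly from a state matrix and scalar input series
# (columns 1..M-1 paired with 2..M).
snapshots_from_matrix <- function(Z, U, dict) {
  M <- ncol(Z)
  Psi <- lift_batch_test(Z, dict, 1:(M - 1))
  Psi1 <- lift_batch_test(Z, dict, 2:M)
  structure(list(
    D_k = rbind(Psi, u = U[1:(M - 1)]),
    D_k1 = rbind(Psi1, u = c(U[2:(M - 1)], 0)),
    states = Z[, 1:(M - 1), drop = FALSE],
    states_next = Z[, 2:M, drop = FALSE],
    phase = "P", lifted_dim = dict$lifted_dim, layout = NULL
  ), class = "snapshot_set")
}

# Window lifting through the public lift() interface only.
lift_batch_test <- function(Z, dict, ends) {
  L <- dict$embedding_length
  vapply(ends, function(k)
    lift(Z[, (k - L + 1):k, drop = FALSE], dict),
    numeric(dict$lifted_dim))
}

# Hand-built switched linear "koopman_model" in the plain 2-dim layout:
# exact discretization of a damped oscillator per phase.  Used to test the
# controller in isolation from identification.
toy_linear_model <- function(k_st = 3, k_sw = 3, b = 0.1,
                             J_st = 0.02, J_sw = 0.01,
                             gain_st = -0.08, gain_sw = 0.08,
                             dt = 1 / 200) {
  phase_mats <- function(k, J, gain) {
    Ac <- matrix(c(0, -k / J, 1, -b / J), 2)
    Bc <- c(0, gain / J)
    # exact ZOH discretization via the augmented-matrix exponential trick
    Mx <- rbind(cbind(Ac, Bc), 0)
    E <- expm_taylor(Mx * dt)
    list(A = E[1:2, 1:2], B = matrix(E[1:2, 3], 2))
  }
  p <- phase_mats(k_st, J_st, gain_st)
  d <- phase_mats(k_sw, J_sw, gain_sw)
  dict <- make_dictionary("state", 1, 2)
  mk <- function(ph) list(K_xx = rbind(cbind(ph$A, 0), c(0, 0, 1)),
                          K_xu = rbind(ph$B, 0),
                          C = cbind(diag(2), 0),
                          A_tilde = ph$A, B_tilde = ph$B)
  structure(list(
    dictionary = dict,
    layout = koopmanfes:::state_layout(2L),
    C = cbind(diag(2), 0),
    phases = list(P = mk(p), D = mk(d)),
    fit_diagnostics = list()
  ), class = "koopman_model")
}

# Scaling-and-squaring-free matrix exponential (small matrices, small norm).
expm_taylor <- function(M, terms = 30) {
  out <- diag(nrow(M))
  term <- diag(nrow(M))
  for (i in seq_len(terms)) {
    term <- term %*% M / i
    out <- out + term
  }
  out
}

# Condensed-QP matrices of the single-phase finite-horizon problem; an
# independent dense oracle for the projected-gradient solver.
dense_qp <- function(A, B, Q, R, S, e0, N) {
  n <- nrow(A)
  Gam <- matrix(0, n * N, N)
  Phi <- matrix(0, n * N, n)
  Ap <- diag(n)
  for (j in 1:N) {
    Ap <- A %*% Ap
    Phi[((j - 1) * n + 1):(j * n), ] <- Ap
    for (i in 1:j) {
      Aji <- diag(n)
      if (j - i > 0) for (q in 1:(j - i)) Aji <- A %*% Aji
      Gam[((j - 1) * n + 1):(j * n), i] <- Aji %*% B
    }
  }
  Qbar <- kronecker(diag(N), Q)
  idx <- ((N - 1) * n + 1):(N * n)
  Qbar[idx, idx] <- S   # stage cost at 1..N-1, terminal weight alone at N
  H <- 2 * (t(Gam) %*% Qbar %*% Gam + R * diag(N))
  f <- 2 * t(Gam) %*% Qbar %*% Phi %*% e0
  c0 <- drop(t(e0) %*% t(Phi[1:n, , drop = FALSE])) # unused constant
  list(H = H, f = f, Gam = Gam, Phi = Phi, Qbar = Qbar)
}
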