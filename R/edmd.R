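#' Assemble phase-restricted snapshot matrices
#'
#' Collects lifted snapshot pairs from one or more trajectories for a single
#' gait phase.  Column `j` of `D_k1` is the lift of the successor of column
#' `j` of `D_k`; both matrices stack the state observables over the input
#' (`[Psi_x; u]`), and every column is drawn from an interval of the
#' requested phase (windows that would straddle a stance/swing transition
#' are dropped, honoring continuity of the states at the switch).  The
#' active input channel is the phase's muscle: plantarflexor current in
#' stance (`"P"`), dorsiflexor current in swing (`"D"`).
#'
#' @param trajs an `ankle_trajectory` or list of them (optionally carrying
#'   `"reference"` attributes, see [augment_states()]).
#' @param dict an [make_dictionary()] object.
#' @param phase `"P"` (stance) or `"D"` (swing).
#' @param balance_to optional column budget: the pair set is thinned to at
#'   most this many columns with evenly spaced (deterministic) subsampling;
#'   used to even out stance/swing snapshot counts.
#' @return a `snapshot_set`: list with `D_k`, `D_k1` (`(P+1) x M` matrices),
#'   `states` (raw states aligned to `D_k` columns), `states_next`, `phase`,
#'   `lifted_dim`, `layout`.
#' @export
assemble_snapshots <- function(trajs, dict, phase = c("P", "D"),
                               balance_to = NULL) {
  phase <- match.arg(phase)
  phase_sigma <- if (phase == "P") 0L else 1L
  if (inherits(trajs, "ankle_trajectory")) trajs <- list(trajs)
  L <- dict$embedding_length
  psi_k <- list(); psi_k1 <- list(); uk <- list(); uk1 <- list()
  zk <- list(); zk1 <- list(); layout <- NULL
  for (tr in trajs) {
    Z <- augment_states(tr, state_dim = dict$state_dim)
    layout <- attr(Z, "layout")
    if (nrow(Z) != dict$state_dim)
      stop_input("trajectory yields %d-dimensional states, dictionary expects %d",
                 nrow(Z), dict$state_dim)
    ends <- valid_pair_ends(tr$sigma, L, phase_sigma)
    if (length(ends) == 0L) next
    u_active <- if (phase == "P") tr$u_pf else tr$u_df
    psi_k[[length(psi_k) + 1L]] <- lift_batch(Z, dict, ends)
    psi_k1[[length(psi_k1) + 1L]] <- lift_batch(Z, dict, ends + 1L)
    uk[[length(uk) + 1L]] <- u_active[ends]
    uk1[[length(uk1) + 1L]] <- u_active[ends + 1L]
    zk[[length(zk) + 1L]] <- Z[, ends, drop = FALSE]
    zk1[[length(zk1) + 1L]] <- Z[, ends + 1L, drop = FALSE]
  }
  if (length(psi_k) == 0L)
    stop_input("no same-phase snapshot pairs found for phase %s", phase)
  Psi <- do.call(cbind, psi_k); Psi1 <- do.call(cbind, psi_k1)
  u <- unlist(uk); u1 <- unlist(uk1)
  Zk <- do.call(cbind, zk); Zk1 <- do.call(cbind, zk1)
  M <- ncol(Psi)
  if (!is.null(balance_to) && M > balance_to) {
    keep <- unique(round(seq(1L, M, length.out = balance_to)))
    Psi <- Psi[, keep, drop = FALSE]; Psi1 <- Psi1[, keep, drop = FALSE]
    u <- u[keep]; u1 <- u1[keep]
    Zk <- Zk[, keep, drop = FALSE]; Zk1 <- Zk1[, keep, drop = FALSE]
  }
  structure(list(
    D_k = rbind(Psi, u = u),
    D_k1 = rbind(Psi1, u = u1),
    states = Zk, states_next = Zk1,
    phase = phase, lifted_dim = dict$lifted_dim, layout = layout
  ), class = "snapshot_set")
}

#' Least-squares EDMD operator fit
#'
#' Solves the snapshot regression `D_k1 ~ K D_k` through the empirical
#' covariance form `K = F G^+`, with `F = (1/M) sum D_k1 D_k'` and
#' `G = (1/M) sum D_k D_k'`.  `G^+` is the SVD pseudoinverse; an optional
#' ridge turns it into `(G + ridge I)^{-1}` for collinear dictionaries.
#' The rows evolving the control observables are fitted and discarded; only
#' the state-observable blocks are returned.
#'
#' @param snaps a `snapshot_set`.
#' @param ridge nonnegative ridge parameter (default `1e-8`; set to 0 for
#'   the plain SVD pseudoinverse).  The tiny default stabilizes collinear
#'   observables (e.g. an angle and its sine at small angles, or adjacent
#'   delayed states at a high sampling rate).
#' @return list with `K_xx` (`P x P`), `K_xu` (`P x m`), `residual`
#'   (Frobenius norm of the one-step fit error), `cond_G`.
#' @export
fit_operator <- function(snaps, ridge = 1e-8) {
  Dk <- snaps$D_k; Dk1 <- snaps$D_k1
  M <- ncol(Dk)
  if (M < 1L) stop_input("need at least one snapshot pair")
  if (all(Dk == 0))
    stop_input("degenerate fit: all snapshot columns are zero (M = %d)", M)
  F_ <- tcrossprod(Dk1, Dk) / M
  G <- tcrossprod(Dk) / M
  K <- if (ridge > 0) {
    F_ %*% solve(G + ridge * diag(nrow(G)))
  } else {
    F_ %*% pinv_svd(G)
  }
  P <- snaps$lifted_dim
  m <- nrow(Dk) - P
  list(K_xx = unname(K[seq_len(P), seq_len(P), drop = FALSE]),
       K_xu = unname(K[seq_len(P), P + seq_len(m), drop = FALSE]),
       residual = frob(Dk1 - K %*% Dk) / sqrt(M),
       cond_G = cond2(G))
}

#' Least-squares state-recovery map
#'
#' Fits the linear map `C` minimizing `||C Psi - z||` over all supplied
#' snapshot sets pooled together (one recovery map is shared by both
#' phases).  Only the state-observable rows of the snapshots enter.
#'
#' @param snaps a `snapshot_set` or list of them (e.g. both phases).
#' @param ridge nonnegative ridge parameter.
#' @return list with `C` (`n x P`), `residual` (RMS reconstruction error on
#'   the training columns), `cond_Psi`.
#' @export
fit_recovery <- function(snaps, ridge = 1e-8) {
  if (inherits(snaps, "snapshot_set")) snaps <- list(snaps)
  P <- snaps[[1]]$lifted_dim
  Psi <- do.call(cbind, lapply(snaps, function(s) s$D_k[seq_len(P), , drop = FALSE]))
  Z <- do.call(cbind, lapply(snaps, function(s) s$states))
  M <- ncol(Psi)
  G <- tcrossprod(Psi) / M
  cnd <- cond2(G)
  if (!is.finite(cnd) || cnd > 1e14)
    warning(sprintf("rank-deficient lifted data (cond %.3g); regularized solve",
                    cnd))
  C <- if (ridge > 0) {
    (tcrossprod(Z, Psi) / M) %*% solve(G + ridge * diag(nrow(G)))
  } else {
    (tcrossprod(Z, Psi) / M) %*% pinv_svd(G)
  }
  list(C = unname(C), residual = frob(C %*% Psi - Z) / sqrt(M),
       cond_Psi = cnd)
}

#' Reduce the lifted operator to state-space predictor matrices
#'
#' Maps the fitted lifted-space blocks down to the original state
#' coordinates: `A = C K_xx C^+`, `B = C K_xu`, where `C^+` is a
#' right-inverse of the (non-square) recovery map.  When snapshot data are
#' supplied, `C^+` is the right-inverse restricted to the lifted training
#' subspace: the least-squares pseudo-lift `E = Psi Z^+` fitted on the
#' training columns, which keeps the reduced dynamics on the manifold the
#' observables actually visited (the minimum-norm Moore-Penrose inverse
#' re-lifts states off that manifold - e.g. it does not map the constant
#' observable back to one - and can introduce spurious unstable modes).
#' Without data the Moore-Penrose inverse is used.
#'
#' @param K_xx,K_xu fitted operator blocks.
#' @param C state-recovery map.
#' @param snaps optional `snapshot_set` or list of them providing the
#'   training columns for the restricted right-inverse.
#' @return list with `A_tilde` (`n x n`), `B_tilde` (`n x m`), `cond_C`.
#' @export
reduce_model <- function(K_xx, K_xu, C, snaps = NULL) {
  cnd <- cond2(C)
  if (!is.finite(cnd) || cnd > 1e10)
    warning(sprintf("ill-conditioned recovery map (cond %.3g)", cnd))
  C_right <- if (is.null(snaps)) {
    pinv_svd(C)
  } else {
    if (inherits(snaps, "snapshot_set")) snaps <- list(snaps)
    P <- snaps[[1]]$lifted_dim
    Psi <- do.call(cbind, lapply(snaps, function(s) s$D_k[seq_len(P), , drop = FALSE]))
    Z <- do.call(cbind, lapply(snaps, function(s) s$states))
    Psi %*% pinv_svd(Z)
  }
  list(A_tilde = unname(C %*% K_xx %*% C_right),
       B_tilde = unname(C %*% K_xu),
       cond_C = cnd)
}

#' Fit a switched Koopman predictor from gait trajectories
#'
#' End-to-end EDMD identification: assembles per-phase snapshot sets,
#' optionally balances their sizes (the stance interval is typically longer
#' than swing, so stance pairs are thinned to the swing count), fits one
#' operator per phase, fits a pooled recovery map, and reduces to the
#' switched linear predictor matrices.
#'
#' @param trajs list of `ankle_trajectory` objects (with references attached
#'   when the 4-dimensional augmented state is used).
#' @param dict an [make_dictionary()] object.
#' @param ridge nonnegative ridge for the least-squares solves.
#' @param balance logical; even out stance/swing snapshot counts.
#' @param per_phase_recovery fit a separate recovery map per phase instead
#'   of the default pooled map.
#' @return a `koopman_model`: per-phase operator blocks and reduced
#'   matrices, the recovery map, the dictionary, and fit diagnostics.
#' @export
fit_koopman <- function(trajs, dict, ridge = 1e-8, balance = TRUE,
                        per_phase_recovery = FALSE) {
  sp <- assemble_snapshots(trajs, dict, "P")
  sd_ <- assemble_snapshots(trajs, dict, "D")
  if (balance) {
    m <- min(ncol(sp$D_k), ncol(sd_$D_k))
    sp <- assemble_snapshots(trajs, dict, "P", balance_to = m)
    sd_ <- assemble_snapshots(trajs, dict, "D", balance_to = m)
  }
  op_p <- fit_operator(sp, ridge)
  op_d <- fit_operator(sd_, ridge)
  if (per_phase_recovery) {
    rec_p <- fit_recovery(sp, ridge)
    rec_d <- fit_recovery(sd_, ridge)
  } else {
    rec_p <- rec_d <- fit_recovery(list(sp, sd_), ridge)
  }
  pooled <- list(sp, sd_)
  red_p <- reduce_model(op_p$K_xx, op_p$K_xu, rec_p$C,
                        snaps = if (per_phase_recovery) sp else pooled)
  red_d <- reduce_model(op_d$K_xx, op_d$K_xu, rec_d$C,
                        snaps = if (per_phase_recovery) sd_ else pooled)
  structure(list(
    dictionary = dict,
    layout = sp$layout,
    C = rec_p$C,
    phases = list(
      P = list(K_xx = op_p$K_xx, K_xu = op_p$K_xu, C = rec_p$C,
               A_tilde = red_p$A_tilde, B_tilde = red_p$B_tilde),
      D = list(K_xx = op_d$K_xx, K_xu = op_d$K_xu, C = rec_d$C,
               A_tilde = red_d$A_tilde, B_tilde = red_d$B_tilde)
    ),
    fit_diagnostics = list(
      n_pairs = c(P = ncol(sp$D_k), D = ncol(sd_$D_k)),
      residual_operator = c(P = op_p$residual, D = op_d$residual),
      residual_recovery = c(P = rec_p$residual, D = rec_d$residual),
      cond_G = c(P = op_p$cond_G, D = op_d$cond_G),
      cond_C = c(P = red_p$cond_C, D = red_d$cond_C)
    )
  ), class = "koopman_model")
}

#' @export
print.koopman_model <- function(x, ...) {
  d <- x$fit_diagnostics
  cat(sprintf("Switched Koopman predictor ('%s' dictionary, L=%d, P=%d, state dim %d)\n",
              x$dictionary$name, x$dictionary$embedding_length,
              x$dictionary$lifted_dim, x$layout$state_dim))
  cat(sprintf("  snapshot pairs: stance %d, swing %d\n",
              d$n_pairs["P"], d$n_pairs["D"]))
  cat(sprintf("  one-step residuals (operator): P %.3g, D %.3g; recovery: %.3g\n",
              d$residual_operator["P"], d$residual_operator["D"],
              d$residual_recovery["P"]))
  invisible(x)
}

#' Multi-step rollout of the switched linear predictor
#'
#' Rolls the identified model forward from an initial window of measured
#' states, switching the operator blocks with the phase flag.  Three rollout
#' paths are provided:
#' \describe{
#'   \item{`"relift"`}{(default) each step lifts the current window of
#'     predicted states, applies the operator once, and recovers the state:
#'     `z_{k+1} = C (K_xx Psi(window_k) + K_xu u_k)`.  This reads the
#'     recovery inverse as the lifting map itself, applies the operator
#'     exactly on the manifold it was trained on, and is the most accurate
#'     multi-step path.}
#'   \item{`"lifted"`}{the initial window is lifted once and the lifted state
#'     evolves linearly, `Psi_{k+1} = K_xx Psi_k + K_xu u_k`, with the state
#'     recovered as `z_k = C Psi_k` (the linear lifted-space predictor; can
#'     drift along poorly excited lifted directions over long rollouts).}
#'   \item{`"reduced"`}{the reduced matrices propagate the raw state,
#'     `z_{k+1} = A z_k + B u_k` (the linear model the controller uses).}
#' }
#'
#' @param model a `koopman_model`.
#' @param z0_window `state_dim x L` matrix of the `L` states preceding the
#'   first prediction (columns oldest to newest; a vector when `L = 1`).
#' @param u_pf_series,u_df_series input currents (mA) for steps
#'   `1..n_steps`; the phase flag selects the active channel.
#' @param sigma_series phase flags for steps `1..n_steps`.
#' @param method `"relift"` (default), `"lifted"`, or `"reduced"`.
#' @return `state_dim x (n_steps + 1)` matrix of states: the measured (or
#'   recovered) anchor state followed by the `n_steps` predictions.
#' @export
predict_koopman <- function(model, z0_window, u_pf_series, u_df_series,
                            sigma_series,
                            method = c("relift", "lifted", "reduced")) {
  method <- match.arg(method)
  if (!all(sigma_series %in% c(0, 1)))
    stop_input("sigma_series must be 0/1")
  n_steps <- length(sigma_series)
  if (length(u_pf_series) != n_steps || length(u_df_series) != n_steps)
    stop_input("input series must match sigma_series length")
  if (is.null(dim(z0_window))) z0_window <- matrix(z0_window, ncol = 1L)
  n <- model$layout$state_dim
  Z <- matrix(NA_real_, n, n_steps + 1L)
  u_active <- ifelse(sigma_series == 0, u_pf_series, u_df_series)
  if (method == "relift") {
    L <- model$dictionary$embedding_length
    if (ncol(z0_window) != L)
      stop_input("initial window must have %d columns", L)
    win <- z0_window
    Z[, 1L] <- win[, L]
    for (k in seq_len(n_steps)) {
      ph <- if (sigma_series[k] == 0) model$phases$P else model$phases$D
      psi <- lift(win, model$dictionary)
      z_next <- drop(ph$C %*% (ph$K_xx %*% psi + ph$K_xu %*% u_active[k]))
      Z[, k + 1L] <- z_next
      win <- cbind(win[, -1L, drop = FALSE], z_next)
    }
  } else if (method == "lifted") {
    psi <- lift(z0_window, model$dictionary)
    Z[, 1L] <- drop(model$C %*% psi)
    for (k in seq_len(n_steps)) {
      ph <- if (sigma_series[k] == 0) model$phases$P else model$phases$D
      psi <- drop(ph$K_xx %*% psi + ph$K_xu %*% u_active[k])
      Z[, k + 1L] <- drop(ph$C %*% psi)
    }
  } else {
    Z[, 1L] <- z0_window[, ncol(z0_window)]
    for (k in seq_len(n_steps)) {
      ph <- if (sigma_series[k] == 0) model$phases$P else model$phases$D
      Z[, k + 1L] <- drop(ph$A_tilde %*% Z[, k] + ph$B_tilde %*% u_active[k])
    }
  }
  Z
}

#' Root-mean-square prediction error of a state channel
#'
#' Per-sample RMSE of the recovered physical channel.  The angle channel is
#' reported in degrees (the accuracy threshold of the identification study
#' is stated in degrees of ankle motion); the velocity channel in deg/s.
#' Plain numeric vectors are compared as-is.
#'
#' @param pred,actual predicted and measured state matrices
#'   (`state_dim x N`, as returned by [predict_koopman()]) or numeric
#'   vectors of an already-extracted channel.
#' @param channel `"angle"` or `"velocity"`.
#' @param layout coordinate layout (defaults to the 4-dimensional augmented
#'   layout when matrices are given).
#' @return scalar RMSE.
#' @export
prediction_rmse <- function(pred, actual, channel = c("angle", "velocity"),
                            layout = NULL) {
  channel <- match.arg(channel)
  chan <- function(x) {
    if (is.null(dim(x))) return(x)
    lay <- layout %||% state_layout(nrow(x))
    w <- if (channel == "angle") lay$angle_weights else lay$velocity_weights
    drop(crossprod(w, x))
  }
  p <- chan(pred); a <- chan(actual)
  if (length(p) != length(a))
    stop_input("prediction and actual sequences have different lengths")
  if (!is.null(dim(pred))) {
    p <- rad2deg(p); a <- rad2deg(a)
  }
  sqrt(mean((p - a)^2))
}

#' Save and load a fitted Koopman model
#'
#' Self-describing plain-text (JSON) container holding the per-phase
#' operator blocks, recovery map, reduced matrices, the dictionary term
#' descriptors and embedding length, and fit diagnostics.  Matrices are
#' written at full double precision, so the round trip is exact.
#'
#' @param model a `koopman_model`.
#' @param path file path.
#' @return `read_koopman_model()` returns a `koopman_model`.
#' @export
write_koopman_model <- function(model, path) {
  # doubles serialized as %.17g strings: IEEE 754 round-trips exactly
  mat <- function(M) list(dim = dim(M),
                          data = sprintf("%.17g", as.vector(unname(M))))
  obj <- list(
    format = "koopmanfes-model",
    version = 1L,
    dictionary = list(name = model$dictionary$name,
                      terms = model$dictionary$terms,
                      constant = model$dictionary$constant,
                      embedding_length = model$dictionary$embedding_length,
                      state_dim = model$dictionary$state_dim),
    layout_kind = model$layout$kind,
    C = mat(model$C),
    phases = lapply(model$phases, function(ph)
      list(K_xx = mat(ph$K_xx), K_xu = mat(ph$K_xu), C = mat(ph$C),
           A_tilde = mat(ph$A_tilde), B_tilde = mat(ph$B_tilde))),
    fit_diagnostics = model$fit_diagnostics
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_koopman_model
#' @export
read_koopman_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "koopmanfes-model"))
    stop_input("not a koopmanfes model file")
  unmat <- function(m) matrix(as.numeric(m$data), m$dim[1], m$dim[2])
  dict <- make_dictionary(obj$dictionary$name,
                          embedding_length = obj$dictionary$embedding_length,
                          state_dim = obj$dictionary$state_dim,
                          terms = obj$dictionary$terms,
                          constant = obj$dictionary$constant)
  phases <- lapply(obj$phases, function(ph)
    list(K_xx = unmat(ph$K_xx), K_xu = unmat(ph$K_xu), C = unmat(ph$C),
         A_tilde = unmat(ph$A_tilde), B_tilde = unmat(ph$B_tilde)))
  diagn <- obj$fit_diagnostics
  diagn <- lapply(diagn, function(v) {
    if (is.list(v)) v <- unlist(v)
    v
  })
  structure(list(
    dictionary = dict,
    layout = state_layout(obj$dictionary$state_dim),
    C = unmat(obj$C),
    phases = phases,
    fit_diagnostics = diagn
  ), class = "koopman_model")
}
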