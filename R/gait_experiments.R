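#' Synthetic gait-data generation configuration
#'
#' The training protocol: independent gait cycles simulated at 200 Hz with
#' 200 samples per cycle, initial angle drawn uniformly from -20 to 25
#' degrees, initial velocity from -2 to 2 rad/s, and FES inputs either
#' ramped linearly from 0 to 30 mA across each phase (the default) or held
#' at a per-cycle random level drawn from 0 to 50 mA.  150 cycles yield the
#' default 30,000-sample training set.
#'
#' @param n_cycles number of gait cycles.
#' @param samples_per_cycle samples per cycle.
#' @param sample_rate sampling frequency (Hz); `samples_per_cycle /
#'   sample_rate` must equal the plant's cycle duration.
#' @param theta0_range_deg initial-angle range (degrees).
#' @param thetadot0_range initial-velocity range (rad/s).
#' @param u_mode `"ramp"` (linear sweep across each phase) or `"random"`
#'   (constant per-cycle level).
#' @param u_range stimulation range (mA); defaults to 0-30 for ramps and
#'   0-50 for random levels.
#' @param ref_amplitude_deg amplitude of the sinusoidal reference attached
#'   to every cycle (degrees).
#' @param seed integer seed recorded with every derived report.
#' @return a `datagen_config` object.
#' @export
datagen_config <- function(n_cycles = 150L,
                           samples_per_cycle = 200L,
                           sample_rate = 200,
                           theta0_range_deg = c(-20, 25),
                           thetadot0_range = c(-2, 2),
                           u_mode = c("ramp", "random"),
                           u_range = NULL,
                           ref_amplitude_deg = 10,
                           seed = 1L) {
  u_mode <- match.arg(u_mode)
  if (is.null(u_range)) u_range <- if (u_mode == "ramp") c(0, 30) else c(0, 50)
  if (n_cycles < 1 || samples_per_cycle < 2 || sample_rate <= 0)
    stop_input("counts and rates must be positive")
  if (diff(theta0_range_deg) <= 0 || diff(thetadot0_range) <= 0 ||
      diff(u_range) < 0)
    stop_input("ranges must be ordered (low, high)")
  if (any(u_range < 0)) stop_input("stimulation range must be nonnegative")
  structure(list(
    n_cycles = as.integer(n_cycles),
    samples_per_cycle = as.integer(samples_per_cycle),
    sample_rate = sample_rate,
    theta0_range_deg = theta0_range_deg,
    thetadot0_range = thetadot0_range,
    u_mode = u_mode, u_range = u_range,
    ref_amplitude_deg = ref_amplitude_deg,
    seed = as.integer(seed)
  ), class = "datagen_config")
}

# Short deterministic tag of a configuration (polynomial hash of its deparse).
config_id <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Generate a synthetic gait training set
#'
#' Simulates `n_cycles` independent gait cycles of the switched nonlinear
#' plant.  Each cycle draws an initial state uniformly from the configured
#' ranges and drives the phase-active muscle (plantarflexor in stance,
#' dorsiflexor in swing) with the configured excitation; a sinusoidal
#' reference spanning the cycle is attached to every trajectory so the
#' 4-dimensional augmented (error, reference) state can be formed.
#' Fully reproducible under the configuration seed.
#'
#' @param cfg a [datagen_config()].
#' @param params an [ankle_params()]; its `cycle_duration` must equal
#'   `samples_per_cycle / sample_rate`.
#' @return list of `ankle_trajectory` objects with attached references;
#'   attributes `"config"` and `"seed"` record provenance.
#' @export
generate_dataset <- function(cfg, params = ankle_params()) {
  if (abs(params$cycle_duration - cfg$samples_per_cycle / cfg$sample_rate) >
      1e-9)
    stop_input("plant cycle_duration (%g s) must equal samples_per_cycle/sample_rate (%g s)",
               params$cycle_duration, cfg$samples_per_cycle / cfg$sample_rate)
  set.seed(cfg$seed)
  n <- cfg$samples_per_cycle
  n_st <- sum(phase_of_time((seq_len(n) - 1L) / cfg$sample_rate, params)$sigma == 0L)
  n_sw <- n - n_st
  ref <- make_reference("sinusoid", amplitude_deg = cfg$ref_amplitude_deg,
                        timing = list(cycle_duration = params$cycle_duration,
                                      stance_fraction = params$stance_fraction,
                                      sample_rate = cfg$sample_rate),
                        duration = params$cycle_duration)
  trajs <- vector("list", cfg$n_cycles)
  for (i in seq_len(cfg$n_cycles)) {
    th0 <- deg2rad(stats::runif(1, cfg$theta0_range_deg[1], cfg$theta0_range_deg[2]))
    om0 <- stats::runif(1, cfg$thetadot0_range[1], cfg$thetadot0_range[2])
    if (cfg$u_mode == "ramp") {
      u_pf <- numeric(n); u_df <- numeric(n)
      u_pf[seq_len(n_st)] <- seq(cfg$u_range[1], cfg$u_range[2],
                                 length.out = n_st)
      u_df[n_st + seq_len(n_sw)] <- seq(cfg$u_range[1], cfg$u_range[2],
                                        length.out = n_sw)
    } else {
      lev_pf <- stats::runif(1, cfg$u_range[1], cfg$u_range[2])
      lev_df <- stats::runif(1, cfg$u_range[1], cfg$u_range[2])
      u_pf <- c(rep(lev_pf, n_st), rep(0, n_sw))
      u_df <- c(rep(0, n_st), rep(lev_df, n_sw))
    }
    tr <- simulate_ankle(c(th0, om0), u_pf, u_df, params,
                         sample_rate = cfg$sample_rate, n_cycles = 1)
    trajs[[i]] <- attach_reference(tr, ref)
  }
  attr(trajs, "config") <- cfg
  attr(trajs, "seed") <- cfg$seed
  attr(trajs, "config_id") <- config_id(cfg)
  trajs
}

#' Construct a reference trajectory
#'
#' Two reference shapes are provided.  `"sinusoid"`: a single-frequency
#' angle reference with the period of the gait cycle and an analytically
#' consistent velocity channel.  `"gait_setpoints"`: piecewise-constant
#' per-phase targets (plantarflexion target in stance, dorsiflexion target
#' in swing), blended across each phase transition with a raised-cosine
#' ramp of width `blend` seconds so the transition is smooth; with
#' `blend = 0` the profile is an exact step and the indices of the velocity
#' discontinuities are recorded in the `"discontinuity_idx"` attribute.
#'
#' @param kind `"sinusoid"` or `"gait_setpoints"`.
#' @param amplitude_deg sinusoid amplitude (degrees).
#' @param timing list with `cycle_duration`, `stance_fraction`,
#'   `sample_rate`.
#' @param duration total duration (s); defaults to one cycle.
#' @param setpoints_deg named vector `c(stance = , swing = )` of per-phase
#'   angle targets (degrees).
#' @param blend transition blend window (s); must fit inside both phases.
#' @return a `reference_trajectory` data frame with columns `time`,
#'   `theta_d`, `theta_dot_d` (radians).
#' @export
make_reference <- function(kind = c("sinusoid", "gait_setpoints"),
                           amplitude_deg = 10,
                           timing = list(cycle_duration = 1,
                                         stance_fraction = 0.6,
                                         sample_rate = 200),
                           duration = timing$cycle_duration,
                           setpoints_deg = c(stance = -15, swing = 15),
                           blend = 0.1) {
  kind <- match.arg(kind)
  T_ <- timing$cycle_duration
  t_st <- timing$stance_fraction * T_
  n <- round(duration * timing$sample_rate)
  time <- (seq_len(n) - 1L) / timing$sample_rate
  if (kind == "sinusoid") {
    if (abs(amplitude_deg) > 20)
      warning("reference amplitude exceeds the +/-20 degree clearance band")
    A <- deg2rad(amplitude_deg)
    w <- 2 * pi / T_
    theta_d <- A * sin(w * time)
    theta_dot_d <- A * w * cos(w * time)
    disc <- integer(0)
  } else {
    if (any(abs(setpoints_deg) > 20))
      warning("set points exceed the +/-20 degree clearance band")
    a_st <- deg2rad(setpoints_deg[["stance"]])
    a_sw <- deg2rad(setpoints_deg[["swing"]])
    if (blend < 0 || blend / 2 >= min(t_st, T_ - t_st))
      stop_input("blend window must be nonnegative and fit inside both phases")
    t_c <- time %% T_
    wrap <- function(d) (d + T_ / 2) %% T_ - T_ / 2  # signed cycle distance
    theta_d <- ifelse(t_c < t_st, a_st, a_sw)
    theta_dot_d <- numeric(n)
    if (blend > 0) {
      for (ev in list(list(at = 0, from = a_sw, to = a_st),
                      list(at = t_st, from = a_st, to = a_sw))) {
        d <- wrap(t_c - ev$at)
        in_bl <- abs(d) <= blend / 2
        s <- (d[in_bl] + blend / 2) / blend          # 0..1 through the blend
        theta_d[in_bl] <- ev$from + (ev$to - ev$from) * (1 - cos(pi * s)) / 2
        theta_dot_d[in_bl] <- (ev$to - ev$from) * pi / (2 * blend) *
          sin(pi * s)
      }
      disc <- integer(0)
    } else {
      disc <- which(diff(theta_d) != 0) + 1L
    }
  }
  out <- structure(
    data.frame(time = time, theta_d = theta_d, theta_dot_d = theta_dot_d),
    class = c("reference_trajectory", "data.frame")
  )
  attr(out, "discontinuity_idx") <- disc
  out
}

#' Prediction-accuracy study across dictionaries and embedding lengths
#'
#' Splits the dataset into training and held-out cycles (by whole cycles,
#' seed-controlled), fits the per-phase switched Koopman predictor for each
#' (dictionary, embedding length) combination, rolls the predictor out over
#' every held-out cycle from its first `L` samples, and reports the
#' angle-channel multi-step RMSE (degrees, mean and SD over held-out
#' cycles) together with a pass flag against the accuracy threshold.
#'
#' @param dataset output of [generate_dataset()].
#' @param dictionaries character vector of dictionary family names (or list
#'   of [make_dictionary()] objects, whose embedding lengths are then used
#'   as-is).
#' @param embeddings integer vector of embedding lengths L.
#' @param train_frac fraction of cycles used for training.
#' @param seed seed for the train/test split.
#' @param rmse_threshold accuracy threshold on the angle RMSE (degrees).
#' @param method rollout path, see [predict_koopman()].
#' @param evaluation `"cycle"` (default): one rollout per held-out cycle,
#'   anchored on its first `L` samples and switching operators at the phase
#'   transition; `"segment"`: one rollout per stance/swing segment,
#'   anchored on the segment's first `L` samples.  Training windows never
#'   straddle a transition, so `"segment"` is the well-posed protocol for
#'   delay-embedded (`L > 1`) predictors and is used by the
#'   embedding-length study.
#' @param ridge,balance passed to [fit_koopman()].
#' @return a data frame with one row per (dictionary, embedding length);
#'   attributes `"seed"` and `"config_id"` record provenance.
#' @export
run_prediction_study <- function(dataset,
                                 dictionaries = "custom",
                                 embeddings = 1L,
                                 train_frac = 0.8,
                                 seed = 1L,
                                 rmse_threshold = 0.5,
                                 method = "relift",
                                 evaluation = c("cycle", "segment"),
                                 ridge = 1e-8,
                                 balance = TRUE) {
  evaluation <- match.arg(evaluation)
  n_cyc <- length(dataset)
  if (n_cyc < 2L) stop_input("need at least two cycles to split")
  set.seed(seed)
  n_test <- max(1L, round((1 - train_frac) * n_cyc))
  test_idx <- sort(sample.int(n_cyc, n_test))
  train <- dataset[-test_idx]
  test <- dataset[test_idx]
  state_dim <- nrow(augment_states(dataset[[1]]))
  combos <- list()
  for (d in dictionaries) for (L in embeddings) {
    dict <- if (inherits(d, "observable_dictionary")) d
            else make_dictionary(d, embedding_length = L, state_dim = state_dim)
    combos[[length(combos) + 1L]] <- dict
  }
  rows <- lapply(combos, function(dict) {
    model <- fit_koopman(train, dict, ridge = ridge, balance = balance)
    rmses <- vapply(test, function(tr) {
      if (evaluation == "cycle") heldout_cycle_rmse(model, tr, method = method)
      else heldout_segment_rmse(model, tr, method = method)
    }, numeric(1))
    data.frame(dictionary = dict$name,
               embedding_length = dict$embedding_length,
               lifted_dim = dict$lifted_dim,
               rmse_mean = mean(rmses),
               rmse_sd = stats::sd(rmses),
               threshold_pass = mean(rmses) <= rmse_threshold,
               n_train = length(train), n_test = length(test),
               seed = seed)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "config_id") <- attr(dataset, "config_id") %||% config_id(dataset[[1]][1, ])
  attr(out, "rmse_threshold") <- rmse_threshold
  out
}

# Multi-step rollout RMSE of one held-out cycle: anchor on the first L
# samples, predict the remainder with the recorded inputs and phase flags
# (switching operators at the phase transition), compare the recovered
# angle channel (degrees).
heldout_cycle_rmse <- function(model, traj, method = "relift") {
  L <- model$dictionary$embedding_length
  Z <- augment_states(traj, state_dim = model$layout$state_dim)
  n <- ncol(Z)
  if (n < L + 2L) stop_input("cycle too short for embedding length %d", L)
  if (length(unique(traj$sigma[seq_len(L)])) != 1L)
    stop_input("the first %d samples must lie in a single phase", L)
  idx <- L:(n - 1L)
  Zp <- predict_koopman(model, Z[, seq_len(L), drop = FALSE],
                        traj$u_pf[idx], traj$u_df[idx], traj$sigma[idx],
                        method = method)
  prediction_rmse(Zp[, -1L, drop = FALSE], Z[, (L + 1L):n, drop = FALSE],
                  channel = "angle", layout = model$layout)
}

# Per-phase-segment rollout RMSE of one held-out cycle: anchor on the first
# L samples of every stance/swing segment and predict to the segment end.
# Delay windows never straddle a phase transition in training, so this is
# the evaluation under which delay-embedded predictors are well posed; it
# is the protocol of the embedding-length study.
heldout_segment_rmse <- function(model, traj, method = "lifted") {
  L <- model$dictionary$embedding_length
  Z <- augment_states(traj, state_dim = model$layout$state_dim)
  sig <- traj$sigma
  bounds <- c(0L, which(diff(sig) != 0L), length(sig))
  errs <- list()
  for (s in seq_len(length(bounds) - 1L)) {
    i0 <- bounds[s] + 1L
    i1 <- bounds[s + 1L]
    if (i1 - i0 + 1L < L + 2L) next
    idx <- (i0 + L - 1L):(i1 - 1L)
    Zp <- predict_koopman(model, Z[, i0:(i0 + L - 1L), drop = FALSE],
                          traj$u_pf[idx], traj$u_df[idx], sig[idx],
                          method = method)
    lay <- model$layout
    w <- lay$angle_weights
    errs[[length(errs) + 1L]] <-
      rad2deg(drop(crossprod(w, Zp[, -1L, drop = FALSE])) -
                drop(crossprod(w, Z[, (i0 + L):i1, drop = FALSE])))
  }
  if (length(errs) == 0L)
    stop_input("no phase segment long enough for embedding length %d", L)
  sqrt(mean(unlist(errs)^2))
}

#' Closed-loop tracking study across gait speeds
#'
#' Treadmill speed cannot be simulated by a single-joint plant, so speeds
#' are mapped to cycle durations (slower walking, longer cycles).  For each
#' speed setting the phase-switched MPC runs against the nonlinear plant on
#' the per-phase set-point reference; per-cycle tracking RMSE is reported
#' separately for the plantarflexion (stance) and dorsiflexion (swing)
#' windows, excluding the first (transient) cycle.  Runs where the solver
#' fails on more than 10 percent of steps are flagged.
#'
#' @param model a fitted `koopman_model`.
#' @param params plant [ankle_params()]; cycle duration is overridden per
#'   speed.
#' @param prob an [mpc_problem()].
#' @param speeds treadmill speeds (m/s), descriptive labels only.
#' @param cycle_durations cycle duration per speed (s).
#' @param n_cycles cycles simulated per speed (the first is discarded as
#'   transient).
#' @param setpoints_deg per-phase targets passed to [make_reference()].
#' @return data frame with one row per speed; attribute `"seed"` records
#'   the (deterministic) run tag.
#' @export
run_closed_loop_study <- function(model, params, prob,
                                  speeds = c(0.1, 0.2, 0.3),
                                  cycle_durations = c(4, 3, 2),
                                  n_cycles = 3L,
                                  setpoints_deg = c(stance = -15, swing = 15)) {
  if (length(speeds) != length(cycle_durations))
    stop_input("speeds and cycle_durations must have the same length")
  rows <- lapply(seq_along(speeds), function(i) {
    cd <- cycle_durations[i]
    p_i <- params
    p_i$cycle_duration <- cd
    timing <- list(cycle_duration = cd,
                   stance_fraction = p_i$stance_fraction,
                   sample_rate = prob$sample_rate)
    duration <- n_cycles * cd
    ref <- make_reference("gait_setpoints", timing = timing,
                          duration = duration + prob$horizon_steps /
                            prob$sample_rate + 1 / prob$sample_rate,
                          setpoints_deg = setpoints_deg)
    x0 <- c(ref$theta_d[1], ref$theta_dot_d[1])
    run <- closed_loop(model, p_i, ref, prob, duration, x0 = x0)
    tr <- run$trajectory
    nrun <- nrow(tr)
    err_deg <- rad2deg(tr$theta - ref$theta_d[seq_len(nrun)])
    cyc <- floor(tr$time / cd) + 1L
    keep <- cyc > 1L
    per_cycle <- function(sig) {
      vapply(sort(unique(cyc[keep])), function(ci) {
        sel <- keep & cyc == ci & tr$sigma == sig
        sqrt(mean(err_deg[sel]^2))
      }, numeric(1))
    }
    r_pf <- per_cycle(0L); r_df <- per_cycle(1L)
    fail_frac <- mean(run$log$solver_status == "error")
    data.frame(speed = speeds[i], cycle_duration = cd,
               rmse_pf_mean = mean(r_pf), rmse_pf_sd = stats::sd(r_pf),
               rmse_df_mean = mean(r_df), rmse_df_sd = stats::sd(r_df),
               solver_failure_frac = fail_frac,
               flagged = fail_frac > 0.1)
  })
  out <- do.call(rbind, rows)
  attr(out, "config_id") <- config_id(list(prob$Q, prob$R, cycle_durations,
                                           setpoints_deg, n_cycles))
  out
}
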