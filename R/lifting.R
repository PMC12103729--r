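#' Observable dictionaries for Koopman lifting
#'
#' A dictionary is an ordered list of scalar basis functions over the state,
#' together with a delay-embedding length `L`.  Lifting a window of `L`
#' consecutive states evaluates every basis function on every delayed state
#' (oldest to newest) and appends a single constant-1 observable, so the
#' lifted dimension is `P = n_terms * L + 1`.  The same dictionary object is
#' used for the stance-phase and swing-phase operator fits, which keeps the
#' two lifted spaces identical across the switch.
#'
#' Three families are built in, over a state vector `x1..xn`:
#' \describe{
#'   \item{`state`}{the raw state coordinates; with `L = 1` the lifting is
#'     the identity (plus the constant), so linear dynamics are represented
#'     exactly.}
#'   \item{`custom`}{for the default 4-dimensional augmented state
#'     (`x1` = angle tracking error, `x2` = reference angle, `x3` = velocity
#'     error, `x4` = reference velocity): the linear terms, `sin`/`cos` of
#'     the two position-like coordinates, their squares and product, and the
#'     product of the two velocity-like coordinates - 12 terms, hence
#'     `P = 13` at `L = 1`.  For a plain 2-dimensional (angle, velocity)
#'     state the same recipe is applied to `(x1, x2)` directly.}
#'   \item{`trig`}{first and second harmonic `sin`/`cos` of every
#'     coordinate.}
#' }
#'
#' @param name `"state"`, `"custom"`, or `"trig"`.
#' @param embedding_length number of past states per lifted vector (L >= 1).
#' @param state_dim dimension of the (augmented) state the dictionary acts
#'   on; 4 for the error-plus-reference augmentation, 2 for the plain joint
#'   state.
#' @param terms optional character vector of term descriptors (expressions in
#'   `x1..xn`, e.g. `"sin(x1)"`, `"x1*x2"`) overriding the named family.
#' @param constant include the trailing constant-1 observable (default TRUE).
#' @return an `observable_dictionary` object.
#' @export
make_dictionary <- function(name = c("state", "custom", "trig"),
                            embedding_length = 1L,
                            state_dim = 4L,
                            terms = NULL,
                            constant = TRUE) {
  name <- match.arg(name)
  if (!is.numeric(embedding_length) || embedding_length < 1)
    stop_input("embedding_length must be >= 1")
  L <- as.integer(embedding_length)
  n <- as.integer(state_dim)
  if (n < 1) stop_input("state_dim must be >= 1")
  xs <- paste0("x", seq_len(n))
  if (is.null(terms)) {
    terms <- switch(
      name,
      state = xs,
      custom = {
        if (n == 4L) {
          c("x1", "x2", "x3", "x4",
            "sin(x1)", "cos(x1)", "sin(x2)", "cos(x2)",
            "x1^2", "x2^2", "x1*x2", "x3*x4")
        } else if (n == 2L) {
          c("x1", "x2",
            "sin(x1)", "cos(x1)", "sin(x2)", "cos(x2)",
            "x1^2", "x2^2", "x1*x2")
        } else {
          stop_input("the custom dictionary is defined for state_dim 4 or 2")
        }
      },
      trig = as.vector(vapply(
        xs, function(v) c(sprintf("sin(%s)", v), sprintf("cos(%s)", v),
                          sprintf("sin(2*%s)", v), sprintf("cos(2*%s)", v)),
        character(4)))
    )
  }
  exprs <- lapply(terms, function(s) parse(text = s)[[1]])
  used <- unique(unlist(lapply(exprs, all.vars)))
  if (!all(used %in% xs))
    stop_input("term descriptors may only use variables %s",
               paste(xs, collapse = ", "))
  d <- list(name = name, terms = terms, exprs = exprs,
            constant = isTRUE(constant), embedding_length = L,
            state_dim = n,
            lifted_dim = length(terms) * L + isTRUE(constant))
  class(d) <- "observable_dictionary"
  d
}

#' @export
print.observable_dictionary <- function(x, ...) {
  cat(sprintf("Observable dictionary '%s': %d terms x L=%d%s -> P=%d (state dim %d)\n",
              x$name, length(x$terms), x$embedding_length,
              if (x$constant) " + const" else "", x$lifted_dim, x$state_dim))
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

# Evaluate all dictionary terms on a batch of states.
# X: state_dim x N matrix; returns n_terms x N matrix.
eval_terms <- function(dict, X) {
  X <- as.matrix(X)
  if (nrow(X) != dict$state_dim)
    stop_input("state has dimension %d, dictionary expects %d",
               nrow(X), dict$state_dim)
  env <- new.env(parent = baseenv())
  for (i in seq_len(dict$state_dim)) assign(paste0("x", i), X[i, ], envir = env)
  out <- vapply(dict$exprs, function(e) {
    v <- eval(e, envir = env)
    if (length(v) == 1L) rep(v, ncol(X)) else v
  }, numeric(ncol(X)))
  if (ncol(X) == 1L) matrix(out, ncol = 1L) else t(out)
}

#' Lift a window of states
#'
#' Deterministic evaluation of every basis function on every delayed state of
#' the window, concatenated oldest to newest, with the constant term last.
#'
#' @param state_window a `state_dim x L` matrix whose columns are consecutive
#'   states, oldest first (a plain vector is accepted when `L = 1`).
#' @param dict an [make_dictionary()] object.
#' @return numeric vector of length `lifted_dim`.
#' @export
lift <- function(state_window, dict) {
  if (is.null(dim(state_window)))
    state_window <- matrix(state_window, ncol = 1L)
  L <- dict$embedding_length
  if (ncol(state_window) != L)
    stop_input("window has %d columns, embedding length is %d",
               ncol(state_window), L)
  assert_finite(state_window, "state window")
  vals <- eval_terms(dict, state_window)   # n_terms x L
  out <- as.vector(vals)                   # column-major: oldest delay first
  if (dict$constant) out <- c(out, 1)
  out
}

# Lift many windows at once.  Z: state_dim x N state matrix; ends: vector of
# window end indices k (window = columns (k-L+1):k).  Returns P x length(ends).
lift_batch <- function(Z, dict, ends) {
  L <- dict$embedding_length
  if (any(ends < L) || any(ends > ncol(Z)))
    stop_input("window end indices out of range")
  vals <- eval_terms(dict, Z)              # n_terms x N
  nt <- nrow(vals)
  blocks <- vector("list", L)
  for (j in seq_len(L)) {                  # delay j: oldest (k-L+1) first
    blocks[[j]] <- vals[, ends - L + j, drop = FALSE]
  }
  Psi <- do.call(rbind, blocks)
  if (dict$constant) Psi <- rbind(Psi, rep(1, length(ends)))
  Psi
}

#' Augmented-state matrix of a trajectory
#'
#' With an attached reference (see [attach_reference()]), builds the
#' 4-dimensional augmented state used throughout identification and control:
#' rows `(e_theta, theta_d, e_theta_dot, theta_dot_d)`, where
#' `e = actual - reference`.  Without a reference, returns the plain
#' 2-dimensional `(theta, theta_dot)` state.
#'
#' @param traj an `ankle_trajectory`, optionally carrying a `"reference"`
#'   attribute.
#' @param state_dim 4 for the augmented state (requires a reference), 2 for
#'   the plain joint state, `NULL` to choose 4 exactly when a reference is
#'   attached.
#' @return a `state_dim x N` matrix with a `"layout"` attribute describing
#'   the coordinate roles.
#' @export
augment_states <- function(traj, state_dim = NULL) {
  ref <- attr(traj, "reference")
  if (!is.null(state_dim) && state_dim == 2L) ref <- NULL
  if (is.null(ref)) {
    if (!is.null(state_dim) && state_dim == 4L)
      stop_input("a reference must be attached to form the augmented state")
    Z <- rbind(traj$theta, traj$theta_dot)
    attr(Z, "layout") <- state_layout(2L)
    return(Z)
  }
  Z <- rbind(traj$theta - ref$theta_d,
             ref$theta_d,
             traj$theta_dot - ref$theta_dot_d,
             ref$theta_dot_d)
  attr(Z, "layout") <- state_layout(4L)
  Z
}

# Coordinate roles of the two supported state layouts.
#  - aug4: z = (e_theta, theta_d, e_omega, omega_d); angle = z1 + z2.
#  - joint2: z = (theta, theta_dot).
state_layout <- function(state_dim) {
  if (state_dim == 4L) {
    list(state_dim = 4L, kind = "aug4",
         err_idx = c(1L, 3L), ref_idx = c(2L, 4L),
         angle_weights = c(1, 1, 0, 0), velocity_weights = c(0, 0, 1, 1))
  } else if (state_dim == 2L) {
    list(state_dim = 2L, kind = "joint2",
         err_idx = c(1L, 2L), ref_idx = integer(0),
         angle_weights = c(1, 0), velocity_weights = c(0, 1))
  } else {
    stop_input("unsupported state dimension %d (use 4 or 2)", state_dim)
  }
}

# Valid training window end-indices for one trajectory and one phase:
# the window (k-L+1):k and the successor sample k+1 must all carry the
# requested phase flag, so no window or snapshot pair straddles a
# stance/swing transition or a trajectory boundary.
valid_pair_ends <- function(sigma, L, phase_sigma) {
  n <- length(sigma)
  if (n < L + 1L) return(integer(0))
  ok <- sigma == phase_sigma
  run <- stats::filter(as.numeric(ok), rep(1, L + 1L), sides = 1)
  ends <- which(!is.na(run) & run == L + 1L) - 1L  # window end k, pair (k, k+1)
  ends[ends >= L]
}
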