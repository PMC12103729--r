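#' Degree/radian conversion
#'
#' Angles are radians everywhere inside the package; degrees appear only at
#' file and report boundaries.
#'
#' @param x numeric vector.
#' @return numeric vector.
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_input("non-finite values in %s", what)
  invisible(x)
}

assert_scalar_num <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("%s must be a finite numeric scalar", what)
  invisible(x)
}

# Moore-Penrose pseudoinverse via SVD.  tol follows the usual
# max(dim) * eps * max(singular value) truncation rule.
pinv_svd <- function(A, tol = NULL) {
  A <- as.matrix(A)
  if (any(!is.finite(A))) stop_input("non-finite matrix in pseudoinverse")
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# 2-norm condition number (ratio of extreme singular values).
cond2 <- function(A) {
  d <- svd(as.matrix(A), nu = 0, nv = 0)$d
  if (min(d) == 0) Inf else max(d) / min(d)
}

frob <- function(A) sqrt(sum(A^2))

symmetrize <- function(S) (S + t(S)) / 2
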