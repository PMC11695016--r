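# Smooth primitives shared by the dynamics and OCP layers. Everything that ends
# up inside a collocation constraint must be C1-smooth, so hard max/abs are
# replaced by softplus/tanh forms with explicit smoothing scales.

softplus <- function(x, scale = 1) {
  # numerically safe scale * log(1 + exp(x / scale))
  z <- x / scale
  out <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  scale * out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Smooth absolute value, |x| ~ sqrt(x^2 + eps^2)
#' @noRd
smooth_abs <- function(x, eps = 1e-6) sqrt(x * x + eps * eps)

#' Smooth positive part
#' @noRd
smooth_pos <- function(x, scale = 1e-4) softplus(x, scale)

#' Degree/radian conversion
#'
#' All file and report interfaces use degrees; internal computation is in
#' radians.
#' @param x Angle(s).
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

#' FNV-1a hash of a character string (used for run manifests)
#' @noRd
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- (h - lo8) + bitwXor(as.integer(lo8), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, split to stay < 2^53
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # h is a double holding a 32-bit value; render as hex in two halves
  hi <- floor(h / 65536)
  sprintf("%04x%04x", as.integer(hi), as.integer(h - hi * 65536))
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
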