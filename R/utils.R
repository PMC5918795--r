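# standard gravity, m/s^2
.g0 <- 9.80665

`%||%` <- function(a, b) if (is.null(a)) b else a

rms <- function(x) sqrt(mean(x^2))

rom <- function(x) max(x) - min(x)

deg <- function(rad) rad * 180 / pi

rad <- function(deg) deg * pi / 180

# cumulative trapezoidal integral of x over t, anchored at 0
cumtrapz1 <- function(t, x) {
  n <- length(x)
  c(0, cumsum(diff(t) * (x[-1] + x[-n]) / 2))
}

# "+z" / "-y" / ... -> unit 3-vector; numeric vectors pass through normalized
parse_axis <- function(axis) {
  if (is.numeric(axis)) {
    stopifnot(length(axis) == 3)
    n <- sqrt(sum(axis^2))
    if (n == 0) stop("axis vector must be nonzero")
    return(axis / n)
  }
  m <- match(axis, c("+x", "-x", "+y", "-y", "+z", "-z"))
  if (is.na(m)) stop("unknown axis specification: ", axis)
  v <- numeric(3)
  v[ceiling(m / 2)] <- if (m %% 2 == 1) 1 else -1
  v
}

# 3x3 rotation matrix about unit axis k by angle (radians)
rotation_matrix <- function(k, angle) {
  k <- k / sqrt(sum(k^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

motion_variables <- function() {
  c("ah_rms", "av_rms", "wh_rms", "wv_rms", "alpha_rom", "gamma_rom")
}

phase_labels <- function() c("pt", "s", "rm")

feature_columns <- function() {
  as.vector(t(outer(motion_variables(), phase_labels(), paste, sep = "_")))
}
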