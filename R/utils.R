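#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rnorm runif sd pnorm pt approx
#' @importFrom utils combn head tail
NULL

# Condition constructor: every pipeline failure carries a subclass so the
# CLI can map it to a distinct exit code.
abort_aq <- function(class, message, data = list()) {
  cond <- structure(
    class = c(class, "araquant_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  stop(cond)
}

stopifnot_contract <- function(ok, message) {
  if (!isTRUE(ok)) abort_aq("araquant_error_contract", message)
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param x numeric vector or matrix of angles in radians.
#' @return object of the same shape with every element wrapped.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi  # map the closed end so the interval is (-pi, pi]
  y
}

# Trapezoidal quadrature wrapper; pracma::trapz for vectors.
trapz_ <- function(x, y) pracma::trapz(x, y)

# Central-difference gradient of a vector sampled at (possibly non-uniform) t.
num_gradient <- function(y, t) {
  n <- length(y)
  stopifnot_contract(n >= 2, "need at least two samples to differentiate")
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (t[2] - t[1])
  g[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  g
}

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

check_uniform_dt <- function(t, tol = 1e-6) {
  dt <- diff(t)
  stopifnot_contract(all(dt > 0), "timestamps must be strictly increasing")
  if ((max(dt) - min(dt)) > tol * stats::median(dt)) {
    abort_aq("araquant_error_contract",
             "timestamps are not uniformly spaced within tolerance")
  }
  stats::median(dt)
}

# Lower median: for even counts take the smaller of the two middle values.
# Used for reference-trajectory construction so the reference is always an
# observed coordinate value.
lower_median <- function(x) {
  s <- sort(x)
  s[floor((length(s) + 1) / 2)]
}
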