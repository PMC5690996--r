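ax6 <- c("tx", "ty", "tz", "pitch", "roll", "yaw")

# n x 6 error matrix from a per-axis generator function(f) or constant vector
mat6 <- function(n, values) {
  m <- matrix(0, n, 6L, dimnames = list(NULL, ax6))
  if (is.function(values)) {
    for (f in seq_len(n)) m[f, ] <- values(f)
  } else {
    m[] <- rep(values, each = n)
  }
  m
}

constant_course <- function(id, n, values) {
  treatment_course(id, mat6(n, values))
}

# course with per-axis linear trend e_f = intercept + slope * f
trend_course <- function(id, n, intercept, slope) {
  treatment_course(id, mat6(n, function(f) intercept + slope * f))
}

random_course <- function(id, n) {
  treatment_course(id, matrix(stats::rnorm(n * 6), n,
                              dimnames = list(NULL, ax6)))
}

expect_equal6 <- function(object, expected, tol = 1e-12) {
  expect_equal(unname(as.numeric(object)), unname(rep(expected, length.out = 6)),
               tolerance = tol)
}
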