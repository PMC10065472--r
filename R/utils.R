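#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published nutrition tables use
#' conventional half-up rounding (0.5 -> 1, 42.9 -> 43 at 0 digits). All
#' reported means in this package go through this helper so printed values
#' match the convention of the surveillance literature.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half away from zero
#' @export
#' @examples
#' round_half_up(42.9)   # 43
#' round_half_up(34.5)   # 35
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Box-Cox transform and inverse
#'
#' Power-family transform used to normalise daily intake amounts before
#' mixed-model fitting: `(x^lambda - 1) / lambda` for `lambda > 0`, `log(x)`
#' at `lambda = 0`.
#'
#' @param x positive numeric vector
#' @param lambda Box-Cox exponent in `[0, 1]`
#' @return transformed values
#' @export
box_cox <- function(x, lambda) {
  stopifnot(all(x > 0), lambda >= 0)
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' @rdname box_cox
#' @param t transformed-scale values
#' @export
inv_box_cox <- function(t, lambda) {
  if (lambda == 0) return(exp(t))
  base <- lambda * t + 1
  base[base < 0] <- 0
  base^(1 / lambda)
}

#' Inverse Box-Cox with within-person variance adjustment
#'
#' Approximates `E[g^{-1}(t + e)]` for `e ~ N(0, sigma_e2)` where `g` is the
#' Box-Cox transform. Exact (lognormal mean) at `lambda = 0`; the identity at
#' `lambda = 1`; a second-order Taylor correction otherwise.
#'
#' @param t transformed-scale value(s)
#' @param lambda Box-Cox exponent
#' @param sigma_e2 within-person variance on the transformed scale
#' @return approximate original-scale expectation
#' @export
back_transform_mean <- function(t, lambda, sigma_e2) {
  if (lambda == 0) return(exp(t + sigma_e2 / 2))
  if (lambda == 1) return(t + 1)  # g(x) = x - 1 at lambda = 1
  base <- pmax(lambda * t + 1, 0)
  g <- base^(1 / lambda)
  # d2/dt2 (lambda t + 1)^(1/lambda) = (1 - lambda) (lambda t + 1)^(1/lambda - 2)
  gpp <- (1 - lambda) * base^(1 / lambda - 2)
  g + 0.5 * sigma_e2 * gpp
}

#' Gauss-Hermite expectation over a normal variable
#'
#' Computes `E[f(X)]` for `X ~ N(mean, sd^2)` by Gauss-Hermite quadrature.
#' Used to integrate the back-transformation over the person random effect.
#'
#' @param f vectorised function
#' @param mean,sd normal parameters (`sd >= 0`; `sd = 0` returns `f(mean)`)
#' @param nodes number of quadrature nodes (default 9)
#' @return scalar expectation
#' @export
#' @examples
#' gh_expect(exp, mean = 0, sd = 1)  # ~ exp(1/2)
gh_expect <- function(f, mean, sd, nodes = 9) {
  if (sd == 0) return(f(mean))
  gh <- pracma::gaussHermite(nodes)
  sum(gh$w * f(mean + sqrt(2) * sd * gh$x)) / sqrt(pi)
}

# Gauss-Hermite expectations for many (mean_i, sd_i) at once; returns vector.
gh_expect_many <- function(f, means, sds, nodes = 9) {
  gh <- pracma::gaussHermite(nodes)
  out <- numeric(length(means))
  w <- gh$w / sqrt(pi)
  for (k in seq_len(nodes)) {
    out <- out + w[k] * f(means + sqrt(2) * sds * gh$x[k])
  }
  out
}

#' Weighted mean helper tolerant of zero total weight
#' @noRd
wmean <- function(x, w) {
  if (sum(w) == 0) return(NA_real_)
  sum(x * w) / sum(w)
}

#' Weighted standard deviation
#' @noRd
wsd <- function(x, w) {
  m <- wmean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}
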