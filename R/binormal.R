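#' Binormal ROC model parameters
#'
#' Under the binormal ROC model the positive-class scores are
#' `N(mu_x, sigma_x^2)` and the negative-class scores `N(mu_y, sigma_y^2)`.
#' The model gives closed-form survival functions and ROC curve and, by
#' quadrature, exact partial and two-way partial areas — the ground truth for
#' the estimator bias studies.
#'
#' @param mu_x,sigma_x mean and standard deviation of the positive scores
#'   (`sigma_x > 0`).
#' @param mu_y,sigma_y mean and standard deviation of the negative scores
#'   (`sigma_y > 0`).
#' @return An object of class `binormal_params`.
#' @examples
#' binormal_params(1.5, 1, 0, 1)
#' @export
binormal_params <- function(mu_x, sigma_x, mu_y, sigma_y) {
  if (!is.finite(mu_x) || !is.finite(mu_y)) {
    stop("means must be finite", call. = FALSE)
  }
  if (!is.finite(sigma_x) || sigma_x <= 0 || !is.finite(sigma_y) || sigma_y <= 0) {
    stop("standard deviations must be positive and finite", call. = FALSE)
  }
  structure(list(mu_x = mu_x, sigma_x = sigma_x,
                 mu_y = mu_y, sigma_y = sigma_y),
            class = "binormal_params")
}

#' @export
print.binormal_params <- function(x, ...) {
  cat(sprintf("<binormal_params> X ~ N(%.3g, %.3g^2), Y ~ N(%.3g, %.3g^2)\n",
              x$mu_x, x$sigma_x, x$mu_y, x$sigma_y))
  invisible(x)
}

as_binormal_params <- function(params) {
  if (inherits(params, "binormal_params")) return(params)
  if (is.numeric(params) && length(params) == 4L) {
    return(binormal_params(params[1], params[2], params[3], params[4]))
  }
  stop("expected 'binormal_params' or numeric (mu_x, sigma_x, mu_y, sigma_y)",
       call. = FALSE)
}

#' Normal survival function
#'
#' `P(score > c) = pnorm((mu - c) / sigma)` for a normal score distribution;
#' applied to the positive class this is the true TPR at threshold `c`, to the
#' negative class the true FPR.
#'
#' @param c threshold (score units).
#' @param mu,sigma normal mean and standard deviation (`sigma > 0`).
#' @return Probability in \[0, 1\].
#' @examples
#' binormal_survival(1.1, 0, 1)  # FPR at threshold 1.1 for N(0,1) negatives
#' @export
binormal_survival <- function(c, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  stats::pnorm((mu - c) / sigma)
}

#' Binormal ROC curve
#'
#' The true ROC value at FPR `u`:
#' `ROC(u) = Phi((mu_x - mu_y + sigma_y * Phi^{-1}(u)) / sigma_x)`, the closed
#' form of `S_F(S_G^{-1}(u))`. Endpoints are `ROC(0) = 0` and `ROC(1) = 1`.
#'
#' @param u FPR value(s) in \[0, 1\] (vectorised).
#' @param params a [binormal_params()].
#' @return TPR value(s) in \[0, 1\].
#' @examples
#' binormal_roc(0.136, binormal_params(1.5, 1, 0, 1))
#' @export
binormal_roc <- function(u, params) {
  params <- as_binormal_params(params)
  if (any(!is.finite(u) | u < 0 | u > 1)) {
    stop("'u' must lie in [0, 1]", call. = FALSE)
  }
  out <- stats::pnorm((params$mu_x - params$mu_y +
                         params$sigma_y * stats::qnorm(u)) / params$sigma_x)
  out[u == 0] <- 0
  out[u == 1] <- 1
  out
}

#' True partial AUC over an FPR range under the binormal model
#'
#' Adaptive quadrature of the density-weighted ROC height
#' \deqn{\frac{1}{\sigma_y}\int \Phi\!\left(\frac{\mu_x - z}{\sigma_x}\right)
#'       \phi\!\left(\frac{\mu_y - z}{\sigma_y}\right) dz}
#' between `z = mu_y - sigma_y * qnorm(u1)` and `mu_y - sigma_y * qnorm(u0)`
#' (infinite limits at the range endpoints 0 and 1 are integrated over the
#' corresponding half line). Absolute tolerance 1e-9.
#'
#' @param params a [binormal_params()].
#' @param u0,u1 FPR range, `0 <= u0 < u1 <= 1`.
#' @return Area in \[0, `u1 - u0`\]. The full range gives the closed-form AUC
#'   `pnorm((mu_x - mu_y) / sqrt(sigma_x^2 + sigma_y^2))`.
#' @examples
#' true_pauc_fpr(binormal_params(2, 1.5, 0, 1), 0.1, 0.4)
#' @export
true_pauc_fpr <- function(params, u0, u1) {
  params <- as_binormal_params(params)
  assert_prob(u0, "u0")
  assert_prob(u1, "u1")
  if (u0 >= u1) stop("need u0 < u1", call. = FALSE)
  z_lo <- params$mu_y - params$sigma_y * stats::qnorm(u1)
  z_hi <- params$mu_y - params$sigma_y * stats::qnorm(u0)
  integrand <- function(z) {
    stats::pnorm((params$mu_x - z) / params$sigma_x) *
      stats::dnorm((params$mu_y - z) / params$sigma_y) / params$sigma_y
  }
  stats::integrate(integrand, lower = z_lo, upper = z_hi,
                   rel.tol = 1e-10, abs.tol = 1e-9,
                   subdivisions = 500L)$value
}

# Specificity attained by the true ROC at the sensitivity bound b_se:
# 1 - S_G(S_F^{-1}(b_se)).
true_spec_at_sens <- function(params, b_se) {
  z <- params$mu_x - params$sigma_x * stats::qnorm(b_se)
  1 - stats::pnorm((params$mu_y - z) / params$sigma_y)
}

#' True flanking-rectangle area (Area B) under the binormal model
#'
#' The rectangle of height `b_se` that sits under the partial-AUC band
#' between the FPR attained at the sensitivity bound and the FPR bound:
#' `(1 - b_sp - S_G(S_F^{-1}(b_se))) * b_se`, evaluated analytically. It may
#' be negative when the true ROC curve misses the rectangle of interest;
#' [true_tpauc()] applies the zero condition before subtracting it.
#'
#' @param params a [binormal_params()].
#' @param bounds a [tpauc_bounds()] (or numeric `c(b_se, b_sp)`).
#' @return Signed area.
#' @examples
#' true_area_b(binormal_params(1.5, 1, 0, 1), tpauc_bounds(0.655, 0.5))
#' @export
true_area_b <- function(params, bounds) {
  params <- as_binormal_params(params)
  bounds <- as_tpauc_bounds(bounds)
  if (bounds$b_se == 0) return(0)
  c_fpr <- 1 - true_spec_at_sens(params, bounds$b_se)
  (1 - bounds$b_sp - c_fpr) * bounds$b_se
}

#' True two-way partial AUC under the binormal model
#'
#' Exact tpAUC: zero when the true ROC does not reach the rectangle (the
#' specificity attained at the sensitivity bound falls below `b_sp`);
#' otherwise the quadrature partial area [true_pauc_fpr()] over the FPR band
#' from `S_G(S_F^{-1}(b_se))` to `1 - b_sp`, minus the analytic
#' [true_area_b()].
#'
#' @param params a [binormal_params()].
#' @param bounds a [tpauc_bounds()] (or numeric `c(b_se, b_sp)`).
#' @return Area in \[0, `(1 - b_se) * (1 - b_sp)`\].
#' @examples
#' true_tpauc(binormal_params(2, 1.5, 0, 1), tpauc_bounds(0.6, 0.6))
#' @export
true_tpauc <- function(params, bounds) {
  params <- as_binormal_params(params)
  bounds <- as_tpauc_bounds(bounds)
  if (bounds$b_se == 0 && bounds$b_sp == 0) {
    return(stats::pnorm((params$mu_x - params$mu_y) /
                          sqrt(params$sigma_x^2 + params$sigma_y^2)))
  }
  c_sp <- true_spec_at_sens(params, bounds$b_se)
  if (c_sp <= bounds$b_sp) return(0)
  u0 <- 1 - c_sp
  u1 <- 1 - bounds$b_sp
  raw <- true_pauc_fpr(params, u0, u1) - true_area_b(params, bounds)
  min(max(raw, 0), bounds$rect_area)
}

#' Sample scores from the binormal model
#'
#' `n_x` positive scores from `N(mu_x, sigma_x^2)` and `n_y` negative scores
#' from `N(mu_y, sigma_y^2)`, reproducible for a fixed seed.
#'
#' @param params a [binormal_params()].
#' @param n_x,n_y class sizes (positive integers).
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return A [score_set()].
#' @examples
#' sample_binormal(binormal_params(1.5, 1, 0, 1), 5, 5, seed = 1)
#' @export
sample_binormal <- function(params, n_x, n_y, seed = NULL) {
  params <- as_binormal_params(params)
  if (n_x < 1 || n_y < 1) {
    stop("class sizes must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  score_set(stats::rnorm(n_x, params$mu_x, params$sigma_x),
            stats::rnorm(n_y, params$mu_y, params$sigma_y))
}
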