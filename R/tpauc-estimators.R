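#' Sensitivity/specificity bounds for the two-way partial AUC
#'
#' The rectangle of interest in ROC space: sensitivity (TPR) at least `b_se`
#' and specificity at least `b_sp` (equivalently FPR at most `1 - b_sp`). The
#' rectangle has area `(1 - b_se) * (1 - b_sp)`, the maximum any tpAUC can
#' attain.
#'
#' @param b_se sensitivity bound in \[0, 1).
#' @param b_sp specificity bound in \[0, 1).
#' @return An object of class `tpauc_bounds` with elements `b_se`, `b_sp`,
#'   `b_fpr = 1 - b_sp` and `rect_area`.
#' @examples
#' tpauc_bounds(0.6, 0.6)
#' @export
tpauc_bounds <- function(b_se, b_sp) {
  assert_prob(b_se, "b_se")
  assert_prob(b_sp, "b_sp")
  if (b_se >= 1 || b_sp >= 1) {
    stop("bounds must be strictly below 1 (the rectangle would be empty)",
         call. = FALSE)
  }
  structure(
    list(b_se = b_se, b_sp = b_sp, b_fpr = 1 - b_sp,
         rect_area = (1 - b_se) * (1 - b_sp)),
    class = "tpauc_bounds"
  )
}

#' @export
print.tpauc_bounds <- function(x, ...) {
  cat(sprintf("<tpauc_bounds> sensitivity >= %.3f, specificity >= %.3f (rectangle area %.4f)\n",
              x$b_se, x$b_sp, x$rect_area))
  invisible(x)
}

as_tpauc_bounds <- function(bounds) {
  if (inherits(bounds, "tpauc_bounds")) return(bounds)
  if (is.numeric(bounds) && length(bounds) == 2L) {
    return(tpauc_bounds(bounds[1], bounds[2]))
  }
  stop("expected 'tpauc_bounds' or a numeric (b_se, b_sp) pair", call. = FALSE)
}

#' Empirical inverse survival function
#'
#' Order-statistic inverse of the empirical survival function S(c) = P(score >
#' c): the value at 1-based index `clamp(floor((1 - u) * n), 1, n)` of the
#' sorted sample. Under this clamped-floor convention `u = 0` returns the
#' sample maximum (no trimming at a vacuous bound, so the trimmed U-statistics
#' reduce to their untrimmed forms) and `u = 1` the minimum.
#'
#' `strict = TRUE` instead reads the index as the largest integer *strictly*
#' smaller than `(1 - u) * n` whenever that product is an integer, the literal
#' textbook convention; it is exposed for comparison only.
#'
#' @param sample numeric vector, at least one value.
#' @param u probability in \[0, 1\].
#' @param strict use the strict-floor convention at integer arguments.
#' @return One sample value.
#' @examples
#' empirical_inverse_survival(1:10, 0.3)  # 7
#' @export
empirical_inverse_survival <- function(sample, u, strict = FALSE) {
  if (length(sample) < 1L) stop("empty sample", call. = FALSE)
  assert_prob(u, "u")
  s <- sort(sample)
  n <- length(s)
  arg <- (1 - u) * n
  # epsilon guards values such as (1 - 0.3) * 10 landing a hair below 7
  k <- floor(arg + 1e-9)
  if (strict && abs(arg - round(arg)) < 1e-9) k <- round(arg) - 1
  s[min(max(k, 1L), n)]
}

#' Mann-Whitney AUC estimate
#'
#' The pairwise concordance count `#\{X_i > Y_j\} / (n_x n_y)` with strict
#' inequality: cross-class ties contribute nothing (the trapezoidal estimator
#' [auc_trapezoid()] instead credits ties at half height). On tie-free data
#' the two estimates coincide exactly.
#'
#' @param scores a [score_set()].
#' @return Probability estimate of P(X > Y) in \[0, 1\].
#' @examples
#' auc_mw(score_set(c(3, 1), c(2, 0)))
#' @export
auc_mw <- function(scores) {
  scores <- as_score_set(scores)
  count_concordant(scores$x_scores, scores$y_scores) /
    (scores$n_x * scores$n_y)
}

# #{(i, j): x_i > y_j}, the double-sum concordance count of the U-statistic,
# evaluated by sorting (findInterval with left-open intervals counts y < x,
# so ties are excluded exactly as the strict inequality requires).
count_concordant <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) return(0)
  sum(findInterval(x, sort(y), left.open = TRUE))
}

#' Trimmed Mann-Whitney partial AUC estimate
#'
#' The one-way partial AUC as a trimmed U-statistic: the concordance sum
#' restricted to pairs whose negative score (for `axis = "fpr"`) or positive
#' score (for `axis = "se"`) falls between the empirical survival inverses at
#' the range ends, normalised by the untrimmed `n_x * n_y`.
#'
#' @param scores a [score_set()].
#' @param axis `"fpr"` to restrict the FPR range (trims Y), `"se"` to restrict
#'   the sensitivity range (trims X).
#' @param lo,hi the range on that axis, `0 <= lo < hi <= 1`.
#' @param strict passed to [empirical_inverse_survival()].
#' @return Area estimate in \[0, `hi - lo`\] (up to trimming granularity).
#' @examples
#' pauc_trimmed_mw(score_set(c(3, 1), c(2, 0)), "se", 0.5, 1)
#' @export
pauc_trimmed_mw <- function(scores, axis = c("fpr", "se"), lo, hi,
                            strict = FALSE) {
  scores <- as_score_set(scores)
  axis <- match.arg(axis)
  assert_prob(lo, "lo")
  assert_prob(hi, "hi")
  if (lo >= hi) stop("need lo < hi", call. = FALSE)
  x <- scores$x_scores
  y <- scores$y_scores
  if (axis == "fpr") {
    y_min <- empirical_inverse_survival(y, hi, strict)
    y_max <- empirical_inverse_survival(y, lo, strict)
    n_conc <- count_concordant(x, y[y >= y_min & y <= y_max])
  } else {
    x_min <- empirical_inverse_survival(x, hi, strict)
    x_max <- empirical_inverse_survival(x, lo, strict)
    n_conc <- count_concordant(x[x >= x_min & x <= x_max], y)
  }
  n_conc / (scores$n_x * scores$n_y)
}

#' Two-way partial AUC: trimmed Mann-Whitney estimator
#'
#' The original tpAUC estimator: the concordance sum over pairs with
#' `X_i <= S_F^{-1}(b_se)` and `Y_j >= S_G^{-1}(1 - b_sp)` (empirical survival
#' inverses), normalised by `n_x * n_y`. This is the O(n_x n_y) reference
#' against which the fast trapezoid-based estimator is compared; with both
#' bounds at zero it reduces to [auc_mw()].
#'
#' @param scores a [score_set()].
#' @param bounds a [tpauc_bounds()] (or numeric `c(b_se, b_sp)`).
#' @param strict passed to [empirical_inverse_survival()].
#' @return Area estimate in \[0, 1\].
#' @examples
#' tpauc_trimmed_mw(score_set(c(3, 1), c(2, 0)), tpauc_bounds(0.5, 0.5))
#' @export
tpauc_trimmed_mw <- function(scores, bounds, strict = FALSE) {
  scores <- as_score_set(scores)
  bounds <- as_tpauc_bounds(bounds)
  x <- scores$x_scores
  y <- scores$y_scores
  x_cut <- empirical_inverse_survival(x, bounds$b_se, strict)
  y_cut <- empirical_inverse_survival(y, 1 - bounds$b_sp, strict)
  count_concordant(x[x <= x_cut], y[y >= y_cut]) / (scores$n_x * scores$n_y)
}

new_tpauc_estimate <- function(value, zero, components, bounds,
                               estimator) {
  structure(
    list(value = value, is_zero_by_condition = zero,
         components = components, bounds = bounds, estimator = estimator),
    class = "tpauc_estimate"
  )
}

#' @export
print.tpauc_estimate <- function(x, ...) {
  cat(sprintf("<tpauc_estimate> %.6f (%s estimator; b_se = %.3f, b_sp = %.3f)\n",
              x$value, x$estimator, x$bounds$b_se, x$bounds$b_sp))
  if (x$is_zero_by_condition) {
    cat("  zero: the ROC curve does not enter the rectangle of interest\n")
  }
  invisible(x)
}

# Clamp an inclusion-exclusion estimate into [0, rectangle area]; cancellation
# can push the raw value a hair outside, anything further is reported.
clamp_estimate <- function(value, rect_area) {
  if (value < 0) {
    if (value < -1e-8) {
      warning(sprintf("tpAUC estimate %.3g below 0; clamped", value),
              call. = FALSE)
    }
    return(0)
  }
  if (value > rect_area) {
    if (value > rect_area + 1e-8) {
      warning(sprintf("tpAUC estimate %.3g above the rectangle area %.3g; clamped",
                      value, rect_area), call. = FALSE)
    }
    return(rect_area)
  }
  value
}

#' Two-way partial AUC: fast trapezoid-based estimator
#'
#' The tpAUC — the area under the ROC curve inside the rectangle where
#' sensitivity is at least `b_se` and specificity at least `b_sp` — assembled
#' from quantities any trapezoidal ROC software provides. The one-way partial
#' areas over sensitivity at least `b_se` and specificity at least `b_sp` each
#' contain the rectangle area plus one flanking region; inclusion-exclusion
#' against the full AUC leaves exactly the area inside the rectangle:
#'
#' \deqn{\widehat{tpAUC} = \widehat{pAUC}_{se} + \widehat{pAUC}_{sp} -
#'       (\widehat{AUC} - b_{se} b_{sp})}
#'
#' applied only when the curve enters the rectangle at all, i.e. when the
#' specificity attained at the sensitivity bound, `c_sp_hat =`
#' [specificity_at_sensitivity()], is at least `b_sp`; otherwise the tpAUC
#' is zero. All building blocks are O(n log n), which is what makes this
#' estimator usable inside bootstrap loops on large samples.
#'
#' @param roc a [build_empirical_roc()] curve.
#' @param bounds a [tpauc_bounds()] (or numeric `c(b_se, b_sp)`).
#' @return A `tpauc_estimate`: `value` (clamped into \[0, rectangle area\]),
#'   `is_zero_by_condition`, and the `components` list
#'   (`auc`, `pauc_se`, `pauc_sp`, `c_sp_hat`).
#' @examples
#' r <- build_empirical_roc(score_set(c(3, 1), c(2, 0)))
#' tpauc_proposed(r, tpauc_bounds(0.5, 0.4))
#' @export
tpauc_proposed <- function(roc, bounds) {
  assert_roc(roc)
  bounds <- as_tpauc_bounds(bounds)
  auc <- auc_trapezoid(roc)
  c_sp <- specificity_at_sensitivity(roc, bounds$b_se)
  if (c_sp < bounds$b_sp) {
    comps <- list(auc = auc, pauc_se = NA_real_, pauc_sp = NA_real_,
                  c_sp_hat = c_sp)
    return(new_tpauc_estimate(0, TRUE, comps, bounds, "proposed"))
  }
  pauc_se <- area_over_tpr(roc, bounds$b_se, 1)
  pauc_sp <- area_over_fpr(roc, 0, 1 - bounds$b_sp)
  raw <- pauc_se + pauc_sp - (auc - bounds$b_se * bounds$b_sp)
  comps <- list(auc = auc, pauc_se = pauc_se, pauc_sp = pauc_sp,
                c_sp_hat = c_sp)
  new_tpauc_estimate(clamp_estimate(raw, bounds$rect_area), FALSE, comps,
                     bounds, "proposed")
}

#' Two-way partial AUC: alternative trapezoid-based estimator
#'
#' Algebraically identical to [tpauc_proposed()] but computed directly from
#' the one-way partial area over the specificity band `[b_sp, c_sp_hat]` minus
#' the rectangle of height `b_se` beneath it:
#' `pAUC_sp(b_sp, c_sp_hat) - (c_sp_hat - b_sp) * b_se`. It skips the full AUC
#' and the sensitivity-side partial area, so it can be marginally faster; the
#' two estimators return the same value to numerical precision.
#'
#' @inheritParams tpauc_proposed
#' @return A `tpauc_estimate`, as for [tpauc_proposed()].
#' @examples
#' r <- build_empirical_roc(score_set(c(3, 1), c(2, 0)))
#' tpauc_alternative(r, tpauc_bounds(0.5, 0.5))
#' @export
tpauc_alternative <- function(roc, bounds) {
  assert_roc(roc)
  bounds <- as_tpauc_bounds(bounds)
  c_sp <- specificity_at_sensitivity(roc, bounds$b_se)
  if (c_sp < bounds$b_sp) {
    comps <- list(auc = NA_real_, pauc_se = NA_real_, pauc_sp = NA_real_,
                  c_sp_hat = c_sp)
    return(new_tpauc_estimate(0, TRUE, comps, bounds, "alternative"))
  }
  pauc_band <- area_over_fpr(roc, 1 - c_sp, 1 - bounds$b_sp)
  raw <- pauc_band - (c_sp - bounds$b_sp) * bounds$b_se
  comps <- list(auc = NA_real_, pauc_se = NA_real_, pauc_sp = pauc_band,
                c_sp_hat = c_sp)
  new_tpauc_estimate(clamp_estimate(raw, bounds$rect_area), FALSE, comps,
                     bounds, "alternative")
}

# Lean internal path used by the simulation experiments and the bootstrap:
# both fast-estimator value and (optionally) the trimmed-MW value from raw
# vectors, skipping S3 construction overhead.
tpauc_value <- function(x, y, b_se, b_sp) {
  roc <- build_empirical_roc(score_set(x, y))
  c_sp <- specificity_at_sensitivity(roc, b_se)
  if (c_sp < b_sp) return(0)
  raw <- area_over_tpr(roc, b_se, 1) + area_over_fpr(roc, 0, 1 - b_sp) -
    (auc_trapezoid(roc) - b_se * b_sp)
  min(max(raw, 0), (1 - b_se) * (1 - b_sp))
}
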