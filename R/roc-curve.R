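#' Empirical ROC curve
#'
#' Build the empirical ROC step curve for the decision rule "classify as
#' positive when score > c". For every distinct observed score `c` the curve
#' gains the vertex `(FPR(c), TPR(c))` with `FPR(c) = #\{Y_j > c\}/n_y` and
#' `TPR(c) = #\{X_i > c\}/n_x` (strict inequality); the anchors `(0,0)` and
#' `(1,1)` are always included and duplicate vertices are dropped. Scores tied
#' across the two classes yield a single diagonal trapezoid segment, which the
#' trapezoidal areas credit at half height (the standard empirical ROC
#' convention).
#'
#' The orientation is fixed: higher scores indicate the positive class. No
#' automatic direction detection is performed.
#'
#' @param scores a [score_set()].
#'
#' @return An object of class `roc_curve`: list with numeric vectors `fpr` and
#'   `tpr` (the vertex coordinates, non-decreasing, in \[0,1\], starting at
#'   `(0,0)` and ending at `(1,1)`) and the class sizes `n_x`, `n_y`.
#' @examples
#' r <- build_empirical_roc(score_set(c(3, 1), c(2, 0)))
#' cbind(r$fpr, r$tpr)
#' @export
build_empirical_roc <- function(scores) {
  scores <- as_score_set(scores)
  xs <- sort(scores$x_scores)
  ys <- sort(scores$y_scores)
  n_x <- scores$n_x
  n_y <- scores$n_y
  cs <- sort(unique(c(xs, ys)), decreasing = TRUE)
  # findInterval counts elements <= c, so n - count gives the strict #{ > c }
  tpr <- (n_x - findInterval(cs, xs)) / n_x
  fpr <- (n_y - findInterval(cs, ys)) / n_y
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  keep <- c(TRUE, diff(fpr) > 0 | diff(tpr) > 0)
  new_roc_curve(fpr[keep], tpr[keep], n_x, n_y)
}

new_roc_curve <- function(fpr, tpr, n_x, n_y) {
  structure(
    list(fpr = as.numeric(fpr), tpr = as.numeric(tpr),
         n_x = as.integer(n_x), n_y = as.integer(n_y)),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d vertices (n_x = %d, n_y = %d), AUC = %.4f\n",
              length(x$fpr), x$n_x, x$n_y, auc_trapezoid(x)))
  invisible(x)
}

assert_roc <- function(roc) {
  if (!inherits(roc, "roc_curve")) {
    stop("expected a 'roc_curve' (see build_empirical_roc())", call. = FALSE)
  }
  invisible(roc)
}

assert_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(p)
}

#' Area under the ROC curve by the trapezoidal rule
#'
#' @param roc a [build_empirical_roc()] curve.
#' @return The AUC in \[0, 1\]. On tie-free data this equals the
#'   Mann-Whitney estimate [auc_mw()] exactly.
#' @examples
#' auc_trapezoid(build_empirical_roc(score_set(c(3, 1), c(2, 0))))
#' @export
auc_trapezoid <- function(roc) {
  assert_roc(roc)
  f <- roc$fpr
  t <- roc$tpr
  k <- length(f)
  sum((f[-1] - f[-k]) * (t[-1] + t[-k]) / 2)
}

# Trapezoid area under the ROC over the FPR window [a, b]; boundaries falling
# inside a segment use linear interpolation of the TPR height.
area_over_fpr <- function(roc, a, b) {
  x1 <- roc$fpr[-length(roc$fpr)]
  x2 <- roc$fpr[-1]
  y1 <- roc$tpr[-length(roc$tpr)]
  y2 <- roc$tpr[-1]
  lo <- pmax(x1, a)
  hi <- pmin(x2, b)
  keep <- which(hi > lo)
  if (length(keep) == 0L) return(0)
  x1 <- x1[keep]; x2 <- x2[keep]; y1 <- y1[keep]; y2 <- y2[keep]
  lo <- lo[keep]; hi <- hi[keep]
  slope <- (y2 - y1) / (x2 - x1)
  h_lo <- y1 + slope * (lo - x1)
  h_hi <- y1 + slope * (hi - x1)
  sum((hi - lo) * (h_lo + h_hi) / 2)
}

# Area between the ROC curve and the line FPR = 1 over the TPR band [a, b]:
# the integral of (1 - FPR(v)) dv, trapezoids along the sensitivity axis.
area_over_tpr <- function(roc, a, b) {
  x1 <- roc$fpr[-length(roc$fpr)]
  x2 <- roc$fpr[-1]
  y1 <- roc$tpr[-length(roc$tpr)]
  y2 <- roc$tpr[-1]
  lo <- pmax(y1, a)
  hi <- pmin(y2, b)
  keep <- which(hi > lo)
  if (length(keep) == 0L) return(0)
  x1 <- x1[keep]; x2 <- x2[keep]; y1 <- y1[keep]; y2 <- y2[keep]
  lo <- lo[keep]; hi <- hi[keep]
  slope <- (x2 - x1) / (y2 - y1)
  f_lo <- x1 + slope * (lo - y1)
  f_hi <- x1 + slope * (hi - y1)
  sum((hi - lo) * ((1 - f_lo) + (1 - f_hi)) / 2)
}

#' Partial AUC over a specificity range
#'
#' Trapezoidal area under the ROC restricted to specificity in
#' `[sp_lo, sp_hi]`, i.e. FPR in `[1 - sp_hi, 1 - sp_lo]`. A range boundary
#' that falls inside a trapezoid is handled by linear interpolation of the ROC
#' height, so partial trapezoids are credited exactly.
#'
#' @param roc a [build_empirical_roc()] curve.
#' @param sp_lo,sp_hi specificity range, `0 <= sp_lo < sp_hi <= 1`.
#' @return Area in \[0, `sp_hi - sp_lo`\]. The full range `(0, 1)` recovers
#'   [auc_trapezoid()].
#' @examples
#' r <- build_empirical_roc(score_set(c(3, 1), c(2, 0)))
#' pauc_specificity(r, 0.75, 1)
#' @export
pauc_specificity <- function(roc, sp_lo, sp_hi) {
  assert_roc(roc)
  assert_prob(sp_lo, "sp_lo")
  assert_prob(sp_hi, "sp_hi")
  if (sp_lo >= sp_hi) stop("need sp_lo < sp_hi", call. = FALSE)
  area_over_fpr(roc, 1 - sp_hi, 1 - sp_lo)
}

#' Partial AUC over a sensitivity range
#'
#' Area of the region between the ROC curve and the right edge of the ROC
#' square (the line FPR = 1) for sensitivity in `[se_lo, se_hi]` — the
#' integral of specificity over that TPR band — computed by the same
#' partial-trapezoid rule as [pauc_specificity()], applied along the TPR axis.
#'
#' @param roc a [build_empirical_roc()] curve.
#' @param se_lo,se_hi sensitivity range, `0 <= se_lo < se_hi <= 1`.
#' @return Area in \[0, `se_hi - se_lo`\]. The full range `(0, 1)` recovers
#'   [auc_trapezoid()].
#' @examples
#' r <- build_empirical_roc(score_set(c(3, 1), c(2, 0)))
#' pauc_sensitivity(r, 0.5, 1)
#' @export
pauc_sensitivity <- function(roc, se_lo, se_hi) {
  assert_roc(roc)
  assert_prob(se_lo, "se_lo")
  assert_prob(se_hi, "se_hi")
  if (se_lo >= se_hi) stop("need se_lo < se_hi", call. = FALSE)
  area_over_tpr(roc, se_lo, se_hi)
}

#' Specificity attained at a sensitivity bound
#'
#' The largest specificity at which the ROC curve reaches sensitivity at least
#' `b_se`. When `b_se` falls strictly between two vertex TPR values the
#' specificity is linearly interpolated between the flanking vertices; on a
#' vertical segment (a sensitivity jump at fixed FPR) the segment's own
#' specificity is returned. The empirical ROC enters the joint
#' sensitivity/specificity rectangle of interest exactly when this value is at
#' least the specificity bound.
#'
#' @param roc a [build_empirical_roc()] curve.
#' @param b_se sensitivity bound in \[0, 1\].
#' @return Specificity in \[0, 1\].
#' @examples
#' r <- build_empirical_roc(score_set(c(3, 1), c(2, 0)))
#' specificity_at_sensitivity(r, 0.75)
#' @export
specificity_at_sensitivity <- function(roc, b_se) {
  assert_roc(roc)
  assert_prob(b_se, "b_se")
  t <- roc$tpr
  f <- roc$fpr
  k <- match(TRUE, t >= b_se)  # first vertex attaining the bound
  if (k == 1L || t[k] == b_se || f[k] == f[k - 1L]) {
    return(1 - f[k])
  }
  slope <- (f[k] - f[k - 1L]) / (t[k] - t[k - 1L])
  1 - (f[k - 1L] + slope * (b_se - t[k - 1L]))
}
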