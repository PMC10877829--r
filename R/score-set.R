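#' Construct a score set
#'
#' Bundle the continuous classification scores of the positive and negative
#' cases. Every estimator in the package takes its data in this form: `x` holds
#' the scores of the positive class (disease present, event, ...), `y` the
#' scores of the negative class. Scores are unitless; higher scores indicate
#' the positive class.
#'
#' @param x numeric vector of positive-class scores (at least one, all finite).
#' @param y numeric vector of negative-class scores (at least one, all finite).
#'
#' @return An object of class `score_set`: a list with elements `x_scores`,
#'   `y_scores`, `n_x` and `n_y`.
#' @examples
#' score_set(c(3, 1), c(2, 0))
#' @export
score_set <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    stop("degenerate labels: both a positive and a negative class are required",
         call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("scores must be finite", call. = FALSE)
  }
  structure(
    list(x_scores = x, y_scores = y,
         n_x = length(x), n_y = length(y)),
    class = "score_set"
  )
}

#' Build a score set from scores and binary labels
#'
#' @param scores numeric vector of scores.
#' @param labels vector of 0/1 labels, 1 marking the positive class; must
#'   contain both classes.
#'
#' @return A [score_set()].
#' @examples
#' split_scores(c(3, 1, 2, 0), c(1, 1, 0, 0))
#' @export
split_scores <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be 0 or 1 (1 = positive class)", call. = FALSE)
  }
  score_set(scores[labels == 1], scores[labels == 0])
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> %d positive, %d negative cases\n", x$n_x, x$n_y))
  invisible(x)
}

as_score_set <- function(scores) {
  if (inherits(scores, "score_set")) return(scores)
  if (is.list(scores) && all(c("x_scores", "y_scores") %in% names(scores))) {
    return(score_set(scores$x_scores, scores$y_scores))
  }
  stop("expected a 'score_set' (see score_set() or split_scores())",
       call. = FALSE)
}
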