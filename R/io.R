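#' Read a delimited score table
#'
#' Reads a headered delimited text file (comma for `.csv`, tab otherwise) with
#' one score and one 0/1 label per record, validating every row: non-numeric
#' scores and labels outside \{0, 1\} are rejected with row-numbered messages,
#' and both classes must be present. An optional second score column supports
#' paired classifier comparison.
#'
#' @param path file path.
#' @param score_col,label_col column names (defaults `"score"`, `"label"`).
#' @param second_score_col optional name of a second score column.
#' @return An object of class `score_table`: list with `scores`, `labels`,
#'   optional `scores_2`, and `path`.
#' @export
read_score_table <- function(path, score_col = "score", label_col = "label",
                             second_score_col = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(score_col, label_col, second_score_col)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  check_numeric <- function(v, col) {
    val <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(val))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or non-finite '%s' at data row(s): %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    val
  }
  scores <- check_numeric(tab[[score_col]], score_col)
  labels <- check_numeric(tab[[label_col]], label_col)
  bad_lab <- which(!(labels %in% c(0, 1)))
  if (length(bad_lab) > 0L) {
    stop(sprintf("labels outside {0, 1} at data row(s): %s",
                 paste(utils::head(bad_lab, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("degenerate labels: both classes required", call. = FALSE)
  }
  out <- list(scores = scores, labels = labels, path = path)
  if (!is.null(second_score_col)) {
    out$scores_2 <- check_numeric(tab[[second_score_col]], second_score_col)
  }
  structure(out, class = "score_table")
}

#' Serialise a result object
#'
#' Writes a [tpauc_proposed()] estimate, a [bootstrap_delta_ci()] comparison,
#' or a [run_bias_experiment()] table to JSON or TSV, including all
#' components, bounds, seed where applicable, and the package version, so
#' results are round-trippable and self-describing.
#'
#' @param result a `tpauc_estimate`, `delta_comparison` or `bias_result`.
#' @param path destination file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  payload <- result_payload(result)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    flat <- result_rows(result)
    flat$tool_version <- as.character(utils::packageVersion("tpaucfast"))
    utils::write.table(flat, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

result_payload <- function(result) {
  version <- as.character(utils::packageVersion("tpaucfast"))
  if (inherits(result, "tpauc_estimate")) {
    list(type = "tpauc_estimate", value = result$value,
         is_zero_by_condition = result$is_zero_by_condition,
         estimator = result$estimator,
         components = result$components,
         bounds = list(b_se = result$bounds$b_se, b_sp = result$bounds$b_sp),
         tool_version = version)
  } else if (inherits(result, "delta_comparison")) {
    list(type = "delta_comparison",
         delta_hat = result$delta_hat, v2_boot = result$v2_boot,
         ci_lo = result$ci_lo, ci_hi = result$ci_hi,
         B = result$B, alpha = result$alpha,
         tpauc_1 = result$tpauc_1, tpauc_2 = result$tpauc_2,
         n_x = result$n_x, n_y = result$n_y, seed = result$seed,
         ci_scaling = result$ci_scaling, tool_version = version)
  } else if (inherits(result, "bias_result")) {
    list(type = "bias_result", rows = as.data.frame(result),
         tool_version = version)
  } else {
    stop("unsupported result type", call. = FALSE)
  }
}

result_rows <- function(result) {
  if (inherits(result, "bias_result")) return(as.data.frame(result))
  payload <- result_payload(result)
  payload$tool_version <- NULL
  flat <- rapply(payload, function(v) v, how = "unlist")
  as.data.frame(as.list(flat), stringsAsFactors = FALSE)
}
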