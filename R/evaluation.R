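# Confusion accounting over the four color/size groups.

group_label <- function(color_group, size_class) paste(color_group, size_class, sep = "/")

#' Confusion table from per-group counts
#'
#' The arithmetic core of the evaluation: per-group correct classification
#' rate `(graded - incorrect) / graded`, and the global rate
#' `(sum graded - sum incorrect) / sum graded` (identically the graded-count
#' weighted mean of the group rates). Full precision is retained in the
#' `rate`/`global_rate` columns; `rate_3dp`/`global_rate_3dp` are rounded to
#' three decimals for reporting.
#'
#' @param graded named integer vector of graded counts per group.
#' @param incorrect integer vector of incorrect counts, aligned with `graded`.
#' @return A list of class `confusion_table` with `groups` (a data.frame) and
#'   the global rates.
#' @export
confusion_from_counts <- function(graded, incorrect) {
  stopifnot(length(graded) == length(incorrect),
            all(incorrect >= 0), all(graded >= 1), all(incorrect <= graded))
  rate <- (graded - incorrect) / graded
  groups <- data.frame(group = if (is.null(names(graded)))
                         as.character(seq_along(graded)) else names(graded),
                       graded = as.integer(graded),
                       incorrect = as.integer(incorrect),
                       rate = rate,
                       rate_3dp = round(rate, 3),
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  global <- (sum(graded) - sum(incorrect)) / sum(graded)
  structure(list(groups = groups,
                 global_rate = global,
                 global_rate_3dp = round(global, 3)),
            class = "confusion_table")
}

#' Summarize predictions against ground truth
#'
#' Compares aligned lists of grade records on their (color group, size class)
#' pair. Groups are keyed by the *truth* group; groups with no graded apples
#' are absent from the table rather than reported as zero.
#'
#' @param predicted,truth equal-length lists of `grade_record` objects (or
#'   data.frames with `color_group` and `size_class` columns).
#' @return A `confusion_table`.
#' @examples
#' a <- list(structure(list(color_group = "red", size_class = "large"),
#'                     class = "grade_record"))
#' summarize_grades(a, a)$global_rate
#' @export
summarize_grades <- function(predicted, truth) {
  pg <- extract_groups(predicted)
  tg <- extract_groups(truth)
  if (length(pg) != length(tg))
    ag_stop("predicted and truth have different lengths",
            "applegrader_value_error")
  groups <- unique(tg)
  graded <- vapply(groups, function(g) sum(tg == g), integer(1))
  incorrect <- vapply(groups, function(g) sum(tg == g & pg != tg), integer(1))
  confusion_from_counts(setNames(graded, groups), incorrect)
}

extract_groups <- function(x) {
  if (is.data.frame(x)) return(group_label(x$color_group, x$size_class))
  vapply(x, function(r) group_label(r$color_group, r$size_class), "")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("Apple classification results\n")
  df <- x$groups
  df$rate <- sprintf("%.3f", df$rate_3dp)
  print(df[, c("group", "graded", "incorrect", "rate")], row.names = FALSE)
  cat(sprintf("Global correct classification rate: %.3f (%d/%d)\n",
              x$global_rate_3dp,
              sum(x$groups$graded) - sum(x$groups$incorrect),
              sum(x$groups$graded)))
  invisible(x)
}

#' Write a confusion table to CSV and/or JSON
#'
#' @param ct a `confusion_table`.
#' @param csv,json optional output paths.
#' @return `ct`, invisibly.
#' @export
write_confusion <- function(ct, csv = NULL, json = NULL) {
  stopifnot(inherits(ct, "confusion_table"))
  if (!is.null(csv)) write.csv(ct$groups, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(groups = ct$groups,
                              global_rate = ct$global_rate,
                              global_rate_3dp = ct$global_rate_3dp),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(ct)
}
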