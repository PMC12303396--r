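# Error assessment: per-label Euclidean distances over a montage, per-scan
# summaries, grand means across participants, and per-position statistics.
#
# Variance convention: population (divide by n), both for the within-scan
# label spread and for the across-participant per-position variance; the
# participant count is recorded alongside.

#' Per-label Euclidean errors between two montages
#'
#' @param a,b [montage_points()] sets with the same `montage_id` and label
#'   sets.
#' @return named numeric vector, label -> distance (mm).
#' @export
pointwise_errors <- function(a, b) {
  ida <- attr(a, "montage_id"); idb <- attr(b, "montage_id")
  if (!identical(ida, idb))
    stop("montage ids differ: ", ida, " vs ", idb, call. = FALSE)
  if (!setequal(a$label, b$label)) {
    diff <- c(setdiff(a$label, b$label), setdiff(b$label, a$label))
    stop("label mismatch; symmetric difference: ",
         paste(diff, collapse = ", "), call. = FALSE)
  }
  idx <- match(a$label, b$label)
  d <- sqrt((a$x - b$x[idx])^2 + (a$y - b$y[idx])^2 + (a$z - b$z[idx])^2)
  stats::setNames(d, a$label)
}

#' Error report for one scan and method
#'
#' Summarises a label -> distance map into the mean/min/max/standard
#' deviation schema used for per-participant reporting.
#'
#' @param errors named numeric vector of distances (mm), label -> error.
#' @param method_id method identifier (e.g. `"scalp_estimation"`).
#' @param participant_id participant identifier.
#' @return object of class `error_report` with fields `per_label`, `mean`,
#'   `minimum`, `maximum`, `std` (population), `n_labels`, `method_id`,
#'   `participant_id`.
#' @export
summarize_errors <- function(errors, method_id = "method",
                             participant_id = "participant") {
  errors <- unlist(errors)
  if (length(errors) == 0L) stop("empty error map", call. = FALSE)
  structure(list(per_label = errors,
                 mean = mean(errors),
                 minimum = min(errors),
                 maximum = max(errors),
                 std = sqrt(mean((errors - mean(errors))^2)),
                 n_labels = length(errors),
                 method_id = method_id,
                 participant_id = participant_id),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %s / %s (%d labels)\n", x$method_id,
              x$participant_id, x$n_labels))
  cat(sprintf("  mean %.2f  min %.2f  max %.2f  std %.2f  (mm)\n",
              x$mean, x$minimum, x$maximum, x$std))
  invisible(x)
}

#' Grand mean across participants for one method
#'
#' Column-wise mean of the per-participant summaries (mean of means, mean of
#' minima, and so on), the convention used for across-participant reporting.
#' The global extremes over all labels and participants are also recorded.
#'
#' @param reports list of [summarize_errors()] reports with a common
#'   `method_id`.
#' @return an `error_report` with `participant_id = "grand_mean"`, attribute
#'   `n_participants`, and attributes `global_min`/`global_max`.
#' @export
grand_mean <- function(reports) {
  if (length(reports) == 0L) stop("no reports", call. = FALSE)
  if (inherits(reports, "error_report")) reports <- list(reports)
  ids <- unique(vapply(reports, `[[`, "", "method_id"))
  if (length(ids) != 1L)
    stop("mixed methods in grand mean: ", paste(ids, collapse = ", "),
         call. = FALSE)
  all_err <- unlist(lapply(reports, `[[`, "per_label"))
  out <- structure(list(
    per_label = NULL,
    mean = mean(vapply(reports, `[[`, 0, "mean")),
    minimum = mean(vapply(reports, `[[`, 0, "minimum")),
    maximum = mean(vapply(reports, `[[`, 0, "maximum")),
    std = mean(vapply(reports, `[[`, 0, "std")),
    n_labels = reports[[1]]$n_labels,
    method_id = ids,
    participant_id = "grand_mean"), class = "error_report")
  attr(out, "n_participants") <- length(reports)
  attr(out, "global_min") <- min(all_err)
  attr(out, "global_max") <- max(all_err)
  out
}

#' Per-position statistics across participants
#'
#' Mean and population variance of the error at each montage position across
#' participants.
#'
#' @param error_maps list of named error vectors (identical label sets).
#' @return object of class `position_stats`: data frame with `label`,
#'   `mean_mm`, `var_mm2` and attribute `n_participants`.
#' @export
position_stats <- function(error_maps) {
  if (length(error_maps) == 0L) stop("no error maps", call. = FALSE)
  labs <- names(error_maps[[1]])
  for (m in error_maps)
    if (!setequal(names(m), labs))
      stop("label mismatch across error maps; symmetric difference: ",
           paste(c(setdiff(names(m), labs), setdiff(labs, names(m))),
                 collapse = ", "), call. = FALSE)
  mat <- vapply(error_maps, function(m) m[labs], numeric(length(labs)))
  mat <- matrix(mat, length(labs))
  mu <- rowMeans(mat)
  va <- rowMeans((mat - mu)^2)
  out <- data.frame(label = labs, mean_mm = mu, var_mm2 = va,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("position_stats", "data.frame")
  attr(out, "n_participants") <- length(error_maps)
  out
}

#' Serialise reports to a delimited table
#'
#' One row per report with the columns `method`, `participant`, `mean_mm`,
#' `min_mm`, `max_mm`, `std_mm` (the per-participant report schema).
#'
#' @param reports list of `error_report` objects.
#' @param path optional CSV output path.
#' @return the data frame, invisibly when writing.
#' @export
error_report_table <- function(reports, path = NULL) {
  if (inherits(reports, "error_report")) reports <- list(reports)
  df <- data.frame(
    method = vapply(reports, `[[`, "", "method_id"),
    participant = vapply(reports, `[[`, "", "participant_id"),
    mean_mm = vapply(reports, `[[`, 0, "mean"),
    min_mm = vapply(reports, `[[`, 0, "minimum"),
    max_mm = vapply(reports, `[[`, 0, "maximum"),
    std_mm = vapply(reports, `[[`, 0, "std"),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Serialise per-position statistics to CSV
#'
#' Columns `label`, `mean_mm`, `var_mm2`, `n`.
#'
#' @param stats a [position_stats()] data frame.
#' @param path CSV output path.
#' @export
position_stats_csv <- function(stats, path) {
  df <- cbind(stats, n = attr(stats, "n_participants"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
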