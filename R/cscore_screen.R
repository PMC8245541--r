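#' Coincidence-detection screen configuration
#'
#' The screen calls a protein a candidate when three replicate-level
#' filters coincide: (1) its ratio is quantified in a majority of
#' replicates, (2) its average oriented ratio crosses a fold-change
#' threshold (default +/-20%: >= 1.2 up, <= 0.8 down), and (3) a strict
#' majority of the detected replicates shift in that same direction.
#' No multiple-testing machinery is involved; replicate coincidence is
#' the error control.
#'
#' @param fc_up_threshold mean-ratio threshold for an up call
#'   (default 1.2).
#' @param fc_down_threshold mean-ratio threshold for a down call
#'   (default 0.8).
#' @param min_detected minimum quantified replicates, or `NULL` for the
#'   majority rule: strictly more than half of total replicates
#'   (3 of 5, 4 of 7).
#' @param mean_type `"arithmetic"` (default) or `"geometric"` average
#'   of the detected oriented ratios. The geometric mean makes the
#'   screen exactly symmetric under ratio inversion.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(fc_up_threshold = 1.2,
                          fc_down_threshold = 0.8,
                          min_detected = NULL,
                          mean_type = c("arithmetic", "geometric")) {
  fc_up_threshold <- check_number(fc_up_threshold, "fc_up_threshold")
  fc_down_threshold <- check_number(fc_down_threshold, "fc_down_threshold")
  if (!(fc_down_threshold < 1 && 1 < fc_up_threshold))
    stopf("need fc_down_threshold < 1 < fc_up_threshold")
  if (!is.null(min_detected))
    min_detected <- check_count(min_detected, "min_detected")
  mean_type <- match.arg(mean_type)
  structure(list(fc_up_threshold = fc_up_threshold,
                 fc_down_threshold = fc_down_threshold,
                 min_detected = min_detected,
                 mean_type = mean_type),
            class = "screen_config")
}

#' Majority detection threshold
#'
#' Strictly more than half of `n` replicates: 3 of 5, 4 of 7.
#'
#' @param n total replicates.
#' @return The smallest count that is a strict majority of `n`.
#' @export
majority_min <- function(n) {
  n <- check_count(n, "n")
  as.integer(floor(n / 2) + 1L)
}

.screen_classes <- c("up", "down", "unchanged", "insufficient")

#' Classify one protein with the coincidence-detection rules
#'
#' @param ratios numeric vector of oriented ratios for one protein,
#'   one entry per replicate; `NA` = not quantified.
#' @param n_replicates total replicates in the experiment (defaults to
#'   `length(ratios)`).
#' @param config a [screen_config()].
#' @return A list: `n_detected`, `mean_ratio` (`NA` if insufficient),
#'   `n_up` (detected replicates with ratio > 1), `n_down` (< 1; a
#'   ratio of exactly 1 counts to neither side), and `class`, one of
#'   `"up"`, `"down"`, `"unchanged"`, `"insufficient"`. A direction tie
#'   (`n_up == n_down`) is never called a candidate: the coincidence
#'   rule demands a strict majority of replicates agreeing.
#' @export
classify_protein <- function(ratios, n_replicates = length(ratios),
                             config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (length(ratios) != n_replicates)
    stopf("'ratios' must have one entry per replicate (%d)", n_replicates)
  present <- !is.na(ratios)
  if (any(!is.finite(ratios[present]) | ratios[present] <= 0))
    stopf("present ratios must be strictly positive and finite")

  min_det <- config$min_detected %||% majority_min(n_replicates)
  n_detected <- sum(present)
  n_up <- sum(ratios[present] > 1)
  n_down <- sum(ratios[present] < 1)

  if (n_detected < min_det)
    return(list(n_detected = n_detected, mean_ratio = NA_real_,
                n_up = n_up, n_down = n_down, class = "insufficient"))

  mean_ratio <- if (config$mean_type == "arithmetic")
    mean(ratios[present]) else exp(mean(log(ratios[present])))
  class <- if (mean_ratio >= config$fc_up_threshold && n_up > n_down)
    "up"
  else if (mean_ratio <= config$fc_down_threshold && n_down > n_up)
    "down"
  else "unchanged"
  list(n_detected = n_detected, mean_ratio = mean_ratio,
       n_up = n_up, n_down = n_down, class = class)
}

#' Run the candidate screen over an oriented ratio table
#'
#' Applies [classify_protein()] to every protein. The result is
#' deterministic and returned in protein-id order regardless of the
#' input row order.
#'
#' @param table an oriented [ratio_table()].
#' @param config a [screen_config()].
#' @return A `data.frame` of class `screen_calls`: `protein_id`,
#'   `gene`, `n_detected`, `mean_ratio`, `n_up`, `n_down`, `class`.
#' @export
run_screen <- function(table, config = screen_config()) {
  stopifnot(inherits(table, "ratio_table"))
  if (!table$oriented)
    stopf("table must be oriented (see orient_ratios) before screening")
  stopifnot(inherits(config, "screen_config"))
  n <- nrow(table$ratios)
  if (n == 0L) {
    out <- data.frame(protein_id = character(), gene = character(),
                      n_detected = integer(), mean_ratio = numeric(),
                      n_up = integer(), n_down = integer(),
                      class = character(), stringsAsFactors = FALSE)
    class(out) <- c("screen_calls", "data.frame")
    return(out)
  }
  calls <- lapply(seq_len(n), function(i)
    classify_protein(table$ratios[i, ], ncol(table$ratios), config))
  out <- data.frame(
    protein_id = rownames(table$ratios),
    gene = table$gene,
    n_detected = vapply(calls, `[[`, integer(1), "n_detected"),
    mean_ratio = vapply(calls, `[[`, numeric(1), "mean_ratio"),
    n_up = vapply(calls, function(c) as.integer(c$n_up), integer(1)),
    n_down = vapply(calls, function(c) as.integer(c$n_down), integer(1)),
    class = vapply(calls, `[[`, character(1), "class"),
    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screen_calls", "data.frame")
  out
}

#' Cohort-level screen summary from raw counts
#'
#' Arithmetic layer shared by [summarize_screen()]: percentages are
#' 100 x count / majority-detected denominator, rounded half-up to one
#' decimal, the convention of the published doughnut plots.
#'
#' @param n_total proteins screened (detected at least once).
#' @param n_detected_majority proteins passing majority detection (the
#'   percentage denominator).
#' @param n_up,n_down candidate counts.
#' @return A list of class `screen_summary` with counts and `pct_up`,
#'   `pct_down`, `pct_unchanged`.
#' @export
screen_summary <- function(n_total, n_detected_majority, n_up, n_down) {
  n_total <- check_count(n_total, "n_total", min = 0L)
  n_detected_majority <- check_count(n_detected_majority,
                                     "n_detected_majority", min = 0L)
  n_up <- check_count(n_up, "n_up", min = 0L)
  n_down <- check_count(n_down, "n_down", min = 0L)
  if (n_up + n_down > n_detected_majority)
    stopf("candidate counts exceed the majority-detected denominator")
  n_unchanged <- n_detected_majority - n_up - n_down
  pct <- function(k) if (n_detected_majority == 0L) 0
    else round_half_up(100 * k / n_detected_majority, 1)
  structure(list(n_total = n_total,
                 n_detected_majority = n_detected_majority,
                 n_up = n_up, n_down = n_down, n_unchanged = n_unchanged,
                 pct_up = pct(n_up), pct_down = pct(n_down),
                 pct_unchanged = pct(n_unchanged)),
            class = "screen_summary")
}

#' Summarize screen calls for one cohort
#'
#' @param calls a `screen_calls` data frame from [run_screen()].
#' @return A [screen_summary()].
#' @export
summarize_screen <- function(calls) {
  stopifnot(is.data.frame(calls), "class" %in% names(calls))
  screen_summary(
    n_total = nrow(calls),
    n_detected_majority = sum(calls$class != "insufficient"),
    n_up = sum(calls$class == "up"),
    n_down = sum(calls$class == "down"))
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("screen summary: %d proteins, %d majority-detected\n",
              x$n_total, x$n_detected_majority))
  cat(sprintf("  up        %5d (%.1f%%)\n", x$n_up, x$pct_up))
  cat(sprintf("  down      %5d (%.1f%%)\n", x$n_down, x$pct_down))
  cat(sprintf("  unchanged %5d (%.1f%%)\n", x$n_unchanged,
              x$pct_unchanged))
  invisible(x)
}

#' Write screen calls / summary
#'
#' @param calls a `screen_calls` data frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_screen_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_screen_calls
#' @param summary a [screen_summary()].
#' @export
write_screen_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
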