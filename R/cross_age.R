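#' Cross-cohort concordance of candidate proteins
#'
#' Compares candidate sets between two cohorts (e.g. young vs aged).
#' The overlap is the set of proteins called a candidate (`up` or
#' `down`) in *both* cohorts; `unchanged` and `insufficient` exclude a
#' protein, since the comparison is over dysregulated sets. Each
#' overlapping protein is classified by concordance: `both_up`,
#' `both_down`, or `reversed` (opposite directions). Matching is by
#' protein id only; gene symbols are carried as annotation and never
#' create or destroy overlap.
#'
#' @param calls_a,calls_b `screen_calls` data frames (see
#'   [run_screen()]) sharing a protein identifier space.
#' @return A list of class `concordance_result`:
#'   \describe{
#'     \item{overlap}{`data.frame` with `protein_id`, `class_a`,
#'       `class_b`, `concordance`, in protein-id order.}
#'     \item{counts}{named integer vector `both_up`, `both_down`,
#'       `reversed`; sums to `n_overlap`.}
#'     \item{n_overlap}{overlap size.}
#'     \item{n_candidates_a,n_candidates_b}{cohort candidate totals.}
#'   }
#' @export
concordance_table <- function(calls_a, calls_b) {
  for (nm in c("a", "b")) {
    calls <- if (nm == "a") calls_a else calls_b
    stopifnot(is.data.frame(calls),
              all(c("protein_id", "class") %in% names(calls)))
    if (anyDuplicated(calls$protein_id))
      stopf("duplicate protein ids in cohort %s", nm)
  }
  cand_a <- calls_a[calls_a$class %in% c("up", "down"), ]
  cand_b <- calls_b[calls_b$class %in% c("up", "down"), ]
  ids <- sort(intersect(cand_a$protein_id, cand_b$protein_id))
  class_a <- cand_a$class[match(ids, cand_a$protein_id)]
  class_b <- cand_b$class[match(ids, cand_b$protein_id)]
  concordance <- ifelse(class_a == class_b,
                        ifelse(class_a == "up", "both_up", "both_down"),
                        "reversed")
  overlap <- data.frame(protein_id = ids, class_a = class_a,
                        class_b = class_b, concordance = concordance,
                        stringsAsFactors = FALSE)
  counts <- c(both_up = sum(concordance == "both_up"),
              both_down = sum(concordance == "both_down"),
              reversed = sum(concordance == "reversed"))
  structure(list(overlap = overlap, counts = counts,
                 n_overlap = length(ids),
                 n_candidates_a = nrow(cand_a),
                 n_candidates_b = nrow(cand_b)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: %d / %d (A) and %d (B) candidates overlap\n",
              x$n_overlap, x$n_candidates_a, x$n_candidates_b))
  for (nm in names(x$counts))
    cat(sprintf("  %-9s %d/%d\n", nm, x$counts[[nm]], x$n_overlap))
  invisible(x)
}

#' Write a concordance result
#'
#' @param result a [concordance_table()] result.
#' @param path output TSV for the per-protein table; a sibling
#'   `<path>.json` receives the category counts.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(result, path) {
  stopifnot(inherits(result, "concordance_result"))
  utils::write.table(result$overlap, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    c(as.list(result$counts), list(n_overlap = result$n_overlap)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
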