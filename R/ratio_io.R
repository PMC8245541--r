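#' Per-protein, per-replicate ratio table
#'
#' The central container of the package: one row per protein group, one
#' column per replicate experiment, holding heavy/medium SILAC ratios.
#' Ratios are dimensionless and strictly positive; `NA` marks a missing
#' (non-quantified) cell. A table is either *raw* (ratios as exported,
#' channel assignment varying with the replicate's label swap) or
#' *oriented* (all ratios expressed as affected-genotype over control,
#' e.g. APP/PS1 : WT), as produced by [orient_ratios()].
#'
#' @param ratios numeric matrix; rownames are protein-group identifiers
#'   (leading accession), colnames are replicate ids. `NA` = missing.
#' @param gene optional character vector of gene symbols, one per row
#'   (annotation only, never used for matching).
#' @param oriented logical; `TRUE` once ratios are affected/control.
#' @return An object of class `ratio_table`.
#' @export
ratio_table <- function(ratios, gene = NULL, oriented = FALSE) {
  if (!is.matrix(ratios) || !is.numeric(ratios))
    stopf("'ratios' must be a numeric matrix")
  if (nrow(ratios) > 0L &&
      (is.null(rownames(ratios)) || anyDuplicated(rownames(ratios))))
    stopf("'ratios' must have unique protein-id rownames")
  if (is.null(rownames(ratios))) rownames(ratios) <- character(0)
  if (is.null(colnames(ratios)) || anyDuplicated(colnames(ratios)))
    stopf("'ratios' must have unique replicate-id colnames")
  vals <- ratios[!is.na(ratios)]
  if (any(!is.finite(vals) | vals <= 0))
    stopf("all present ratios must be strictly positive and finite")
  if (is.null(gene)) gene <- rep(NA_character_, nrow(ratios))
  if (length(gene) != nrow(ratios))
    stopf("'gene' must have one entry per protein")
  structure(
    list(ratios = ratios, gene = as.character(gene),
         oriented = isTRUE(oriented)),
    class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("ratio_table: %d proteins x %d replicates (%s)\n",
              nrow(x$ratios), ncol(x$ratios),
              if (x$oriented) "oriented affected/control" else "raw H/M"))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$ratios)),
              100 * mean(is.na(x$ratios))))
  invisible(x)
}

#' @export
dim.ratio_table <- function(x) dim(x$ratios)

#' Replicate label design
#'
#' Maps each replicate experiment to its isotope-channel orientation.
#' SILAC label assignment is alternated between biological replicates
#' ("label swap") so that systematic channel biases cancel; `forward`
#' means the affected genotype carries the heavy channel (raw H/M ratio
#' is already affected/control), `swapped` means the channels were
#' reversed and the raw ratio must be inverted.
#'
#' @param replicate_id character vector of unique replicate ids.
#' @param orientation `"forward"` or `"swapped"`, one per replicate.
#' @param cohort optional cohort label (e.g. `"young"`, `"aged"`).
#' @return A `data.frame` of class `label_design`.
#' @export
label_design <- function(replicate_id, orientation,
                         cohort = NA_character_) {
  replicate_id <- as.character(replicate_id)
  if (anyDuplicated(replicate_id))
    stopf("replicate ids must be unique")
  orientation <- as.character(orientation)
  if (!all(orientation %in% c("forward", "swapped")))
    stopf("'orientation' must be 'forward' or 'swapped'")
  if (length(orientation) != length(replicate_id))
    stopf("'orientation' must have one entry per replicate")
  d <- data.frame(replicate_id = replicate_id,
                  orientation = orientation,
                  cohort = rep_len(as.character(cohort),
                                   length(replicate_id)),
                  stringsAsFactors = FALSE)
  class(d) <- c("label_design", "data.frame")
  d
}

#' Read a label design from TSV or YAML
#'
#' @param path file with columns/keys `replicate_id`, `orientation`,
#'   optionally `cohort`. Format chosen by extension (`.yml`/`.yaml`
#'   vs tab-separated text).
#' @return A [label_design()].
#' @export
read_label_design <- function(path) {
  if (!file.exists(path)) stopf("design file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$replicates)) y <- y$replicates
    d <- do.call(rbind, lapply(y, function(r)
      data.frame(replicate_id = as.character(r$replicate_id),
                 orientation = as.character(r$orientation),
                 cohort = as.character(r$cohort %||% NA),
                 stringsAsFactors = FALSE)))
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("replicate_id", "orientation")
  if (!all(need %in% names(d)))
    stopf("design must provide columns: %s", paste(need, collapse = ", "))
  label_design(d$replicate_id, d$orientation,
               if ("cohort" %in% names(d)) d$cohort else NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# proteinGroups column names (MaxQuant dialect)
.pg_id_col      <- "Protein IDs"
.pg_gene_col    <- "Gene names"
.pg_rev_col     <- "Reverse"
.pg_con_col     <- "Potential contaminant"
.pg_site_col    <- "Only identified by site"
.pg_ratio_stem  <- "Ratio H/M normalized "

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated protein-group quantitation table, drops the
#' standard artifact rows, and extracts one normalized H/M ratio column
#' per replicate experiment. Rows marked reverse (decoy), potential
#' contaminant or (by default) only-identified-by-site are removed and
#' counted in the attached filter report. Ratio cells that are empty,
#' `"NaN"` or `"0"` become missing: a zero ratio is non-physical and is
#' treated as a failed quantification, not a measurement.
#'
#' @param path tab-separated file with a header row.
#' @param ratio_pattern regular expression locating the ratio columns;
#'   the remainder of the column name is the replicate id.
#' @param filter_only_site drop "Only identified by site" rows
#'   (default `TRUE`).
#' @return A raw (unoriented) [ratio_table()] keyed by the leading
#'   accession of each protein group, with attribute `filter_report`,
#'   a named integer vector (`reverse`, `contaminant`, `only_site`).
#' @export
read_protein_groups <- function(path,
                                ratio_pattern = paste0("^", .pg_ratio_stem),
                                filter_only_site = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!.pg_id_col %in% names(df))
    stopf("not a proteinGroups table: missing '%s' column", .pg_id_col)
  ratio_cols <- grep(ratio_pattern, names(df), value = TRUE)
  if (length(ratio_cols) == 0L)
    stopf("no ratio columns matching pattern '%s' in header", ratio_pattern)

  flagged <- function(col) {
    if (!col %in% names(df)) rep(FALSE, nrow(df))
    else df[[col]] %in% c("+", "TRUE", "true", "1")
  }
  rev_f  <- flagged(.pg_rev_col)
  con_f  <- flagged(.pg_con_col) & !rev_f
  site_f <- flagged(.pg_site_col) & !rev_f & !con_f & filter_only_site
  report <- c(reverse = sum(rev_f), contaminant = sum(con_f),
              only_site = sum(site_f))
  df <- df[!(rev_f | con_f | site_f), , drop = FALSE]

  ids <- vapply(strsplit(df[[.pg_id_col]], ";", fixed = TRUE),
                `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stopf("duplicate protein ids after taking leading accession: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gene <- if (.pg_gene_col %in% names(df)) df[[.pg_gene_col]]
          else rep(NA_character_, nrow(df))

  mat <- matrix(NA_real_, nrow(df), length(ratio_cols),
                dimnames = list(ids, sub(ratio_pattern, "", ratio_cols)))
  for (j in seq_along(ratio_cols)) {
    raw <- df[[ratio_cols[j]]]
    raw[raw %in% c("", "NaN", "nan", "NA", "0")] <- NA
    mat[, j] <- suppressWarnings(as.numeric(raw))
  }
  mat[!is.na(mat) & mat <= 0] <- NA  # any other non-positive export quirk

  tab <- ratio_table(mat, gene = gene, oriented = FALSE)
  attr(tab, "filter_report") <- report
  tab
}

#' Orient raw ratios into affected/control fold changes
#'
#' Applies the replicate label design: forward replicates pass through
#' unchanged, label-swapped replicates are inverted element-wise
#' (ratio -> 1/ratio), so that every column reads as affected genotype
#' over control. Missing stays missing. Orientation of an all-forward
#' design is the identity; applied twice with an all-swapped design it
#' returns the original table (reciprocal involution).
#'
#' @param table a raw [ratio_table()].
#' @param design a [label_design()] covering every replicate column.
#' @return An oriented [ratio_table()].
#' @export
orient_ratios <- function(table, design) {
  stopifnot(inherits(table, "ratio_table"), inherits(design, "label_design"))
  reps <- colnames(table$ratios)
  missing_reps <- setdiff(reps, design$replicate_id)
  if (length(missing_reps))
    stopf("design lacks replicates: %s", paste(missing_reps, collapse = ", "))
  unknown <- setdiff(design$replicate_id, reps)
  if (length(unknown))
    stopf("design names unknown replicate ids: %s",
          paste(unknown, collapse = ", "))
  ori <- design$orientation[match(reps, design$replicate_id)]
  mat <- table$ratios
  sw <- ori == "swapped"
  mat[, sw] <- 1 / mat[, sw, drop = FALSE]
  out <- ratio_table(mat, gene = table$gene, oriented = TRUE)
  attr(out, "filter_report") <- attr(table, "filter_report")
  out
}

#' Write / read the canonical oriented ratio TSV
#'
#' Plain tab-separated export: `protein_id`, `gene`, then one column
#' per replicate; missing cells are empty.
#'
#' @param table a [ratio_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(table, path) {
  stopifnot(inherits(table, "ratio_table"))
  df <- data.frame(protein_id = rownames(table$ratios),
                   gene = table$gene,
                   table$ratios, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ratio_table
#' @param oriented whether the file holds oriented ratios (default `TRUE`).
#' @export
read_ratio_table <- function(path, oriented = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("protein_id", "gene") %in% names(df)))
    stopf("not a ratio table: expected 'protein_id' and 'gene' columns")
  mat <- as.matrix(df[, setdiff(names(df), c("protein_id", "gene")),
                      drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df$protein_id
  ratio_table(mat, gene = df$gene, oriented = oriented)
}
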