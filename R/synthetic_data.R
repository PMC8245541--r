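#' Configuration for a simulated BONLAC experiment
#'
#' Defines the generative model used by [simulate_experiment()]. Each
#' protein gets a latent log10 abundance and a true fold change
#' (affected/control); each replicate measurement adds independent
#' multiplicative log-normal noise, split equally (in variance) between
#' the two isotope channels so that per-channel detectability can react
#' to the realized channel intensity. The affected genotype's channel is
#' additionally scaled by `global_synthesis_scale`, emulating a global
#' suppression of de novo synthesis; this scaling lowers detectability
#' of the affected channel but is absent from emitted ratios, as ratio
#' normalization removes global shifts. A cell is missing when either
#' channel falls below the logistic detection curve — missingness is
#' therefore not-at-random, coupled to genotype and abundance.
#'
#' Defaults emulate the young-cohort study conditions: ~2500 proteins
#' over 5 biological replicates with alternating label swaps, ~20%
#' global synthesis suppression in the affected genotype, a minority of
#' dysregulated proteins, and dropout tuned so that roughly 70% of
#' proteins reach majority detection.
#'
#' @param n_proteins,n_replicates counts.
#' @param frac_up,frac_down fractions of proteins with increased /
#'   decreased synthesis; `frac_up + frac_down <= 1`.
#' @param effect_fc_up,effect_fc_down true fold changes planted in the
#'   up / down classes; must bracket 1.
#' @param noise_sd_log2 sd of multiplicative replicate noise on log2
#'   ratios.
#' @param base_abundance_log10_mean,base_abundance_log10_sd latent
#'   per-protein log10 abundance distribution.
#' @param global_synthesis_scale multiplier in (0, 1] on the affected
#'   genotype's channel intensity.
#' @param dropout_midpoint log10 abundance at which per-channel
#'   detection probability is 50%; `NA` disables dropout entirely.
#' @param dropout_slope steepness of the logistic detection curve
#'   (per log10 unit).
#' @param swap_pattern character vector (`"forward"`/`"swapped"`), one
#'   per replicate; default alternates starting forward.
#' @param seed integer seed; same config + seed gives byte-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2500L,
                       n_replicates = 5L,
                       frac_up = 0.04,
                       frac_down = 0.06,
                       effect_fc_up = 1.6,
                       effect_fc_down = 0.625,
                       noise_sd_log2 = 0.25,
                       base_abundance_log10_mean = 6,
                       base_abundance_log10_sd = 1,
                       global_synthesis_scale = 0.8,
                       dropout_midpoint = 5,
                       dropout_slope = 2,
                       swap_pattern = NULL,
                       seed = 1L) {
  n_proteins   <- check_count(n_proteins, "n_proteins")
  n_replicates <- check_count(n_replicates, "n_replicates")
  frac_up   <- check_number(frac_up, "frac_up", 0, 1)
  frac_down <- check_number(frac_down, "frac_down", 0, 1)
  if (frac_up + frac_down > 1)
    stopf("frac_up + frac_down must not exceed 1")
  effect_fc_up   <- check_number(effect_fc_up, "effect_fc_up")
  effect_fc_down <- check_number(effect_fc_down, "effect_fc_down")
  if (!(effect_fc_down < 1 && 1 < effect_fc_up))
    stopf("need effect_fc_down < 1 < effect_fc_up")
  if (effect_fc_down <= 0) stopf("'effect_fc_down' must be positive")
  noise_sd_log2 <- check_number(noise_sd_log2, "noise_sd_log2", 0)
  base_abundance_log10_mean <-
    check_number(base_abundance_log10_mean, "base_abundance_log10_mean")
  base_abundance_log10_sd <-
    check_number(base_abundance_log10_sd, "base_abundance_log10_sd", 0)
  global_synthesis_scale <-
    check_number(global_synthesis_scale, "global_synthesis_scale")
  if (global_synthesis_scale <= 0 || global_synthesis_scale > 1)
    stopf("'global_synthesis_scale' must be in (0, 1]")
  dropout_midpoint <- check_number(dropout_midpoint, "dropout_midpoint",
                                   allow_na = TRUE)
  dropout_slope <- check_number(dropout_slope, "dropout_slope", 0)
  if (is.null(swap_pattern))
    swap_pattern <- rep_len(c("forward", "swapped"), n_replicates)
  swap_pattern <- as.character(swap_pattern)
  if (!all(swap_pattern %in% c("forward", "swapped")))
    stopf("'swap_pattern' entries must be 'forward' or 'swapped'")
  if (length(swap_pattern) != n_replicates)
    stopf("'swap_pattern' must have one entry per replicate")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(
    n_proteins = n_proteins, n_replicates = n_replicates,
    frac_up = frac_up, frac_down = frac_down,
    effect_fc_up = effect_fc_up, effect_fc_down = effect_fc_down,
    noise_sd_log2 = noise_sd_log2,
    base_abundance_log10_mean = base_abundance_log10_mean,
    base_abundance_log10_sd = base_abundance_log10_sd,
    global_synthesis_scale = global_synthesis_scale,
    dropout_midpoint = dropout_midpoint, dropout_slope = dropout_slope,
    swap_pattern = swap_pattern, seed = seed), class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path document whose keys mirror the [sim_config()] arguments.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(sim_config, lst)
}

#' Simulate a BONLAC experiment with known ground truth
#'
#' Draws per-protein classes and latent abundances, then per-cell
#' channel intensities, dropout and ratio noise under the model in
#' [sim_config()]. The emitted table is *raw*: each replicate's H/M
#' ratio follows its label-swap flag, so the orientation step of the
#' ingest path ([orient_ratios()]) is exercised downstream. All
#' randomness comes from one stream seeded from the config, with a
#' fixed protein-order draw sequence, so identical configs give
#' byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{table}{raw [ratio_table()] (`NA` = dropped out).}
#'     \item{truth}{`data.frame` with `protein_id`,
#'       `class` (`"up"`/`"down"`/`"null"`) and `true_fc`.}
#'     \item{design}{the matching [label_design()].}
#'   }
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_proteins; r <- config$n_replicates
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  class <- rep("null", n)
  dys <- sample.int(n, n_up + n_down)
  class[dys[seq_len(n_up)]] <- "up"
  if (n_down > 0) class[dys[n_up + seq_len(n_down)]] <- "down"
  true_fc <- ifelse(class == "up", config$effect_fc_up,
                    ifelse(class == "down", config$effect_fc_down, 1))

  ids <- sprintf("P%05d", seq_len(n))
  abund <- stats::rnorm(n, config$base_abundance_log10_mean,
                        config$base_abundance_log10_sd)

  # per-channel log2 noise; difference has sd = noise_sd_log2
  ch_sd <- config$noise_sd_log2 / sqrt(2)
  e_ctl <- matrix(stats::rnorm(n * r, 0, ch_sd), n, r)
  e_aff <- matrix(stats::rnorm(n * r, 0, ch_sd), n, r)

  log10_2 <- log10(2)
  a_ctl <- abund + e_ctl * log10_2
  a_aff <- abund + log10(true_fc) + log10(config$global_synthesis_scale) +
    e_aff * log10_2

  if (is.na(config$dropout_midpoint)) {
    present <- matrix(TRUE, n, r)
  } else {
    p_ctl <- stats::plogis(config$dropout_slope *
                             (a_ctl - config$dropout_midpoint))
    p_aff <- stats::plogis(config$dropout_slope *
                             (a_aff - config$dropout_midpoint))
    u_ctl <- matrix(stats::runif(n * r), n, r)
    u_aff <- matrix(stats::runif(n * r), n, r)
    present <- (u_ctl < p_ctl) & (u_aff < p_aff)
  }

  oriented <- true_fc * 2^(e_aff - e_ctl)   # global scale normalized away
  raw <- oriented
  sw <- config$swap_pattern == "swapped"
  raw[, sw] <- 1 / raw[, sw, drop = FALSE]
  raw[!present] <- NA_real_
  dimnames(raw) <- list(ids, sprintf("rep%d", seq_len(r)))

  tab <- ratio_table(raw, gene = sprintf("Gene%d", seq_len(n)),
                     oriented = FALSE)
  truth <- data.frame(protein_id = ids, class = class, true_fc = true_fc,
                      stringsAsFactors = FALSE)
  design <- label_design(colnames(raw), config$swap_pattern)
  list(table = tab, truth = truth, design = design)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a western-blot densitometry table
#'
#' Generates band and lane total-protein densities for wild-type and
#' transgenic lanes of one blot such that, after the in-lane
#' normalization of [normalize_blot()], the transgenic group mean
#' converges to `true_ratio` as `noise_sd` goes to 0. Lane totals vary
#' moderately between lanes so the normalization is actually exercised;
#' band/total for a lane is exactly group mean + Gaussian noise, which
#' makes the downstream two-sample t test follow the closed-form
#' noncentral-t power.
#'
#' @param n_wt,n_tg lanes per group (each >= 2).
#' @param true_ratio transgenic/wild-type ratio of normalized density.
#' @param noise_sd sd of the per-lane normalized density.
#' @param seed integer seed.
#' @param blot_id label stored in the `blot` column.
#' @return A `data.frame`: `lane_id`, `group` (`"WT"`/`"TG"`), `band`,
#'   `total`, `blot`.
#' @export
simulate_blot <- function(n_wt, n_tg, true_ratio, noise_sd, seed = 1L,
                          blot_id = "blot1") {
  n_wt <- check_count(n_wt, "n_wt", min = 2L)
  n_tg <- check_count(n_tg, "n_tg", min = 2L)
  true_ratio <- check_number(true_ratio, "true_ratio")
  if (true_ratio <= 0) stopf("'true_ratio' must be positive")
  if (length(noise_sd) != 1L || !is.finite(noise_sd) || noise_sd < 0)
    stopf("'noise_sd' must be a single non-negative number")
  seed <- check_count(seed, "seed", min = 0L)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_wt + n_tg
  group <- c(rep("WT", n_wt), rep("TG", n_tg))
  mu <- ifelse(group == "WT", 1, true_ratio)
  rel <- mu + stats::rnorm(n, 0, noise_sd)        # band/total per lane
  total <- 100 * exp(stats::rnorm(n, 0, 0.05))    # lane loading variation
  if (any(rel <= 0))
    stopf("noise_sd too large: produced non-positive band density")
  data.frame(lane_id = sprintf("lane%02d", seq_len(n)),
             group = group, band = rel * total, total = total,
             blot = blot_id, stringsAsFactors = FALSE)
}

#' Write a ratio table as a MaxQuant-style proteinGroups fixture
#'
#' Serializes a [ratio_table()] into the tab-separated proteinGroups
#' dialect consumed by [read_protein_groups()], optionally sprinkling
#' in decoy (`REV__`) and contaminant (`CON__`) rows that the reader is
#' expected to filter. Round-tripping a raw table through this writer,
#' the reader and [orient_ratios()] reproduces the oriented table
#' exactly.
#'
#' @param table a non-empty [ratio_table()].
#' @param path output file.
#' @param n_contaminants,n_reverse number of artifact rows to add.
#' @return `path`, invisibly.
#' @export
write_maxquant_fixture <- function(table, path, n_contaminants = 0L,
                                   n_reverse = 0L) {
  stopifnot(inherits(table, "ratio_table"))
  if (nrow(table$ratios) == 0L)
    stopf("refusing to write an empty proteinGroups fixture")
  n_contaminants <- check_count(n_contaminants, "n_contaminants", min = 0L)
  n_reverse <- check_count(n_reverse, "n_reverse", min = 0L)

  # %.17g round-trips IEEE doubles exactly through as.numeric()
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  mat <- apply(table$ratios, 2, fmt)
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1)
  df <- data.frame(
    `Protein IDs` = rownames(table$ratios),
    `Gene names` = ifelse(is.na(table$gene), "", table$gene),
    Reverse = "", `Potential contaminant` = "",
    `Only identified by site` = "",
    mat, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:5)] <- paste0(.pg_ratio_stem, colnames(table$ratios))

  art_row <- function(id, flag_col) {
    r <- df[1, , drop = FALSE]
    r[["Protein IDs"]] <- id
    r[["Gene names"]] <- ""
    r[, -(1:5)] <- "0.9"   # plausible filler ratios; filtered anyway
    r[[flag_col]] <- "+"
    r
  }
  if (n_reverse > 0)
    for (i in seq_len(n_reverse))
      df <- rbind(df, art_row(sprintf("REV__Q%05d", i), .pg_rev_col))
  if (n_contaminants > 0)
    for (i in seq_len(n_contaminants))
      df <- rbind(df, art_row(sprintf("CON__Q%05d", i), .pg_con_col))

  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
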