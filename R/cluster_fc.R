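#' Build a mean-normalized log fold-change matrix across cohorts
#'
#' Restricts to the proteins quantified (majority rule) in every
#' cohort, takes each cohort's mean oriented ratio per protein, log
#' transforms (base 2 by default) and centers, yielding the
#' heatmap-ready matrix clustered by [average_linkage_tree()]. With
#' `values = "replicates"`, individual replicate ratios form the
#' columns instead of cohort means; replicate cells missing for a
#' majority-detected protein are filled with that protein's cohort mean
#' so the matrix is complete.
#'
#' @param cohorts named list. For `values = "cohort_mean"` (default), a
#'   list of `screen_calls` data frames ([run_screen()]), whose
#'   `mean_ratio` already averages the detected replicates with the
#'   screen's mean type. For `values = "replicates"`, a list of
#'   oriented [ratio_table()]s.
#' @param values `"cohort_mean"` or `"replicates"`.
#' @param log_base base of the log transform (default 2).
#' @param center `"protein"` (row centering, default), `"cohort"`
#'   (column centering) or `"none"`.
#' @param window optional length-2 ratio window, e.g. `c(0.85, 1.15)`:
#'   proteins whose cohort mean ratios all fall inside are annotated as
#'   within-window (attribute `in_window`), an annotation, not a filter.
#' @return A numeric matrix (rows = proteins, columns = cohorts or
#'   replicates) with attributes `log_base`, `center`, and optionally
#'   `in_window`.
#' @export
build_fc_matrix <- function(cohorts,
                            values = c("cohort_mean", "replicates"),
                            log_base = 2,
                            center = c("protein", "cohort", "none"),
                            window = NULL) {
  values <- match.arg(values)
  center <- match.arg(center)
  log_base <- check_number(log_base, "log_base")
  if (log_base <= 0 || log_base == 1) stopf("'log_base' must be > 0, != 1")
  if (!is.list(cohorts) || length(cohorts) < 2L)
    stopf("need at least 2 cohorts")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))

  if (values == "cohort_mean") {
    calls <- lapply(cohorts, function(x) {
      stopifnot(is.data.frame(x), all(c("protein_id", "mean_ratio",
                                        "class") %in% names(x)))
      x
    })
    kept <- lapply(calls, function(x)
      x$protein_id[x$class != "insufficient"])
    ids <- sort(Reduce(intersect, kept))
    if (length(ids) == 0L)
      stopf("cohort overlap is empty: no protein majority-detected in all cohorts")
    means <- vapply(calls, function(x)
      x$mean_ratio[match(ids, x$protein_id)], numeric(length(ids)))
    if (length(ids) == 1L) means <- matrix(means, nrow = 1)
    dimnames(means) <- list(ids, names(cohorts))
    mat <- log(means, base = log_base)
  } else {
    tabs <- cohorts
    ok <- vapply(tabs, function(t)
      inherits(t, "ratio_table") && t$oriented, logical(1))
    if (!all(ok)) stopf("'cohorts' must be oriented ratio_table objects")
    kept <- lapply(tabs, function(t) {
      det <- rowSums(!is.na(t$ratios))
      rownames(t$ratios)[det >= majority_min(ncol(t$ratios))]
    })
    ids <- sort(Reduce(intersect, kept))
    if (length(ids) == 0L)
      stopf("cohort overlap is empty: no protein majority-detected in all cohorts")
    cols <- lapply(names(tabs), function(nm) {
      r <- tabs[[nm]]$ratios[ids, , drop = FALSE]
      fill <- rowMeans(r, na.rm = TRUE)      # cohort mean imputation
      for (j in seq_len(ncol(r))) r[is.na(r[, j]), j] <- fill[is.na(r[, j])]
      colnames(r) <- paste(nm, colnames(r), sep = ".")
      r
    })
    means <- vapply(names(tabs), function(nm) {
      r <- tabs[[nm]]$ratios[ids, , drop = FALSE]
      rowMeans(r, na.rm = TRUE)
    }, numeric(length(ids)))
    if (length(ids) == 1L) means <- matrix(means, nrow = 1,
                                           dimnames = list(ids, names(tabs)))
    mat <- log(do.call(cbind, cols), base = log_base)
  }

  if (center == "protein") mat <- mat - rowMeans(mat)
  if (center == "cohort") mat <- sweep(mat, 2, colMeans(mat))
  attr(mat, "log_base") <- log_base
  attr(mat, "center") <- center
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < 1, window[2] > 1)
    if (values == "replicates") {
      mr <- means
    } else {
      mr <- vapply(calls, function(x)
        x$mean_ratio[match(ids, x$protein_id)], numeric(length(ids)))
      if (length(ids) == 1L) mr <- matrix(mr, nrow = 1)
    }
    attr(mat, "in_window") <-
      apply(mr >= window[1] & mr <= window[2], 1, all)
  }
  mat
}

#' Agglomerative average-linkage clustering (UPGMA update)
#'
#' Unweighted average linkage on Euclidean row distances: at each step
#' the two clusters with the smallest mean pairwise cross distance are
#' merged, and distances to the new cluster are the size-weighted
#' Lance-Williams average, which keeps them equal to the arithmetic
#' mean over all cross-cluster leaf pairs. When two candidate merges
#' tie exactly, the pair whose smallest original row indices are
#' lexicographically least is merged, making the tree deterministic
#' across platforms. Average linkage is inversion-free, so merge
#' heights are non-decreasing.
#'
#' @param mat numeric matrix with >= 2 rows and finite values (e.g.
#'   from [build_fc_matrix()]).
#' @return An object of class `c("bonlac_tree", "hclust")` with the
#'   standard `merge`, `height`, `order`, `labels` components, usable
#'   with [stats::cutree()], [plot()] and [ape::as.phylo()].
#' @export
average_linkage_tree <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (!is.numeric(mat) || nrow(mat) < 2L)
    stopf("'mat' must be a numeric matrix with >= 2 rows")
  if (any(!is.finite(mat))) stopf("'mat' contains non-finite values")
  n <- nrow(mat)
  labels <- rownames(mat) %||% as.character(seq_len(n))

  d <- as.matrix(stats::dist(mat, method = "euclidean"))
  diag(d) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  minleaf <- seq_len(n)          # smallest original index per cluster
  node <- -seq_len(n)            # hclust coding: negative = leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    # rows/cols of retired clusters are already Inf
    m <- min(d)
    hit <- which(d == m, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest leaf indices
    key <- cbind(pmin(minleaf[hit[, 1]], minleaf[hit[, 2]]),
                 pmax(minleaf[hit[, 1]], minleaf[hit[, 2]]))
    pick <- order(key[, 1], key[, 2])[1]
    i <- hit[pick, 1]; j <- hit[pick, 2]

    a <- node[i]; b <- node[j]
    # canonical row: leaf before internal; leaves by ascending index
    merge[step, ] <- if (xor(a < 0, b < 0)) {
      if (a < 0) c(a, b) else c(b, a)
    } else if (a < 0) c(max(a, b), min(a, b)) else c(min(a, b), max(a, b))
    height[step] <- m

    # Lance-Williams UPGMA update into slot i
    k <- which(active); k <- k[k != i & k != j]
    d[i, k] <- d[k, i] <-
      (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    node[i] <- step
    active[j] <- FALSE
    d[j, ] <- d[, j] <- Inf
  }

  tree <- structure(
    list(merge = merge, height = height, order = .leaf_order(merge, n),
         labels = labels, method = "average",
         dist.method = "euclidean",
         call = match.call()),
    class = c("bonlac_tree", "hclust"))
  tree
}

# left-to-right leaf traversal of an hclust merge matrix
.leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

#' Cut a cluster tree into k groups
#'
#' Removes the k-1 highest merges (for an inversion-free tree this is
#' the standard height cut) and labels the resulting groups 1..k in
#' order of their first leaf.
#'
#' @param tree a tree from [average_linkage_tree()] (or any `hclust`).
#' @param k number of groups, between 1 and the number of leaves.
#' @return Named integer vector of group memberships, one per leaf.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$height) + 1L
  k <- check_count(k, "k")
  if (k > n) stopf("'k' must be between 1 and the number of leaves (%d)", n)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  # merges are height-sorted, so dropping the k-1 highest = keeping
  # the first n-k
  keep <- seq_len(n - k)
  members <- vector("list", n - 1L)
  for (s in keep) {
    pair <- tree$merge[s, ]
    reps <- vapply(pair, function(nd)
      if (nd < 0) -nd else find(members[[nd]]), integer(1))
    root <- min(reps)
    parent[reps] <- root
    members[[s]] <- root
  }
  # members[] of a kept merge may later be absorbed; find() resolves it
  grp_raw <- vapply(seq_len(n), function(i) find(i), integer(1))
  first_seen <- unique(grp_raw)
  grp <- match(grp_raw, first_seen)
  names(grp) <- tree$labels
  grp
}

#' Export a cluster tree as Newick
#'
#' Branch lengths are derived from the merge heights (each edge spans
#' the height difference between child and parent nodes).
#'
#' @param tree a tree from [average_linkage_tree()].
#' @param path output file; if `NULL`, the Newick string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
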