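# Independent oracles and small generators shared across tests.

# Brute-force average-linkage agglomeration: at every step recompute the
# mean pairwise Euclidean distance between every pair of current
# clusters directly from the original distance matrix, merge the
# minimum (ties: lexicographically smallest pair of smallest member
# indices). Returns hclust-style merge/height for comparison.
upgma_oracle <- function(mat) {
  n <- nrow(mat)
  D <- as.matrix(stats::dist(mat, method = "euclidean"))
  clusters <- as.list(seq_len(n))
  node <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    bestd <- Inf; best <- NULL; bestkey <- c(Inf, Inf)
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      dij <- mean(D[clusters[[i]], clusters[[j]]])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      better <- dij < bestd ||
        (dij == bestd && (key[1] < bestkey[1] ||
                            (key[1] == bestkey[1] && key[2] < bestkey[2])))
      if (better) { bestd <- dij; best <- c(i, j); bestkey <- key }
    }
    i <- best[1]; j <- best[2]
    a <- node[i]; b <- node[j]
    merge[step, ] <- if (xor(a < 0, b < 0)) {
      if (a < 0) c(a, b) else c(b, a)
    } else if (a < 0) c(max(a, b), min(a, b)) else c(min(a, b), max(a, b))
    height[step] <- bestd
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    node[i] <- step
    clusters[[j]] <- NULL
    node <- node[-j]
  }
  list(merge = merge, height = height)
}

# random oriented ratio table with missing cells, for property tests
random_ratio_table <- function(n_proteins, n_replicates, miss_prob = 0.2,
                               sd_log2 = 0.5) {
  mat <- matrix(2^stats::rnorm(n_proteins * n_replicates, 0, sd_log2),
                n_proteins, n_replicates,
                dimnames = list(sprintf("P%04d", seq_len(n_proteins)),
                                sprintf("rep%d", seq_len(n_replicates))))
  mat[stats::runif(length(mat)) < miss_prob] <- NA
  # keep at least one present value per protein so the table is valid
  for (i in which(rowSums(!is.na(mat)) == 0)) mat[i, 1] <- 1
  ratio_table(mat, oriented = TRUE)
}

# screen truth agreement for one simulated experiment
sim_agreement <- function(cfg) {
  sim <- simulate_experiment(cfg)
  calls <- run_screen(orient_ratios(sim$table, sim$design))
  truth <- sim$truth[match(calls$protein_id, sim$truth$protein_id), ]
  detected <- calls$class != "insufficient"
  map <- c(up = "up", down = "down", null = "unchanged")
  mean(calls$class[detected] == map[truth$class[detected]])
}
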