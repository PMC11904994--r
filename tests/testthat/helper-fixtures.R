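# Shared fixtures: small synthetic objects and independent brute-force
# oracles used across test files.

toy_spots <- function(x, y, type, sample_id = NULL) {
  df <- data.frame(spot_id = sprintf("SP%03d", seq_along(x)), x = x, y = y,
                   cell_type = type, stringsAsFactors = FALSE)
  if (!is.null(sample_id)) df$sample_id <- sample_id
  df
}

# O(n^2) nearest-type distance, self-exclusion by row index
oracle_nearest <- function(spots, source_type, target_type) {
  src <- which(spots$cell_type == source_type)
  tgt <- which(spots$cell_type == target_type)
  vapply(src, function(i) {
    cand <- setdiff(tgt, i)
    min(sqrt((spots$x[cand] - spots$x[i])^2 + (spots$y[cand] - spots$y[i])^2))
  }, numeric(1))
}

# brute-force pairwise AUC with half-credit ties
oracle_auc <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# brute-force integrated ssGSEA running sum; positions ordered by
# decreasing expression with ties broken by gene id (matching the
# documented walk order), ranks averaged for ties
oracle_ssgsea <- function(x, ids, set, alpha) {
  G <- length(x)
  ord <- order(-x, ids)
  r <- rank(-x, ties.method = "average")
  in_set <- ids %in% set
  k <- sum(in_set)
  w_all <- (G - r + 1)^alpha
  hit_tot <- sum(w_all[in_set])
  run <- 0; ph <- 0; pm <- 0
  for (pos in seq_len(G)) {
    g <- ord[pos]
    if (in_set[g]) ph <- ph + w_all[g] / hit_tot else pm <- pm + 1 / (G - k)
    run <- run + (ph - pm)
  }
  run
}

# a tiny matrix whose QC metrics are fully controlled: each cell's detected
# gene count and mito fraction are set by construction
make_qc_matrix <- function(n_genes_detected, mito_frac, total = 10000L,
                           n_genes = 6000L, n_mito = 10L) {
  genes <- c(sprintf("MT-%d", seq_len(n_mito)),
             sprintf("NU%04d", seq_len(n_genes - n_mito)))
  m <- matrix(0L, n_genes, length(n_genes_detected),
              dimnames = list(genes, sprintf("c%d", seq_along(n_genes_detected))))
  for (j in seq_along(n_genes_detected)) {
    mito_counts <- round(total * mito_frac[j])
    m[1L, j] <- mito_counts                      # one mito gene carries it all
    k <- n_genes_detected[j] - (mito_counts > 0)
    m[n_mito + seq_len(k), j] <- 1L
    # top up the first detected gene so the total and fraction are exact
    m[n_mito + 1L, j] <- m[n_mito + 1L, j] + (total - mito_counts - k)
  }
  m
}

small_sc_config <- function(seed = 3L, effect = 3,
                            pairs = data.frame(
                              ligand = c("LIGA", "LIGB", "LIGC"),
                              receptor = c("RECA", "RECB", "RECC"),
                              source = "fibroblast", target = "endothelial",
                              effect = 3)) {
  pairs$effect <- effect
  sc_sim_config(
    cells_per_type = c(endothelial = 100L, fibroblast = 100L, tumor = 100L),
    planted_lr_pairs = pairs, n_shared_genes = 200L, seed = seed)
}
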