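#' Differential expression between two sample groups
#'
#' Per-gene Welch two-sample t-test on log2 values. The linear-scale fold
#' change is `2^(mean_A - mean_B)`; a gene is flagged when its p-value
#' passes `p_threshold` and its fold change passes `fc_threshold` in the
#' requested direction (`"both"` accepts FC >= threshold or <= 1/threshold).
#' Genes with zero variance in both groups get p = 1 when the means are
#' equal (and p = 0 when they differ). An auxiliary Benjamini-Hochberg
#' column is emitted but takes no part in flagging.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param group_a,group_b column IDs (or indices) of the two groups, each of
#'   size >= 2.
#' @param p_threshold,fc_threshold flagging gates (fc_threshold >= 1).
#' @param direction `"both"`, `"up"` (up in A) or `"down"`.
#' @return A data.frame: `gene_id`, `mean_a`, `mean_b`, `log2_fc`,
#'   `fold_change`, `t`, `p_value`, `p_adj`, `flagged`.
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    p_threshold = 0.05, fc_threshold = 1.5,
                                    direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  expr <- as.matrix(expr)
  if (fc_threshold < 1) stop("'fc_threshold' must be >= 1", call. = FALSE)
  A <- expr[, group_a, drop = FALSE]
  B <- expr[, group_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 samples", call. = FALSE)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1L, var); vb <- apply(B, 1L, var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  zero_var <- se2 == 0
  p[zero_var] <- ifelse(ma[zero_var] == mb[zero_var], 1, 0)
  tstat[zero_var] <- ifelse(ma[zero_var] == mb[zero_var], 0,
                            sign(ma - mb)[zero_var] * Inf)
  fc <- 2^(ma - mb)
  fc_pass <- switch(direction,
                    both = fc >= fc_threshold | fc <= 1 / fc_threshold,
                    up = fc >= fc_threshold,
                    down = fc <= 1 / fc_threshold)
  data.frame(gene_id = rownames(expr), mean_a = ma, mean_b = mb,
             log2_fc = ma - mb, fold_change = fc, t = tstat, p_value = p,
             p_adj = p.adjust(p, "BH"),
             flagged = p < p_threshold & fc_pass,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Weighted Kolmogorov-Smirnov enrichment score of a gene set against a
# ranked list. `stats_sorted` must be sorted decreasing; `pos` are the
# (sorted) positions of the set genes in that ordering. Returns the signed
# maximum deviation of the running sum, evaluated at the piecewise-linear
# extrema (just after each hit and just before it).
calc_es <- function(stats_sorted, pos, weight = 1) {
  n <- length(stats_sorted)
  k <- length(pos)
  w <- abs(stats_sorted[pos])^weight
  W <- sum(w)
  if (W == 0) { w <- rep(1, k); W <- k }   # all-zero stats: unweighted steps
  hit_cum <- cumsum(w) / W
  miss_before <- (pos - seq_len(k)) / (n - k)
  top <- hit_cum - miss_before             # value just after each hit
  bottom <- c(0, hit_cum[-k]) - miss_before  # value just before each hit
  es_pos <- max(top)
  es_neg <- min(bottom)
  if (es_pos >= -es_neg) es_pos else es_neg
}

#' Preranked gene-set enrichment with a set-permutation null
#'
#' Classic weighted Kolmogorov-Smirnov enrichment: genes are ordered by
#' decreasing ranking statistic; in-set genes step up proportionally to
#' |stat|^1, out-of-set genes step down by 1/(n - k); the enrichment score
#' (ES) is the maximum deviation of the running sum. The null distribution
#' comes from random gene sets of equal size; NES = ES divided by the mean
#' |null ES| of matching sign, and p = (1 + #{same-sign null at least as
#' extreme}) / (1 + #{same-sign null}).
#'
#' @param stats named numeric vector of per-gene ranking statistics (e.g.
#'   signed t from [differential_expression()]).
#' @param gene_set character vector of gene IDs.
#' @param n_perm number of random sets (>= 100).
#' @param seed integer RNG seed for the permutations.
#' @param weight stat weight exponent (classic default 1).
#' @param min_overlap minimum set genes present in `stats`.
#' @return A list: `es`, `nes`, `p`, `leading_edge` (set genes up to the ES
#'   extremum), `n_perm`, `overlap`.
#' @export
gsea_preranked <- function(stats, gene_set, n_perm = 1000L, seed = 1L,
                           weight = 1, min_overlap = 3L) {
  if (is.null(names(stats))) stop("'stats' must be a named vector")
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  genes <- names(s)
  n <- length(s)
  in_set <- genes %in% unique(gene_set)
  k <- sum(in_set)
  if (k < min_overlap) {
    stop(sprintf("set overlap %d below minimum %d", k, min_overlap),
         call. = FALSE)
  }
  if (k >= n) stop("gene set covers the whole ranking", call. = FALSE)
  pos <- which(in_set)
  es <- calc_es(s, pos, weight)

  null_es <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      calc_es(s, sort(sample.int(n, k)), weight)
    }, numeric(1))
  })
  same <- null_es[sign(null_es) == sign(es)]
  if (length(same) == 0L) {
    warning("no same-sign permutations; p reported at the permutation floor")
    p <- 1 / (n_perm + 1)
    nes <- sign(es)
  } else {
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- es / mean(abs(same))
  }

  # leading edge: set genes up to (and including) the running-sum extremum
  w <- abs(s[pos])^weight; W <- sum(w)
  if (W == 0) { w <- rep(1, k); W <- k }
  hit_cum <- cumsum(w) / W
  miss_before <- (pos - seq_len(k)) / (n - k)
  if (es >= 0) {
    j <- which.max(hit_cum - miss_before)
    le <- genes[pos[seq_len(j)]]
  } else {
    j <- which.min(c(0, hit_cum[-k]) - miss_before)
    le <- genes[pos[pos >= pos[j]]]
  }
  list(es = es, nes = nes, p = p, leading_edge = le,
       n_perm = n_perm, overlap = k)
}

#' Over-representation of a gene set among hit genes
#'
#' One-sided hypergeometric tail test on the 2x2 table of hits x set
#' membership within the universe, with a Haldane-corrected odds ratio when
#' a margin cell is zero.
#'
#' @param hits character vector of selected genes (must lie in `universe`).
#' @param universe character vector of all tested genes.
#' @param gene_set character vector of set genes (intersected with the
#'   universe).
#' @return A list: `p` (P(overlap >= observed)), `odds_ratio`, `overlap`,
#'   `set_size`, `n_hits`, `universe_size`.
#' @export
overrepresentation <- function(hits, universe, gene_set) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe",
                                     call. = FALSE)
  set_in <- intersect(unique(gene_set), universe)
  if (length(set_in) == 0L) stop("gene set does not intersect the universe",
                                 call. = FALSE)
  N <- length(universe); K <- length(set_in); h <- length(hits)
  ov <- length(intersect(hits, set_in))
  p <- phyper(ov - 1, K, N - K, h, lower.tail = FALSE)
  a <- ov; b <- h - ov; cc <- K - ov; d <- N - K - h + ov
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  list(p = p, odds_ratio = (a * d) / (b * cc), overlap = ov, set_size = K,
       n_hits = h, universe_size = N)
}

#' Per-signature, per-group mean enrichment scores
#'
#' Scores every signature on every sample with [ssgsea_score()] and
#' averages within groups — the statistic behind signature-by-group
#' heatmaps (e.g. collagen and immune programs in sensitive versus
#' resistant tissue).
#'
#' @param expr genes x samples log2 expression matrix.
#' @param group per-sample group labels.
#' @param sets named list of gene sets.
#' @param alpha ssGSEA weight exponent.
#' @return A signatures x groups matrix of mean scores.
#' @export
signature_contrast_stats <- function(expr, group, sets, alpha = 0.25) {
  expr <- as.matrix(expr)
  group <- factor(group)
  stopifnot(ncol(expr) == length(group))
  scores <- ssgsea_score(expr, sets, alpha = alpha)  # samples x sets
  scores <- matrix(scores, ncol = length(sets),
                   dimnames = list(colnames(expr), names(sets)))
  out <- vapply(levels(group), function(g) {
    colMeans(scores[group == g, , drop = FALSE])
  }, numeric(length(sets)))
  matrix(out, nrow = length(sets),
         dimnames = list(names(sets), levels(group)))
}
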