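#' Single-sample gene-set enrichment (ssGSEA running sum)
#'
#' Rank-based single-sample enrichment in the ssGSEA family. Per sample,
#' genes are ranked by descending expression (average ranks for ties; ties
#' in the walk order are broken by gene ID so the score is invariant to the
#' row order of the matrix). Walking the ranked list, in-set genes
#' contribute steps `(G - rank + 1)^alpha` normalised by the in-set total,
#' out-of-set genes contribute `1 / (G - k)` where `G` is the number of
#' genes and `k` the in-set overlap; the score is the sum of the running
#' difference over all positions (the integrated statistic). The score
#' depends on within-sample ranks only, so it is invariant to any strictly
#' monotone per-sample transform.
#'
#' @param expr numeric genes x samples matrix with gene IDs as rownames.
#' @param gene_set character vector of gene IDs (one set), or a named list
#'   of such vectors to score several sets at once.
#' @param alpha rank weight exponent (>= 0); 0.25 by default.
#' @param min_overlap minimum number of set genes that must be present in
#'   the matrix.
#' @return For a single set, a named per-sample score vector; for a list of
#'   sets, a samples x sets matrix.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25, min_overlap = 2L) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("'expr' must have gene IDs as rownames")
  if (is.list(gene_set)) {
    res <- vapply(gene_set, function(s)
      ssgsea_score(expr, s, alpha = alpha, min_overlap = min_overlap),
      numeric(ncol(expr)))
    if (ncol(expr) == 1L) res <- matrix(res, nrow = 1L,
                                        dimnames = list(colnames(expr),
                                                        names(gene_set)))
    return(res)
  }
  genes <- rownames(expr)
  G <- length(genes)
  in_set <- genes %in% unique(gene_set)
  k <- sum(in_set)
  if (k < min_overlap) {
    stop(sprintf("gene set overlap with the matrix is %d (< %d required) for set of size %d",
                 k, min_overlap, length(unique(gene_set))), call. = FALSE)
  }
  if (k == G) stop("gene set covers the whole matrix; no out-of-set genes",
                   call. = FALSE)
  miss_step <- 1 / (G - k)
  apply(expr, 2L, function(x) {
    ord <- order(-x, genes)           # descending; ties broken by gene ID
    r <- rank(-x, ties.method = "average")
    w <- (G - r + 1)^alpha
    hit <- in_set[ord]
    hit_steps <- ifelse(hit, w[ord], 0)
    hit_cum <- cumsum(hit_steps) / sum(hit_steps)
    miss_cum <- cumsum(ifelse(hit, 0, miss_step))
    sum(hit_cum - miss_cum)
  })
}

#' Reference profiles for cell-fraction deconvolution
#'
#' @param profiles non-negative genes x cell-types matrix of mean expression
#'   on the linear scale; must include an `endothelial` column for
#'   [deconvolve_endothelial()].
#' @return A `reference_profiles` object.
#' @export
reference_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)) || is.null(colnames(profiles))) {
    stop("reference profiles need gene rownames and cell-type colnames")
  }
  if (any(profiles < 0)) stop("reference profiles must be non-negative")
  structure(list(profiles = profiles), class = "reference_profiles")
}

# Exact simplex-constrained least squares: min ||R f - b|| s.t. f >= 0,
# sum(f) <= 1. Small number of reference types: enumerate KKT support sets,
# solving each restricted problem with and without the sum constraint
# binding, and keep the feasible candidate with the smallest residual.
cls_fractions <- function(R, b) {
  k <- ncol(R)
  best <- rep(0, k)
  best_rss <- sum(b^2)                      # f = 0 candidate
  solve_ls <- function(A, y) {
    qr.coef(qr(A), y)
  }
  for (mask in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    RS <- R[, S, drop = FALSE]
    f <- tryCatch(solve_ls(RS, b), error = function(e) NULL)
    if (!is.null(f) && !anyNA(f) && all(f >= -1e-12) && sum(f) <= 1 + 1e-12) {
      full <- rep(0, k); full[S] <- pmax(f, 0)
      if (sum(full) > 1) full <- full / sum(full)
      rss <- sum((R %*% full - b)^2)
      if (rss < best_rss - 1e-12) { best <- full; best_rss <- rss }
    }
    # sum-to-one binding: KKT system [RS'RS 1; 1' 0]
    m <- length(S)
    K <- rbind(cbind(crossprod(RS), rep(1, m)), c(rep(1, m), 0))
    rhs <- c(crossprod(RS, b), 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (!is.null(sol)) {
      f <- sol[seq_len(m)]
      if (!anyNA(f) && all(f >= -1e-9)) {
        full <- rep(0, k); full[S] <- pmax(f, 0)
        full <- full / sum(full)
        rss <- sum((R %*% full - b)^2)
        if (rss < best_rss - 1e-12) { best <- full; best_rss <- rss }
      }
    }
  }
  best
}

#' Endothelial fraction by constrained least-squares deconvolution
#'
#' Estimates per-sample cell-type fractions by solving, on the linear
#' scale, `min || R f - b ||_2` subject to `f >= 0` and `sum(f) <= 1` over
#' the reference types, and returns the endothelial component. Bulk input
#' on the log2 scale is linearised as `2^x - 1` before the fit.
#'
#' @param expr genes x samples expression matrix.
#' @param ref a [reference_profiles()] object with an `endothelial` type.
#' @param is_log if `TRUE` (default) `expr` holds log2(x + 1) values.
#' @param min_overlap minimum shared genes between `expr` and `ref`.
#' @return Named per-sample endothelial fractions in \[0, 1\]. The full
#'   fraction matrix is attached as attribute `"fractions"`.
#' @export
deconvolve_endothelial <- function(expr, ref, is_log = TRUE,
                                   min_overlap = 10L) {
  stopifnot(inherits(ref, "reference_profiles"))
  expr <- as.matrix(expr)
  shared <- intersect(rownames(expr), rownames(ref$profiles))
  if (length(shared) < min_overlap) {
    stop(sprintf("only %d genes shared between matrix and reference (< %d required)",
                 length(shared), min_overlap), call. = FALSE)
  }
  if (!"endothelial" %in% colnames(ref$profiles)) {
    stop("reference profiles lack an 'endothelial' type", call. = FALSE)
  }
  R <- ref$profiles[shared, , drop = FALSE]
  if (qr(R)$rank < ncol(R)) {
    warning("rank-deficient reference profiles; pseudo-solution returned")
  }
  B <- expr[shared, , drop = FALSE]
  if (is_log) B <- pmax(2^B - 1, 0)
  fr <- apply(B, 2L, function(b) cls_fractions(R, b))
  fr <- matrix(fr, nrow = ncol(R),
               dimnames = list(colnames(R), colnames(expr)))
  out <- fr["endothelial", ]
  attr(out, "fractions") <- t(fr)
  out
}

#' Composite angiogenesis score from six features
#'
#' Averages the six angiogenesis-related features (four pathway enrichment
#' scores, the deconvolution endothelial fraction, and the marker-based
#' endothelial score). Because enrichment scores and fractions live on
#' different scales, each feature is z-scored across samples before
#' averaging by default; a feature constant across samples is dropped with
#' a warning when standardising.
#'
#' @param features samples x features numeric matrix or data.frame
#'   (normally 6 columns).
#' @param standardize z-score each feature across samples first.
#' @return Named per-sample composite score vector.
#' @export
angiogenesis_composite <- function(features, standardize = TRUE) {
  features <- as.matrix(features)
  if (!is.numeric(features) || anyNA(features)) {
    stop("'features' must be a complete numeric matrix")
  }
  if (standardize) {
    if (nrow(features) < 2L) {
      stop("standardization needs at least 2 samples")
    }
    sds <- apply(features, 2L, sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping constant feature(s): %s",
                      paste(colnames(features)[sds == 0], collapse = ", ")))
      features <- features[, sds > 0, drop = FALSE]
      if (ncol(features) == 0L) stop("all features constant; no score computable")
    }
    features <- scale(features)
  }
  rowMeans(features)
}

#' Correlation between two per-sample score vectors
#'
#' Pearson (t-approximation p-value) or Spearman rank correlation, as used
#' for score-versus-feature association.
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r` and `p`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  if (var(x) == 0 || var(y) == 0) {
    stop("correlation undefined: zero variance in input", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Per-sample feature panel with composite angiogenesis score
#'
#' Computes the six angiogenesis-related features per sample — enrichment
#' scores of the supplied angiogenesis pathway sets, the deconvolution
#' endothelial fraction, and the marker-based endothelial enrichment score —
#' together with collagen and immune program scores, and aggregates the six
#' into the composite angiogenesis score.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param angio_sets named list of angiogenesis pathway gene sets
#'   (typically four).
#' @param endothelial_set endothelial marker gene set.
#' @param collagen_set,immune_set program gene sets for the subtype scores.
#' @param ref a [reference_profiles()] object; `NULL` drops the
#'   deconvolution feature (the composite then averages the remaining
#'   features).
#' @param alpha ssGSEA weight exponent.
#' @param standardize passed to [angiogenesis_composite()].
#' @return A `feature_panel` data.frame: one row per sample with the
#'   individual features, `angiogenesis_score`, `collagen_score` and
#'   `immune_score`.
#' @export
build_feature_panel <- function(expr, angio_sets, endothelial_set,
                                collagen_set, immune_set, ref = NULL,
                                alpha = 0.25, standardize = TRUE) {
  expr <- as.matrix(expr)
  feats <- ssgsea_score(expr, angio_sets, alpha = alpha)
  feats <- cbind(feats,
                 endothelial_score = ssgsea_score(expr, endothelial_set,
                                                  alpha = alpha))
  if (!is.null(ref)) {
    feats <- cbind(feats,
                   endothelial_fraction = deconvolve_endothelial(expr, ref))
  }
  panel <- data.frame(
    sample_id = colnames(expr),
    feats,
    angiogenesis_score = angiogenesis_composite(feats,
                                                standardize = standardize),
    collagen_score = ssgsea_score(expr, collagen_set, alpha = alpha),
    immune_score = ssgsea_score(expr, immune_set, alpha = alpha),
    stringsAsFactors = FALSE, row.names = NULL)
  class(panel) <- c("feature_panel", "data.frame")
  panel
}
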