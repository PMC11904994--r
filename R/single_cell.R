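# Recompute per-cell QC metadata from the count matrix itself.
cell_qc_metrics <- function(counts, mito_prefix = "MT-") {
  counts <- as.matrix(counts)
  mito <- startsWith(rownames(counts), mito_prefix)
  tot <- colSums(counts)
  data.frame(
    mito_fraction = colSums(counts[mito, , drop = FALSE]) / pmax(tot, 1),
    n_detected_genes = colSums(counts > 0))
}

#' Quality-control filter for single-cell data
#'
#' Keeps a cell iff its mitochondrial fraction does not exceed `mito_max`
#' and its detected-gene count lies in `[min_genes, max_genes]`. Only
#' strict exceedance excludes: a cell at exactly the mitochondrial cap or
#' at either gene-count boundary is kept. Metrics are recomputed from the
#' counts (mitochondrial genes identified by `mito_prefix`), so the filter
#' is idempotent.
#'
#' @param sc an `sc_dataset` (from [gen_sc_dataset()] or [read_mtx_dir()]),
#'   or a bare genes x cells count matrix.
#' @param mito_max maximum mitochondrial fraction (default 0.10).
#' @param min_genes,max_genes detected-gene bounds (defaults 200 and 5000).
#' @param mito_prefix rowname prefix identifying mitochondrial genes.
#' @return A list: `data` (the filtered object, same shape as the input)
#'   and `report` (cells in/out and counts removed per criterion; a cell
#'   failing several criteria counts in each).
#' @export
qc_filter <- function(sc, mito_max = 0.10, min_genes = 200L,
                      max_genes = 5000L, mito_prefix = "MT-") {
  counts <- if (inherits(sc, "sc_dataset")) sc$counts else sc
  qc <- cell_qc_metrics(counts, mito_prefix)
  fail_mito <- qc$mito_fraction > mito_max
  fail_low <- qc$n_detected_genes < min_genes
  fail_high <- qc$n_detected_genes > max_genes
  keep <- !(fail_mito | fail_low | fail_high)
  report <- data.frame(n_input = ncol(counts), n_kept = sum(keep),
                       removed_mito = sum(fail_mito),
                       removed_low_genes = sum(fail_low),
                       removed_high_genes = sum(fail_high))
  if (!any(keep)) warning("QC removed every cell")
  if (inherits(sc, "sc_dataset")) {
    out <- sc
    out$counts <- counts[, keep, drop = FALSE]
    out$meta <- sc$meta[keep, , drop = FALSE]
    rownames(out$meta) <- NULL
  } else {
    out <- counts[, keep, drop = FALSE]
  }
  list(data = out, report = report)
}

#' Library-size normalization of counts
#'
#' Scales each cell to a common total and applies log1p, so cells with
#' proportional raw counts become identical.
#'
#' @param counts genes x cells count matrix.
#' @param target_total common post-scaling total per cell.
#' @return genes x cells matrix of log1p-normalized values.
#' @export
normalize_cells <- function(counts, target_total = 1e4) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  log1p(sweep(counts, 2L, tot, "/") * target_total)
}

#' Normalize, select variable genes and embed cells by PCA
#'
#' Library-size normalization and log1p, selection of the top `n_hvg`
#' genes by variance of the log values, per-gene centering, then PCA
#' keeping `n_pcs` components (reduced with a warning when cells are
#' scarce). Optional per-batch centering of the embedding stands in for
#' heavier batch integration.
#'
#' @param sc an `sc_dataset` or genes x cells count matrix (post-QC).
#' @param n_hvg number of highly-variable genes (capped at the gene count).
#' @param n_pcs number of principal components.
#' @param batch optional per-cell batch labels for embedding centering.
#' @param target_total see [normalize_cells()].
#' @return A list: `embedding` (cells x n_pcs), `var_explained`
#'   (per-component fraction), `hvg` (selected gene IDs), `norm` (the
#'   normalized matrix, all genes).
#' @export
normalize_reduce <- function(sc, n_hvg = 4000L, n_pcs = 40L, batch = NULL,
                             target_total = 1e4) {
  counts <- if (inherits(sc, "sc_dataset")) sc$counts else sc
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 cells to reduce", call. = FALSE)
  norm <- normalize_cells(counts, target_total)
  n_hvg <- min(n_hvg, nrow(norm))
  gene_var <- apply(norm, 1L, var)
  hvg <- names(sort(gene_var, decreasing = TRUE))[seq_len(n_hvg)]
  max_pcs <- min(ncol(norm) - 1L, n_hvg)
  if (n_pcs > max_pcs) {
    warning(sprintf("reducing n_pcs from %d to %d (limited by cells/genes)",
                    n_pcs, max_pcs))
    n_pcs <- max_pcs
  }
  pc <- prcomp(t(norm[hvg, , drop = FALSE]), center = TRUE, scale. = FALSE)
  emb <- pc$x[, seq_len(n_pcs), drop = FALSE]
  if (!is.null(batch)) {
    stopifnot(length(batch) == ncol(norm))
    for (b in unique(batch)) {
      idx <- batch == b
      emb[idx, ] <- scale(emb[idx, , drop = FALSE], center = TRUE,
                          scale = FALSE)
    }
  }
  rownames(emb) <- colnames(norm)
  list(embedding = emb,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       hvg = hvg, norm = norm)
}

#' Cluster cells and annotate clusters by marker expression
#'
#' Graph-based community detection (Louvain on a shared kNN graph of the
#' embedding) or k-means with a fixed seed. Each cluster is labelled with
#' the cell type whose marker list has the highest mean z-scaled
#' expression in the cluster; ties break lexicographically with a warning.
#'
#' @param embedding cells x dims matrix (from [normalize_reduce()]).
#' @param norm genes x cells normalized expression matrix.
#' @param marker_map named list, cell type -> marker gene IDs. Types with
#'   no marker present in the matrix are skipped with a warning.
#' @param method `"louvain"` or `"kmeans"`.
#' @param k number of clusters; required for `"kmeans"`, ignored by
#'   `"louvain"` (`k = 1` short-circuits to a single cluster).
#' @param knn neighbourhood size of the graph.
#' @param seed integer RNG seed (clustering initialisation).
#' @return A list: `label` (per-cell type), `cluster` (per-cell cluster id).
#' @export
cluster_annotate <- function(embedding, norm, marker_map,
                             method = c("louvain", "kmeans"), k = NULL,
                             knn = 15L, seed = 1L) {
  method <- match.arg(method)
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  stopifnot(ncol(norm) == n)
  present <- vapply(marker_map, function(g) any(g %in% rownames(norm)),
                    logical(1))
  if (!all(present)) {
    warning(sprintf("no markers present for type(s): %s",
                    paste(names(marker_map)[!present], collapse = ", ")))
    marker_map <- marker_map[present]
  }
  if (length(marker_map) == 0L) stop("no annotatable types", call. = FALSE)

  cluster <- if (!is.null(k) && k == 1L) {
    rep(1L, n)
  } else if (method == "kmeans") {
    if (is.null(k)) stop("k-means clustering needs 'k'", call. = FALSE)
    local_seed(seed, kmeans(embedding, centers = k, nstart = 10L)$cluster)
  } else {
    knn <- min(knn, n - 1L)
    d <- as.matrix(dist(embedding))
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(d[i, ])[2:(knn + 1L)]
      cbind(i, nb)
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    local_seed(seed,
               as.integer(igraph::membership(igraph::cluster_louvain(g))))
  }

  # per-gene z-scale across cells, then cluster x type mean marker score
  marker_genes <- unique(unlist(marker_map))
  marker_genes <- intersect(marker_genes, rownames(norm))
  M <- norm[marker_genes, , drop = FALSE]
  sds <- apply(M, 1L, sd)
  sds[sds == 0] <- 1
  Z <- (M - rowMeans(M)) / sds
  types <- sort(names(marker_map))
  label_of <- character(max(cluster))
  for (cl in sort(unique(cluster))) {
    sc_mean <- vapply(types, function(ty) {
      g <- intersect(marker_map[[ty]], marker_genes)
      mean(Z[g, cluster == cl, drop = FALSE])
    }, numeric(1))
    topv <- max(sc_mean)
    top <- types[sc_mean == topv]
    if (length(top) > 1L) {
      warning(sprintf("marker-score tie in cluster %d: %s; choosing '%s'",
                      cl, paste(top, collapse = ", "), top[1L]))
    }
    label_of[cl] <- top[1L]
  }
  list(label = label_of[cluster], cluster = cluster)
}

#' Ligand-receptor interaction test by cell-type label permutation
#'
#' For every ordered cell-type pair (source, target) and every
#' ligand-receptor pair, the interaction score is the mean of the ligand's
#' mean expression in the source type and the receptor's mean in the
#' target type. Significance comes from permuting the cell-type labels:
#' p = (1 + #\{null score >= observed\}) / (1 + n_perm). A combination
#' whose ligand (receptor) is expressed in fewer than `min_expr_frac` of
#' the source (target) cells is floored to score 0, p = 1. Pairs whose
#' genes are absent from the matrix are skipped and listed in `skipped`.
#'
#' @param norm genes x cells normalized expression matrix.
#' @param label per-cell type labels (>= 2 types).
#' @param pairs data.frame with columns `ligand` and `receptor`.
#' @param n_perm number of label permutations.
#' @param seed integer RNG seed.
#' @param min_expr_frac expressed-fraction gate (default 0.10).
#' @param alpha significance threshold on p.
#' @return A list: `results` (one row per source/target/pair combination),
#'   `counts` (source x target matrix of significant-pair counts),
#'   `skipped` (pair rows with absent genes).
#' @export
lr_permutation_test <- function(norm, label, pairs, n_perm = 1000L,
                                seed = 1L, min_expr_frac = 0.10,
                                alpha = 0.05) {
  norm <- as.matrix(norm)
  stopifnot(ncol(norm) == length(label))
  n_perm <- check_count(n_perm, "n_perm")
  types <- sort(unique(as.character(label)))
  if (length(types) < 2L) stop("need >= 2 cell types", call. = FALSE)
  pairs <- as.data.frame(pairs)
  ok <- pairs$ligand %in% rownames(norm) & pairs$receptor %in% rownames(norm)
  skipped <- pairs[!ok, , drop = FALSE]
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no ligand-receptor pair has both genes in the matrix",
                              call. = FALSE)
  genes <- unique(c(pairs$ligand, pairs$receptor))
  E <- norm[genes, , drop = FALSE]
  # canonical cell order so results do not depend on input column order
  if (!is.null(colnames(E))) {
    ord <- order(colnames(E))
    E <- E[, ord, drop = FALSE]
    label <- label[ord]
  }

  type_f <- factor(label, levels = types)
  n_per <- as.integer(table(type_f))
  ind <- vapply(types, function(t) as.numeric(type_f == t),
                numeric(length(label)))
  type_means <- function(M_ind) (E %*% M_ind) %*% diag(1 / n_per)
  obs <- type_means(ind)                     # genes x types
  colnames(obs) <- types
  expr_frac <- ((E > 0) %*% ind) %*% diag(1 / n_per)
  colnames(expr_frac) <- types

  combos <- expand.grid(pair = seq_len(nrow(pairs)), source = types,
                        target = types, stringsAsFactors = FALSE)
  lig <- pairs$ligand[combos$pair]
  rec <- pairs$receptor[combos$pair]
  li <- match(lig, genes); ri <- match(rec, genes)
  si <- match(combos$source, types); ti <- match(combos$target, types)
  score <- 0.5 * (obs[cbind(li, si)] + obs[cbind(ri, ti)])
  gated <- expr_frac[cbind(li, si)] >= min_expr_frac &
    expr_frac[cbind(ri, ti)] >= min_expr_frac

  exceed <- integer(length(score))
  local_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(length(label))
      pm <- type_means(ind[perm, , drop = FALSE])
      null_score <- 0.5 * (pm[cbind(li, si)] + pm[cbind(ri, ti)])
      exceed <- exceed + (null_score >= score)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  score[!gated] <- 0
  p[!gated] <- 1

  results <- data.frame(source = combos$source, target = combos$target,
                        ligand = lig, receptor = rec, score = score,
                        p = p, significant = p < alpha,
                        stringsAsFactors = FALSE)
  counts <- matrix(0L, length(types), length(types),
                   dimnames = list(source = types, target = types))
  agg <- tapply(results$significant, list(results$source, results$target), sum)
  counts[rownames(agg), colnames(agg)] <- agg
  list(results = results, counts = counts, skipped = skipped)
}
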