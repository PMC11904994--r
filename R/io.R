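#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then gene IDs. Duplicate
#' genes within a set are removed with a warning; a line with no genes or
#' fewer than three fields is rejected with its line number.
#'
#' @param path file path.
#' @return Named list of unique gene-ID vectors, with per-set descriptions
#'   in attribute `"description"`; empty (with a warning) for an empty file.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning(sprintf("empty GMT file: %s", path))
    return(structure(list(), description = character()))
  }
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT line %d in %s: need name, description and >= 1 gene",
                   i, path), call. = FALSE)
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop(sprintf("empty gene set '%s' at line %d in %s", f[1L], i, path),
           call. = FALSE)
    }
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes in set '%s' (line %d) deduplicated",
                      f[1L], i))
      genes <- unique(genes)
    }
    sets[[f[1L]]] <- genes
    descs[f[1L]] <- f[2L]
  }
  structure(sets, description = descs)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of gene-ID vectors.
#' @param path output path.
#' @param description per-set descriptions (recycled).
#' @export
write_gmt <- function(sets, path, description = "") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-by-samples expression TSV
#'
#' First column holds gene IDs, header holds sample IDs, cells are numeric.
#' Non-numeric cells are rejected with their coordinates; duplicate gene
#' IDs are an error by default or collapsed by per-sample maximum.
#'
#' @param path file path.
#' @param dedup `"error"` or `"max"`.
#' @return Numeric genes x samples matrix.
#' @export
read_expression_tsv <- function(path, dedup = c("error", "max")) {
  dedup <- match.arg(dedup)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 2L) stop("expression TSV needs gene IDs plus >= 1 sample",
                          call. = FALSE)
  genes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at data row %d, column '%s' in %s",
                   v[bad], bad, names(vals)[j], path), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    if (dedup == "error") {
      stop(sprintf("duplicate gene ID '%s' in %s",
                   genes[duplicated(genes)][1L], path), call. = FALSE)
    }
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(idx) {
      apply(m[idx, , drop = FALSE], 2L, max)
    }))
  }
  m
}

#' Write a genes-by-samples expression TSV
#'
#' @param expr genes x samples matrix.
#' @param path output path.
#' @param id_column header name of the gene-ID column.
#' @export
write_expression_tsv <- function(expr, path, id_column = "gene_id") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MatrixMarket triplet directory
#'
#' Expects `matrix.mtx` (genes x cells, 1-based on disk), `features.tsv`
#' (gene IDs, first column) and `barcodes.tsv` (cell IDs); dimensions must
#' agree with the sidecar files.
#'
#' @param dir directory path.
#' @return An `sc_dataset`-shaped list with `counts` (dense integer matrix
#'   with dimnames) and `meta` (cell_id plus QC metrics recomputed from the
#'   counts).
#' @export
read_mtx_dir <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  bc <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feat, bc)) {
    if (!file.exists(f)) stop(sprintf("missing file: %s", f), call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE)[[1L]]
  cells <- read.delim(bc, header = FALSE, stringsAsFactors = FALSE)[[1L]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop(sprintf("MTX dimensions %dx%d disagree with %d features / %d barcodes",
                 nrow(m), ncol(m), length(genes), length(cells)),
         call. = FALSE)
  }
  dimnames(m) <- list(genes, cells)
  storage.mode(m) <- "integer"
  meta <- cbind(data.frame(cell_id = cells, stringsAsFactors = FALSE),
                cell_qc_metrics(m))
  structure(list(counts = m, meta = meta), class = "sc_dataset")
}

#' Write counts as a MatrixMarket triplet directory
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @export
write_mtx_dir <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a CSV with a provenance header
#'
#' Provenance (package version, seed, parameters) is written as `#`
#' comment lines above a standard CSV body.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param provenance named list of key-value pairs.
#' @export
write_csv_provenance <- function(df, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# angiocol %s", as.character(packageVersion("angiocol"))),
             con)
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k,
                       paste(format(provenance[[k]]), collapse = " ")), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written with a provenance header
#'
#' @param path file path.
#' @return A data.frame (comment lines skipped).
#' @export
read_csv_provenance <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Assemble and validate a pipeline configuration
#'
#' Collects the thresholds used across the pipeline, validates their
#' ranges, and records the seed that every stochastic stage consumes.
#'
#' @param seed integer seed recorded in every output's provenance header.
#' @param p_threshold,fc_threshold differential-expression gates
#'   (`fc_threshold` >= 1).
#' @param mito_max,min_genes,max_genes single-cell QC gates.
#' @param n_hvg,n_pcs reduction parameters.
#' @param n_perm permutation count for GSEA and the LR test.
#' @param alpha ssGSEA weight exponent.
#' @param out_dir output directory for [run_pipeline()].
#' @param ... further named entries (e.g. input paths) kept verbatim.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, p_threshold = 0.05, fc_threshold = 1.5,
                            mito_max = 0.10, min_genes = 200L,
                            max_genes = 5000L, n_hvg = 4000L, n_pcs = 40L,
                            n_perm = 1000L, alpha = 0.25,
                            out_dir = "angiocol_out", ...) {
  cfg <- list(seed = check_count(seed, "seed", min = 0L),
              p_threshold = check_number(p_threshold, "p_threshold", 0, 1),
              fc_threshold = check_number(fc_threshold, "fc_threshold"),
              mito_max = check_number(mito_max, "mito_max", 0, 1),
              min_genes = check_count(min_genes, "min_genes", min = 0L),
              max_genes = check_count(max_genes, "max_genes", min = 0L),
              n_hvg = check_count(n_hvg, "n_hvg"),
              n_pcs = check_count(n_pcs, "n_pcs"),
              n_perm = check_count(n_perm, "n_perm"),
              alpha = check_number(alpha, "alpha", min = 0),
              out_dir = out_dir, ...)
  if (cfg$fc_threshold < 1) stop_config("'fc_threshold' must be >= 1")
  if (cfg$max_genes < cfg$min_genes) stop_config("'max_genes' < 'min_genes'")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on files
#'
#' Executes the branches whose inputs are configured, writing every output
#' as a provenance-headed CSV under `config$out_dir`. Bulk branch
#' (`expr_tsv` + `sets_gmt`, optionally `ref_tsv`): feature panel ->
#' transcriptomic subtypes -> differential expression (armored & cold vs
#' rest) -> preranked GSEA per configured set. Cell branch (`sc_dir` +
#' `lr_pairs_csv` + `marker_gmt`): QC -> reduction -> annotation -> LR
#' permutation test. Spatial branch (`spots_csv`): per-sample
#' co-localization. Survival branch (`survival_csv`): KM curve + log-rank.
#' Reruns with the same configuration are byte-identical.
#'
#' The bulk gene-set GMT must contain sets named `COLLAGEN` and `IMMUNE`,
#' a set named `ENDOTHELIAL_MARKERS`, and at least one other set (treated
#' as the angiogenesis pathway signatures).
#'
#' @param config a [pipeline_config()] with input paths among the `...`
#'   entries: `expr_tsv`, `sets_gmt`, `ref_tsv`, `sc_dir`, `lr_pairs_csv`,
#'   `marker_gmt`, `spots_csv`, `survival_csv`.
#' @return Invisibly, the named list of written file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- config[c("seed", "p_threshold", "fc_threshold", "mito_max",
                   "min_genes", "max_genes", "n_hvg", "n_pcs", "n_perm",
                   "alpha")]
  written <- list()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_csv_provenance(df, path, prov)
    written[[name]] <<- path
  }

  if (!is.null(config$expr_tsv)) {
    if (is.null(config$sets_gmt)) {
      stop("bulk branch needs 'sets_gmt' alongside 'expr_tsv'", call. = FALSE)
    }
    expr <- read_expression_tsv(config$expr_tsv)
    sets <- read_gmt(config$sets_gmt)
    need <- c("COLLAGEN", "IMMUNE", "ENDOTHELIAL_MARKERS")
    if (!all(need %in% names(sets))) {
      stop(sprintf("bulk gene sets must include %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    }
    angio_sets <- sets[setdiff(names(sets), need)]
    if (length(angio_sets) == 0L) {
      stop("no angiogenesis pathway sets in the GMT", call. = FALSE)
    }
    ref <- if (!is.null(config$ref_tsv)) {
      reference_profiles(read_expression_tsv(config$ref_tsv))
    }
    panel <- build_feature_panel(expr, angio_sets,
                                 sets[["ENDOTHELIAL_MARKERS"]],
                                 sets[["COLLAGEN"]], sets[["IMMUNE"]],
                                 ref = ref, alpha = config$alpha)
    emit(panel, "feature_panel.csv")
    calls <- assign_transcriptomic_subtype(panel$collagen_score,
                                           panel$immune_score,
                                           collagen_cut = config$collagen_cut,
                                           immune_cut = config$immune_cut,
                                           sample_id = panel$sample_id)
    emit(calls, "subtypes.csv")
    ac <- calls$sample_id[calls$subtype == "armored_cold"]
    rest <- calls$sample_id[calls$subtype != "armored_cold"]
    if (length(ac) >= 2L && length(rest) >= 2L) {
      deg <- differential_expression(expr, ac, rest,
                                     p_threshold = config$p_threshold,
                                     fc_threshold = config$fc_threshold)
      emit(deg, "deg.csv")
      stats <- setNames(deg$t, deg$gene_id)
      gsea <- do.call(rbind, lapply(names(angio_sets), function(nm) {
        g <- gsea_preranked(stats, angio_sets[[nm]], n_perm = config$n_perm,
                            seed = config$seed)
        data.frame(set = nm, es = g$es, nes = g$nes, p = g$p,
                   leading_edge_size = length(g$leading_edge),
                   stringsAsFactors = FALSE)
      }))
      emit(gsea, "gsea.csv")
    }
  }

  if (!is.null(config$sc_dir)) {
    if (is.null(config$marker_gmt) || is.null(config$lr_pairs_csv)) {
      stop("cell branch needs 'marker_gmt' and 'lr_pairs_csv' alongside 'sc_dir'",
           call. = FALSE)
    }
    sc <- read_mtx_dir(config$sc_dir)
    qcd <- qc_filter(sc, mito_max = config$mito_max,
                     min_genes = config$min_genes,
                     max_genes = config$max_genes)
    emit(qcd$report, "sc_qc_report.csv")
    red <- normalize_reduce(qcd$data, n_hvg = config$n_hvg,
                            n_pcs = config$n_pcs)
    markers <- read_gmt(config$marker_gmt)
    ann <- cluster_annotate(red$embedding, red$norm, markers,
                            seed = config$seed)
    emit(data.frame(cell_id = colnames(red$norm), cluster = ann$cluster,
                    cell_type = ann$label, stringsAsFactors = FALSE),
         "sc_labels.csv")
    pairs <- read_csv_provenance(config$lr_pairs_csv)
    lr <- lr_permutation_test(red$norm, ann$label, pairs,
                              n_perm = config$n_perm, seed = config$seed)
    emit(lr$results, "lr_results.csv")
    cm <- as.data.frame(as.table(lr$counts), stringsAsFactors = FALSE)
    names(cm) <- c("source", "target", "n_significant")
    emit(cm, "lr_counts.csv")
  }

  if (!is.null(config$spots_csv)) {
    spots <- read_csv_provenance(config$spots_csv)
    emit(multi_sample_summary(spots), "spatial_summary.csv")
  }

  if (!is.null(config$survival_csv)) {
    surv <- read_csv_provenance(config$survival_csv)
    emit(km_estimate(surv), "km_curve.csv")
    lr_t <- logrank_test(surv)
    emit(data.frame(statistic = lr_t$statistic, df = lr_t$df, p = lr_t$p),
         "logrank.csv")
  }

  if (length(written) == 0L) {
    stop("configuration names no inputs; nothing to run", call. = FALSE)
  }
  invisible(written)
}
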