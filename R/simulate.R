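#' Configuration for a synthetic bulk expression cohort
#'
#' Describes a log2-scale bulk cohort carrying three planted
#' immuno-collagenic subtypes (quiescent, armored & cold, soft & hot). The
#' gene universe is partitioned into disjoint collagen-program,
#' immune-program, angiogenesis-program and background blocks. Armored &
#' cold samples receive a log2 shift on collagen-program genes; soft & hot
#' samples a shift on immune-program genes; the angiogenesis-program shift
#' is coupled to the per-sample collagen shift through `angio_coupling`, so
#' the collagen-angiogenesis correlation is a planted, tunable quantity.
#'
#' @param n_samples,n_genes cohort dimensions (genes >= sum of block sizes).
#' @param subtype_proportions length-3 numeric summing to 1, in the order
#'   quiescent, armored_cold, soft_hot.
#' @param collagen_effect log2 shift added to collagen-program genes in
#'   armored & cold samples.
#' @param immune_effect log2 shift added to immune-program genes in
#'   soft & hot samples.
#' @param angio_coupling coefficient linking the per-sample
#'   angiogenesis-program shift to the per-sample collagen shift.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param n_collagen,n_immune,n_angio program block sizes; `n_angio` must be
#'   divisible by 4 so the block can stand in for four angiogenesis pathway
#'   signatures.
#' @param seed integer RNG seed.
#' @return A `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_samples = 400L, n_genes = 1000L,
                            subtype_proportions = c(quiescent = 0.5,
                                                    armored_cold = 0.25,
                                                    soft_hot = 0.25),
                            collagen_effect = 2, immune_effect = 2,
                            angio_coupling = 1, noise_sd = 0.5,
                            n_collagen = 40L, n_immune = 40L, n_angio = 60L,
                            seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_genes <- check_count(n_genes, "n_genes")
  if (!is.numeric(subtype_proportions) || length(subtype_proportions) != 3L ||
      any(subtype_proportions < 0) ||
      abs(sum(subtype_proportions) - 1) > 1e-9) {
    stop_config("'subtype_proportions' must be 3 non-negative numbers summing to 1")
  }
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  n_collagen <- check_count(n_collagen, "n_collagen")
  n_immune <- check_count(n_immune, "n_immune")
  n_angio <- check_count(n_angio, "n_angio")
  if (n_angio %% 4L != 0L) stop_config("'n_angio' must be divisible by 4")
  if (n_genes < n_collagen + n_immune + n_angio + 10L) {
    stop_config("'n_genes' too small for the requested program blocks")
  }
  structure(list(
    n_samples = n_samples, n_genes = n_genes,
    subtype_proportions = setNames(as.numeric(subtype_proportions),
                                   c("quiescent", "armored_cold", "soft_hot")),
    collagen_effect = check_number(collagen_effect, "collagen_effect"),
    immune_effect = check_number(immune_effect, "immune_effect"),
    angio_coupling = check_number(angio_coupling, "angio_coupling"),
    noise_sd = noise_sd,
    n_collagen = n_collagen, n_immune = n_immune, n_angio = n_angio,
    seed = check_count(seed, "seed", min = 0L)
  ), class = "bulk_sim_config")
}

#' Generate a synthetic bulk cohort with planted subtypes
#'
#' Expression is drawn on the log2 scale: per-gene baselines uniform in
#' \[4, 10\], Gaussian noise, plus the planted program shifts. The
#' per-sample collagen activity is `collagen_effect` for armored & cold
#' samples plus a small continuous jitter (sd = `collagen_effect` / 5), and
#' the angiogenesis-program shift is `angio_coupling` times that activity,
#' so collagen and angiogenesis scores covary smoothly across the cohort.
#'
#' @param config a [bulk_sim_config()].
#' @return A list of class `bulk_cohort` with elements `expr` (genes x
#'   samples log2 matrix), `subtype` (factor of planted labels), `programs`
#'   (named list of gene-ID vectors: collagen, immune, angiogenesis,
#'   endothelial_markers, background), `angio_sets` (the angiogenesis block
#'   split into four pathway-sized gene sets), and `collagen_activity`
#'   (the planted per-sample collagen shift).
#' @export
gen_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "bulk_sim_config"))
  local_seed(config$seed, {
    ng <- config$n_genes
    ns <- config$n_samples
    gene_ids <- sprintf("GENE%04d", seq_len(ng))
    sample_ids <- sprintf("S%04d", seq_len(ns))
    i_col <- seq_len(config$n_collagen)
    i_imm <- config$n_collagen + seq_len(config$n_immune)
    i_ang <- config$n_collagen + config$n_immune + seq_len(config$n_angio)
    i_bg <- setdiff(seq_len(ng), c(i_col, i_imm, i_ang))

    subtype <- factor(
      sample(names(config$subtype_proportions), ns, replace = TRUE,
             prob = config$subtype_proportions),
      levels = names(config$subtype_proportions))

    baseline <- runif(ng, 4, 10)
    expr <- matrix(rnorm(ng * ns, sd = config$noise_sd), ng, ns) + baseline
    dimnames(expr) <- list(gene_ids, sample_ids)

    jitter_sd <- abs(config$collagen_effect) / 5
    collagen_activity <- config$collagen_effect * (subtype == "armored_cold") +
      if (jitter_sd > 0) rnorm(ns, 0, jitter_sd) else 0
    immune_shift <- config$immune_effect * (subtype == "soft_hot")
    angio_shift <- config$angio_coupling * collagen_activity

    expr[i_col, ] <- expr[i_col, ] + rep(collagen_activity, each = length(i_col))
    expr[i_imm, ] <- expr[i_imm, ] + rep(immune_shift, each = length(i_imm))
    expr[i_ang, ] <- expr[i_ang, ] + rep(angio_shift, each = length(i_ang))

    angio_genes <- gene_ids[i_ang]
    quarter <- length(angio_genes) / 4L
    angio_sets <- split(angio_genes, rep(seq_len(4L), each = quarter))
    names(angio_sets) <- sprintf("ANGIO_PATHWAY_%d", 1:4)

    structure(list(
      expr = expr,
      subtype = subtype,
      programs = list(collagen = gene_ids[i_col],
                      immune = gene_ids[i_imm],
                      angiogenesis = angio_genes,
                      endothelial_markers = angio_sets[[4L]],
                      background = gene_ids[i_bg]),
      angio_sets = angio_sets,
      collagen_activity = as.numeric(collagen_activity),
      baseline = setNames(baseline, gene_ids),
      config = config
    ), class = "bulk_cohort")
  })
}

#' Synthetic reference profiles for endothelial deconvolution
#'
#' Builds linear-scale mean profiles for three reference populations on
#' top of a per-gene baseline: endothelial (angiogenesis-program genes
#' elevated `boost`-fold), fibroblast (collagen-program genes elevated)
#' and an unmodified "other" population. With the baseline of the
#' generating cohort ([gen_bulk_cohort()]`$baseline`), the fitted
#' endothelial fraction of a sample grows monotonically with its planted
#' angiogenesis-program shift.
#'
#' @param programs the `programs` element of a `bulk_cohort`.
#' @param gene_ids gene universe (rows of the target expression matrix).
#' @param baseline per-gene log2 baseline (named or ordered as `gene_ids`);
#'   a flat baseline of 1 linear unit if omitted.
#' @param boost linear-scale fold elevation of the population's program.
#' @return A `reference_profiles` list with `profiles` (genes x types,
#'   linear scale) including an `endothelial` column.
#' @export
synthetic_reference_profiles <- function(programs, gene_ids, baseline = NULL,
                                         boost = 8) {
  lin <- if (is.null(baseline)) rep(1, length(gene_ids))
         else pmax(2^baseline - 1, 0)
  base <- matrix(lin, length(gene_ids), 3,
                 dimnames = list(gene_ids, c("endothelial", "fibroblast", "other")))
  i_ang <- gene_ids %in% programs$angiogenesis
  i_col <- gene_ids %in% programs$collagen
  base[i_ang, "endothelial"] <- base[i_ang, "endothelial"] * boost
  base[i_col, "fibroblast"] <- base[i_col, "fibroblast"] * boost
  reference_profiles(base)
}

#' Configuration for a synthetic single-cell dataset
#'
#' Cells of each type express a type-specific marker block plus a shared
#' housekeeping block, with negative-binomial counts. Mitochondrial genes
#' form a named `MT-` prefix block so the mitochondrial fraction is
#' computable from the matrix itself; each cell's target fraction is drawn
#' from its type's `mito_fraction_dist` entry. Planted ligand-receptor
#' pairs elevate the ligand gene only in the source type and the receptor
#' only in the target type.
#'
#' @param cells_per_type named integer vector, cell type -> cell count.
#' @param nb_mean,nb_dispersion negative-binomial mean and size for
#'   expressed blocks (markers are boosted by `marker_boost`).
#' @param mito_fraction_dist either a length-2 numeric `c(mean, sd)` applied
#'   to all types, or a named list of such vectors per type.
#' @param planted_lr_pairs `NULL` or a data.frame with columns `ligand`,
#'   `receptor`, `source`, `target`, `effect` (log2 elevation).
#' @param n_marker_genes,n_shared_genes,n_mito_genes block sizes.
#' @param marker_boost multiplicative elevation of a type's own markers.
#' @param background_mean NB mean for genes outside a cell's expressed blocks.
#' @param lr_background_mean NB mean of planted ligand/receptor genes outside
#'   their source/target type; the low default keeps them under a 10%
#'   expressed-fraction gate there.
#' @param n_batches number of batches cells are cycled through.
#' @param seed integer RNG seed.
#' @return An `sc_sim_config` list.
#' @export
sc_sim_config <- function(cells_per_type, nb_mean = 4, nb_dispersion = 2,
                          mito_fraction_dist = c(mean = 0.04, sd = 0.015),
                          planted_lr_pairs = NULL,
                          n_marker_genes = 25L, n_shared_genes = 400L,
                          n_mito_genes = 10L, marker_boost = 10,
                          background_mean = 0.3, lr_background_mean = 0.02,
                          n_batches = 2L, seed = 1L) {
  if (length(cells_per_type) == 0L || is.null(names(cells_per_type)) ||
      any(!nzchar(names(cells_per_type)))) {
    stop_config("'cells_per_type' must be a non-empty named vector")
  }
  if (any(cells_per_type < 0) || any(cells_per_type != round(cells_per_type))) {
    stop_config("'cells_per_type' entries must be non-negative integers")
  }
  nb_mean <- check_number(nb_mean, "nb_mean", min = 0)
  nb_dispersion <- check_number(nb_dispersion, "nb_dispersion")
  if (nb_dispersion <= 0) stop_config("'nb_dispersion' must be > 0")
  types <- names(cells_per_type)
  if (is.numeric(mito_fraction_dist)) {
    mito_fraction_dist <- setNames(
      rep(list(c(mean = unname(mito_fraction_dist[1]),
                 sd = unname(mito_fraction_dist[2]))), length(types)), types)
  }
  for (ty in types) {
    m <- mito_fraction_dist[[ty]]
    if (is.null(m) || m[1] < 0 || m[1] > 1) {
      stop_config("mito fraction mean for type '%s' must lie in [0, 1]", ty)
    }
  }
  if (!is.null(planted_lr_pairs)) {
    need <- c("ligand", "receptor", "source", "target", "effect")
    if (!is.data.frame(planted_lr_pairs) ||
        !all(need %in% names(planted_lr_pairs))) {
      stop_config("'planted_lr_pairs' needs columns %s",
                  paste(need, collapse = ", "))
    }
    bad <- setdiff(c(planted_lr_pairs$source, planted_lr_pairs$target), types)
    if (length(bad)) {
      stop_config("planted pair references unknown cell type '%s'", bad[1])
    }
  }
  structure(list(
    cells_per_type = setNames(as.integer(cells_per_type), types),
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    mito_fraction_dist = mito_fraction_dist,
    planted_lr_pairs = planted_lr_pairs,
    n_marker_genes = check_count(n_marker_genes, "n_marker_genes"),
    n_shared_genes = check_count(n_shared_genes, "n_shared_genes"),
    n_mito_genes = check_count(n_mito_genes, "n_mito_genes"),
    marker_boost = check_number(marker_boost, "marker_boost", min = 1),
    background_mean = check_number(background_mean, "background_mean", min = 0),
    lr_background_mean = check_number(lr_background_mean, "lr_background_mean",
                                      min = 0),
    n_batches = check_count(n_batches, "n_batches"),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "sc_sim_config")
}

#' Generate a synthetic annotated single-cell dataset
#'
#' @param config an [sc_sim_config()].
#' @return A list of class `sc_dataset` with `counts` (genes x cells integer
#'   matrix), `meta` (data.frame: cell_id, batch, true_type, mito_fraction,
#'   n_detected_genes), `marker_map` (type -> marker gene list, suitable for
#'   [cluster_annotate()]), and `lr_pairs` (the planted pair table).
#' @export
gen_sc_dataset <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  local_seed(config$seed, {
    types <- names(config$cells_per_type)
    n_cells <- sum(config$cells_per_type)
    if (n_cells == 0L) stop_config("no cells requested")
    cell_type <- rep(types, config$cells_per_type)

    marker_genes <- lapply(types, function(ty) {
      sprintf("%s-MK%02d", toupper(gsub("[^A-Za-z0-9]", "", ty)),
              seq_len(config$n_marker_genes))
    })
    names(marker_genes) <- types
    shared_genes <- sprintf("HK%04d", seq_len(config$n_shared_genes))
    mito_genes <- sprintf("MT-%d", seq_len(config$n_mito_genes))
    lr <- config$planted_lr_pairs
    lr_genes <- if (is.null(lr)) character() else
      unique(c(as.character(lr$ligand), as.character(lr$receptor)))
    gene_ids <- c(unlist(marker_genes, use.names = FALSE), shared_genes,
                  lr_genes, mito_genes)
    if (anyDuplicated(gene_ids)) stop_config("gene ID collision in simulation")
    ng <- length(gene_ids)

    # per-gene-per-cell NB mean
    mu <- matrix(config$background_mean, ng, n_cells,
                 dimnames = list(gene_ids, NULL))
    mu[shared_genes, ] <- config$nb_mean
    for (ty in types) {
      mu[marker_genes[[ty]], cell_type == ty] <-
        config$nb_mean * config$marker_boost
    }
    if (!is.null(lr)) {
      mu[lr_genes, ] <- config$lr_background_mean
      for (i in seq_len(nrow(lr))) {
        lg <- as.character(lr$ligand[i]); rg <- as.character(lr$receptor[i])
        eff <- 2^lr$effect[i]
        mu[lg, cell_type == lr$source[i]] <- config$nb_mean * eff
        mu[rg, cell_type == lr$target[i]] <- config$nb_mean * eff
      }
    }
    nonmito <- setdiff(gene_ids, mito_genes)
    counts <- matrix(0L, ng, n_cells, dimnames = list(gene_ids, NULL))
    counts[nonmito, ] <- matrix(
      rnbinom(length(nonmito) * n_cells, size = config$nb_dispersion,
              mu = mu[nonmito, ]), length(nonmito), n_cells)

    # mitochondrial counts hit a per-cell target fraction
    target_frac <- vapply(seq_len(n_cells), function(j) {
      d <- config$mito_fraction_dist[[cell_type[j]]]
      min(max(rnorm(1, d[1], d[2]), 0), 0.9)
    }, numeric(1))
    nonmito_tot <- colSums(counts)
    mito_tot <- round(target_frac / (1 - target_frac) * nonmito_tot)
    for (j in seq_len(n_cells)) {
      if (mito_tot[j] > 0) {
        counts[mito_genes, j] <- as.integer(
          rmultinom(1, mito_tot[j], rep(1, length(mito_genes))))
      }
    }

    cell_ids <- sprintf("CELL%05d", seq_len(n_cells))
    colnames(counts) <- cell_ids
    meta <- data.frame(
      cell_id = cell_ids,
      batch = sprintf("batch%d", (seq_len(n_cells) - 1L) %% config$n_batches + 1L),
      true_type = cell_type,
      mito_fraction = colSums(counts[mito_genes, , drop = FALSE]) /
        pmax(colSums(counts), 1),
      n_detected_genes = colSums(counts > 0),
      stringsAsFactors = FALSE)
    rownames(meta) <- NULL

    structure(list(counts = counts, meta = meta,
                   marker_map = lapply(marker_genes, head, 5L),
                   lr_pairs = lr, config = config),
              class = "sc_dataset")
  })
}

#' Configuration for a synthetic spatial sample
#'
#' @param n_fibro,n_endo,n_other spot counts for fibroblast, endothelial and
#'   a pooled "other" annotation.
#' @param field_size square field side length (array units).
#' @param coloc_sd sd of the endothelial displacement around a uniformly
#'   sampled fibroblast anchor; `Inf` places endothelial spots uniformly
#'   (no co-localization).
#' @param other_types labels the `n_other` spots are cycled through.
#' @param seed integer RNG seed.
#' @return A `spatial_sim_config` list.
#' @export
spatial_sim_config <- function(n_fibro = 50L, n_endo = 50L, n_other = 100L,
                               field_size = 100, coloc_sd = 2,
                               other_types = c("tumor", "immune"),
                               seed = 1L) {
  n_fibro <- check_count(n_fibro, "n_fibro", min = 0L)
  n_endo <- check_count(n_endo, "n_endo", min = 0L)
  n_other <- check_count(n_other, "n_other", min = 0L)
  field_size <- check_number(field_size, "field_size")
  if (field_size <= 0) stop_config("'field_size' must be > 0")
  if (!(is.numeric(coloc_sd) && length(coloc_sd) == 1L &&
        (is.infinite(coloc_sd) || coloc_sd > 0))) {
    stop_config("'coloc_sd' must be > 0 or Inf (uniform placement)")
  }
  structure(list(n_fibro = n_fibro, n_endo = n_endo, n_other = n_other,
                 field_size = field_size, coloc_sd = coloc_sd,
                 other_types = as.character(other_types),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "spatial_sim_config")
}

#' Generate a synthetic spatial spot table
#'
#' Fibroblast and other-type spots are uniform on the field; endothelial
#' spots are drawn Normal(anchor, coloc_sd^2) around uniformly chosen
#' fibroblast anchors and clipped to the field (uniform when
#' `coloc_sd = Inf` or no fibroblasts exist).
#'
#' @param config a [spatial_sim_config()].
#' @return A data.frame (`spot_id`, `x`, `y`, `cell_type`).
#' @export
gen_spatial_sample <- function(config) {
  stopifnot(inherits(config, "spatial_sim_config"))
  local_seed(config$seed, {
    fs <- config$field_size
    unif <- function(n) cbind(runif(n, 0, fs), runif(n, 0, fs))
    fib <- unif(config$n_fibro)
    oth <- unif(config$n_other)
    if (is.infinite(config$coloc_sd) || config$n_fibro == 0L) {
      endo <- unif(config$n_endo)
    } else {
      anchor <- fib[sample.int(config$n_fibro, config$n_endo, replace = TRUE),
                    , drop = FALSE]
      endo <- anchor + matrix(rnorm(2L * config$n_endo, 0, config$coloc_sd),
                              ncol = 2L)
      endo <- pmin(pmax(endo, 0), fs)
    }
    xy <- rbind(fib, endo, oth)
    labels <- c(rep("fibroblast", config$n_fibro),
                rep("endothelial", config$n_endo),
                if (config$n_other > 0L)
                  rep_len(config$other_types, config$n_other))
    data.frame(spot_id = sprintf("SPOT%05d", seq_len(nrow(xy))),
               x = xy[, 1], y = xy[, 2], cell_type = labels,
               stringsAsFactors = FALSE)
  })
}

#' Configuration for synthetic survival data
#'
#' @param n_per_group subjects per marker group.
#' @param hazard_low,hazard_high exponential event rates of the marker-low
#'   and marker-high groups.
#' @param censor_rate exponential censoring rate (0 = no censoring).
#' @param seed integer RNG seed.
#' @return A `surv_sim_config` list.
#' @export
surv_sim_config <- function(n_per_group = 50L, hazard_low = 0.05,
                            hazard_high = 0.2, censor_rate = 0.02,
                            seed = 1L) {
  hazard_low <- check_number(hazard_low, "hazard_low")
  hazard_high <- check_number(hazard_high, "hazard_high")
  if (hazard_low <= 0 || hazard_high <= 0) {
    stop_config("hazard rates must be > 0")
  }
  structure(list(n_per_group = check_count(n_per_group, "n_per_group"),
                 hazard_low = hazard_low, hazard_high = hazard_high,
                 censor_rate = check_number(censor_rate, "censor_rate", min = 0),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "surv_sim_config")
}

#' Generate synthetic survival records
#'
#' Event times are exponential with the group's hazard; censoring times are
#' independent exponential with `censor_rate`. Observed time is the minimum
#' and the event indicator is 1 iff the event occurred first.
#'
#' @param config a [surv_sim_config()].
#' @return A data.frame (`subject_id`, `time`, `event`, `group`) with
#'   `group` in `{"low", "high"}`.
#' @export
gen_survival <- function(config) {
  stopifnot(inherits(config, "surv_sim_config"))
  local_seed(config$seed, {
    n <- config$n_per_group
    group <- rep(c("low", "high"), each = n)
    ev_time <- c(rexp(n, config$hazard_low), rexp(n, config$hazard_high))
    cen_time <- if (config$censor_rate > 0) rexp(2L * n, config$censor_rate)
                else rep(Inf, 2L * n)
    data.frame(subject_id = sprintf("SUBJ%04d", seq_len(2L * n)),
               time = pmin(ev_time, cen_time),
               event = as.integer(ev_time <= cen_time),
               group = group, stringsAsFactors = FALSE)
  })
}
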