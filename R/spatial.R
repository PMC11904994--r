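#' Nearest-spot Euclidean distance from one cell type to another
#'
#' For every spot of `source_type`, the minimum Euclidean distance to any
#' spot of `target_type`. When source and target types coincide, the spot
#' itself is excluded, so duplicate coordinates give distance 0 to the
#' *other* spot, never to self.
#'
#' @param spots data.frame with columns `spot_id`, `x`, `y`, `cell_type`.
#' @param source_type,target_type cell-type labels.
#' @return Named (by `spot_id`) per-source-spot distance vector.
#' @export
nearest_type_distance <- function(spots, source_type, target_type) {
  stopifnot(all(c("spot_id", "x", "y", "cell_type") %in% names(spots)))
  if (any(!is.finite(spots$x)) || any(!is.finite(spots$y))) {
    stop("spot coordinates must be finite", call. = FALSE)
  }
  src <- which(spots$cell_type == source_type)
  tgt <- which(spots$cell_type == target_type)
  if (length(src) == 0L) stop(sprintf("no spots of source type '%s'",
                                      source_type), call. = FALSE)
  if (length(tgt) == 0L) stop(sprintf("no spots of target type '%s'",
                                      target_type), call. = FALSE)
  dx <- outer(spots$x[src], spots$x[tgt], "-")
  dy <- outer(spots$y[src], spots$y[tgt], "-")
  d2 <- dx * dx + dy * dy
  self <- outer(src, tgt, "==")
  d2[self] <- Inf
  if (any(rowSums(!self) == 0L)) {
    stop("a source spot has no non-self target spot", call. = FALSE)
  }
  setNames(sqrt(apply(d2, 1L, min)), spots$spot_id[src])
}

#' Mean pairwise distance variant of [nearest_type_distance()]
#'
#' @inheritParams nearest_type_distance
#' @return Named per-source-spot mean distance to all target spots
#'   (self excluded).
#' @export
mean_type_distance <- function(spots, source_type, target_type) {
  src <- which(spots$cell_type == source_type)
  tgt <- which(spots$cell_type == target_type)
  if (length(src) == 0L || length(tgt) == 0L) {
    stop("missing source or target type", call. = FALSE)
  }
  dx <- outer(spots$x[src], spots$x[tgt], "-")
  dy <- outer(spots$y[src], spots$y[tgt], "-")
  d <- sqrt(dx * dx + dy * dy)
  d[outer(src, tgt, "==")] <- NA
  setNames(rowMeans(d, na.rm = TRUE), spots$spot_id[src])
}

# Mann-Whitney with normal approximation and tie correction; complete ties
# return p = 1 (zero-variance degenerate case).
mw_test <- function(a, b) {
  if (length(unique(c(a, b))) == 1L) {
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Co-localization of a source cell type with a reference type
#'
#' Compares the nearest-spot distance from source spots to the reference
#' type against their distance to other types, the operational test of
#' "positioned closer to fibroblasts". Two modes: `"pooled"` contrasts
#' distance-to-reference with distance to the nearest spot of any other
#' type (source and reference excluded); `"per_type"` runs one comparison
#' per other type. Tests are two-sided Mann-Whitney with normal
#' approximation and tie correction; comparisons with fewer than 3
#' distances on either side are skipped with a warning.
#'
#' @param spots spot data.frame (see [nearest_type_distance()]).
#' @param source_type source cell type (default `"endothelial"`).
#' @param reference_type reference cell type (default `"fibroblast"`).
#' @param mode `"pooled"` or `"per_type"`.
#' @param distance `"nearest"` (default) or `"mean"` pairwise.
#' @return A data.frame with one row per comparison: `comparison`,
#'   `median_ref`, `median_other`, `U`, `p`, `ref_closer`.
#' @export
colocalization_test <- function(spots, source_type = "endothelial",
                                reference_type = "fibroblast",
                                mode = c("pooled", "per_type"),
                                distance = c("nearest", "mean")) {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  dist_fun <- if (distance == "nearest") nearest_type_distance
              else mean_type_distance
  d_ref <- dist_fun(spots, source_type, reference_type)
  other_types <- setdiff(unique(spots$cell_type),
                         c(source_type, reference_type))
  if (length(other_types) == 0L) {
    stop("no non-reference type present", call. = FALSE)
  }
  empty <- data.frame(comparison = character(), median_ref = numeric(),
                      median_other = numeric(), U = numeric(), p = numeric(),
                      ref_closer = logical(), stringsAsFactors = FALSE)
  one_row <- function(name, d_other) {
    if (length(d_ref) < 3L || length(d_other) < 3L) {
      warning(sprintf("comparison '%s' skipped: fewer than 3 distances", name))
      return(empty)
    }
    tst <- mw_test(d_ref, d_other)
    data.frame(comparison = name, median_ref = median(d_ref),
               median_other = median(d_other), U = tst$U, p = tst$p,
               ref_closer = median(d_ref) < median(d_other),
               stringsAsFactors = FALSE)
  }
  if (mode == "pooled") {
    pooled <- spots
    pooled$cell_type[pooled$cell_type %in% other_types] <- ".other"
    d_other <- nearest_type_distance(pooled, source_type, ".other")
    if (distance == "mean") d_other <- {
      mean_type_distance(pooled, source_type, ".other")
    }
    one_row("pooled_other", d_other)
  } else {
    do.call(rbind, lapply(other_types, function(ty) {
      one_row(ty, dist_fun(spots, source_type, ty))
    }))
  }
}

#' Per-sample co-localization summaries
#'
#' Runs [colocalization_test()] independently on each sample; distances are
#' never pooled across samples, since coordinates are not comparable across
#' arrays.
#'
#' @param samples a list of spot data.frames, or one data.frame with a
#'   `sample_id` column.
#' @param ... passed to [colocalization_test()].
#' @return A data.frame with one row per sample and comparison, plus a
#'   `sample_id` column; empty (zero-row) for empty input.
#' @export
multi_sample_summary <- function(samples, ...) {
  if (is.data.frame(samples)) {
    stopifnot("sample_id" %in% names(samples))
    samples <- split(samples, samples$sample_id)
  }
  if (length(samples) == 0L) {
    return(data.frame(sample_id = character(), comparison = character(),
                      median_ref = numeric(), median_other = numeric(),
                      U = numeric(), p = numeric(), ref_closer = logical(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(samples))) names(samples) <- as.character(seq_along(samples))
  out <- do.call(rbind, lapply(names(samples), function(id) {
    res <- colocalization_test(samples[[id]], ...)
    if (nrow(res) == 0L) return(NULL)
    cbind(sample_id = id, res, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) multi_sample_summary(list()) else out
}
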