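#' Immuno-collagenic subtype from histology scores
#'
#' Applies the pathology rule verbatim: soft & hot = TIIC score >= 3 and
#' fibrosis score 0-1; armored & cold = TIIC score <= 2 and fibrosis score
#' 2-3; quiescent = TIIC score <= 2 and fibrosis score 0-1. Any (TIIC,
#' fibrosis) combination not covered by the three rules (i.e. TIIC >= 3
#' with fibrosis 2-3) is `unclassified`.
#'
#' @param tiic_score integer vector, tumor-infiltrating immune cell score
#'   (>= 0).
#' @param fibrosis_score integer vector in 0..3.
#' @param sample_id optional sample identifiers.
#' @return A data.frame (`sample_id`, `subtype`, `basis = "histologic"`),
#'   `subtype` a factor with levels quiescent, armored_cold, soft_hot,
#'   unclassified.
#' @export
assign_histologic_subtype <- function(tiic_score, fibrosis_score,
                                      sample_id = NULL) {
  if (any(!is.finite(tiic_score)) || any(tiic_score < 0) ||
      any(tiic_score != round(tiic_score))) {
    stop("'tiic_score' must be non-negative integers", call. = FALSE)
  }
  if (any(!is.finite(fibrosis_score)) || any(fibrosis_score < 0) ||
      any(fibrosis_score > 3) || any(fibrosis_score != round(fibrosis_score))) {
    stop("'fibrosis_score' must be integers in 0..3", call. = FALSE)
  }
  stopifnot(length(tiic_score) == length(fibrosis_score))
  low_fib <- fibrosis_score <= 1
  high_fib <- fibrosis_score >= 2
  subtype <- rep("unclassified", length(tiic_score))
  subtype[tiic_score >= 3 & low_fib] <- "soft_hot"
  subtype[tiic_score <= 2 & high_fib] <- "armored_cold"
  subtype[tiic_score <= 2 & low_fib] <- "quiescent"
  if (is.null(sample_id)) sample_id <- sprintf("S%04d", seq_along(subtype))
  data.frame(sample_id = sample_id,
             subtype = factor(subtype, levels = c("quiescent", "armored_cold",
                                                  "soft_hot", "unclassified")),
             basis = "histologic", stringsAsFactors = FALSE)
}

#' Immuno-collagenic subtype from transcriptomic scores
#'
#' Samples at or above the immune cutpoint are soft & hot; among
#' immune-low samples those at or above the collagen cutpoint are armored &
#' cold and the rest quiescent. High-collagen/high-immune samples are rare
#' in practice and fold into soft & hot by default (`high_high =
#' "unclassified"` emits them separately). Cutpoints default to cohort
#' medians; exact thresholds are cohort conventions and should be supplied
#' when known (e.g. quantiles matched to expected subtype prevalence).
#'
#' @param collagen_score,immune_score per-sample scores.
#' @param collagen_cut,immune_cut numeric cutpoints; `NULL` uses the cohort
#'   median (needs n >= 4).
#' @param high_high what to call immune-high & collagen-high samples.
#' @param sample_id optional sample identifiers.
#' @return A data.frame (`sample_id`, `subtype`, `basis = "transcriptomic"`).
#' @export
assign_transcriptomic_subtype <- function(collagen_score, immune_score,
                                          collagen_cut = NULL,
                                          immune_cut = NULL,
                                          high_high = c("soft_hot",
                                                        "unclassified"),
                                          sample_id = NULL) {
  high_high <- match.arg(high_high)
  stopifnot(length(collagen_score) == length(immune_score))
  if (any(!is.finite(collagen_score)) || any(!is.finite(immune_score))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (is.null(collagen_cut) || is.null(immune_cut)) {
    if (length(collagen_score) < 4L) {
      stop("deriving median cutpoints needs at least 4 samples", call. = FALSE)
    }
    if (is.null(collagen_cut)) collagen_cut <- median(collagen_score)
    if (is.null(immune_cut)) immune_cut <- median(immune_score)
  }
  imm_hi <- immune_score >= immune_cut
  col_hi <- collagen_score >= collagen_cut
  subtype <- ifelse(imm_hi, "soft_hot",
                    ifelse(col_hi, "armored_cold", "quiescent"))
  if (high_high == "unclassified") subtype[imm_hi & col_hi] <- "unclassified"
  if (is.null(sample_id)) sample_id <- sprintf("S%04d", seq_along(subtype))
  data.frame(sample_id = sample_id,
             subtype = factor(subtype, levels = c("quiescent", "armored_cold",
                                                  "soft_hot", "unclassified")),
             basis = "transcriptomic", stringsAsFactors = FALSE)
}

#' Data-driven score cutpoint for subtype assignment
#'
#' Either the cohort median or the midpoint of the largest gap between
#' consecutive sorted scores within a central quantile window. The
#' largest-gap rule suits well-separated bimodal score distributions
#' (e.g. a strongly shifted program in a subset of samples), where a
#' fixed quantile would mislabel boundary samples whenever the realized
#' subtype prevalence drifts from its expectation.
#'
#' @param x per-sample scores (>= 4 finite values).
#' @param method `"median"` or `"largest_gap"`.
#' @param window quantile range searched for the gap (avoids tails).
#' @return A single numeric cutpoint.
#' @export
derive_cutpoint <- function(x, method = c("median", "largest_gap"),
                            window = c(0.15, 0.95)) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("need at least 4 finite values", call. = FALSE)
  if (method == "median") return(median(x))
  s <- sort(x)
  n <- length(s)
  lo <- max(1L, floor(window[1] * n))
  hi <- min(n - 1L, ceiling(window[2] * n))
  gaps <- s[(lo + 1L):(hi + 1L)] - s[lo:hi]
  i <- lo + which.max(gaps) - 1L
  (s[i] + s[i + 1L]) / 2
}

#' ROC curve and AUC for discriminating a class by a score
#'
#' AUC is the probability that a random positive outscores a random
#' negative, with ties counting one half — computed rank-equivalently over
#' all positive x negative pairs.
#'
#' @param score per-sample numeric values.
#' @param label logical (or 0/1) vector; `TRUE` = positive class.
#' @return A list with `auc` and `curve`, a data.frame of (FPR, TPR) points
#'   ordered from (0,0) to (1,1).
#' @export
roc_auc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(score >= t & label) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & !label) / n_neg, numeric(1))
  list(auc = auc,
       curve = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

# Dunn's pairwise z-tests on rank sums after a Kruskal-Wallis test,
# Holm-adjusted. Tie-corrected variance.
dunn_pairwise <- function(values, group) {
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  groups <- levels(group)
  mean_r <- tapply(r, group, mean)
  n_g <- tapply(r, group, length)
  combs <- utils::combn(groups, 2L)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    a <- combs[1L, i]; b <- combs[2L, i]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[i] <- (mean_r[[a]] - mean_r[[b]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  data.frame(group1 = combs[1L, ], group2 = combs[2L, ], z = z,
             p = p, p_adj = p.adjust(p, "holm"), stringsAsFactors = FALSE)
}

#' Omnibus group contrast with pairwise comparisons
#'
#' Compares a per-sample value across subtype groups: one-way ANOVA with
#' Tukey HSD pairwise comparisons, or Kruskal-Wallis with Dunn's pairwise
#' z-tests (Holm-adjusted). Degenerate data with zero between- and
#' within-group variance return statistic 0 and p = 1.
#'
#' @param values per-sample numeric vector.
#' @param group group labels (coerced to factor; empty levels dropped).
#' @param method `"anova"` or `"kruskal"`.
#' @return A list: `summary` (per-group n/mean/sd), `statistic`, `p`,
#'   `pairwise` (data.frame), `method`.
#' @export
group_contrast <- function(values, group, method = c("anova", "kruskal")) {
  method <- match.arg(method)
  group <- droplevels(factor(group))
  stopifnot(length(values) == length(group))
  n_g <- table(group)
  if (length(n_g) < 2L || any(n_g < 2L)) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  summ <- data.frame(group = names(n_g), n = as.integer(n_g),
                     mean = as.numeric(tapply(values, group, mean)),
                     sd = as.numeric(tapply(values, group, sd)),
                     stringsAsFactors = FALSE)
  if (var(values) == 0) {
    pw <- data.frame(group1 = character(), group2 = character(),
                     diff = numeric(), p_adj = numeric())
    return(list(summary = summ, statistic = 0, p = 1, pairwise = pw,
                method = method))
  }
  if (method == "anova") {
    fit <- aov(values ~ group)
    tab <- summary(fit)[[1L]]
    tk <- TukeyHSD(fit)$group
    pw <- data.frame(
      group1 = sub("-.*", "", rownames(tk)),
      group2 = sub(".*-", "", rownames(tk)),
      diff = tk[, "diff"], p_adj = tk[, "p adj"],
      stringsAsFactors = FALSE, row.names = NULL)
    list(summary = summ, statistic = tab[1L, "F value"],
         p = tab[1L, "Pr(>F)"], pairwise = pw, method = "anova")
  } else {
    kw <- kruskal.test(values, group)
    list(summary = summ, statistic = unname(kw$statistic),
         p = kw$p.value, pairwise = dunn_pairwise(values, group),
         method = "kruskal")
  }
}
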