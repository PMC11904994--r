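test_that("ssGSEA matches the brute-force running-sum oracle", {
  # the 5-gene single-sample instance, enumerated position by position
  x <- c(5, 4, 3, 2, 1)
  ids <- paste0("g", 1:5)
  m <- matrix(x, 5, 1, dimnames = list(ids, "s1"))
  expect_equal(ssgsea_score(m, c("g1", "g2"), alpha = 0.25),
               c(s1 = oracle_ssgsea(x, ids, c("g1", "g2"), 0.25)),
               tolerance = 1e-12)

  # random instances, several set sizes and alphas, including ties
  set.seed(42)
  for (i in 1:20) {
    G <- sample(10:60, 1)
    ids <- sprintf("G%03d", seq_len(G))
    x <- round(rnorm(G), 1)            # rounding induces rank ties
    set <- sample(ids, sample(2:(G - 2), 1))
    alpha <- sample(c(0, 0.25, 1), 1)
    m <- matrix(x, G, 1, dimnames = list(ids, "s"))
    expect_equal(unname(ssgsea_score(m, set, alpha = alpha)),
                 oracle_ssgsea(x, ids, set, alpha), tolerance = 1e-12)
  }
})

test_that("ssGSEA depends on ranks only and ignores gene order", {
  set.seed(1)
  m <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("G%02d", 1:50), paste0("s", 1:4)))
  set <- sample(rownames(m), 10)
  base <- ssgsea_score(m, set)
  expect_equal(ssgsea_score(exp(m), set), base, tolerance = 1e-12)
  expect_equal(ssgsea_score(m * 3 + 7, set), base, tolerance = 1e-12)
  perm <- sample(nrow(m))
  expect_equal(ssgsea_score(m[perm, ], set), base, tolerance = 1e-12)
})

test_that("a set holding the top gene outscores one holding the bottom gene", {
  set.seed(2)
  m <- matrix(rnorm(120), 30, 4, dimnames = list(sprintf("G%02d", 1:30), NULL))
  for (j in 1:4) {
    ord <- order(-m[, j])
    top <- rownames(m)[ord[1:2]]
    bottom <- rownames(m)[ord[29:30]]
    expect_gt(ssgsea_score(m[, j, drop = FALSE], top)[1],
              ssgsea_score(m[, j, drop = FALSE], bottom)[1])
  }
})

test_that("insufficient set overlap raises a named scoring error", {
  m <- matrix(1:20, 10, 2, dimnames = list(paste0("g", 1:10), NULL))
  expect_error(ssgsea_score(m, c("g1", "absent1", "absent2")), "overlap")
})

# dense grid search over the constrained simplex, coarse-to-fine
oracle_cls_grid <- function(R, b, step = 1e-3) {
  k <- ncol(R)
  G <- crossprod(R); h <- crossprod(R, b)
  rss <- function(f) as.numeric(t(f) %*% G %*% f - 2 * t(f) %*% h + sum(b^2))
  grid_around <- function(center, width, step) {
    axes <- lapply(seq_len(k), function(i) {
      seq(max(0, center[i] - width), min(1, center[i] + width), by = step)
    })
    names(axes) <- colnames(R)
    g <- as.matrix(expand.grid(axes))
    g <- g[rowSums(g) <= 1 + 1e-12, , drop = FALSE]
    vals <- apply(g, 1, rss)
    g[which.min(vals), ]
  }
  f <- grid_around(rep(0.5, k), 0.5, max(step, 0.02))
  if (step < 0.02) f <- grid_around(f, 0.02, step)
  f
}

test_that("deconvolution recovers exact and mixed reference columns", {
  set.seed(3)
  genes <- sprintf("G%02d", 1:30)
  R <- matrix(runif(90, 0.5, 5), 30, 3,
              dimnames = list(genes, c("endothelial", "fibroblast", "other")))
  ref <- reference_profiles(R)

  pure <- matrix(R[, "endothelial"], 30, 1, dimnames = list(genes, "s1"))
  expect_equal(as.numeric(deconvolve_endothelial(pure, ref, is_log = FALSE)), 1,
               tolerance = 1e-6)

  mix <- matrix(0.3 * R[, "endothelial"] + 0.7 * R[, "fibroblast"], 30, 1,
                dimnames = list(genes, "s1"))
  est <- as.numeric(deconvolve_endothelial(mix, ref, is_log = FALSE))
  expect_equal(est, 0.3, tolerance = 1e-4)
  grid <- oracle_cls_grid(R, mix[, 1], step = 1e-3)
  expect_lt(abs(est - grid[["endothelial"]]), 1e-3)

  zero <- matrix(0, 30, 1, dimnames = list(genes, "s1"))
  expect_equal(as.numeric(deconvolve_endothelial(zero, ref, is_log = FALSE)), 0)
})

test_that("deconvolution matches the grid-search oracle on noisy 3-type data", {
  set.seed(4)
  genes <- sprintf("G%02d", 1:25)
  R <- matrix(runif(75, 0.2, 4), 25, 3,
              dimnames = list(genes, c("endothelial", "fibroblast", "other")))
  ref <- reference_profiles(R)
  for (i in 1:5) {
    f_true <- c(runif(1, 0, 0.6), runif(1, 0, 0.3), runif(1, 0, 0.1))
    b <- as.numeric(R %*% f_true) + rnorm(25, sd = 0.05)
    m <- matrix(pmax(b, 0), 25, 1, dimnames = list(genes, "s"))
    est <- as.numeric(deconvolve_endothelial(m, ref, is_log = FALSE))
    expect_gte(est, 0); expect_lte(est, 1)
    grid <- oracle_cls_grid(R, m[, 1], step = 1e-3)
    expect_lt(abs(est - grid[["endothelial"]]), 1.5e-3)
  }
})

test_that("deconvolution validates overlap and reference shape", {
  genes <- paste0("g", 1:5)
  R <- matrix(1, 5, 2, dimnames = list(genes, c("endothelial", "other")))
  m <- matrix(1, 5, 1, dimnames = list(genes, "s"))
  expect_error(deconvolve_endothelial(m, reference_profiles(R),
                                      min_overlap = 10), "shared")
  expect_warning(deconvolve_endothelial(m, reference_profiles(R),
                                        is_log = FALSE, min_overlap = 2),
                 "rank-deficient")
})

test_that("composite score averages standardized features correctly", {
  f <- matrix(3.7, 1, 6)
  expect_equal(unname(angiogenesis_composite(f, standardize = FALSE)), 3.7)

  # hand-computed z-score-then-mean on a printed 3-sample table
  tab <- rbind(c(1, 10, 0.2), c(2, 20, 0.4), c(3, 60, 0.9))
  z <- apply(tab, 2, function(v) (v - mean(v)) / sd(v))
  expect_equal(unname(angiogenesis_composite(tab)), unname(rowMeans(z)))
  expect_equal(mean(angiogenesis_composite(tab)), 0, tolerance = 1e-12)

  expect_warning(out <- angiogenesis_composite(cbind(tab, 5)), "constant")
  expect_equal(unname(out), unname(rowMeans(z)))

  # permutation equivariance over samples
  set.seed(5)
  f6 <- matrix(rnorm(60), 10, 6)
  perm <- sample(10)
  expect_equal(angiogenesis_composite(f6)[perm],
               angiogenesis_composite(f6[perm, ]))
})

test_that("correlation matches the covariance formula and flags degeneracy", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(2.0, 3.1, 2.5, 6.3, 3.9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate(x, y)$r, r_hand, tolerance = 1e-12)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, max(rank(x)) + 1 - rank(x), "spearman")$r, -1)
  expect_error(correlate(rep(1, 5), y), "zero variance")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("feature panel carries six features and a recomputable composite", {
  bc <- gen_bulk_cohort(bulk_sim_config(n_samples = 50, n_genes = 300,
                                        seed = 17))
  ref <- synthetic_reference_profiles(bc$programs, rownames(bc$expr),
                                      bc$baseline)
  panel <- build_feature_panel(bc$expr, bc$angio_sets,
                               bc$programs$endothelial_markers,
                               bc$programs$collagen, bc$programs$immune,
                               ref = ref)
  feats <- c(names(bc$angio_sets), "endothelial_score", "endothelial_fraction")
  expect_true(all(feats %in% names(panel)))
  expect_true(all(panel$endothelial_fraction >= 0 &
                    panel$endothelial_fraction <= 1))
  recomputed <- angiogenesis_composite(as.matrix(panel[, feats]))
  expect_equal(panel$angiogenesis_score, unname(recomputed))
})
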