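test_that("histologic rule reproduces the pathology definitions exhaustively", {
  grid <- expand.grid(tiic = 0:5, fibrosis = 0:3)
  calls <- assign_histologic_subtype(grid$tiic, grid$fibrosis)
  expected <- with(grid, ifelse(
    tiic >= 3 & fibrosis <= 1, "soft_hot", ifelse(
      tiic <= 2 & fibrosis >= 2, "armored_cold", ifelse(
        tiic <= 2 & fibrosis <= 1, "quiescent", "unclassified"))))
  expect_equal(as.character(calls$subtype), expected)
  expect_equal(unique(calls$basis), "histologic")

  # the three quoted cases
  expect_equal(as.character(
    assign_histologic_subtype(3, 1)$subtype), "soft_hot")
  expect_equal(as.character(
    assign_histologic_subtype(2, 3)$subtype), "armored_cold")
  expect_equal(as.character(
    assign_histologic_subtype(4, 3)$subtype), "unclassified")

  expect_error(assign_histologic_subtype(1, 4), "0..3")
  expect_error(assign_histologic_subtype(-1, 1), "non-negative")
})

test_that("transcriptomic rule is forced at the extremes", {
  col <- c(9, 0, 1, 2, 3, 4)
  imm <- c(0, 0, 9, 8, 7, 6)
  calls <- assign_transcriptomic_subtype(col, imm, collagen_cut = 5,
                                         immune_cut = 5)
  expect_equal(as.character(calls$subtype[1]), "armored_cold")
  expect_equal(as.character(calls$subtype[2]), "quiescent")
  expect_equal(as.character(calls$subtype[3]), "soft_hot")
  # high-high folds into soft_hot by default, unclassified on request
  calls2 <- assign_transcriptomic_subtype(c(9, 9), c(9, 0), collagen_cut = 5,
                                          immune_cut = 5)
  expect_equal(as.character(calls2$subtype), c("soft_hot", "armored_cold"))
  calls3 <- assign_transcriptomic_subtype(c(9, 9), c(9, 0), collagen_cut = 5,
                                          immune_cut = 5,
                                          high_high = "unclassified")
  expect_equal(as.character(calls3$subtype[1]), "unclassified")

  expect_error(assign_transcriptomic_subtype(1:3, 1:3), "4 samples")
})

test_that("quantile-cut assignment is invariant to common monotone transforms", {
  set.seed(6)
  col <- rnorm(40); imm <- rnorm(40)
  assign_q <- function(cs, is) {
    assign_transcriptomic_subtype(cs, is,
                                  collagen_cut = quantile(cs, 0.75),
                                  immune_cut = quantile(is, 0.6))$subtype
  }
  base <- assign_q(col, imm)
  expect_equal(assign_q(exp(col), exp(imm)), base)
  expect_equal(assign_q(col * 10 + 3, imm * 10 + 3), base)
})

test_that("cutpoint derivation finds the between-cluster gap", {
  expect_equal(derive_cutpoint(c(1, 2, 3, 100)), 2.5)     # median default
  # two clear clusters: the largest-gap cut falls between them
  set.seed(44)
  x <- c(rnorm(30, 0), rnorm(10, 20))
  cut <- derive_cutpoint(x, "largest_gap")
  expect_true(cut > 5 && cut < 15)
  expect_equal(sum(x >= cut), 10L)
  expect_error(derive_cutpoint(c(1, 2, 3), "largest_gap"), "4 finite")
})

test_that("subtype recovery on a planted cohort exceeds 95%", {
  bc <- gen_bulk_cohort(bulk_sim_config(n_samples = 400, n_genes = 400,
                                        collagen_effect = 3, immune_effect = 3,
                                        angio_coupling = 1, noise_sd = 0.5,
                                        seed = 8))
  panel <- build_feature_panel(bc$expr, bc$angio_sets,
                               bc$programs$endothelial_markers,
                               bc$programs$collagen, bc$programs$immune)
  calls <- assign_transcriptomic_subtype(
    panel$collagen_score, panel$immune_score,
    collagen_cut = derive_cutpoint(panel$collagen_score, "largest_gap"),
    immune_cut = derive_cutpoint(panel$immune_score, "largest_gap"))
  expect_gte(mean(as.character(calls$subtype) == as.character(bc$subtype)),
             0.95)
  # the armored & cold group carries the highest composite angiogenesis score
  by_type <- tapply(panel$angiogenesis_score, bc$subtype, mean)
  expect_identical(names(which.max(by_type)), "armored_cold")
})

test_that("AUC equals the brute-force pairwise probability", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(T, T, F, F, F, T))$auc, 0.5)
  # 6-point toy set with a tie, enumerated over the 6 pairs
  s <- c(3, 5, 5, 7, 2, 5)
  l <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(s, l)$auc, oracle_auc(s, l))

  set.seed(7)
  for (n in c(10, 57, 200)) {
    s <- sample(round(rnorm(n), 1))
    l <- runif(n) < 0.4
    if (!any(l) || all(l)) l[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(s, l)$auc, oracle_auc(s, l))
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  s <- rnorm(80); l <- runif(80) < 0.5
  expect_equal(roc_auc(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("ROC curve runs from (0,0) to (1,1) monotonically", {
  set.seed(9)
  r <- roc_auc(rnorm(50), runif(50) < 0.3)
  expect_equal(r$curve[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("group contrasts handle degenerate and planted-shift data", {
  g <- rep(c("a", "b", "c"), each = 10)
  res0 <- group_contrast(rep(5, 30), g)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  set.seed(10)
  power <- vapply(1:60, function(i) {
    v <- rnorm(150)
    v[101:150] <- v[101:150] + 1      # +1 sd shift in the third group
    group_contrast(v, rep(c("q", "s", "ac"), each = 50))$p < 0.001
  }, logical(1))
  expect_gte(mean(power), 0.95)

  # ANOVA matches stats::oneway and Kruskal matches stats::kruskal.test
  set.seed(11)
  v <- rnorm(30); gf <- factor(g)
  res_a <- group_contrast(v, gf, "anova")
  expect_equal(res_a$p, summary(aov(v ~ gf))[[1]][1, "Pr(>F)"])
  res_k <- group_contrast(v, gf, "kruskal")
  expect_equal(res_k$p, kruskal.test(v, gf)$p.value)
  expect_equal(nrow(res_k$pairwise), 3)
  expect_true(all(res_k$pairwise$p_adj >= res_k$pairwise$p))
  expect_error(group_contrast(1:3, c("a", "a", "b")), "2 samples")
})

test_that("null ANOVA p-values across replicates are approximately uniform", {
  set.seed(12)
  ps <- vapply(1:300, function(i) {
    group_contrast(rnorm(45), rep(letters[1:3], each = 15))$p
  }, numeric(1))
  expect_lt(ks.test(ps, "punif")$statistic, 0.1)
})
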