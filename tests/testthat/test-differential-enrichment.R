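test_that("differential expression gates by p and fold change as stated", {
  set.seed(13)
  m <- matrix(rnorm(20 * 10, mean = 8, sd = 0.01), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  m["g01", ] <- 8                                 # identical in both groups
  m["g02", 1:5] <- 9; m["g02", 6:10] <- 8         # FC 2, near-zero variance
  m["g03", 1:5] <- 8 + log2(1.4); m["g03", 6:10] <- 8  # FC 1.4, tiny p
  deg <- differential_expression(m, 1:5, 6:10)
  expect_false(deg$flagged[deg$gene_id == "g01"])
  expect_equal(deg$p_value[deg$gene_id == "g01"], 1)
  expect_true(deg$flagged[deg$gene_id == "g02"])
  g3 <- deg[deg$gene_id == "g03", ]
  expect_lt(g3$p_value, 1e-6)
  expect_false(g3$flagged)                         # FC gate fails at 1.5
  expect_equal(g3$fold_change, 1.4, tolerance = 1e-12)

  # flag invariant holds on random data, and direction flags restrict it
  set.seed(14)
  r <- matrix(rnorm(500 * 12, 8, 1), 500, 12,
              dimnames = list(sprintf("r%03d", 1:500), NULL))
  d2 <- differential_expression(r, 1:6, 7:12)
  expect_equal(d2$flagged,
               d2$p_value < 0.05 & (d2$fold_change >= 1.5 |
                                      d2$fold_change <= 1 / 1.5))
  up <- differential_expression(r, 1:6, 7:12, direction = "up")
  expect_equal(up$flagged, up$p_value < 0.05 & up$fold_change >= 1.5)
  expect_error(differential_expression(r, 1, 2:12), "2 samples")
})

test_that("Welch t matches stats::t.test per gene", {
  set.seed(15)
  m <- matrix(rnorm(5 * 14, 8), 5, 14, dimnames = list(paste0("g", 1:5), NULL))
  deg <- differential_expression(m, 1:7, 8:14)
  for (i in 1:5) {
    tt <- t.test(m[i, 1:7], m[i, 8:14])
    expect_equal(deg$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(deg$t[i], unname(tt$statistic), tolerance = 1e-12)
  }
})

# brute-force weighted KS running sum over every position
oracle_es <- function(stats, set, weight = 1) {
  s <- sort(stats, decreasing = TRUE)
  inset <- names(s) %in% set
  k <- sum(inset); n <- length(s)
  w <- abs(s)^weight
  tot <- sum(w[inset])
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- run + if (inset[i]) w[i] / tot else -1 / (n - k)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

test_that("GSEA enrichment score matches hand enumeration", {
  stats <- setNames(c(3.2, 2.5, 1.9, 1.2, 0.4, -0.8, -1.7, -2.6),
                    paste0("g", 1:8))
  set <- c("g1", "g3", "g4")
  res <- gsea_preranked(stats, set, n_perm = 200, seed = 1)
  expect_equal(res$es, oracle_es(stats, set), tolerance = 1e-12)
  expect_gt(res$es, 0)
  expect_true(all(res$leading_edge %in% set))

  # a set of bottom-ranked genes scores negative with matching magnitude
  set_b <- c("g6", "g7", "g8")
  res_b <- gsea_preranked(stats, set_b, n_perm = 200, seed = 1)
  expect_equal(res_b$es, oracle_es(stats, set_b), tolerance = 1e-12)
  expect_lt(res_b$es, 0)
  expect_equal(sign(res_b$nes), sign(res_b$es))

  set.seed(16)
  for (i in 1:10) {
    st <- setNames(rnorm(40), sprintf("x%02d", 1:40))
    se <- sample(names(st), 8)
    expect_equal(gsea_preranked(st, se, n_perm = 100, seed = 2)$es,
                 oracle_es(st, se), tolerance = 1e-12)
  }
})

test_that("GSEA ES agrees with fgsea on the same ranking", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  st <- setNames(rnorm(100), sprintf("f%03d", 1:100))
  se <- sample(names(st), 15)
  ours <- gsea_preranked(st, se, n_perm = 100, seed = 1)$es
  fg <- suppressWarnings(
    fgsea::fgsea(list(s = se), st, nperm = 100, gseaParam = 1))
  expect_equal(ours, fg$ES, tolerance = 1e-6)
})

test_that("top-of-ranking sets reach the permutation floor", {
  set.seed(18)
  st <- setNames(sort(rnorm(300), decreasing = TRUE), sprintf("t%03d", 1:300))
  res <- gsea_preranked(st, names(st)[1:20], n_perm = 1000, seed = 3)
  expect_gt(res$es, 0)
  expect_lte(res$p, 0.01)                 # effectively at the add-one floor
  expect_gte(res$p, 1 / 1001)
  expect_equal(res$leading_edge, names(st)[1:20])
})

test_that("GSEA p-values are valid under random rankings", {
  set.seed(19)
  ps <- vapply(1:200, function(i) {
    st <- setNames(rnorm(120), sprintf("n%03d", 1:120))
    gsea_preranked(st, sample(names(st), 10), n_perm = 200, seed = i)$p
  }, numeric(1))
  expect_lt(suppressWarnings(ks.test(ps, "punif")$statistic), 0.12)
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("over-representation matches exact combinatorial enumeration", {
  u <- sprintf("u%02d", 1:20)
  set <- u[1:5]
  hits <- c(u[1:4], u[10])
  res <- overrepresentation(hits, u, set)
  # exact tail: sum over overlaps >= 4 of the hypergeometric pmf
  exact <- sum(vapply(4:5, function(k) {
    choose(5, k) * choose(15, 5 - k) / choose(20, 5)
  }, numeric(1)))
  expect_equal(res$p, exact, tolerance = 1e-12)
  expect_equal(res$overlap, 4)

  expect_equal(overrepresentation(u[6:10], u, u[1:5])$p, 1)
  expect_equal(overrepresentation(u, u, u)$p, 1)
  expect_error(overrepresentation("z", u, set), "subset")
  expect_error(overrepresentation(u[1], character(), set), "empty universe")

  # sweep of small universes against full enumeration
  set.seed(20)
  for (i in 1:25) {
    N <- sample(5:30, 1)
    uu <- sprintf("q%02d", seq_len(N))
    ss <- sample(uu, sample(1:N, 1))
    hh <- sample(uu, sample(1:N, 1))
    ov <- length(intersect(hh, ss))
    exact <- sum(vapply(ov:min(length(ss), length(hh)), function(k) {
      choose(length(ss), k) * choose(N - length(ss), length(hh) - k) /
        choose(N, length(hh))
    }, numeric(1)))
    expect_equal(overrepresentation(hh, uu, ss)$p, exact, tolerance = 1e-12)
  }
})

test_that("signature-by-group means compose ssGSEA scores", {
  set.seed(21)
  m <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("G%02d", 1:50), paste0("s", 1:4)))
  sets <- list(A = rownames(m)[1:10], B = rownames(m)[11:25])
  tab <- signature_contrast_stats(m, c("x", "x", "y", "y"), sets)
  expect_equal(dim(tab), c(2L, 2L))
  scores <- ssgsea_score(m, sets)
  expect_equal(tab["A", "x"], mean(scores[1:2, "A"]))

  # identical groups show zero difference
  m2 <- cbind(m, m)
  tab2 <- signature_contrast_stats(m2, rep(c("g1", "g2"), each = 4), sets)
  expect_equal(tab2[, "g1"], tab2[, "g2"])

  # single signature, single group: one cell, the mean score
  tab3 <- signature_contrast_stats(m, rep("only", 4), sets["A"])
  expect_equal(dim(tab3), c(1L, 1L))
  expect_equal(tab3[1, 1], mean(scores[, "A"]))

  # planted collagen shift ranks collagen signatures top by group difference
  bc <- gen_bulk_cohort(bulk_sim_config(n_samples = 60, n_genes = 300,
                                        collagen_effect = 2, seed = 22))
  sig <- list(collagen = bc$programs$collagen,
              immune = bc$programs$immune,
              background = bc$programs$background[1:40])
  grp <- ifelse(bc$subtype == "armored_cold", "resistant", "sensitive")
  tabs <- signature_contrast_stats(bc$expr, grp, sig)
  diffs <- tabs[, "resistant"] - tabs[, "sensitive"]
  expect_identical(names(which.max(diffs)), "collagen")
})
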