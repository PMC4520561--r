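toy_binding <- function(scores, categories = NULL, condition = "c1") {
  n <- length(scores)
  ids <- sprintf("g%03d", seq_len(n))
  if (is.null(categories)) categories <- rep("OTHER", n)
  structure(data.frame(
    gene_id = ids, condition = condition, category = categories,
    length_nt = 1000L, rpkm_extract = 1, rpkm_pulldown = scores,
    binding_score = scores, defined = !is.na(scores),
    stringsAsFactors = FALSE), class = c("binding_table", "data.frame"))
}

test_that("rank_and_bin builds near-equal contiguous rank blocks", {
  set.seed(1)
  l100 <- rank_and_bin(toy_binding(runif(100)), n_bins = 10)
  expect_equal(l100$bin_sizes, rep(10L, 10))
  expect_equal(l100$genes$rank, 1:100)
  expect_false(is.unsorted(l100$genes$binding_score))

  l101 <- rank_and_bin(toy_binding(runif(101)), n_bins = 10)
  expect_equal(l101$bin_sizes, c(11L, rep(10L, 9)))

  # all-tied scores: binning equals lexicographic gene order
  lt <- rank_and_bin(toy_binding(rep(1, 40)), n_bins = 4)
  expect_equal(lt$genes$gene_id, sprintf("g%03d", 1:40))

  # undefined scores excluded and reported
  s <- runif(30); s[c(3, 7)] <- NA
  lna <- rank_and_bin(toy_binding(s), n_bins = 4)
  expect_setequal(lna$excluded, c("g003", "g007"))
  expect_identical(nrow(lna$genes), 28L)

  expect_error(rank_and_bin(toy_binding(runif(5)), n_bins = 10), "5 defined")
})

test_that("category quotas are exact and smoothing matches brute force", {
  set.seed(2)
  cats <- sample(c("MPR", "CPR", "OTHER"), 120, replace = TRUE)
  l <- rank_and_bin(toy_binding(runif(120), cats), n_bins = 10)
  q <- category_quota(l, smooth_window = 3)

  # identity smoothing
  q1 <- category_quota(l, smooth_window = 1)
  expect_equal(q1$smoothed, q1$raw)

  # quota conservation: sum over bins of quota * binsize = category total
  for (cat in colnames(q$raw)) {
    expect_equal(sum(q$raw[, cat] * q$bin_sizes),
                 sum(l$genes$category == cat))
  }
  # quotas within a bin sum to one over categories
  expect_equal(unname(rowSums(q$raw)), rep(1, 10))

  # single-category landscape
  lall <- rank_and_bin(toy_binding(runif(50), rep("MPR", 50)), n_bins = 5)
  expect_equal(unname(category_quota(lall)$raw[, "MPR"]), rep(1, 5))

  # brute-force moving average, several windows
  for (w in c(3, 5, 7)) {
    qs <- category_quota(l, smooth_window = w)
    for (cat in colnames(qs$raw)) {
      expect_equal(unname(qs$smoothed[, cat]),
                   brute_smooth(unname(qs$raw[, cat]), w))
    }
  }
  expect_error(category_quota(l, smooth_window = 2), "odd")
})

test_that("top and bottom sets follow the ceiling rule and swap on reversal", {
  set.seed(3)
  b10 <- toy_binding(runif(10))
  s10 <- top_bottom_sets(b10, fraction = 0.3)
  expect_identical(length(s10$top), 3L)
  expect_identical(length(s10$bottom), 3L)
  expect_length(intersect(s10$top, s10$bottom), 0)

  # the published landscape size: 30% of 2731 genes = 820 by ceiling
  b2731 <- toy_binding(runif(2731))
  expect_identical(top_bottom_sets(b2731, 0.30)$k, 820)

  # reversing the score vector swaps top and bottom exactly
  sc <- runif(57)
  f <- top_bottom_sets(toy_binding(sc), 0.3)
  r <- top_bottom_sets(toy_binding(-sc), 0.3)
  expect_setequal(f$top, r$bottom)
  expect_setequal(f$bottom, r$top)

  expect_error(top_bottom_sets(b10, 0.5), "fraction")
})

test_that("hypergeometric enrichment matches closed forms", {
  # all 5 category members drawn in a 5-gene selection from 10
  r <- enrichment_test(letters[1:5], letters[1:5], letters[1:10])
  expect_equal(r$p_hypergeometric, 1 / choose(10, 5))
  expect_equal(r$fold_enrichment, 2)

  # symmetric instance: N=4, K=2, n=2, k=1 -> P(X >= 1) = 5/6
  r2 <- enrichment_test(c("a", "c"), c("a", "b"), c("a", "b", "c", "d"))
  expect_equal(r2$p_hypergeometric, 5 / 6)

  # k = 0 -> enriched-tail p = 1
  r3 <- enrichment_test(c("c", "d"), c("a", "b"), letters[1:10])
  expect_equal(r3$p_hypergeometric, 1)
  expect_identical(r3$direction, "depleted")

  expect_error(enrichment_test(c("z"), letters[1:3], letters[1:10]),
               "outside the background")
})

test_that("hypergeometric tails equal exhaustive enumeration for N <= 12", {
  for (N in c(5, 8, 12)) {
    bg <- sprintf("x%02d", 1:N)
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 3 + 1, N %/% 2)) {
        sel <- bg[seq_len(n)]
        cat_genes <- bg[seq_len(K)]
        k <- length(intersect(sel, cat_genes))
        r <- enrichment_test(sel, cat_genes, bg)
        expect_equal(r$p_hypergeometric, enum_hyper_tail(k, K, n, N),
                     tolerance = 1e-12)
        # and for every achievable k, via the lchoose oracle
        for (kk in max(0, n + K - N):min(K, n)) {
          expect_equal(stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE),
                       enum_hyper_tail(kk, K, n, N), tolerance = 1e-12)
          expect_equal(stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE),
                       lchoose_hyper_tail(kk, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("tail identities and monotonicity hold", {
  bg <- sprintf("x%02d", 1:40)
  cat_genes <- bg[1:12]
  for (n in c(5, 13, 20)) {
    sel <- bg[seq_len(n) * 2]  # an arbitrary but deterministic selection
    r <- enrichment_test(sel, cat_genes, bg)
    pmf <- stats::dhyper(r$k, r$K, r$N - r$K, r$n)
    expect_equal(r$p_hypergeometric + r$p_depletion, 1 + pmf)
    expect_gte(r$p_ease, r$p_hypergeometric)
  }

  # adding a category member to the selection never raises the enriched p
  sel <- bg[c(1, 2, 20, 25, 30)]
  p0 <- enrichment_test(sel, cat_genes, bg)$p_hypergeometric
  p1 <- enrichment_test(c(sel, bg[3]), cat_genes, bg)$p_hypergeometric
  expect_lte(p1, p0)
})

test_that("the published top/bottom-30% counts are extreme under sampling", {
  # 213 of 471 membrane-protein mRNAs in the top 820 of 2731 detected genes
  p_mpr <- lchoose_hyper_tail(213, 471, 820, 2731)
  expect_lt(p_mpr, 1e-12)
  expect_equal(stats::phyper(212, 471, 2731 - 471, 820, lower.tail = FALSE),
               p_mpr, tolerance = 1e-9)
  # 487 of 1363 cytoplasmic-protein mRNAs in the bottom 820
  p_cpr <- lchoose_hyper_tail(487, 1363, 820, 2731)
  expect_lt(p_cpr, 1e-6)
})

test_that("landscape_report ties the stages together deterministically", {
  set.seed(77)
  cats <- sample(c("MPR", "CPR", "OTHER"), 400, replace = TRUE,
                 prob = c(0.2, 0.5, 0.3))
  score <- rlnorm(400, meanlog = ifelse(cats == "MPR", 0.7, 0), sdlog = 0.4)
  bt <- toy_binding(score, cats)
  rep1 <- landscape_report(bt, select_genes = c("g001", "g002"))
  rep2 <- landscape_report(bt, select_genes = c("g001", "g002"))
  expect_identical(rep1, rep2)

  e <- rep1$c1$enrichment
  expect_gt(e$fold_enrichment[e$set == "top" & e$category == "MPR"], 1)
  expect_lt(e$fold_enrichment[e$set == "bottom" & e$category == "MPR"], 1)
  expect_identical(nrow(rep1$c1$selected), 2L)
  expect_equal(nrow(e), 6L)  # 3 categories x 2 sets
  # Bonferroni uses the number of tests actually performed
  expect_equal(e$p_bonferroni, pmin(1, e$p_value * 6))

  # on a null simulation every category's fold enrichment is near 1
  null <- run_pipeline_once(seed = 505, mpr_effect = 0)
  repn <- landscape_report(null$binding)
  en <- repn$Mg2$enrichment
  expect_true(all(abs(en$fold_enrichment[en$K > 50] - 1) < 0.2))
})
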