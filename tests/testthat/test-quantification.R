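make_toy <- function() {
  # 5 genes (one noncoding), 2 conditions would be overkill here: 1 condition,
  # 2 replicates per fraction with unequal library sizes
  counts <- matrix(
    c(100L, 200L,  50L, 400L, 250L,
      110L, 180L,  60L, 380L, 270L,
      400L,  40L,  10L, 800L, 250L,
      380L,  60L,   0L, 760L, 300L),
    nrow = 5,
    dimnames = list(c("gA", "gB", "gC", "gD", "gR"),
                    c("ex1", "ex2", "pd1", "pd2")))
  ann <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gR"),
    length_nt = c(500L, 1000L, 2000L, 250L, 1500L),
    category = c("MPR", "CPR", "OTHER", "MPR", "NONCODING"),
    stringsAsFactors = FALSE)
  ct <- toy_count_table(counts, c("extract", "extract", "pulldown", "pulldown"),
                        replicates = c(1, 2, 1, 2))
  list(counts = ct, ann = ann)
}

test_that("RPKM follows the reads-per-kilobase-per-million formula", {
  ann <- data.frame(gene_id = "g1", length_nt = 1000L, category = "OTHER")
  m <- matrix(100L, 1, 1, dimnames = list("g1", "s1"))
  ct <- toy_count_table(m, "extract")
  # the single gene carries the whole library, so pad the total to 1e6 reads
  ann2 <- rbind(ann, data.frame(gene_id = "pad", length_nt = 1000L,
                                category = "OTHER"))
  m2 <- rbind(m, pad = 999900L)
  r <- compute_rpkm(toy_count_table(m2, "extract"), ann2)
  expect_equal(r$rpkm["g1", "s1"], 100)

  # hand-computed toy table
  toy <- make_toy()
  r2 <- compute_rpkm(toy$counts, toy$ann)
  tot <- colSums(toy$counts$counts[c("gA", "gB", "gC", "gD"), ])  # coding only
  for (g in c("gA", "gB", "gC", "gD")) {
    len_kb <- toy$ann$length_nt[toy$ann$gene_id == g] / 1000
    for (s in colnames(toy$counts$counts)) {
      expect_equal(r2$rpkm[g, s],
                   toy$counts$counts[g, s] / len_kb / (tot[[s]] / 1e6))
    }
  }
})

test_that("RPKM is invariant to uniform count scaling and reconstructs counts", {
  toy <- make_toy()
  r <- compute_rpkm(toy$counts, toy$ann)

  doubled <- toy$counts
  doubled$counts[, "ex1"] <- doubled$counts[, "ex1"] * 2L
  r2 <- compute_rpkm(doubled, toy$ann)
  expect_equal(r2$rpkm[, "ex1"], r$rpkm[, "ex1"])

  # count(g,s) = RPKM * length_kb * mapped_total / 1e6, exactly
  rebuilt <- r$rpkm * (r$annotation$length_nt / 1000) *
    rep(r$mapped_totals / 1e6, each = nrow(r$rpkm))
  expect_equal(rebuilt, r$counts + 0, tolerance = 1e-12)
})

test_that("RPKM join and sample errors are informative", {
  toy <- make_toy()
  expect_error(compute_rpkm(toy$counts, toy$ann[-1, ]), "gA")
  zero <- toy$counts
  zero$counts[, "pd1"] <- 0L
  expect_error(compute_rpkm(zero, toy$ann), "zero mapped reads")
})

test_that("detection filter removes noncoding and poorly-detected genes", {
  toy <- make_toy()
  r <- compute_rpkm(toy$counts, toy$ann)
  f <- filter_detected(r, min_rpkm = 1, min_samples = 1)
  # gR is noncoding despite strong counts; gC has a zero pulldown replicate
  # but passes with min_samples = 1
  expect_identical(
    f$exclusions$reason[f$exclusions$gene_id == "gR"], "noncoding")
  expect_true(all(c("gA", "gB", "gC", "gD") %in% rownames(f$rpkm)))

  # min_samples = 2 now drops gC (detected in only one pulldown replicate)
  f2 <- filter_detected(r, min_rpkm = 1, min_samples = 2)
  expect_identical(
    f2$exclusions$reason[f2$exclusions$gene_id == "gC"], "poorly_detected")

  # a gene with zero counts everywhere is poorly detected
  toy0 <- make_toy()
  toy0$counts$counts["gA", ] <- 0L
  f0 <- filter_detected(compute_rpkm(toy0$counts, toy0$ann), min_rpkm = 1)
  expect_identical(f0$exclusions$reason[f0$exclusions$gene_id == "gA"],
                   "poorly_detected")
})

test_that("detection filter equals the brute-force rule and is monotone", {
  set.seed(41)
  n <- 30
  ann <- data.frame(gene_id = sprintf("g%02d", 1:n),
                    length_nt = sample(200:2000, n),
                    category = sample(c("MPR", "CPR", "OTHER", "NONCODING"),
                                      n, replace = TRUE))
  m <- matrix(rnbinom(n * 4, mu = 30, size = 2), nrow = n,
              dimnames = list(ann$gene_id, c("e1", "e2", "p1", "p2")))
  ct <- toy_count_table(m, c("extract", "extract", "pulldown", "pulldown"),
                        replicates = c(1, 2, 1, 2))
  r <- compute_rpkm(ct, ann)

  prev <- NULL
  for (thr in c(0.5, 2, 10, 50)) {
    f <- filter_detected(r, min_rpkm = thr, min_samples = 1)
    keep_brute <- vapply(seq_len(n), function(i) {
      ann$category[i] != "NONCODING" &&
        any(r$rpkm[i, c("e1", "e2")] >= thr) &&
        any(r$rpkm[i, c("p1", "p2")] >= thr)
    }, logical(1))
    expect_setequal(rownames(f$rpkm), ann$gene_id[keep_brute])
    if (!is.null(prev)) expect_true(all(rownames(f$rpkm) %in% prev))
    prev <- rownames(f$rpkm)
  }
})

test_that("binding scores divide pull-down RPKM by extract RPKM", {
  toy <- make_toy()
  bt <- binding_scores(toy$counts, toy$ann, min_rpkm = 0, min_samples = 0)
  r <- compute_rpkm(toy$counts, toy$ann)
  # pooled-counts pooling: sum replicate counts, recompute RPKM
  tot <- colSums(toy$counts$counts[c("gA", "gB", "gC", "gD"), ])
  for (g in c("gA", "gB", "gD")) {
    len_kb <- toy$ann$length_nt[toy$ann$gene_id == g] / 1000
    ex <- sum(toy$counts$counts[g, c("ex1", "ex2")]) / len_kb /
      (sum(tot[c("ex1", "ex2")]) / 1e6)
    pd <- sum(toy$counts$counts[g, c("pd1", "pd2")]) / len_kb /
      (sum(tot[c("pd1", "pd2")]) / 1e6)
    expect_equal(bt$binding_score[bt$gene_id == g], pd / ex)
  }

  # equal RPKMs in both fractions give score 1; 4 vs 2 gives 2
  m <- matrix(c(10L, 90L, 10L, 90L), 2,
              dimnames = list(c("a", "b"), c("e", "p")))
  ann2 <- data.frame(gene_id = c("a", "b"), length_nt = c(100L, 100L),
                     category = "OTHER")
  b2 <- binding_scores(toy_count_table(m, c("extract", "pulldown")), ann2,
                       min_rpkm = 0, min_samples = 0)
  expect_equal(b2$binding_score, c(1, 1))

  m3 <- matrix(c(20L, 80L, 40L, 60L), 2,
               dimnames = list(c("a", "b"), c("e", "p")))
  b3 <- binding_scores(toy_count_table(m3, c("extract", "pulldown")), ann2,
                       min_rpkm = 0, min_samples = 0)
  expect_equal(b3$binding_score[b3$gene_id == "a"], 2)
})

test_that("binding score pooling modes agree for equal library sizes", {
  set.seed(13)
  n <- 20
  ann <- data.frame(gene_id = sprintf("g%02d", 1:n),
                    length_nt = sample(300:3000, n), category = "OTHER")
  base <- matrix(rnbinom(n * 4, mu = 50, size = 5), nrow = n,
                 dimnames = list(ann$gene_id, c("e1", "e2", "p1", "p2")))
  # force equal library sizes per fraction by adding a balancing gene
  pad <- max(colSums(base)) * 2L - colSums(base)
  m <- rbind(base, pad = pad)
  annp <- rbind(ann, data.frame(gene_id = "pad", length_nt = 1000L,
                                category = "OTHER"))
  ct <- toy_count_table(m, c("extract", "extract", "pulldown", "pulldown"),
                        replicates = c(1, 2, 1, 2))
  b1 <- binding_scores(ct, annp, min_rpkm = 0, min_samples = 0,
                       pooling = "pooled_counts")
  b2 <- binding_scores(ct, annp, min_rpkm = 0, min_samples = 0,
                       pooling = "mean_rpkm")
  expect_equal(b1$binding_score, b2$binding_score)
})

test_that("binding score is invariant to uniform library scaling", {
  toy <- make_toy()
  bt <- binding_scores(toy$counts, toy$ann, min_rpkm = 0, min_samples = 0)
  scaled <- toy$counts
  scaled$counts[, c("pd1", "pd2")] <- scaled$counts[, c("pd1", "pd2")] * 3L
  bt2 <- binding_scores(scaled, toy$ann, min_rpkm = 0, min_samples = 0)
  expect_equal(bt$binding_score, bt2$binding_score)
})

test_that("zero extract RPKM is flagged undefined, not dropped", {
  m <- matrix(c(0L, 100L, 50L, 50L), 2,
              dimnames = list(c("a", "b"), c("e", "p")))
  ann <- data.frame(gene_id = c("a", "b"), length_nt = 500L,
                    category = "OTHER")
  bt <- binding_scores(toy_count_table(m, c("extract", "pulldown")), ann,
                       min_rpkm = 0, min_samples = 0)
  expect_identical(bt$defined, c(FALSE, TRUE))
  expect_true(is.na(bt$binding_score[1]))
  expect_identical(nrow(bt), 2L)
})

test_that("null simulations give median binding scores near one", {
  res <- run_pipeline_once(seed = 404, mpr_effect = 0)
  expect_gt(res$median_score, 0.8)
  expect_lt(res$median_score, 1.25)
})
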