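# Independent brute-force oracles and tiny fixture builders shared across
# the test files. Everything here deliberately avoids the package's own
# code paths for the quantity being checked.

# per-window T/U fraction by naive character counting
brute_u_profile <- function(sequence, window, step = 1) {
  x <- strsplit(toupper(sequence), "")[[1]]
  starts <- seq(0, length(x) - window, by = step)
  vapply(starts, function(p) {
    sum(x[(p + 1):(p + window)] %in% c("T", "U")) / window
  }, numeric(1))
}

# exhaustive upper hypergeometric tail: enumerate every n-subset of a
# background whose first K members form the category
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# independent tail sum on the log-binomial scale (no phyper)
lchoose_hyper_tail <- function(k, K, n, N) {
  i <- seq.int(k, min(K, n))
  if (length(i) == 0 || k > min(K, n)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# naive centred moving average with symmetric shrink at the edges
brute_smooth <- function(v, window) {
  h <- (window - 1) %/% 2
  vapply(seq_along(v), function(i) {
    hh <- min(h, i - 1, length(v) - i)
    mean(v[(i - hh):(i + hh)])
  }, numeric(1))
}

# a deterministic toy count table: g genes x (extract + pulldown) x reps
toy_count_table <- function(counts, fractions, conditions = "c1",
                            replicates = NULL) {
  if (is.null(replicates)) replicates <- seq_along(fractions)
  samples <- data.frame(
    sample_id = colnames(counts), fraction = fractions,
    condition = rep(conditions, length.out = ncol(counts)),
    replicate = replicates, stringsAsFactors = FALSE)
  bindscape::count_table(counts, samples)
}

# single-condition simulation config used throughout the pipeline tests
pipeline_config <- function(seed, mpr_effect = 0, n_genes = 2000,
                            libsize = 1e6, binding_sd = 0.25) {
  bindscape::sim_config(
    n_genes = n_genes, conditions = "Mg2",
    binding_effect = list(Mg2 = c(MPR = mpr_effect, CPR = 0, SPR = 0,
                                  CSP = 0, OTHER = 0)),
    binding_sd = binding_sd, n_replicates = 3, libsize = libsize, seed = seed)
}

# run the simulate -> quantify -> enrich pipeline once; returns the MPR
# top-set enrichment together with summaries used by the calibration tests
run_pipeline_once <- function(seed, mpr_effect = 0, fraction = 0.30) {
  ds <- bindscape::simulate_dataset(pipeline_config(seed, mpr_effect))
  bt <- bindscape::binding_scores(ds$counts, ds$annotation)
  sets <- bindscape::top_bottom_sets(bt, fraction = fraction)
  mpr <- ds$annotation$gene_id[ds$annotation$category == "MPR"]
  er <- bindscape::enrichment_test(sets$top, mpr, sets$background)
  quota <- bindscape::category_quota(bindscape::rank_and_bin(bt),
                                     smooth_window = 3)
  list(p = er$p_hypergeometric,
       median_score = stats::median(bt$binding_score, na.rm = TRUE),
       rho = stats::cor(quota$smoothed[, "MPR"],
                        seq_len(nrow(quota$smoothed)), method = "spearman"),
       binding = bt, annotation = ds$annotation)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# upper-tail p for given (k, K, n, N) via the package interface, built from
# an explicit selection with exactly k category members
hypergeom_result_for <- function(k, K, n, N, bg) {
  sel <- c(bg[seq_len(k)],
           if (n - k > 0) bg[(K + 1):(K + n - k)])
  cat_genes <- bg[seq_len(K)]
  bindscape::enrichment_test(sel, cat_genes, bg)$p_hypergeometric
}
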