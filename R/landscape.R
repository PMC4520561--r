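#' Rank genes by binding score and assign percentile bins
#'
#' Sorts defined-score genes ascending by binding score (ties broken by
#' gene id, so the landscape is identical across platforms) and cuts the
#' ranking into `n_bins` contiguous blocks of near-equal size, the classic
#' "each 10th percentile" construction. When the gene count is not a multiple
#' of `n_bins`, the remainder genes go to the lowest bins.
#'
#' @param binding a `binding_table` restricted to one condition (or pass
#'   `condition` to select one).
#' @param n_bins number of percentile bins (default 10 = deciles).
#' @param condition condition label to select when `binding` holds several.
#' @return A list of class `binding_landscape`: `genes` (data frame with
#'   `gene_id`, `category`, `binding_score`, `rank`, `bin`), `n_bins`,
#'   `bin_sizes`, and `excluded` (gene ids with undefined scores).
#' @export
rank_and_bin <- function(binding, n_bins = 10L, condition = NULL) {
  binding <- pick_condition(binding, condition)
  n_bins <- as.integer(n_bins)
  defined <- binding[binding$defined & !is.na(binding$binding_score), ]
  excluded <- setdiff(binding$gene_id, defined$gene_id)
  n <- nrow(defined)
  if (n < n_bins) {
    stop("only ", n, " defined-score genes for ", n_bins, " bins", call. = FALSE)
  }
  ord <- order(defined$binding_score, defined$gene_id)
  defined <- defined[ord, ]
  base <- n %/% n_bins
  extra <- n %% n_bins
  bin_sizes <- base + as.integer(seq_len(n_bins) <= extra)
  genes <- data.frame(
    gene_id = defined$gene_id,
    category = defined$category,
    binding_score = defined$binding_score,
    rank = seq_len(n),
    bin = rep(seq_len(n_bins), times = bin_sizes),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  structure(list(genes = genes, n_bins = n_bins, bin_sizes = bin_sizes,
                 excluded = excluded),
            class = "binding_landscape")
}

pick_condition <- function(binding, condition) {
  stopifnot(is.data.frame(binding),
            all(c("gene_id", "binding_score", "defined") %in% names(binding)))
  conds <- unique(binding$condition)
  if (!is.null(condition)) {
    if (!condition %in% conds) {
      stop("condition ", condition, " not present", call. = FALSE)
    }
    binding <- binding[binding$condition == condition, ]
  } else if (length(conds) > 1) {
    stop("binding table holds conditions ", paste(conds, collapse = ", "),
         "; pick one with `condition=`", call. = FALSE)
  }
  binding
}

#' Per-bin category quotas with moving-average smoothing
#'
#' The raw quota of a category in a bin is the fraction of the bin's genes
#' belonging to that category. The smoothed curve is a centred moving average
#' over bins whose window shrinks symmetrically at the edges (so bin 1 of a
#' 3-wide window is just itself, bin 2 averages bins 1-3, ...).
#'
#' @param landscape a [rank_and_bin()] result.
#' @param smooth_window odd window width in bins (1 = no smoothing).
#' @param categories categories to report; default: all present.
#' @return A list of class `quota_curves` with matrices `raw` and `smoothed`
#'   (bins x categories) and `bin_sizes`.
#' @export
category_quota <- function(landscape, smooth_window = 3L, categories = NULL) {
  stopifnot(inherits(landscape, "binding_landscape"))
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    stop("smooth_window must be odd and >= 1", call. = FALSE)
  }
  g <- landscape$genes
  if (is.null(categories)) categories <- sort(unique(g$category))
  nb <- landscape$n_bins
  raw <- matrix(0, nrow = nb, ncol = length(categories),
                dimnames = list(paste0("bin", seq_len(nb)), categories))
  for (ci in seq_along(categories)) {
    cnt <- tabulate(g$bin[g$category == categories[ci]], nbins = nb)
    raw[, ci] <- cnt / landscape$bin_sizes
  }
  half <- (smooth_window - 1L) %/% 2L
  smoothed <- raw
  for (i in seq_len(nb)) {
    h <- min(half, i - 1L, nb - i)
    smoothed[i, ] <- colMeans(raw[(i - h):(i + h), , drop = FALSE])
  }
  structure(list(raw = raw, smoothed = smoothed,
                 bin_sizes = landscape$bin_sizes),
            class = "quota_curves")
}

#' Top and bottom fractions of the binding landscape
#'
#' The top set holds the `ceiling(fraction * N)` highest-scoring
#' defined-score genes, the bottom set the same number from the low end
#' (ties broken by gene id in both directions). `fraction` must be < 0.5 and
#' the two sets must not overlap.
#'
#' @inheritParams rank_and_bin
#' @param fraction fraction of defined-score genes per set (default 0.30).
#' @return A list of class `landscape_sets`: `top`, `bottom` (gene id
#'   vectors), `k` (set size), `n` (defined-score genes), `background`.
#' @export
top_bottom_sets <- function(binding, fraction = 0.30, condition = NULL) {
  binding <- pick_condition(binding, condition)
  if (fraction <= 0 || fraction >= 0.5) {
    stop("fraction must be in (0, 0.5)", call. = FALSE)
  }
  defined <- binding[binding$defined & !is.na(binding$binding_score), ]
  n <- nrow(defined)
  k <- ceiling(fraction * n)
  if (2 * k > n) {
    stop("top and bottom sets of size ", k, " would overlap (n = ", n, ")",
         call. = FALSE)
  }
  bottom <- defined$gene_id[order(defined$binding_score, defined$gene_id)][seq_len(k)]
  top <- defined$gene_id[order(-defined$binding_score, defined$gene_id)][seq_len(k)]
  structure(list(top = top, bottom = bottom, k = k, n = n,
                 background = defined$gene_id),
            class = "landscape_sets")
}

#' Hypergeometric category enrichment of a gene set
#'
#' Tests whether a category is over-represented in a selected gene set drawn
#' from a background. The enriched-tail p-value is the exact upper
#' hypergeometric tail P(X >= k); the EASE variant (the conservative score
#' used by the DAVID annotation tool) replaces k by k - 1. Depletion is
#' reported through the lower tail P(X <= k), which has correct discrete-tail
#' semantics. Bonferroni correction multiplies the directional p-value by
#' `n_tests`, capped at 1.
#'
#' @param selected character vector of selected gene ids (must be a subset of
#'   `background`).
#' @param category_genes gene ids belonging to the category (ids outside the
#'   background are ignored).
#' @param background character vector of all eligible gene ids.
#' @param method `"hypergeometric"` (default) or `"ease"`: which statistic
#'   the directional p-value and Bonferroni correction use. Both are always
#'   reported.
#' @param n_tests Bonferroni multiplicity (>= 1).
#' @return A list of class `enrichment_result` with `N`, `K`, `n`, `k`,
#'   `fold_enrichment`, `p_hypergeometric` (upper tail), `p_ease`,
#'   `p_depletion` (lower tail), `direction`, `p_value` (directional, per
#'   `method`), `p_bonferroni`, `method`, `n_tests`.
#' @examples
#' r <- enrichment_test(letters[1:5], letters[1:5], letters[1:10])
#' r$p_hypergeometric  # 1/choose(10, 5)
#' @export
enrichment_test <- function(selected, category_genes, background,
                            method = c("hypergeometric", "ease"),
                            n_tests = 1L) {
  method <- match.arg(method)
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  if (anyDuplicated(background)) stop("duplicate ids in background", call. = FALSE)
  stray <- setdiff(selected, background)
  if (length(stray) > 0) {
    stop("selected genes outside the background: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  K <- length(intersect(category_genes, background))
  n <- length(unique(selected))
  k <- length(intersect(selected, category_genes))
  res <- hypergeom_enrichment(k, K, n, N)

  direction <- if (is.nan(res$fold) || res$fold >= 1) "enriched" else "depleted"
  p_dir <- if (direction == "enriched") {
    if (method == "ease") res$p_ease else res$p_upper
  } else {
    res$p_lower
  }
  structure(list(N = N, K = K, n = n, k = k,
                 fold_enrichment = res$fold,
                 p_hypergeometric = res$p_upper,
                 p_ease = res$p_ease,
                 p_depletion = res$p_lower,
                 direction = direction,
                 p_value = p_dir,
                 p_bonferroni = min(1, p_dir * n_tests),
                 method = method, n_tests = as.integer(n_tests)),
            class = "enrichment_result")
}

# Exact tails of the hypergeometric contingency (k of n selected in a
# category of size K within a background of N).
hypergeom_enrichment <- function(k, K, n, N) {
  if (k > K || k > n || n > N || K > N) {
    stop("inconsistent counts: k=", k, " K=", K, " n=", n, " N=", N,
         call. = FALSE)
  }
  p_upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_lower <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  k_ease <- max(k - 1, 0)
  p_ease <- stats::phyper(k_ease - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  fold <- if (expected > 0) (k / n) / (K / N) else NaN
  list(p_upper = p_upper, p_lower = p_lower, p_ease = p_ease, fold = fold)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: k/n = %d/%d vs K/N = %d/%d (fold %.3g, %s)\n",
              x$k, x$n, x$K, x$N, x$fold_enrichment, x$direction))
  cat(sprintf("  p (hypergeometric upper) = %.3g, p (EASE) = %.3g, p (lower) = %.3g\n",
              x$p_hypergeometric, x$p_ease, x$p_depletion))
  cat(sprintf("  directional p [%s] = %.3g, Bonferroni x%d = %.3g\n",
              x$method, x$p_value, x$n_tests, x$p_bonferroni))
  invisible(x)
}

#' Full binding-landscape report
#'
#' Per condition: the extract-vs-pull-down scatter table, the percentile
#' landscape with raw and smoothed category quota curves, the top/bottom
#' sets, an enrichment test for every category in both sets, and (optionally)
#' the binding scores of a hand-picked gene panel.
#'
#' @param binding a `binding_table` (any number of conditions).
#' @param n_bins,smooth_window,fraction,method see [rank_and_bin()],
#'   [category_quota()], [top_bottom_sets()], [enrichment_test()].
#' @param n_tests Bonferroni multiplicity; default = number of categories
#'   tested x 2 sets.
#' @param select_genes optional gene ids whose binding values are tabulated
#'   (the "selected transcripts" bar-plot data).
#' @return A list of class `landscape_report`, one element per condition,
#'   each with `scatter`, `landscape`, `quota`, `sets`, `enrichment` (data
#'   frame, one row per set x category), `selected`.
#' @export
landscape_report <- function(binding, n_bins = 10L, smooth_window = 3L,
                             fraction = 0.30,
                             method = c("hypergeometric", "ease"),
                             n_tests = NULL, select_genes = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(binding, "data.frame"))
  conditions <- unique(binding$condition)
  report <- list()
  for (cond in conditions) {
    b <- binding[binding$condition == cond, ]
    landscape <- rank_and_bin(b, n_bins = n_bins)
    quota <- category_quota(landscape, smooth_window = smooth_window)
    sets <- top_bottom_sets(b, fraction = fraction)
    categories <- sort(unique(landscape$genes$category))
    m <- if (is.null(n_tests)) length(categories) * 2L else n_tests
    rows <- list()
    for (set_name in c("top", "bottom")) {
      for (cat in categories) {
        er <- enrichment_test(sets[[set_name]],
                              b$gene_id[b$category == cat],
                              sets$background, method = method, n_tests = m)
        rows[[paste(set_name, cat)]] <- data.frame(
          set = set_name, category = cat, N = er$N, K = er$K, n = er$n,
          k = er$k, fold_enrichment = er$fold_enrichment,
          p_hypergeometric = er$p_hypergeometric, p_ease = er$p_ease,
          p_depletion = er$p_depletion, direction = er$direction,
          p_value = er$p_value, p_bonferroni = er$p_bonferroni,
          stringsAsFactors = FALSE)
      }
    }
    enrichment <- do.call(rbind, rows)
    rownames(enrichment) <- NULL
    selected <- NULL
    if (!is.null(select_genes)) {
      selected <- b[b$gene_id %in% select_genes,
                    c("gene_id", "category", "binding_score", "defined")]
      rownames(selected) <- NULL
    }
    scatter <- b[, c("gene_id", "category", "rpkm_extract", "rpkm_pulldown")]
    rownames(scatter) <- NULL
    report[[cond]] <- list(condition = cond, scatter = scatter,
                           landscape = landscape, quota = quota, sets = sets,
                           enrichment = enrichment, selected = selected)
  }
  structure(report, class = "landscape_report")
}

#' @export
print.landscape_report <- function(x, ...) {
  for (cond in names(x)) {
    r <- x[[cond]]
    cat("Condition ", cond, ": ", nrow(r$landscape$genes),
        " ranked genes in ", r$landscape$n_bins, " bins; sets of ",
        r$sets$k, "\n", sep = "")
    sig <- r$enrichment[r$enrichment$p_bonferroni < 0.05, ]
    if (nrow(sig) > 0) {
      for (i in seq_len(nrow(sig))) {
        cat(sprintf("  %s set: %s %s (fold %.2f, p_bonf %.2g)\n",
                    sig$set[i], sig$category[i], sig$direction[i],
                    sig$fold_enrichment[i], sig$p_bonferroni[i]))
      }
    } else {
      cat("  no category passes Bonferroni at 0.05\n")
    }
  }
  invisible(x)
}

#' Plot smoothed category quota curves across percentile bins
#'
#' @param x a `quota_curves` object.
#' @param categories categories to draw (default: all).
#' @param ... passed to [graphics::matplot()].
#' @method plot quota_curves
#' @export
plot.quota_curves <- function(x, categories = NULL, ...) {
  m <- x$smoothed
  if (!is.null(categories)) m <- m[, categories, drop = FALSE]
  graphics::matplot(seq_len(nrow(m)), m, type = "b", pch = 19, lty = 1,
                    xlab = "binding-score percentile bin",
                    ylab = "category quota", ...)
  graphics::legend("topleft", legend = colnames(m), col = seq_len(ncol(m)),
                   pch = 19, bty = "n")
  invisible(x)
}
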