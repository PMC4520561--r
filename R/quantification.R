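#' Construct a count table
#'
#' Couples a genes x samples matrix of non-negative integer read counts with
#' its sample metadata (fraction, condition, replicate) — the unit of input
#' for RPKM normalisation and binding-score computation.
#'
#' @param counts integer matrix, rownames = gene ids, colnames = sample ids.
#' @param samples data frame with columns `sample_id`, `fraction`
#'   (`"extract"` or `"pulldown"`), `condition`, `replicate`; one row per
#'   column of `counts`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, samples) {
  stopifnot(is.matrix(counts),
            all(c("sample_id", "fraction", "condition", "replicate") %in%
                  names(samples)))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  }
  if (!identical(colnames(counts), samples$sample_id)) {
    samples <- samples[match(colnames(counts), samples$sample_id), ]
    if (anyNA(samples$sample_id)) {
      stop("every count column needs a metadata row", call. = FALSE)
    }
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  bad <- setdiff(unique(samples$fraction), c("extract", "pulldown"))
  if (length(bad) > 0) {
    stop("fraction must be 'extract' or 'pulldown', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("  fractions: ", paste(unique(x$samples$fraction), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

check_annotation <- function(annotation) {
  stopifnot(all(c("gene_id", "length_nt", "category") %in% names(annotation)))
  if (anyDuplicated(annotation$gene_id)) {
    stop("duplicate gene ids in annotation", call. = FALSE)
  }
  if (any(annotation$length_nt < 1)) stop("gene lengths must be >= 1 nt", call. = FALSE)
  invisible(annotation)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM(g, s) = count(g, s) / (length_kb(g)) / (mapped_total(s) / 1e6)`.
#' By default the per-sample mapped total is computed after removing
#' `NONCODING` genes (rRNA/tRNA and other non-coding loci are conventionally
#' excluded before mRNA quantification); set `totals = "all"` to use raw
#' column sums.
#'
#' @param counts a [count_table()].
#' @param annotation gene annotation data frame (`gene_id`, `length_nt`,
#'   `category`); every counted gene must be annotated.
#' @param totals `"coding"` (default) or `"all"`: which genes enter the
#'   per-sample mapped-read denominator.
#' @return An object of class `rpkm_table`: list with `rpkm` matrix,
#'   `samples` metadata, `mapped_totals`, and the matched `annotation`.
#' @examples
#' ann <- data.frame(gene_id = "g1", length_nt = 1000, category = "OTHER")
#' m <- matrix(100L, 1, 1, dimnames = list("g1", "s1"))
#' s <- data.frame(sample_id = "s1", fraction = "extract",
#'                 condition = "c", replicate = 1)
#' compute_rpkm(count_table(m, s), ann)$rpkm  # 100 / 1 kb / (100/1e6) = 1e6
#' @export
compute_rpkm <- function(counts, annotation, totals = c("coding", "all")) {
  stopifnot(inherits(counts, "count_table"))
  totals <- match.arg(totals)
  check_annotation(annotation)
  genes <- rownames(counts$counts)
  missing <- setdiff(genes, annotation$gene_id)
  if (length(missing) > 0) {
    stop("genes missing from annotation: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" ... (%d total)", length(missing)),
         call. = FALSE)
  }
  ann <- annotation[match(genes, annotation$gene_id), ]
  coding <- ann$category != "NONCODING"
  mt <- if (totals == "coding") {
    colSums(counts$counts[coding, , drop = FALSE])
  } else {
    colSums(counts$counts)
  }
  if (any(mt == 0)) {
    stop("zero mapped reads in sample(s): ",
         paste(colnames(counts$counts)[mt == 0], collapse = ", "), call. = FALSE)
  }
  rpkm <- sweep(counts$counts / (ann$length_nt / 1000), 2, mt / 1e6, `/`)
  structure(list(rpkm = rpkm, samples = counts$samples, mapped_totals = mt,
                 annotation = ann, counts = counts$counts),
            class = "rpkm_table")
}

#' Detection filter for expression tables
#'
#' Removes `NONCODING` genes outright and keeps a protein-coding gene only if
#' its RPKM reaches `min_rpkm` in at least `min_samples` samples of *each*
#' fraction (detected in both the extract and the pull-down). Every removal is
#' reported with its reason.
#'
#' @param expr an `rpkm_table` from [compute_rpkm()].
#' @param min_rpkm detection threshold (RPKM).
#' @param min_samples minimum qualifying samples per fraction.
#' @return An `rpkm_table` restricted to retained genes, with an `exclusions`
#'   element (data frame `gene_id`, `reason` in `noncoding` /
#'   `poorly_detected`).
#' @export
filter_detected <- function(expr, min_rpkm = 1, min_samples = 1L) {
  stopifnot(inherits(expr, "rpkm_table"), min_rpkm >= 0, min_samples >= 0)
  ann <- expr$annotation
  noncoding <- ann$category == "NONCODING"

  detected <- rep(TRUE, nrow(expr$rpkm))
  for (fr in c("extract", "pulldown")) {
    cols <- expr$samples$fraction == fr
    if (!any(cols)) {
      stop("no ", fr, " samples present; cannot apply the detected-in-both rule",
           call. = FALSE)
    }
    n_ok <- rowSums(expr$rpkm[, cols, drop = FALSE] >= min_rpkm)
    detected <- detected & (n_ok >= min_samples)
  }

  keep <- !noncoding & detected
  exclusions <- data.frame(
    gene_id = ann$gene_id[!keep],
    reason = ifelse(noncoding[!keep], "noncoding", "poorly_detected"),
    stringsAsFactors = FALSE)

  out <- expr
  out$rpkm <- expr$rpkm[keep, , drop = FALSE]
  out$counts <- expr$counts[keep, , drop = FALSE]
  out$annotation <- ann[keep, ]
  out$exclusions <- exclusions
  out
}

#' Per-gene binding scores from paired extract / pull-down libraries
#'
#' For each condition, replicate libraries are combined (by default by summing
#' counts and recomputing RPKM on the pooled library; alternatively by
#' averaging per-replicate RPKMs) and the binding score is
#' `RPKM_pulldown / RPKM_extract`. Genes whose pooled extract RPKM is zero are
#' flagged `defined = FALSE` with `binding_score = NA`, never dropped.
#'
#' @param expr a filtered `rpkm_table` (see [filter_detected()]); an
#'   unfiltered one is accepted.
#' @param pooling `"pooled_counts"` (default) or `"mean_rpkm"`.
#' @return A data frame of class `binding_table`: `gene_id`, `condition`,
#'   `category`, `length_nt`, `rpkm_extract`, `rpkm_pulldown`,
#'   `binding_score`, `defined`.
#' @export
binding_score <- function(expr, pooling = c("pooled_counts", "mean_rpkm")) {
  stopifnot(inherits(expr, "rpkm_table"))
  pooling <- match.arg(pooling)
  smp <- expr$samples
  ann <- expr$annotation
  out <- list()
  for (cond in unique(smp$condition)) {
    pooled <- list()
    for (fr in c("extract", "pulldown")) {
      cols <- smp$condition == cond & smp$fraction == fr
      if (!any(cols)) {
        stop("condition ", cond, " has no ", fr, " samples", call. = FALSE)
      }
      pooled[[fr]] <- if (pooling == "pooled_counts") {
        cnt <- rowSums(expr$counts[, cols, drop = FALSE])
        tot <- sum(expr$mapped_totals[cols])
        cnt / (ann$length_nt / 1000) / (tot / 1e6)
      } else {
        rowMeans(expr$rpkm[, cols, drop = FALSE])
      }
    }
    defined <- pooled$extract > 0
    out[[cond]] <- data.frame(
      gene_id = ann$gene_id,
      condition = cond,
      category = ann$category,
      length_nt = ann$length_nt,
      rpkm_extract = pooled$extract,
      rpkm_pulldown = pooled$pulldown,
      binding_score = ifelse(defined, pooled$pulldown / pooled$extract, NA_real_),
      defined = defined,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("binding_table", "data.frame")
  res
}

#' One-call quantification pipeline
#'
#' [compute_rpkm()] + [filter_detected()] + [binding_score()].
#'
#' @inheritParams compute_rpkm
#' @inheritParams filter_detected
#' @inheritParams binding_score
#' @return A `binding_table`; the exclusion report is attached as the
#'   `"exclusions"` attribute.
#' @export
binding_scores <- function(counts, annotation, min_rpkm = 1, min_samples = 1L,
                           pooling = c("pooled_counts", "mean_rpkm"),
                           totals = c("coding", "all")) {
  expr <- compute_rpkm(counts, annotation, totals = match.arg(totals))
  expr <- filter_detected(expr, min_rpkm = min_rpkm, min_samples = min_samples)
  bt <- binding_score(expr, pooling = match.arg(pooling))
  attr(bt, "exclusions") <- expr$exclusions
  bt
}
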