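#' Simulate a gene annotation table
#'
#' Draws a gene universe of `config$n_genes` genes with categories apportioned
#' by largest-remainder rounding of `config$category_fractions` (so the
#' composition is exactly reproducible) and log-normal lengths floored at
#' 90 nt. Category labels are shuffled across gene ids so gene order carries no
#' category signal.
#'
#' @param config a [sim_config()] object.
#' @return A data frame with columns `gene_id`, `length_nt`, `category`.
#' @examples
#' ann <- simulate_annotation(sim_config(n_genes = 100, seed = 7))
#' table(ann$category)
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  counts <- largest_remainder(config$category_fractions, n)
  categories <- rep(names(config$category_fractions), counts)
  categories <- sample(categories)
  lengths <- pmax(90L, as.integer(round(
    stats::rlnorm(n, config$length_meanlog, config$length_sdlog))))
  width <- max(4L, nchar(as.character(n)))
  data.frame(
    gene_id = sprintf(paste0("g%0", width, "d"), seq_len(n)),
    length_nt = lengths,
    category = categories,
    stringsAsFactors = FALSE)
}

#' Simulate extract and pull-down count libraries
#'
#' For every condition and replicate, generates one total-extract and one
#' pull-down library. Expected extract counts are proportional to
#' abundance x length; expected pull-down counts to
#' abundance x length x binding propensity, where
#' `log2(propensity) = binding_effect[category][condition] + gene noise`
#' with gene noise ~ Normal(0, `binding_sd`) drawn once per gene. Each
#' library is scaled to an expected total of `libsize` reads and counts are
#' drawn negative-binomially with the shared dispersion.
#'
#' @param annotation data frame from [simulate_annotation()] (or any table
#'   with `gene_id`, `length_nt`, `category`).
#' @param config a [sim_config()] object.
#' @return A list with elements `counts` (a [count_table()]) and `truth`
#'   (data frame of per-gene true abundance and per-condition propensity).
#' @examples
#' cfg <- sim_config(n_genes = 50, libsize = 1e5, seed = 3)
#' sim <- simulate_counts(simulate_annotation(cfg), cfg)
#' head(sim$truth)
#' @export
simulate_counts <- function(annotation, config) {
  validate_sim_config(config)
  stopifnot(all(c("gene_id", "length_nt", "category") %in% names(annotation)))
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  n <- nrow(annotation)

  abundance <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  gene_noise <- stats::rnorm(n, 0, config$binding_sd)

  propensity <- sapply(config$conditions, function(cond) {
    eff <- config$binding_effect[[cond]]
    shift <- eff[annotation$category]
    shift[is.na(shift)] <- 0
    2^(unname(shift) + gene_noise)
  })
  propensity <- matrix(propensity, nrow = n,
                       dimnames = list(NULL, config$conditions))

  size <- 1 / config$nb_dispersion
  mu_extract <- abundance * annotation$length_nt
  mu_extract <- mu_extract / sum(mu_extract) * config$libsize

  sample_meta <- expand.grid(
    replicate = seq_len(config$n_replicates),
    fraction = c("extract", "pulldown"),
    condition = config$conditions,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sample_meta$sample_id <- sprintf("%s_%s_rep%d", sample_meta$condition,
                                   sample_meta$fraction, sample_meta$replicate)
  sample_meta <- sample_meta[, c("sample_id", "fraction", "condition", "replicate")]

  counts <- matrix(0L, nrow = n, ncol = nrow(sample_meta),
                   dimnames = list(annotation$gene_id, sample_meta$sample_id))
  for (j in seq_len(nrow(sample_meta))) {
    cond <- sample_meta$condition[j]
    mu <- if (sample_meta$fraction[j] == "extract") {
      mu_extract
    } else {
      m <- abundance * annotation$length_nt * propensity[, cond]
      m / sum(m) * config$libsize
    }
    counts[, j] <- stats::rnbinom(n, size = size, mu = mu)
  }

  truth <- data.frame(
    gene_id = annotation$gene_id,
    category = annotation$category,
    length_nt = annotation$length_nt,
    abundance = abundance,
    stringsAsFactors = FALSE)
  for (cond in config$conditions) {
    truth[[paste0("propensity_", cond)]] <- propensity[, cond]
  }

  list(counts = count_table(counts, sample_meta), truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper producing annotation, counts and ground truth in one
#' call.
#'
#' @inheritParams simulate_counts
#' @return A list with `annotation`, `counts` and `truth`.
#' @export
simulate_dataset <- function(config) {
  annotation <- simulate_annotation(config)
  sim <- simulate_counts(annotation, config)
  list(annotation = annotation, counts = sim$counts, truth = sim$truth)
}

#' Simulate a qPCR Ct table from ground-truth abundances
#'
#' Cycle-of-threshold values follow the standard exponential model:
#' `Ct = intercept - log2(relative abundance) + Normal(0, noise_sd)`.
#' Extract/input samples report the true abundance; pull-down samples report
#' abundance multiplied by the gene's binding propensity in that sample's
#' condition.
#'
#' @param truth data frame with `gene_id`, `abundance` and, for pull-down
#'   samples, a `propensity_<condition>` column (as returned by
#'   [simulate_counts()], or built by hand).
#' @param samples data frame with columns `sample_id`, `role`
#'   (`"extract"`/`"input"` or `"pulldown"`/`"fraction"`), and optionally
#'   `condition` and `replicate` (default 1).
#' @param genes character vector of gene ids to measure (default: all in
#'   `truth`). Unknown ids are an error.
#' @param noise_sd Gaussian noise on Ct, in cycles.
#' @param intercept Ct of a transcript with relative abundance 1.
#' @param seed integer seed.
#' @return A data frame with columns `gene_id`, `sample_id`, `role`,
#'   `condition`, `replicate`, `ct`.
#' @examples
#' truth <- data.frame(gene_id = c("a", "b"), abundance = c(1, 4))
#' samples <- data.frame(sample_id = "s1", role = "extract")
#' ct <- simulate_ct(truth, samples, noise_sd = 0)
#' diff(ct$ct)  # 4-fold abundance => exactly -2 cycles
#' @export
simulate_ct <- function(truth, samples, genes = NULL, noise_sd = 0.2,
                        intercept = 35, seed = 1L) {
  stopifnot(all(c("gene_id", "abundance") %in% names(truth)),
            all(c("sample_id", "role") %in% names(samples)))
  if (is.null(genes)) genes <- truth$gene_id
  unknown <- setdiff(genes, truth$gene_id)
  if (length(unknown) > 0) {
    stop("genes not present in ground truth: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(samples$condition)) samples$condition <- NA_character_
  if (is.null(samples$replicate)) samples$replicate <- 1L
  set.seed(seed)

  idx <- match(genes, truth$gene_id)
  out <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    role <- samples$role[j]
    rel <- truth$abundance[idx]
    if (role %in% c("pulldown", "fraction")) {
      cond <- samples$condition[j]
      pcols <- grep("^propensity_", names(truth), value = TRUE)
      pcol <- if (!is.na(cond)) paste0("propensity_", cond) else pcols[1]
      if (is.na(pcol) || !pcol %in% names(truth)) {
        stop("no propensity column for pull-down sample ",
             samples$sample_id[j], call. = FALSE)
      }
      rel <- rel * truth[[pcol]][idx]
    }
    ct <- intercept - log2(rel) + stats::rnorm(length(rel), 0, noise_sd)
    out[[j]] <- data.frame(
      gene_id = genes,
      sample_id = samples$sample_id[j],
      role = role,
      condition = samples$condition[j],
      replicate = samples$replicate[j],
      ct = ct,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate an ORF-like sequence with U-rich segments
#'
#' Builds a DNA sequence of `3 * n_codons` nucleotides that starts with ATG,
#' ends with a TAA stop, contains no internal in-frame stop codons, and whose
#' designated codon segments carry an elevated T (= U in the transcript)
#' fraction, mimicking the uracil-rich stretches that encode transmembrane
#' helices. Within each segment the exact number of T positions is fixed to
#' the target fraction; outside segments bases are uniform over A,C,G,T.
#'
#' @param n_codons total codons including the start and terminal stop.
#' @param u_rich_segments list of numeric triples
#'   `c(start_codon, end_codon, target_U_fraction)` with 0-based, half-open
#'   codon coordinates inside `[0, n_codons)`; segments must not overlap and
#'   targets must lie in (0, 1).
#' @param seed integer seed.
#' @return A single character string of length `3 * n_codons`.
#' @examples
#' s <- simulate_orf(138, list(c(10, 30, 0.5)), seed = 1)
#' nchar(s)  # 414
#' @export
simulate_orf <- function(n_codons, u_rich_segments = list(), seed = 1L) {
  n_codons <- as.integer(n_codons)
  if (n_codons < 2) stop("n_codons must be >= 2", call. = FALSE)
  segs <- lapply(u_rich_segments, function(s) {
    if (length(s) != 3) {
      stop("each segment must be (start_codon, end_codon, target_U_fraction)",
           call. = FALSE)
    }
    list(start = as.integer(s[1]), end = as.integer(s[2]), target = s[3])
  })
  for (s in segs) {
    if (s$start < 0 || s$end > n_codons || s$start >= s$end) {
      stop("segment [", s$start, ", ", s$end, ") outside [0, ", n_codons, ")",
           call. = FALSE)
    }
    if (s$target <= 0 || s$target >= 1) {
      stop("target_U_fraction must be in (0, 1)", call. = FALSE)
    }
  }
  if (length(segs) > 1) {
    ord <- order(vapply(segs, `[[`, integer(1), "start"))
    segs <- segs[ord]
    for (i in seq_len(length(segs) - 1)) {
      if (segs[[i]]$end > segs[[i + 1]]$start) {
        stop("U-rich segments overlap", call. = FALSE)
      }
    }
  }

  set.seed(seed)
  len <- 3L * n_codons
  x <- character(len)
  x[1:3] <- c("A", "T", "G")
  x[(len - 2):len] <- c("T", "A", "A")
  fixed <- c(1:3, (len - 2):len)

  in_segment <- logical(len)
  for (s in segs) {
    pos <- (3L * s$start + 1L):(3L * s$end)
    in_segment[pos] <- TRUE
    free <- setdiff(pos, fixed)
    fixed_t <- sum(x[intersect(pos, fixed)] == "T")
    need_t <- round(s$target * length(pos)) - fixed_t
    need_t <- max(0L, min(length(free), need_t))
    t_pos <- if (need_t > 0) sample(free, need_t) else integer(0)
    x[t_pos] <- "T"
    rest <- setdiff(free, t_pos)
    x[rest] <- sample(c("A", "C", "G"), length(rest), replace = TRUE)
  }
  outside <- which(!in_segment & !seq_len(len) %in% fixed)
  x[outside] <- sample(c("A", "C", "G", "T"), length(outside), replace = TRUE)

  # recode internal in-frame stops with a T-count-preserving substitution
  for (i in setdiff(seq_len(n_codons - 1L), 1L)) {
    p <- 3L * (i - 1L) + 1L
    codon <- paste(x[p:(p + 2L)], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) {
      x[p + 2L] <- "C"  # TAA->TAC (Tyr), TAG->TAC, TGA->TGC (Cys)
    }
  }
  paste(x, collapse = "")
}
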