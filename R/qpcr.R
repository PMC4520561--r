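#' Fraction-to-input abundance ratio from Ct values
#'
#' One qPCR cycle is a two-fold difference in template, so the abundance of a
#' gene in a fraction (ribosomal pool, pull-down eluate, ...) relative to the
#' input extract is `2^(Ct_input - Ct_fraction)`. Vectorised; missing Ct
#' values (no amplification) yield `NA`, never 0.
#'
#' @param ct_input Ct of the input/extract.
#' @param ct_fraction Ct of the fraction/pull-down.
#' @return `2^(ct_input - ct_fraction)`.
#' @examples
#' fraction_ratio(22, 20)  # 4: the fraction holds 4x the input concentration
#' @export
fraction_ratio <- function(ct_input, ct_fraction) {
  bad <- (!is.na(ct_input) & (ct_input <= 0 | !is.finite(ct_input))) |
    (!is.na(ct_fraction) & (ct_fraction <= 0 | !is.finite(ct_fraction)))
  if (any(bad)) stop("Ct values must be finite and > 0", call. = FALSE)
  2^(ct_input - ct_fraction)
}

#' Per-gene fraction ratios from a Ct table
#'
#' Averages replicate Cts per (gene, role) — standard qPCR practice — and
#' applies [fraction_ratio()] to the mean Cts. The SEM column is computed
#' from per-replicate ratios where replicates pair up across roles.
#'
#' @param ct data frame with columns `gene_id`, `role`, `replicate`, `ct`
#'   (e.g. from [simulate_ct()] or [read_ct_table()]).
#' @param input_role,fraction_role role labels of the input and fraction
#'   samples.
#' @return Data frame `gene_id`, `ct_input`, `ct_fraction`, `ratio`, `sem`,
#'   `n_replicates`.
#' @export
ct_fraction_ratios <- function(ct, input_role = "extract",
                               fraction_role = "pulldown") {
  stopifnot(all(c("gene_id", "role", "ct") %in% names(ct)))
  if (is.null(ct$replicate)) ct$replicate <- 1L
  genes <- unique(ct$gene_id)
  out <- data.frame(gene_id = genes, ct_input = NA_real_,
                    ct_fraction = NA_real_, ratio = NA_real_, sem = NA_real_,
                    n_replicates = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    gi <- ct[ct$gene_id == genes[i], ]
    ci <- gi$ct[gi$role == input_role]
    cf <- gi$ct[gi$role == fraction_role]
    if (length(ci) == 0 || length(cf) == 0) next  # not detected in one role
    out$ct_input[i] <- mean(ci, na.rm = TRUE)
    out$ct_fraction[i] <- mean(cf, na.rm = TRUE)
    out$ratio[i] <- fraction_ratio(out$ct_input[i], out$ct_fraction[i])
    reps_i <- gi$replicate[gi$role == input_role]
    reps_f <- gi$replicate[gi$role == fraction_role]
    common <- intersect(reps_i, reps_f)
    out$n_replicates[i] <- length(common)
    if (length(common) >= 2) {
      per_rep <- vapply(common, function(r) {
        fraction_ratio(mean(gi$ct[gi$role == input_role & gi$replicate == r]),
                       mean(gi$ct[gi$role == fraction_role & gi$replicate == r]))
      }, numeric(1))
      out$sem[i] <- stats::sd(per_rep) / sqrt(length(per_rep))
    }
  }
  out
}

#' Relative quantities against an endogenous control and a calibrator
#'
#' Classic comparative-Ct quantification: within each sample,
#' `dCt(g) = mean Ct(g) - mean Ct(control)` (replicates averaged on the Ct
#' scale), per-gene dCt is averaged over the samples in which the gene was
#' measured, and `RQ(g) = 2^(dCt(calibrator) - dCt(g))`, so the calibrator
#' gene has RQ = 1 by construction. Because dCt is formed within a sample,
#' RQ is invariant to per-sample plate offsets.
#'
#' @param ct data frame with `gene_id`, `sample_id`, `replicate`, `ct`.
#' @param control_gene endogenous control present in every sample used
#'   (default `"rnpB"`, the RNase P RNA).
#' @param calibrator_gene gene whose RQ defines 1.
#' @param targets genes to quantify (default: all except the control).
#' @return Data frame `gene_id`, `delta_ct`, `rq`, `sem`, `n_samples`; SEM is
#'   over per-sample RQ values.
#' @export
relative_quantity <- function(ct, control_gene = "rnpB", calibrator_gene,
                              targets = NULL) {
  stopifnot(all(c("gene_id", "sample_id", "ct") %in% names(ct)))
  if (is.null(ct$replicate)) ct$replicate <- 1L
  if (!control_gene %in% ct$gene_id) {
    stop("control gene ", control_gene, " absent from the Ct table", call. = FALSE)
  }
  if (!calibrator_gene %in% ct$gene_id) {
    stop("calibrator gene ", calibrator_gene, " absent from the Ct table",
         call. = FALSE)
  }
  if (is.null(targets)) targets <- setdiff(unique(ct$gene_id), control_gene)

  mean_ct <- function(gene, sample) {
    v <- ct$ct[ct$gene_id == gene & ct$sample_id == sample]
    if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
  }
  delta_ct_per_sample <- function(gene) {
    samples <- unique(ct$sample_id[ct$gene_id == gene])
    vapply(samples, function(s) {
      ctrl <- mean_ct(control_gene, s)
      if (is.na(ctrl)) {
        stop("control gene ", control_gene, " missing from sample ", s,
             call. = FALSE)
      }
      mean_ct(gene, s) - ctrl
    }, numeric(1))
  }

  dct_cal <- mean(delta_ct_per_sample(calibrator_gene))
  out <- data.frame(gene_id = targets, delta_ct = NA_real_, rq = NA_real_,
                    sem = NA_real_, n_samples = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(targets)) {
    d <- delta_ct_per_sample(targets[i])
    out$delta_ct[i] <- mean(d)
    out$rq[i] <- 2^(dct_cal - out$delta_ct[i])
    out$n_samples[i] <- length(d)
    if (length(d) >= 2) {
      per_sample_rq <- 2^(dct_cal - d)
      out$sem[i] <- stats::sd(per_sample_rq) / sqrt(length(d))
    }
  }
  out
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 relative input over a dilution
#' series. A perfect assay doubles template every cycle, giving slope
#' `-1/log10(2) = -3.32`; amplification efficiency is
#' `10^(-1/slope) - 1`. The conventional primer QC window accepts
#' `-3.6 <= slope <= -3` with `R^2 > 0.995`.
#'
#' @param log10_input numeric vector of log10 relative template amounts
#'   (or a 2-column data frame `log10_input`, `ct`).
#' @param ct Ct values, same length.
#' @return A list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `qc_pass`, `n_points`, `points`.
#' @examples
#' curve <- fit_standard_curve(0:-4, 20 + 3.321928 * (0:4))
#' curve$qc_pass
#' @export
fit_standard_curve <- function(log10_input, ct) {
  if (is.data.frame(log10_input)) {
    ct <- log10_input$ct
    log10_input <- log10_input$log10_input
  }
  stopifnot(length(log10_input) == length(ct))
  keep <- stats::complete.cases(log10_input, ct)
  x <- log10_input[keep]; y <- ct[keep]
  if (length(unique(x)) < 3) {
    stop("standard curve needs >= 3 distinct input levels", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("zero variance in input levels", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r_squared <- 1 - ss_res / ss_tot
  efficiency <- 10^(-1 / slope) - 1
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, efficiency = efficiency,
                 qc_pass = slope >= -3.6 && slope <= -3 && r_squared > 0.995,
                 n_points = length(y),
                 points = data.frame(log10_input = x, ct = y)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: slope %.4f, intercept %.2f, R^2 %.5f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  efficiency %.1f%%, QC %s (-3.6 <= slope <= -3, R^2 > 0.995)\n",
              100 * x$efficiency, if (x$qc_pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Normalise densitometry signals to a reference lane
#'
#' @param values named numeric vector of lane signals.
#' @param reference name of the reference lane (its value becomes 100%).
#' @return Named numeric vector of percentages.
#' @examples
#' densitometry_normalize(c(Ra = 8, Rb = 4), "Ra")
#' @export
densitometry_normalize <- function(values, reference) {
  stopifnot(!is.null(names(values)))
  if (!reference %in% names(values)) {
    stop("reference lane ", reference, " not found", call. = FALSE)
  }
  ref <- values[[reference]]
  if (is.na(ref) || ref <= 0) {
    stop("reference signal must be > 0", call. = FALSE)
  }
  100 * values / ref
}
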