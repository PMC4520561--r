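#' Simulation configuration for synthetic pull-down datasets
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' gene universe composition, length and abundance distributions, per-category
#' binding effects per condition, replication, library size and
#' negative-binomial dispersion.
#'
#' Defaults emulate a bacterial pull-down experiment: ~17% of mRNAs encode
#' multi-pass membrane proteins (MPR), half encode cytoplasmic proteins (CPR),
#' a small secretory class (SPR), a handful of cold-shock-protein transcripts
#' (CSP), and the remainder uncategorised. Two Mg2+ conditions are simulated,
#' with a stronger membrane-protein binding preference at high Mg2+.
#'
#' @param n_genes number of genes to simulate (>= 10).
#' @param category_fractions named numeric vector of category proportions,
#'   names from `MPR, CPR, SPR, CSP, OTHER, NONCODING`; must sum to 1.
#' @param length_meanlog,length_sdlog log-normal parameters for gene length
#'   in nucleotides (lengths are floored at 90 nt and rounded).
#' @param abundance_meanlog,abundance_sdlog log-normal parameters for true
#'   relative extract abundance.
#' @param conditions character vector of condition labels.
#' @param binding_effect named list, one element per condition, each a named
#'   numeric vector of log2 binding-propensity shifts per category. Categories
#'   absent from a vector get effect 0. `NULL` builds a default in which MPRs
#'   are enriched and CPRs depleted, more strongly under the second condition.
#' @param binding_sd standard deviation (log2 units) of gene-level binding
#'   noise around the category effect.
#' @param n_replicates replicate libraries per (condition, fraction).
#' @param libsize expected total reads per library.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0. Values near zero approach Poisson.
#' @param ct_intercept qPCR cycle threshold for a transcript of relative
#'   abundance 1 (Ct = intercept - log2(abundance)).
#' @param seed integer seed governing all generators driven by this config.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 42)
#' cfg$category_fractions
#' @export
sim_config <- function(n_genes = 2000,
                       category_fractions = c(MPR = 0.17, CPR = 0.50,
                                              SPR = 0.15, CSP = 0.005,
                                              OTHER = 0.175),
                       length_meanlog = log(900),
                       length_sdlog = 0.45,
                       abundance_meanlog = 0,
                       abundance_sdlog = 1.5,
                       conditions = c("Mg2", "Mg15"),
                       binding_effect = NULL,
                       binding_sd = 0.25,
                       n_replicates = 3,
                       libsize = 2e6,
                       nb_dispersion = 0.05,
                       ct_intercept = 35,
                       seed = 1L) {
  if (is.null(binding_effect)) {
    binding_effect <- default_binding_effect(conditions)
  }
  cfg <- structure(
    list(n_genes = as.integer(n_genes),
         category_fractions = category_fractions,
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog,
         conditions = as.character(conditions),
         binding_effect = binding_effect,
         binding_sd = binding_sd,
         n_replicates = as.integer(n_replicates),
         libsize = libsize,
         nb_dispersion = nb_dispersion,
         ct_intercept = ct_intercept,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
gene_categories <- function() {
  c("MPR", "CPR", "SPR", "CSP", "OTHER", "NONCODING")
}

default_binding_effect <- function(conditions) {
  # first condition: moderate MPR preference; later conditions stronger,
  # while CSP-mRNA association is strongest at low Mg2+
  base <- c(MPR = 1, CPR = -0.5, SPR = -0.5, CSP = 1.5, OTHER = 0)
  high <- c(MPR = 1.5, CPR = -0.75, SPR = -0.75, CSP = 1, OTHER = 0)
  eff <- vector("list", length(conditions))
  names(eff) <- conditions
  for (i in seq_along(conditions)) {
    eff[[i]] <- if (i == 1) base else high
  }
  eff
}

validate_sim_config <- function(cfg) {
  fr <- cfg$category_fractions
  if (is.null(names(fr)) || any(names(fr) == "")) {
    stop("category_fractions must be a fully named vector", call. = FALSE)
  }
  bad <- setdiff(names(fr), gene_categories())
  if (length(bad) > 0) {
    stop("unknown categories in category_fractions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(fr < 0)) stop("category_fractions must be non-negative", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("category_fractions must sum to 1 (got ", sum(fr), ")", call. = FALSE)
  }
  if (cfg$n_genes < 10) stop("n_genes must be >= 10", call. = FALSE)
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (cfg$libsize <= 0) stop("libsize must be > 0", call. = FALSE)
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (cfg$binding_sd < 0) stop("binding_sd must be >= 0", call. = FALSE)
  if (length(cfg$conditions) < 1) stop("need at least one condition", call. = FALSE)
  missing_cond <- setdiff(cfg$conditions, names(cfg$binding_effect))
  if (length(missing_cond) > 0) {
    stop("binding_effect missing conditions: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  genes:      ", x$n_genes, "\n")
  cat("  categories: ",
      paste(sprintf("%s=%.3g", names(x$category_fractions),
                    x$category_fractions), collapse = " "), "\n")
  cat("  conditions: ", paste(x$conditions, collapse = ", "),
      " x ", x$n_replicates, " replicates\n", sep = "")
  cat("  libsize:    ", format(x$libsize, big.mark = ","),
      "  dispersion: ", x$nb_dispersion, "\n")
  cat("  seed:       ", x$seed, "\n")
  invisible(x)
}

# Largest-remainder apportionment of n among the given fractions.
# Ties in the fractional remainders are broken by vector order.
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
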