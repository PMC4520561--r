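#' Read and write the pipeline's plain-text table formats
#'
#' Annotation tables are tab-separated with columns `gene_id`, `length_nt`,
#' `category`; count tables are tab-separated with `gene_id` first and one
#' column per sample, accompanied by a sample-metadata sidecar (`sample_id`,
#' `fraction`, `condition`, `replicate`); Ct tables are comma-separated with
#' `gene_id`, `sample_id`, `replicate`, `ct` (plus optional `role`,
#' `condition`).
#'
#' @param path file path.
#' @name bindscape-io
NULL

#' @rdname bindscape-io
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_annotation(ann)
  ann
}

#' @rdname bindscape-io
#' @param annotation an annotation data frame.
#' @export
write_annotation <- function(annotation, path) {
  check_annotation(annotation)
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname bindscape-io
#' @param samples_path path of the sample-metadata sidecar TSV.
#' @export
read_counts <- function(path, samples_path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1]]
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  count_table(m, samples)
}

#' @rdname bindscape-io
#' @param counts a [count_table()].
#' @export
write_counts <- function(counts, path, samples_path) {
  stopifnot(inherits(counts, "count_table"))
  tab <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(counts$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname bindscape-io
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "sample_id", "ct") %in% names(ct)))
  ct
}

#' @rdname bindscape-io
#' @param ct a Ct data frame.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname bindscape-io
#' @param binding a `binding_table`.
#' @export
write_binding_table <- function(binding, path) {
  utils::write.table(binding, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings; sequences are handled in this package as
#' plain named character vectors.
#'
#' @param path FASTA file path.
#' @return `read_sequences()`: named character vector of sequences.
#' @export
read_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_sequences
#' @param sequences named character vector of nucleotide sequences.
#' @export
write_sequences <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Emits the annotation TSV, counts TSV with its sample sidecar, and the
#' ground-truth TSV, so a dataset can be regenerated, inspected or consumed
#' by external tools.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_annotation(dataset$annotation, file.path(dir, "annotation.tsv"))
  write_counts(dataset$counts, file.path(dir, "counts.tsv"),
               file.path(dir, "samples.tsv"))
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
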