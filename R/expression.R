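# TPM quantification of metatranscriptome gene counts, per-genome
# highly-expressed flags, and genome / gene-set aggregation.

#' Transcripts per million from gene read counts
#'
#' TPM for gene g is (rg x rl x 1e6) / (flg x T) where rg is the number of
#' reads mapped to the gene, rl the (constant) read length, flg the feature
#' (CDS) length in nucleotides, and T the sum of rg x rl / flg over all
#' genes. The read length cancels between numerator and denominator, so TPM
#' is invariant to rl; it is kept in the interface because the definition
#' carries it. TPM sums to 1e6 over all genes.
#'
#' @param counts Nonnegative integer read counts per gene.
#' @param lengths Positive feature lengths (nt), parallel to `counts`.
#' @param readLength Constant read length in nt (default 150, as for
#'   2 x 150 bp paired-end sequencing).
#' @return Numeric TPM vector (named like `counts` if it has names).
#' @examples
#' computeTPM(c(10, 30), c(100, 300))  # both 5e5
#' @export
computeTPM <- function(counts, lengths, readLength = 150) {
  if (length(counts) != length(lengths))
    stop("'counts' and 'lengths' lengths differ", call. = FALSE)
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  if (any(counts < 0)) stop("read counts must be >= 0", call. = FALSE)
  if (readLength <= 0) stop("'readLength' must be > 0", call. = FALSE)
  # rl cancels between numerator and T, so it is factored out here; this
  # also makes TPM exactly (not just approximately) invariant to rl
  perGene <- counts / lengths
  total <- sum(perGene)
  if (total == 0)
    stop("degenerate input: all read counts are zero (T = 0)", call. = FALSE)
  perGene * 1e6 / total
}

#' Flag genes expressed above their genome's median TPM
#'
#' A gene is highly expressed when its TPM is strictly greater than the
#' median TPM over all genes of the same genome (zero-count genes
#' included; for an even number of genes the median is the mean of the
#' central pair). With a single gene, or all genes tied, no gene exceeds
#' its own median and none is flagged.
#'
#' @param table data.frame with columns `genome_id` and `tpm`.
#' @return Logical vector parallel to the rows of `table`.
#' @examples
#' highlyExpressedFlags(data.frame(genome_id = "g",
#'                                 tpm = c(0, 10, 20)))  # F F T
#' @export
highlyExpressedFlags <- function(table) {
  stopifnot(all(c("genome_id", "tpm") %in% names(table)))
  med <- stats::ave(table$tpm, table$genome_id,
                    FUN = function(x) stats::median(x))
  table$tpm > med
}

#' Per-genome percentage of total community TPM
#'
#' @param table data.frame with columns `genome_id` and `tpm`.
#' @return Named numeric vector of percentages summing to 100, one entry
#'   per genome (full-community denominator).
#' @export
genomeExpressionFraction <- function(table) {
  stopifnot(all(c("genome_id", "tpm") %in% names(table)))
  if (!nrow(table)) stop("empty expression table", call. = FALSE)
  s <- tapply(table$tpm, table$genome_id, sum)
  stats::setNames(as.numeric(100 * s / sum(s)), names(s))
}

#' Sum TPM over labelled gene sets, per genome
#'
#' Genes carrying several labels contribute to each. Requested labels with
#' no genes anywhere in the map produce zero rows and a warning.
#'
#' @param table data.frame with `gene_id`, `genome_id`, `tpm`.
#' @param sets data.frame with `gene_id` and `labels` (semicolon-separated
#'   set labels, e.g. KO ids, pathway modules, or `"MHC"`).
#' @param labels Character vector of labels to aggregate.
#' @return data.frame `genome_id`, `label`, `tpm_sum` for every
#'   genome x requested-label combination.
#' @export
aggregateSetTPM <- function(table, sets, labels) {
  stopifnot(all(c("gene_id", "genome_id", "tpm") %in% names(table)),
            all(c("gene_id", "labels") %in% names(sets)),
            length(labels) > 0)
  lab_list <- strsplit(as.character(sets$labels), ";")
  long <- data.frame(
    gene_id = rep(sets$gene_id, lengths(lab_list)),
    label = trimws(unlist(lab_list)), stringsAsFactors = FALSE)
  unknown <- setdiff(labels, unique(long$label))
  if (length(unknown))
    warning(sprintf("label(s) not present in gene-set map: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  genomes <- sort(unique(table$genome_id))
  out <- expand.grid(genome_id = genomes, label = labels,
                     stringsAsFactors = FALSE)
  out$tpm_sum <- mapply(function(g, l) {
    ids <- long$gene_id[long$label == l]
    sum(table$tpm[table$genome_id == g & table$gene_id %in% ids])
  }, out$genome_id, out$label)
  out
}

#' Build an expression table from a counts table
#'
#' Computes TPM per Eq.-style normalization and the per-genome
#' highly-expressed flags in one step.
#'
#' @param counts data.frame with `gene_id`, `genome_id`, `read_count`,
#'   `feature_length_nt`.
#' @param readLength Constant read length, nt (default 150).
#' @return The input with `tpm` and `highly_expressed` columns appended.
#' @export
buildExpressionTable <- function(counts, readLength = 150) {
  stopifnot(all(c("gene_id", "genome_id", "read_count",
                  "feature_length_nt") %in% names(counts)))
  counts$tpm <- computeTPM(counts$read_count, counts$feature_length_nt,
                           readLength)
  counts$highly_expressed <- highlyExpressedFlags(counts)
  counts
}
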