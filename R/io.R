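# Readers and writers for the pipeline's on-disk formats: reactor series
# TSV, evidence tables, GFF3 gene tables, counts tables, gene-set maps,
# protein FASTA and precomputed hit tables.

.readTSV <- function(path, required, what) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop(sprintf("%s '%s' is missing column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  d
}

#' Read a reactor time-series TSV (plus optional feed events)
#'
#' Expected columns: `day`, `methane_umol_per_L`, `mn2_dissolved`,
#' `mn2_adsorbed`, `mn2_carbonate` (optional `fe2_dissolved`, `fe2_total`).
#' The feed-event TSV has columns `day`, `birnessite_g`.
#'
#' @param path Series TSV path.
#' @param feedPath Optional feed-event TSV path.
#' @return A [ReactorSeries-class].
#' @export
readReactorSeries <- function(path, feedPath = NULL) {
  d <- .readTSV(path, .REACTOR_COLS, "reactor series")
  feed <- if (!is.null(feedPath))
    .readTSV(feedPath, c("day", "birnessite_g"), "feed events") else NULL
  reactorSeries(d, feed)
}

#' Write a reactor series to TSV
#'
#' @param series A [ReactorSeries-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeReactorSeries <- function(series, path) {
  utils::write.table(seriesData(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a localization/domain evidence table
#'
#' TSV with columns `gene_id`, `signal_peptide` (TRUE/FALSE or yes/no),
#' `localization` (extracellular/membrane/cytoplasmic/unknown), `domains`
#' (semicolon-separated labels; may be empty).
#'
#' @param path TSV path.
#' @return data.frame with `signal_peptide` coerced to logical.
#' @export
readEvidenceTable <- function(path) {
  d <- .readTSV(path, c("gene_id", "signal_peptide", "localization"),
                "evidence table")
  sp <- tolower(as.character(d$signal_peptide))
  d$signal_peptide <- sp %in% c("true", "yes", "1", "t", "y")
  if (!"domains" %in% names(d)) d$domains <- ""
  d$domains[is.na(d$domains)] <- ""
  d
}

#' Read a gene table from GFF3 or TSV
#'
#' GFF3 CDS features (1-based inclusive coordinates, `ID` attribute as the
#' gene id, `product` as the functional label) or a TSV with columns
#' `gene_id`, `contig`, `start`, `end`, `strand` and optional `label`.
#' Coordinates are kept 1-based inclusive in the returned table; the
#' cluster-context logic works on gene ranks, not base positions.
#'
#' @param path `.gff`/`.gff3` or `.tsv` path.
#' @return data.frame `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `label`.
#' @export
readGeneTable <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type %in% c("CDS", "gene")]
    md <- as.data.frame(gr)
    d <- data.frame(
      gene_id = as.character(md$ID), contig = as.character(md$seqnames),
      start = md$start, end = md$end, strand = as.character(md$strand),
      label = if ("product" %in% names(md))
        ifelse(is.na(md$product), "", as.character(md$product)) else "",
      stringsAsFactors = FALSE)
  } else {
    d <- .readTSV(path, c("gene_id", "contig", "start", "end", "strand"),
                  "gene table")
    if (!"label" %in% names(d)) d$label <- ""
  }
  if (any(d$start > d$end) || any(d$start <= 0))
    stop("gene coordinates must satisfy 0 < start <= end", call. = FALSE)
  d
}

#' Write a gene table as GFF3
#'
#' CDS features, 1-based inclusive coordinates, `ID` and `product`
#' attributes.
#'
#' @param genes Gene table data.frame (see [readGeneTable()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmnAOM\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
                     genes$contig, genes$start, genes$end, genes$strand,
                     genes$gene_id,
                     if ("label" %in% names(genes)) genes$label else ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-gene counts table
#'
#' TSV with columns `gene_id`, `genome_id`, `read_count`,
#' `feature_length_nt`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readCountsTable <- function(path) {
  .readTSV(path, c("gene_id", "genome_id", "read_count",
                   "feature_length_nt"), "counts table")
}

#' Read a gene-set map
#'
#' TSV with columns `gene_id`, `labels` (semicolon-separated set labels).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readGeneSetMap <- function(path) {
  .readTSV(path, c("gene_id", "labels"), "gene-set map")
}

#' Read a protein FASTA as a named AAStringSet
#'
#' Headers are truncated at the first whitespace to yield gene ids.
#'
#' @param path FASTA path.
#' @return A named `Biostrings::AAStringSet`.
#' @export
readProteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  aa
}

#' Write a proteome FASTA
#'
#' @param proteins Named `AAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(proteins, path) {
  Biostrings::writeXStringSet(.asAAStringSet(proteins), path)
  invisible(path)
}

#' Read a precomputed tabular hit file (BLAST outfmt-6-like subset)
#'
#' TSV with columns `query_id`, `subject_id`, `score`, `identity` — the
#' import path for hits computed by an external aligner on real data.
#'
#' @param path TSV path.
#' @return data.frame usable wherever [reciprocalBestHits()] output is.
#' @export
readHitsTable <- function(path) {
  .readTSV(path, c("query_id", "subject_id", "score", "identity"),
           "hits table")
}

#' Write synthetic fixtures to a directory
#'
#' Serializes a [simulateProteome()] result to the formats the pipeline
#' reads (protein FASTA, evidence TSV, GFF3 gene table, truth TSV) plus a
#' `manifest.json` recording the seed.
#'
#' @param sim A [simulateProteome()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
writeProteomeFixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteome = file.path(dir, "proteome.faa"),
    evidence = file.path(dir, "evidence.tsv"),
    genes = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeProteome(sim$proteins, paths[["proteome"]])
  utils::write.table(sim$evidence, paths[["evidence"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGeneTable(sim$genes, paths[["genes"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = sim$seed, genome_id = sim$genome_id,
                            n_proteins = nrow(sim$truth)),
                       paths[["manifest"]], auto_unbox = TRUE)
  invisible(paths)
}
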