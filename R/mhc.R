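# Multiheme c-type cytochrome (MHC) screen: CXXCH heme-binding motif
# scanning, classification, localization/S-layer flags and gene-cluster
# context.

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

# default labels marking menaquinone:cytochrome-c-oxidoreductase components
.OXIDOREDUCTASE_PATTERN <-
  "b-type cytochrome|cytochrome b|\\bcytb\\b|nrfd|4fe-4s|ferredoxin|bc1|b6f"

.motifToRegex <- function(pattern) {
  if (!grepl("^[A-Z]+$", pattern))
    stop("motif pattern must be uppercase letters (X = any residue)",
         call. = FALSE)
  paste0("(?=", gsub("X", ".", pattern, fixed = TRUE), ")")
}

#' Scan a protein sequence for CXXCH heme-binding motifs
#'
#' Finds every position where the canonical heme-c attachment motif
#' Cys-X-X-Cys-His occurs. Matches are located with a lookahead so that
#' overlapping occurrences are all counted. Offsets are 0-based.
#'
#' @param sequence A single uppercase amino-acid string (standard 20
#'   residues plus X).
#' @param patterns Character vector of motif patterns, `X` meaning any
#'   residue (default the canonical `"CXXCH"`; variants such as `"CXXXCH"`
#'   may be added).
#' @return Sorted integer vector of 0-based motif start offsets.
#' @examples
#' scanHemeMotifs("MACAACHGG")  # 3
#' @export
scanHemeMotifs <- function(sequence, patterns = "CXXCH") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  chars <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(chars), .AA_ALPHABET)
  if (length(bad))
    stop(sprintf("invalid residues in sequence: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  hits <- integer()
  for (p in patterns) {
    m <- gregexpr(.motifToRegex(p), sequence, perl = TRUE)[[1L]]
    if (m[1L] != -1L) hits <- c(hits, as.integer(m) - 1L)
  }
  sort(unique(hits))
}

.emptyEvidenceRow <- function(gene_id) {
  data.frame(gene_id = gene_id, signal_peptide = FALSE,
             localization = "unknown", domains = "",
             stringsAsFactors = FALSE)
}

.evidenceRow <- function(gene_id, evidence, warn = TRUE) {
  if (is.null(evidence) || !nrow(evidence)) {
    if (warn) warning(sprintf("gene '%s' absent from evidence table",
                              gene_id), call. = FALSE)
    return(.emptyEvidenceRow(gene_id))
  }
  i <- match(gene_id, evidence$gene_id)
  if (is.na(i)) {
    if (warn) warning(sprintf("gene '%s' absent from evidence table",
                              gene_id), call. = FALSE)
    return(.emptyEvidenceRow(gene_id))
  }
  evidence[i, , drop = FALSE]
}

.hasDomain <- function(domains, pattern) {
  if (is.na(domains) || !nzchar(domains)) return(FALSE)
  any(grepl(pattern, strsplit(domains, ";")[[1L]], ignore.case = TRUE))
}

#' Classify a protein as a putative multiheme cytochrome
#'
#' A protein is a putative MHC when it carries at least `minMotifs` CXXCH
#' motifs (default 3, one motif per covalently bound heme c). A
#' cytochrome-domain hit in the evidence table is recorded as corroboration
#' but is not required for classification.
#'
#' @param sequence Amino-acid string.
#' @param geneId,genomeId Identifiers carried into the annotation.
#' @param evidence Optional evidence data.frame (`gene_id`,
#'   `signal_peptide`, `localization`, `domains`; domains
#'   semicolon-separated).
#' @param minMotifs Minimum motif count for MHC status (>= 1, default 3).
#' @param patterns Motif patterns for [scanHemeMotifs()].
#' @return One-row data.frame with `gene_id`, `genome_id`,
#'   `heme_motif_count`, `motif_positions` (comma-joined 0-based offsets),
#'   `is_mhc`, `cytochrome_domain`, `is_extracellular_candidate`,
#'   `is_slayer_fusion`, `cluster_context` (initialized `"standalone"`).
#' @export
classifyMHC <- function(sequence, geneId, genomeId = NA_character_,
                        evidence = NULL, minMotifs = 3, patterns = "CXXCH") {
  if (minMotifs < 1) stop("'minMotifs' must be >= 1", call. = FALSE)
  pos <- scanHemeMotifs(sequence, patterns)
  is_mhc <- length(pos) >= minMotifs
  ev <- .evidenceRow(geneId, evidence, warn = !is.null(evidence))
  data.frame(
    gene_id = geneId, genome_id = genomeId,
    heme_motif_count = length(pos),
    motif_positions = paste(pos, collapse = ","),
    is_mhc = is_mhc,
    cytochrome_domain = .hasDomain(ev$domains, "cytochrome"),
    is_extracellular_candidate = flagExtracellular(is_mhc, ev),
    is_slayer_fusion = detectSlayerFusion(is_mhc, ev),
    cluster_context = "standalone",
    stringsAsFactors = FALSE)
}

#' Flag an MHC as an extracellular electron-transfer candidate
#'
#' True when the protein is an MHC and carries a signal peptide and/or is
#' predicted extracellular ("and/or" read as inclusive OR). Non-MHCs are
#' never flagged.
#'
#' @param isMhc Logical MHC status.
#' @param evidenceRow One evidence row (`signal_peptide`, `localization`).
#' @return Logical.
#' @export
flagExtracellular <- function(isMhc, evidenceRow) {
  if (!isTRUE(isMhc)) return(FALSE)
  isTRUE(as.logical(evidenceRow$signal_peptide)) ||
    identical(as.character(evidenceRow$localization), "extracellular")
}

#' Detect an MHC/S-layer fusion protein
#'
#' True when the protein is an MHC and an S-layer domain appears among its
#' domain hits. Such fusions are candidates for conducting electrons across
#' the archaeal surface layer.
#'
#' @param isMhc Logical MHC status.
#' @param evidenceRow One evidence row with a `domains` field
#'   (semicolon-separated labels).
#' @return Logical.
#' @export
detectSlayerFusion <- function(isMhc, evidenceRow) {
  if (!isTRUE(isMhc)) return(FALSE)
  .hasDomain(evidenceRow$domains, "s-layer|s_layer|slayer")
}

#' Annotate MHCs with menaquinone-oxidoreductase gene-cluster context
#'
#' An MHC is in `"oxidoreductase-cluster"` context when a gene labelled as
#' a menaquinone:cytochrome-c oxidoreductase component (b-type cytochrome,
#' NrfD-like, 4Fe-4S ferredoxin, bc1/b6f-like) lies within `window` genes
#' up- or downstream on the same contig (strand-agnostic, gene-rank
#' distance); otherwise `"standalone"`. MHCs missing from the gene table
#' stay `"standalone"` with a warning.
#'
#' @param annotations Annotation data.frame from [classifyMHC()] /
#'   [screenGenome()].
#' @param genes Gene table data.frame: `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `label` (free-text functional label).
#' @param window Number of neighbouring genes on each side (default 5).
#' @param oxidoreductasePattern Regex matched (case-insensitively) against
#'   neighbour labels.
#' @return `annotations` with `cluster_context` filled in.
#' @export
annotateClusterContext <- function(annotations, genes, window = 5,
                                   oxidoreductasePattern =
                                     .OXIDOREDUCTASE_PATTERN) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "contig", "start") %in% names(genes)))
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  annotations$cluster_context <- "standalone"
  for (r in which(annotations$is_mhc)) {
    gid <- annotations$gene_id[r]
    i <- match(gid, genes$gene_id)
    if (is.na(i)) {
      warning(sprintf("MHC gene '%s' missing coordinates; context standalone",
                      gid), call. = FALSE)
      next
    }
    same <- which(genes$contig == genes$contig[i])
    rank <- match(i, same)
    neigh <- same[seq(max(1L, rank - window),
                      min(length(same), rank + window))]
    neigh <- setdiff(neigh, i)
    lab <- if ("label" %in% names(genes)) genes$label[neigh] else character()
    if (length(lab) && any(grepl(oxidoreductasePattern, lab,
                                 ignore.case = TRUE)))
      annotations$cluster_context[r] <- "oxidoreductase-cluster"
  }
  annotations
}

#' Screen a genome's proteome for multiheme cytochromes
#'
#' Runs the CXXCH motif scan over every protein, classifies MHCs, applies
#' the extracellular and S-layer-fusion flags from the evidence table, and
#' (when a gene table is supplied) annotates oxidoreductase gene-cluster
#' context. An empty proteome yields an empty report.
#'
#' @param proteome A named `Biostrings::AAStringSet` (names are gene ids)
#'   or a named character vector of sequences.
#' @param evidence Optional evidence data.frame (see [classifyMHC()]).
#' @param genes Optional gene table (see [annotateClusterContext()]).
#' @param genomeId Genome identifier recorded on the report.
#' @param minMotifs Minimum motif count (default 3).
#' @param patterns Motif patterns (default `"CXXCH"`).
#' @param window Cluster-context window (default 5).
#' @return An [MHCScreenReport-class].
#' @examples
#' screenGenome(c(g1 = "MACAACHCAACHWCAACH", g2 = "MKKLL"), genomeId = "demo")
#' @export
screenGenome <- function(proteome, evidence = NULL, genes = NULL,
                         genomeId = "genome", minMotifs = 3,
                         patterns = "CXXCH", window = 5) {
  ids <- names(proteome)
  seqs <- stats::setNames(as.character(proteome), ids)
  if (length(seqs) && (is.null(ids) || any(!nzchar(ids))))
    stop("proteome sequences must be named by gene id", call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene_id in proteome: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  ann <- do.call(rbind, lapply(seq_along(seqs), function(i)
    classifyMHC(seqs[[i]], ids[i], genomeId, evidence,
                minMotifs = minMotifs, patterns = patterns)))
  if (is.null(ann))
    ann <- classifyMHC("A", "..", genomeId)[0L, , drop = FALSE]
  if (!is.null(genes) && any(ann$is_mhc))
    ann <- annotateClusterContext(ann, genes, window = window)
  summary <- list(
    n_proteins = nrow(ann),
    n_mhc = sum(ann$is_mhc),
    n_extracellular = sum(ann$is_extracellular_candidate),
    n_slayer_fusion = sum(ann$is_slayer_fusion),
    n_oxidoreductase_cluster =
      sum(ann$is_mhc & ann$cluster_context == "oxidoreductase-cluster"),
    n_standalone = sum(ann$is_mhc & ann$cluster_context == "standalone"))
  new("MHCScreenReport", annotations = ann, summary = summary,
      genomeId = genomeId)
}
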