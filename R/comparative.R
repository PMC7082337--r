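# Reciprocal-best-hit orthology, average amino acid identity (AAI),
# MHC ortholog families and Ward hierarchical clustering.

.asAAStringSet <- function(x) {
  if (methods::is(x, "AAStringSet")) x
  else Biostrings::AAStringSet(unlist(as.list(x)))
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties and a
#' BLOSUM62 substitution matrix (a desk-scale stand-in for BLAST scoring in
#' reciprocal-best-hit searches). Identity is the percentage of aligned
#' columns — including gapped columns — that are identical residue matches.
#'
#' @param seqA,seqB Amino-acid strings (non-empty).
#' @param substitutionMatrix Name of a predefined matrix or a matrix
#'   (default `"BLOSUM62"`).
#' @param gapOpening,gapExtension Positive gap costs (defaults 10 and 0.5).
#' @return data.frame row: `score`, `identity` (percent), `aligned_columns`,
#'   plus the aligned strings `aligned_a`, `aligned_b`.
#' @examples
#' globalAlign("HEAGAWGHEE", "PAWHEAE")
#' @export
globalAlign <- function(seqA, seqB, substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5) {
  if (!nzchar(seqA) || !nzchar(seqB))
    stop("sequences must be non-empty", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  matches <- sum(pa == sa & pa != "-")
  cols <- length(pa)
  data.frame(score = Biostrings::score(aln),
             identity = 100 * matches / cols,
             aligned_columns = cols,
             aligned_a = paste(pa, collapse = ""),
             aligned_b = paste(sa, collapse = ""),
             stringsAsFactors = FALSE)
}

.scoreMatrix <- function(A, B, substitutionMatrix, gapOpening, gapExtension) {
  S <- matrix(NA_real_, length(A), length(B),
              dimnames = list(names(A), names(B)))
  for (i in seq_along(A)) {
    S[i, ] <- Biostrings::pairwiseAlignment(
      rep(A[i], length(B)), B, type = "global",
      substitutionMatrix = substitutionMatrix,
      gapOpening = gapOpening, gapExtension = gapExtension,
      scoreOnly = TRUE)
  }
  S
}

.bestHit <- function(scores) {
  # unique best hit with deterministic lexicographic tie-break
  best <- max(scores)
  cand <- sort(names(scores)[scores == best])
  cand[1L]
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is reported when b is a's highest-scoring hit in proteome
#' B and a is b's highest-scoring hit in A, under global alignment scores.
#' Score ties are broken by lexicographic gene id, so the result is
#' deterministic and symmetric in the order of the two proteomes. Pairs
#' whose score falls below `scoreFloor` are discarded (unrelated proteins
#' score negatively under BLOSUM62 global alignment).
#'
#' @param proteomeA,proteomeB Named `AAStringSet`s (or named character
#'   vectors) of protein sequences.
#' @param substitutionMatrix,gapOpening,gapExtension See [globalAlign()].
#' @param scoreFloor Minimum alignment score for a reported pair
#'   (default 0).
#' @return data.frame `query_id`, `subject_id`, `score`, `identity`
#'   (percent identical aligned columns for the pair's global alignment).
#' @export
reciprocalBestHits <- function(proteomeA, proteomeB,
                               substitutionMatrix = "BLOSUM62",
                               gapOpening = 10, gapExtension = 0.5,
                               scoreFloor = 0) {
  A <- .asAAStringSet(proteomeA); B <- .asAAStringSet(proteomeB)
  if (!length(A) || !length(B))
    stop("both proteomes must be non-empty", call. = FALSE)
  if (is.null(names(A)) || is.null(names(B)))
    stop("proteomes must be named by gene id", call. = FALSE)
  S <- .scoreMatrix(A, B, substitutionMatrix, gapOpening, gapExtension)
  rowOf <- function(a) stats::setNames(S[a, ], colnames(S))
  colOf <- function(b) stats::setNames(S[, b], rownames(S))
  bestB <- vapply(rownames(S), function(a) .bestHit(rowOf(a)), character(1))
  bestA <- vapply(colnames(S), function(b) .bestHit(colOf(b)), character(1))
  keep <- names(bestB)[bestA[bestB] == names(bestB) &
                         S[cbind(names(bestB), bestB)] >= scoreFloor]
  keep <- sort(keep)
  if (!length(keep))
    return(data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(keep, function(a) {
    b <- bestB[[a]]
    aln <- globalAlign(as.character(A[[a]]), as.character(B[[b]]),
                       substitutionMatrix, gapOpening, gapExtension)
    data.frame(query_id = a, subject_id = b, score = aln$score,
               identity = aln$identity, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Average amino acid identity from ortholog pairs
#'
#' Unweighted mean of per-pair percent identities, the standard AAI
#' statistic for delineating microbial species and genera.
#'
#' @param pairs data.frame with an `identity` column, as returned by
#'   [reciprocalBestHits()] or read from a precomputed hit table.
#' @return AAI percentage.
#' @export
computeAAI <- function(pairs) {
  if (is.null(pairs) || !nrow(pairs))
    stop("AAI undefined: no ortholog pairs", call. = FALSE)
  mean(pairs$identity)
}

#' Build MHC ortholog families across genomes
#'
#' Restricts each proteome to its MHC genes, runs reciprocal best hits
#' between every genome pair, and takes connected components of the
#' resulting cross-genome graph as ortholog families (a deliberate,
#' documented approximation of full orthology inference). Genes hit by no
#' RBH edge form singleton families. Family ids are assigned
#' deterministically by the lexicographically smallest member.
#'
#' @param proteomes Named list of named `AAStringSet`s (one per genome).
#' @param mhcGeneIds Named list (same names) of MHC gene-id vectors — e.g.
#'   `annotations(report)$gene_id[annotations(report)$is_mhc]`.
#' @param ... Alignment parameters passed to [reciprocalBestHits()].
#' @return List with `counts` (integer matrix, families x genomes) and
#'   `members` (data.frame `family_id`, `genome_id`, `gene_id`).
#' @export
buildMHCFamilies <- function(proteomes, mhcGeneIds, ...) {
  genomes <- sort(names(proteomes))
  sub <- lapply(genomes, function(g) {
    ids <- intersect(names(.asAAStringSet(proteomes[[g]])),
                     mhcGeneIds[[g]])
    .asAAStringSet(proteomes[[g]])[ids]
  })
  names(sub) <- genomes
  vertex <- function(g, id) {
    if (!length(id)) return(character(0))
    paste(g, id, sep = "|")
  }
  verts <- unlist(lapply(genomes, function(g)
    vertex(g, names(sub[[g]]))), use.names = FALSE)
  edges <- character()
  if (length(genomes) >= 2L) {
    for (i in seq_len(length(genomes) - 1L)) for (j in seq(i + 1L,
                                                           length(genomes))) {
      if (!length(sub[[i]]) || !length(sub[[j]])) next
      rbh <- reciprocalBestHits(sub[[i]], sub[[j]], ...)
      if (nrow(rbh))
        edges <- c(edges, rbind(vertex(genomes[i], rbh$query_id),
                                vertex(genomes[j], rbh$subject_id)))
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(verts)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  members <- data.frame(
    vertex = names(comp), comp = unname(comp), stringsAsFactors = FALSE)
  parts <- strsplit(members$vertex, "|", fixed = TRUE)
  members$genome_id <- vapply(parts, `[`, character(1), 1L)
  members$gene_id <- vapply(parts, function(p)
    paste(p[-1L], collapse = "|"), character(1))
  # deterministic family ids from the smallest member vertex
  rep_member <- tapply(members$vertex, members$comp, function(v) sort(v)[1L])
  fam_order <- sort(rep_member)
  fam_id <- stats::setNames(sprintf("fam_%03d", seq_along(fam_order)),
                            names(fam_order))
  members$family_id <- fam_id[as.character(members$comp)]
  members <- members[order(members$family_id, members$genome_id,
                           members$gene_id),
                     c("family_id", "genome_id", "gene_id")]
  rownames(members) <- NULL
  counts <- table(factor(members$family_id, levels = unique(members$family_id)),
                  factor(members$genome_id, levels = genomes))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  list(counts = counts, members = members)
}

#' Ward (ward.D2) hierarchical clustering of a family-count matrix
#'
#' Agglomerative clustering on Euclidean distances under Ward's
#' minimum-variance criterion with squared dissimilarities inside the
#' criterion (the `ward.D2` convention). Items are ordered
#' lexicographically by name before clustering so ties resolve
#' deterministically.
#'
#' @param matrix Numeric matrix (e.g. `counts` from [buildMHCFamilies()]).
#' @param axis Cluster `"families"` (rows, default) or `"genomes"`
#'   (columns).
#' @return An [stats::hclust] object.
#' @export
wardCluster <- function(matrix, axis = c("families", "genomes")) {
  axis <- match.arg(axis)
  x <- if (axis == "genomes") t(matrix) else matrix
  if (nrow(x) < 2L) stop("need >= 2 items to cluster", call. = FALSE)
  x <- x[order(rownames(x)), , drop = FALSE]
  stats::hclust(stats::dist(x), method = "ward.D2")
}

#' Export a dendrogram as Newick
#'
#' @param hc An [stats::hclust] object (e.g. from [wardCluster()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
exportNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
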