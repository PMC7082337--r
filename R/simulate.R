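# Deterministic synthetic-data generators with ground truth for every
# pipeline stage: planted-motif proteomes, diverged proteome pairs,
# multinomial count tables, and reactor time series.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
           "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# background residue frequencies: uniform with cysteine down-weighted so
# accidental CXXCH motifs are rare before rejection sampling
.BG_PROBS <- {
  p <- rep(1, 20); names(p) <- .AA20; p["C"] <- 0.2; p / sum(p)
}

.randomMotifFreeSeq <- function(len, maxTries = 200L) {
  for (t in seq_len(maxTries)) {
    s <- paste(sample(.AA20, len, replace = TRUE, prob = .BG_PROBS),
               collapse = "")
    if (!grepl("C..CH", s)) return(s)
  }
  # deterministic fallback: strip any remaining motif-forming cysteines
  gsub("C", "A", s)
}

.plantMotifs <- function(len, nMotifs, maxTries = 200L) {
  if (nMotifs * 5L > len)
    stop(sprintf("cannot pack %d motifs into %d residues", nMotifs, len),
         call. = FALSE)
  for (t in seq_len(maxTries)) {
    s <- strsplit(.randomMotifFreeSeq(len), "")[[1L]]
    # non-overlapping 5-residue slots
    starts <- sort(sample(seq_len(len %/% 5L), nMotifs)) * 5L - 4L
    for (st in starts) {
      s[st] <- "C"
      s[st + 1L:2L] <- sample(setdiff(.AA20, "C"), 2, replace = TRUE)
      s[st + 3L] <- "C"
      s[st + 4L] <- "H"
    }
    seq <- paste(s, collapse = "")
    if (length(scanHemeMotifs(seq)) == nMotifs)
      return(list(sequence = seq, positions = starts - 1L))
  }
  stop("failed to plant motifs without accidental extras", call. = FALSE)
}

#' Simulate a proteome with planted multiheme cytochromes
#'
#' Generates `nProteins` protein sequences, of which the first `nMhc` are
#' planted multiheme cytochromes carrying exactly the requested number of
#' non-overlapping CXXCH motifs; all remaining proteins (and all positions
#' outside planted motifs) are guaranteed motif-free by rejection sampling,
#' so motif-recovery tests are exact. Evidence labels (signal peptide,
#' localization, S-layer domain) and a gene table — with a subset of MHCs
#' placed adjacent to oxidoreductase-labelled genes — are generated
#' alongside, together with a truth table.
#'
#' @param nProteins Total proteins (default 100).
#' @param nMhc Number of planted MHCs (default 10; must be <= `nProteins`).
#' @param hemeCounts Integer vector of motif counts for the planted MHCs,
#'   recycled to length `nMhc`. Default `3:12`; include large values such
#'   as 113 to emulate giant S-layer-fused cytochromes.
#' @param fractionExtracellular Fraction of MHCs given signal peptide
#'   and/or extracellular localization (default 0.4).
#' @param nSlayer Number of MHCs given an S-layer domain hit (default 2).
#' @param nClustered Number of MHCs placed next to an
#'   oxidoreductase-labelled gene (default half of `nMhc`).
#' @param lengthRange Background protein length range (default 200-400 aa).
#' @param genomeId Genome id recorded throughout (default "sim").
#' @param seed Integer seed; identical seeds give identical output.
#' @return List: `proteins` (`AAStringSet`), `evidence`, `genes`, `truth`
#'   (data.frames). Truth columns: `gene_id`, `is_mhc`, `heme_count`,
#'   `extracellular`, `slayer`, `cluster_context`.
#' @examples
#' sim <- simulateProteome(nProteins = 20, nMhc = 4, seed = 1)
#' screenGenome(sim$proteins, sim$evidence, sim$genes)
#' @export
simulateProteome <- function(nProteins = 100, nMhc = 10,
                             hemeCounts = 3:12,
                             fractionExtracellular = 0.4,
                             nSlayer = min(2, nMhc),
                             nClustered = ceiling(nMhc / 2),
                             lengthRange = c(200, 400),
                             genomeId = "sim", seed = 1) {
  if (nMhc > nProteins) stop("nMhc must be <= nProteins", call. = FALSE)
  if (nSlayer > nMhc || nClustered > nMhc)
    stop("nSlayer and nClustered must be <= nMhc", call. = FALSE)
  set.seed(seed)
  hemeCounts <- rep_len(hemeCounts, length.out = max(nMhc, 1L))[seq_len(nMhc)]

  ids <- sprintf("%s_%04d", genomeId, seq_len(nProteins))
  seqs <- character(nProteins)
  heme <- integer(nProteins)
  for (i in seq_len(nProteins)) {
    if (i <= nMhc) {
      len <- max(sample(lengthRange[1L]:lengthRange[2L], 1L),
                 hemeCounts[i] * 7L + 20L)
      pl <- .plantMotifs(len, hemeCounts[i])
      seqs[i] <- pl$sequence
      heme[i] <- hemeCounts[i]
    } else {
      seqs[i] <- .randomMotifFreeSeq(
        sample(lengthRange[1L]:lengthRange[2L], 1L))
    }
  }

  is_mhc <- seq_len(nProteins) <= nMhc
  n_extra <- round(fractionExtracellular * nMhc)
  extra <- is_mhc & seq_len(nProteins) <= n_extra
  slayer <- is_mhc & seq_len(nProteins) <= nSlayer
  # extracellular evidence split between signal peptide and localization
  sigp <- extra & (seq_len(nProteins) %% 2L == 1L)
  loc <- ifelse(extra & !sigp, "extracellular",
                ifelse(is_mhc, "membrane", "cytoplasmic"))
  domains <- ifelse(is_mhc, "Cytochrome_c", "")
  domains[slayer] <- paste0(domains[slayer], ";S-layer")
  evidence <- data.frame(gene_id = ids, signal_peptide = sigp,
                         localization = loc, domains = domains,
                         stringsAsFactors = FALSE)

  # gene table: clustered MHCs live on contig ctg1, each followed by an
  # oxidoreductase-component gene; all other genes go to ctg2 so that
  # non-clustered MHCs are guaranteed outside any context window
  clustered <- is_mhc & seq_len(nProteins) <= nClustered
  rows <- list()
  pos <- 1L
  k <- 0L
  for (i in seq_len(nProteins)) {
    glen <- nchar(seqs[i]) * 3L
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = ids[i], genome_id = genomeId,
      contig = if (clustered[i]) "ctg1" else "ctg2",
      start = pos, end = pos + glen - 1L, strand = "+",
      label = if (is_mhc[i]) "multiheme cytochrome" else "hypothetical",
      stringsAsFactors = FALSE)
    pos <- pos + glen + 100L
    if (clustered[i]) {
      k <- k + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("%s_oxr%03d", genomeId, k), genome_id = genomeId,
        contig = "ctg1", start = pos, end = pos + 899L, strand = "+",
        label = "b-type cytochrome", stringsAsFactors = FALSE)
      pos <- pos + 1000L
    }
  }
  genes <- do.call(rbind, rows)

  truth <- data.frame(
    gene_id = ids, is_mhc = is_mhc, heme_count = heme,
    extracellular = extra & is_mhc, slayer = slayer,
    cluster_context = ifelse(clustered, "oxidoreductase-cluster",
                             ifelse(is_mhc, "standalone", NA_character_)),
    stringsAsFactors = FALSE)

  list(proteins = Biostrings::AAStringSet(stats::setNames(seqs, ids)),
       evidence = evidence, genes = genes, truth = truth,
       seed = seed, genome_id = genomeId)
}

#' Simulate a diverged copy of a proteome at a target identity
#'
#' Each residue is substituted, independently with probability
#' `1 - targetIdentity`, by a uniformly chosen different residue, so the
#' expected pairwise identity of each protein to its source equals
#' `targetIdentity` (no indels). Mirrors species-level divergence used to
#' benchmark AAI recovery.
#'
#' @param proteins Named `AAStringSet` (or named character vector).
#' @param targetIdentity Target per-site identity in (0, 1].
#' @param seed Integer seed.
#' @param suffix Suffix appended to gene ids of the copy (default "_b").
#' @return List: `proteins` (diverged `AAStringSet`), `truth` (data.frame
#'   `gene_id`, `source_id`, `target_identity`, `realized_identity`).
#' @export
simulateDivergedPair <- function(proteins, targetIdentity, seed = 1,
                                 suffix = "_b") {
  if (targetIdentity <= 0 || targetIdentity > 1)
    stop("'targetIdentity' must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  src <- as.character(.asAAStringSet(proteins))
  out <- character(length(src))
  realized <- numeric(length(src))
  for (i in seq_along(src)) {
    chars <- strsplit(src[[i]], "")[[1L]]
    hit <- stats::runif(length(chars)) < (1 - targetIdentity)
    if (any(hit))
      chars[hit] <- vapply(chars[hit], function(a)
        sample(setdiff(.AA20, a), 1L), character(1))
    out[i] <- paste(chars, collapse = "")
    realized[i] <- 1 - mean(hit)
  }
  ids <- paste0(names(src), suffix)
  list(proteins = Biostrings::AAStringSet(stats::setNames(out, ids)),
       truth = data.frame(gene_id = ids, source_id = names(src),
                          target_identity = targetIdentity,
                          realized_identity = realized,
                          stringsAsFactors = FALSE))
}

#' Simulate read counts from a TPM truth vector
#'
#' Counts are drawn multinomially with per-gene probability proportional to
#' `tpmTruth x lengths` — the inverse of the TPM normalization — so that
#' [computeTPM()] recovers the truth in expectation as depth grows.
#'
#' @param tpmTruth Nonnegative TPM truth vector (rescaled to sum to 1e6 if
#'   it does not already).
#' @param lengths Positive feature lengths (nt), parallel to `tpmTruth`.
#' @param totalReads Total mapped reads (> 0).
#' @param readLength Read length recorded in the output (default 150; TPM
#'   itself is invariant to it).
#' @param genomeIds Optional genome assignment per gene (default "sim").
#' @param seed Integer seed.
#' @return List: `counts` (data.frame `gene_id`, `genome_id`, `read_count`,
#'   `feature_length_nt`), `truth` (data.frame with `tpm_truth`),
#'   `read_length`.
#' @export
simulateCounts <- function(tpmTruth, lengths, totalReads,
                           readLength = 150, genomeIds = "sim", seed = 1) {
  if (totalReads <= 0) stop("'totalReads' must be > 0", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be > 0", call. = FALSE)
  if (length(tpmTruth) != length(lengths))
    stop("'tpmTruth' and 'lengths' lengths differ", call. = FALSE)
  set.seed(seed)
  tpmTruth <- tpmTruth / sum(tpmTruth) * 1e6
  prob <- tpmTruth * lengths
  counts <- as.integer(stats::rmultinom(1L, size = totalReads,
                                        prob = prob / sum(prob)))
  ids <- sprintf("gene_%04d", seq_along(tpmTruth))
  genomeIds <- rep_len(genomeIds, length(tpmTruth))
  list(counts = data.frame(gene_id = ids, genome_id = genomeIds,
                           read_count = counts,
                           feature_length_nt = as.integer(lengths),
                           stringsAsFactors = FALSE),
       truth = data.frame(gene_id = ids, genome_id = genomeIds,
                          tpm_truth = tpmTruth, stringsAsFactors = FALSE),
       read_length = readLength, seed = seed)
}

#' Simulate a reactor time series with known rates and pool structure
#'
#' Methane declines linearly at `ch4Rate` and total extractable Mn(II)
#' rises at `mnRate`, both with i.i.d. Gaussian noise. Mn(II) is split into
#' dissolved/adsorbed/carbonate pools by `poolFractions` (dissolved < 3% by
#' default, matching the observation that justifies dropping it from rate
#' mass balances). A birnessite feed event applies a step drop to the
#' dissolved pool from that day onward (adsorption onto the fresh oxide),
#' moving the removed Mn(II) into the adsorbed pool so the extractable
#' total keeps rising.
#'
#' @param days Sampling days (default weekly over 21 d: `c(0, 7, 14, 21)`).
#' @param ch4Rate Methane consumption rate, umol/L/day (default 44.5).
#' @param mnRate Mn(II) production rate, umol/L/day (default 184.7).
#' @param noiseSd Gaussian noise s.d. on concentrations (default 5).
#' @param ch4Start,mnStart Starting concentrations, umol/L.
#' @param poolFractions Named fractions `dissolved`, `adsorbed`,
#'   `carbonate` summing to 1 (default 0.02/0.55/0.43).
#' @param feedEvents Optional data.frame `day`, `birnessite_g`; each event
#'   halves the dissolved pool from that day onward.
#' @param seed Integer seed.
#' @return List: `series` ([ReactorSeries-class]), `truth` (list of the
#'   generating parameters).
#' @examples
#' sim <- simulateReactorSeries(noiseSd = 0, seed = 1)
#' estimateRate(seriesData(sim$series)$day,
#'              seriesData(sim$series)$methane_umol_per_L, "consumption")
#' @export
simulateReactorSeries <- function(days = c(0, 7, 14, 21),
                                  ch4Rate = 44.5, mnRate = 184.7,
                                  noiseSd = 5, ch4Start = 2000,
                                  mnStart = 500,
                                  poolFractions = c(dissolved = 0.02,
                                                    adsorbed = 0.55,
                                                    carbonate = 0.43),
                                  feedEvents = NULL, seed = 1) {
  if (!length(days)) stop("'days' must be nonempty", call. = FALSE)
  if (ch4Rate < 0 || mnRate < 0)
    stop("rates must be nonnegative", call. = FALSE)
  if (abs(sum(poolFractions) - 1) > 1e-9)
    stop("'poolFractions' must sum to 1", call. = FALSE)
  set.seed(seed)
  days <- sort(days)
  ch4 <- pmax(0, ch4Start - ch4Rate * days +
                stats::rnorm(length(days), 0, noiseSd))
  mn_total <- pmax(0, mnStart + mnRate * days +
                     stats::rnorm(length(days), 0, noiseSd))
  dis <- mn_total * poolFractions[["dissolved"]]
  ads <- mn_total * poolFractions[["adsorbed"]]
  carb <- mn_total * poolFractions[["carbonate"]]
  if (!is.null(feedEvents) && nrow(feedEvents)) {
    for (fd in feedEvents$day) {
      after <- days >= fd
      drop <- dis * 0.5 * after
      dis <- dis - drop
      ads <- ads + drop  # adsorbed onto the fresh oxide
    }
  }
  series <- reactorSeries(
    data.frame(day = days, methane_umol_per_L = ch4,
               mn2_dissolved = dis, mn2_adsorbed = ads,
               mn2_carbonate = carb),
    feedEvents = feedEvents)
  list(series = series,
       truth = list(ch4_rate = ch4Rate, mn_rate = mnRate,
                    noise_sd = noiseSd, pool_fractions = poolFractions,
                    days = days, seed = seed))
}
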