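# Greedy ANI clustering of viral contigs into vOTUs, with CD-HIT-equivalent
# semantics (-c identity over the local alignment, -aS coverage of the
# shorter sequence, longest-first greedy order).

# blastn-like local alignment scoring; exact Smith-Waterman via Biostrings.
# The substitution matrix is built once per session (cached).
.aln_cache <- new.env(parent = emptyenv())

.aln_matrix <- function() {
  if (is.null(.aln_cache$mat)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
    # N never counts as a match
    m[, "N"] <- -3; m["N", ] <- -3
    .aln_cache$mat <- m
  }
  .aln_cache$mat
}

#' Local-alignment identity between two sequences
#'
#' Computes the best local (Smith-Waterman) alignment of two nucleotide
#' sequences and returns the identity over the alignment — matches divided
#' by alignment columns, gap columns included — together with the fraction
#' of the shorter sequence covered by the aligned region. These are the two
#' quantities the greedy vOTU clustering thresholds (CD-HIT's `-c` and
#' `-aS` semantics).
#'
#' @param a,b Nucleotide strings or `DNAString`s.
#' @return List with `identity` (matches / alignment columns, in `[0,1]`),
#'   `coverage_shorter` (aligned span on the shorter sequence divided by its
#'   length) and `score`.
#' @examples
#' alignmentIdentity("ACGTACGTACGT", "ACGTACGAACGT")$identity
#' @export
alignmentIdentity <- function(a, b) {
  if (!is(a, "DNAString")) a <- Biostrings::DNAString(as.character(a))
  if (!is(b, "DNAString")) b <- Biostrings::DNAString(as.character(b))
  if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    pattern = b, subject = a, type = "local",
    substitutionMatrix = .aln_matrix(), gapOpening = 5, gapExtension = 2)
  ni <- Biostrings::nindel(aln)
  cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
    Biostrings::insertion(ni)[1, "WidthSum"] +
    Biostrings::deletion(ni)[1, "WidthSum"]
  if (cols == 0)
    return(list(identity = 0, coverage_shorter = 0, score = 0))
  span_b <- Biostrings::width(Biostrings::pattern(aln))
  list(identity = Biostrings::nmatch(aln) / cols,
       coverage_shorter = span_b / length(b),
       score = Biostrings::score(aln))
}

# Short-word prefilter (CD-HIT-style): probe evenly spaced 16-mers of the
# candidate against the representative. A pair at >= 95% identity over >=
# 85% of the candidate retains intact probes with overwhelming probability,
# while unrelated pairs essentially never do; pairs with < `min_hits`
# intact probes cannot plausibly meet the thresholds and skip the
# quadratic alignment. Deterministic (fixed probe positions).
.kmer_screen <- function(cand, rep, k = 16L, n_probes = 30L, min_hits = 2L) {
  if (nchar(cand) < 40 * k) return(TRUE)
  starts <- unique(round(seq(1, nchar(cand) - k + 1, length.out = n_probes)))
  hits <- 0L
  for (s in starts) {
    if (grepl(substr(cand, s, s + k - 1L), rep, fixed = TRUE)) {
      hits <- hits + 1L
      if (hits >= min_hits) return(TRUE)
    }
  }
  FALSE
}

#' Greedy clustering of viral contigs into vOTUs
#'
#' CD-HIT-style greedy incremental clustering: sequences are sorted by
#' length descending (ties by id ascending) and each sequence joins the
#' first existing representative against which its local-alignment identity
#' is at least `identity` with the alignment covering at least `short_cov`
#' of the shorter sequence; otherwise it founds a new cluster. Because
#' candidates are processed longest-first, the candidate is always the
#' shorter sequence, mirroring CD-HIT's `-aS` under `-d 0` sorting. The
#' partition is therefore independent of input file order. Sequences with
#' more than 50% `N` are excluded with a warning.
#'
#' @param x A [ViralSeqSet-class] of predicted viral contigs.
#' @param identity Identity threshold over the alignment (default 0.95).
#' @param short_cov Minimum aligned fraction of the shorter sequence
#'   (default 0.85).
#' @return A [VOTUCatalog-class]; empty input yields an empty catalog.
#' @examples
#' vs <- ViralSeqSet(c(a = strrep("ACGT", 50), b = strrep("ACGT", 50)))
#' length(clusterVOTUs(vs))  # one cluster, representative "a"
#' @export
clusterVOTUs <- function(x, identity = 0.95, short_cov = 0.85) {
  stopifnot(is(x, "ViralSeqSet"))
  empty <- data.frame(member_id = character(), representative_id = character(),
                      identity_to_rep = numeric(),
                      coverage_of_shorter = numeric(), length = integer(),
                      stringsAsFactors = FALSE)
  params <- list(identity = identity, short_cov = short_cov)
  if (length(x) == 0)
    return(new("VOTUCatalog", members = empty, params = params,
               filterFlags = data.frame()))
  nfrac <- Biostrings::alphabetFrequency(sequences(x), as.prob = TRUE)[, "N"]
  if (any(nfrac > 0.5)) {
    .warnf("excluding %d sequence(s) with > 50%% N", sum(nfrac > 0.5))
    x <- x[nfrac <= 0.5]
    if (length(x) == 0)
      return(new("VOTUCatalog", members = empty, params = params,
                 filterFlags = data.frame()))
  }
  lens <- seqLengths(x)
  ord <- order(-lens, names(lens), method = "radix")
  ids <- names(lens)[ord]
  seqs <- as.character(sequences(x))[ids]
  dna <- lapply(seqs, Biostrings::DNAString)
  reps <- character(0)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    assigned <- FALSE
    for (r in reps) {
      if (!.kmer_screen(seqs[[id]], seqs[[r]])) next
      al <- alignmentIdentity(dna[[r]], dna[[id]])
      if (al$identity >= identity && al$coverage_shorter >= short_cov) {
        rows[[i]] <- data.frame(member_id = id, representative_id = r,
                                identity_to_rep = al$identity,
                                coverage_of_shorter = al$coverage_shorter,
                                length = unname(lens[id]),
                                stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      rows[[i]] <- data.frame(member_id = id, representative_id = id,
                              identity_to_rep = 1, coverage_of_shorter = 1,
                              length = unname(lens[id]),
                              stringsAsFactors = FALSE)
    }
  }
  new("VOTUCatalog", members = do.call(rbind, rows), params = params,
      filterFlags = data.frame())
}

#' Filter a vOTU catalog by length, quality and detection
#'
#' A vOTU survives iff its representative is at least `min_len` bp, its
#' representative's quality tier is not `not_determined`, and the vOTU is
#' detected (breadth >= the detection threshold) in at least one sample.
#' vOTUs absent from the quality table are treated as `not_determined` and
#' logged. Per-sequence flags record the representative's verdicts for
#' every member.
#'
#' @param catalog A [VOTUCatalog-class].
#' @param quality data.frame from [readQualityTable()] (columns `contig_id`,
#'   `quality_tier`).
#' @param detection Logical samples-x-vOTUs matrix (the
#'   [detectionMask()] of an [AbundanceMatrix-class]); column names are
#'   representative ids. Representatives without a column are undetected.
#' @param min_len Minimum representative length in bp (default 10000).
#' @return The catalog restricted to surviving vOTUs, with `filterFlags`
#'   recording per-member verdicts (`passed_length`, `passed_quality`,
#'   `passed_detection`, `passed`).
#' @export
filterCatalog <- function(catalog, quality, detection, min_len = 10000L) {
  stopifnot(is(catalog, "VOTUCatalog"))
  m <- memberTable(catalog)
  if (nrow(m) == 0) return(catalog)
  reps <- unique(m$representative_id)
  rep_len <- m$length[match(reps, m$member_id)]
  tier <- quality$quality_tier[match(reps, quality$contig_id)]
  if (anyNA(tier)) {
    .warnf("%d representative(s) absent from quality table; treated as not_determined",
           sum(is.na(tier)))
    tier[is.na(tier)] <- "not_determined"
  }
  detected <- vapply(reps, function(r) {
    if (is.null(colnames(detection)) || !r %in% colnames(detection))
      return(FALSE)
    any(detection[, r])
  }, logical(1))
  ok_len <- rep_len >= min_len
  ok_qual <- tier != "not_determined"
  keep <- ok_len & ok_qual & detected
  ri <- match(m$representative_id, reps)
  flags <- data.frame(member_id = m$member_id,
                      representative_id = m$representative_id,
                      passed_length = ok_len[ri],
                      passed_quality = ok_qual[ri],
                      passed_detection = detected[ri],
                      passed = keep[ri], stringsAsFactors = FALSE)
  out <- m[keep[ri], , drop = FALSE]
  rownames(out) <- NULL
  new("VOTUCatalog", members = out, params = catalog@params,
      filterFlags = flags)
}

#' Summarize auxiliary metabolic gene categories
#'
#' Counts distilled AMG categories and reports the unclassified fraction
#' (records with an empty `distilled_category`) as a percentage with one
#' decimal, the convention for reporting metabolic novelty.
#'
#' @param amgs data.frame of AMG records (see [readAMGTable()]).
#' @return List with `counts` (named integer vector by category), `total`,
#'   `n_unclassified` and `unclassified_pct` (`NA` for an empty table).
#' @examples
#' amgs <- data.frame(votu_id = "v1", gene_id = paste0("g", 1:5),
#'                    distilled_category = c("energy", "", "", "carbon",
#'                                           "carbon"),
#'                    distilled_module = "")
#' summarizeAMGs(amgs)$unclassified_pct  # 40.0
#' @export
summarizeAMGs <- function(amgs) {
  total <- nrow(amgs)
  if (total == 0)
    return(list(counts = integer(0), total = 0L, n_unclassified = 0L,
                unclassified_pct = NA_real_))
  unclass <- is.na(amgs$distilled_category) | amgs$distilled_category == ""
  cats <- table(amgs$distilled_category[!unclass])
  list(counts = stats::setNames(as.integer(cats), names(cats)),
       total = as.integer(total), n_unclassified = as.integer(sum(unclass)),
       unclassified_pct = round(100 * sum(unclass) / total, 1))
}

#' Quality-tier histogram of catalog members
#'
#' @param catalog A [VOTUCatalog-class].
#' @param quality data.frame with `contig_id`, `quality_tier`; members
#'   absent from it count as `not_determined`.
#' @return Named integer vector over the five quality tiers.
#' @export
summarizeQuality <- function(catalog, quality) {
  stopifnot(is(catalog, "VOTUCatalog"))
  m <- memberTable(catalog)
  tier <- quality$quality_tier[match(m$member_id, quality$contig_id)]
  tier[is.na(tier)] <- "not_determined"
  counts <- table(factor(tier, levels = .QUALITY_TIERS))
  stats::setNames(as.integer(counts), names(counts))
}
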