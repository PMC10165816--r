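#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
NULL

.QUALITY_TIERS <- c("complete", "high", "medium", "low", "not_determined")
.REGIONS <- c("antarctic_peninsula", "northern_victoria_land",
              "southern_victoria_land")
.ROCK_TYPES <- c("sandstone", "granite", "quartz", "basalt_dolerite")
.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")
.VC_RANKS <- c("class", "order", "family", "genus")

#' Collection of predicted viral contigs
#'
#' A `ViralSeqSet` wraps a [Biostrings::DNAStringSet] of predicted viral
#' contigs together with per-contig annotation: the source sample, the
#' genome-quality tier (the usual completeness vocabulary
#' `complete`/`high`/`medium`/`low`/`not_determined`) and a provirus flag.
#' Contig ids are the names of the sequence set and must be unique;
#' sequences are restricted to the alphabet `A`, `C`, `G`, `T`, `N`.
#'
#' @slot seqs A named [Biostrings::DNAStringSet]; names are contig ids.
#' @slot info A [S4Vectors::DataFrame] with columns `sample_id`,
#'   `quality_tier` and `is_provirus`, one row per contig.
#'
#' @seealso [readViralFasta()], [generatePopulation()]
#' @exportClass ViralSeqSet
setClass("ViralSeqSet",
         representation(seqs = "DNAStringSet", info = "DataFrame"))

setValidity("ViralSeqSet", function(object) {
  msgs <- character()
  ids <- names(object@seqs)
  if (length(object@seqs) > 0 && (is.null(ids) || anyNA(ids) || any(ids == "")))
    msgs <- c(msgs, "all sequences must be named by a contig id")
  if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicated contig ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (nrow(object@info) != length(object@seqs))
    msgs <- c(msgs, "info must have one row per sequence")
  need <- c("sample_id", "quality_tier", "is_provirus")
  if (!all(need %in% colnames(object@info)))
    msgs <- c(msgs, sprintf("info must have columns %s",
                            paste(need, collapse = ", ")))
  else if (!all(object@info$quality_tier %in% .QUALITY_TIERS))
    msgs <- c(msgs, "quality_tier outside the allowed vocabulary")
  if (length(object@seqs) > 0) {
    freq <- Biostrings::alphabetFrequency(object@seqs)
    bad <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                        drop = FALSE]) > 0
    if (any(bad))
      msgs <- c(msgs, sprintf("sequences contain characters outside ACGTN: %s",
                              paste(utils::head(ids[bad], 5), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ViralSeqSet
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector
#'   of nucleotide strings, which is converted).
#' @param sample_id Character vector of source-sample ids, recycled to the
#'   number of sequences.
#' @param quality_tier Quality tiers; defaults to `"not_determined"`.
#' @param is_provirus Logical provirus flags; defaults to `FALSE`.
#' @return A [ViralSeqSet-class] object.
#' @examples
#' vs <- ViralSeqSet(c(v1 = "ACGTACGT", v2 = "GGGTTTAA"), sample_id = "s1")
#' seqLengths(vs)
#' @export
ViralSeqSet <- function(seqs, sample_id = NA_character_,
                        quality_tier = "not_determined",
                        is_provirus = FALSE) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  n <- length(seqs)
  info <- S4Vectors::DataFrame(
    sample_id = rep_len(as.character(sample_id), n),
    quality_tier = rep_len(as.character(quality_tier), n),
    is_provirus = rep_len(as.logical(is_provirus), n),
    row.names = names(seqs))
  new("ViralSeqSet", seqs = seqs, info = info)
}

#' Catalog of vOTU clusters
#'
#' Result of greedy average-nucleotide-identity clustering of viral contigs
#' into viral operational taxonomic units (vOTUs). Each input sequence is a
#' member of exactly one cluster; the representative is the longest member
#' (ties broken by lexicographically smallest id) and members are never
#' longer than their representative.
#'
#' @slot members A data.frame with one row per input sequence: `member_id`,
#'   `representative_id`, `identity_to_rep`, `coverage_of_shorter`, `length`.
#' @slot params List with the clustering parameters `identity` and
#'   `short_cov`.
#' @slot filterFlags A data.frame of per-sequence catalog-filter verdicts
#'   (`passed_length`, `passed_quality`, `passed_detection`), populated by
#'   [filterCatalog()]; zero rows before filtering.
#'
#' @seealso [clusterVOTUs()], [filterCatalog()]
#' @exportClass VOTUCatalog
setClass("VOTUCatalog",
         representation(members = "data.frame", params = "list",
                        filterFlags = "data.frame"))

setValidity("VOTUCatalog", function(object) {
  m <- object@members
  need <- c("member_id", "representative_id", "identity_to_rep",
            "coverage_of_shorter", "length")
  if (!all(need %in% colnames(m)))
    return(sprintf("members must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(m$member_id))
    return("each sequence may appear in exactly one cluster")
  if (nrow(m) > 0) {
    if (!all(m$representative_id %in% m$member_id))
      return("every representative must itself be a member")
    replen <- m$length[match(m$representative_id, m$member_id)]
    if (any(m$length > replen))
      return("members must never be longer than their representative")
  }
  TRUE
})

#' Sample-by-vOTU abundance matrix
#'
#' Trimmed-mean ("tpmean") coverage values per sample and vOTU with a
#' same-shaped detection mask. Cells where the vOTU failed the
#' breadth-of-coverage detection rule are exactly zero and flagged
#' undetected. Rows are samples, columns are vOTUs.
#'
#' @slot values Non-negative numeric matrix, samples x vOTUs.
#' @slot detection Logical matrix of the same shape.
#' @slot params List with `breadth_min`, `trim_fraction` and the upstream
#'   read-mapping identity recorded as provenance (`mapping_identity`).
#'
#' @seealso [buildAbundanceMatrix()]
#' @exportClass AbundanceMatrix
setClass("AbundanceMatrix",
         representation(values = "matrix", detection = "matrix",
                        params = "list"))

setValidity("AbundanceMatrix", function(object) {
  v <- object@values; d <- object@detection
  if (!identical(dim(v), dim(d)))
    return("values and detection must have identical shape")
  if (!identical(dimnames(v), dimnames(d)))
    return("values and detection must share dimnames")
  if (is.null(rownames(v)) && nrow(v) > 0)
    return("rows must be labeled by sample id")
  if (anyNA(v) || any(v < 0))
    return("abundance values must be non-negative and non-missing")
  if (any(v[!d] != 0))
    return("undetected cells must hold exactly 0")
  TRUE
})

#' Gene-sharing viral clusters
#'
#' Partition of phage genomes into viral clusters (VCs) from a gene-sharing
#' network, with the usual per-genome status vocabulary: `clustered` (placed
#' in a VC), `singleton` (shares no genes with any other genome), `overlap`
#' (significant edges into two or more VCs without being placed in one) and
#' `outlier` (shares genes but cannot confidently be placed). VC taxonomy is
#' assigned from reference members; VCs without references are `Unique VC`.
#'
#' @slot edges data.frame of pairwise gene-sharing edges: `from`, `to`,
#'   `weight` (-log10 hypergeometric tail probability), `shared`,
#'   `significant`.
#' @slot vcs Named list mapping VC id to member genome ids.
#' @slot status Named character vector over all genomes.
#' @slot vcTaxonomy data.frame with `vc_id`, one column per rank
#'   (class, order, family, genus; `NA` = unassigned) and a `label`.
#' @slot genomes Character vector of all genome ids in the network.
#' @slot references Character vector of reference genome ids.
#'
#' @seealso [edgeWeights()], [clusterGraph()], [assignStatus()],
#'   [assignVCTaxonomy()]
#' @exportClass ViralClusterSet
setClass("ViralClusterSet",
         representation(edges = "data.frame", vcs = "list",
                        status = "character", vcTaxonomy = "data.frame",
                        genomes = "character", references = "character"))

setValidity("ViralClusterSet", function(object) {
  memb <- unlist(object@vcs, use.names = FALSE)
  if (anyDuplicated(memb))
    return("every clustered genome must belong to exactly one VC")
  if (!all(memb %in% object@genomes))
    return("VC members must be known genomes")
  if (length(object@status) > 0) {
    if (!setequal(names(object@status), object@genomes))
      return("status must cover exactly the input genomes")
    if (!all(object@status %in% c("clustered", "singleton", "outlier",
                                  "overlap")))
      return("unknown status label")
  }
  TRUE
})
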