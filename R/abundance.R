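# Coverage-derived detection and trimmed-mean abundance.

#' Breadth of coverage
#'
#' Fraction of a vOTU's positions covered by at least one read; the
#' standard detection criterion for read-mapping-based virome surveys.
#'
#' @param cov Coverage data.frame (see [readCoverageBed()]).
#' @param votu_id,sample_id Which record to evaluate.
#' @param votu_length Length of the vOTU in bp (> 0).
#' @return Fraction in `[0, 1]`.
#' @examples
#' cov <- data.frame(votu_id = "v1", sample_id = "s1", start = 0L,
#'                   end = 80L, depth = 3L)
#' coverageBreadth(cov, "v1", "s1", 100)  # 0.8
#' @export
coverageBreadth <- function(cov, votu_id, sample_id, votu_length) {
  if (votu_length <= 0) .stopf("votu_length must be > 0")
  sel <- cov$votu_id == votu_id & cov$sample_id == sample_id & cov$depth >= 1
  sub <- cov[sel, , drop = FALSE]
  if (nrow(sub) > 0 && max(sub$end) > votu_length)
    .stopf("coverage for %s extends past the contig length (%d > %d)",
           votu_id, max(sub$end), as.integer(votu_length))
  sum(sub$end - sub$start) / votu_length
}

#' Trimmed mean of per-base depth (tpmean)
#'
#' Sorts per-base depths, removes `floor(trim_fraction * n)` positions from
#' each tail and returns the mean of the remainder — the "trimmed pileup
#' coverage" abundance measure. Trimming removes by sorted position, so
#' ties are handled deterministically. `trim_fraction = 0` is the plain
#' arithmetic mean.
#'
#' @param depth Per-base depth vector (non-empty).
#' @param trim_fraction Fraction trimmed from each tail, in `[0, 0.5)`.
#' @return Non-negative numeric.
#' @examples
#' tpMean(c(0, 0, 5, 5, 5, 5, 5, 5, 5, 100), 0.10)  # 4.375
#' @export
tpMean <- function(depth, trim_fraction = 0.10) {
  if (length(depth) == 0) .stopf("tpMean: empty depth vector")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    .stopf("trim_fraction must lie in [0, 0.5)")
  k <- floor(trim_fraction * length(depth))
  s <- sort(depth)
  if (k > 0) s <- s[seq(k + 1, length(s) - k)]
  mean(s)
}

#' Build the detection-filtered abundance matrix
#'
#' One row per sample, one column per vOTU. A cell holds the trimmed-mean
#' depth ([tpMean()]) if the vOTU's breadth in that sample reaches
#' `breadth_min` (threshold inclusive: exactly 75% passes), else exactly 0
#' with `detection = FALSE`. vOTUs detected in no sample are dropped from
#' the matrix.
#'
#' @param cov Coverage data.frame.
#' @param votu_lengths Named integer vector of vOTU lengths (or a
#'   [ViralSeqSet-class]); coverage for a vOTU not listed here is an error.
#' @param samples Sample ids forming the rows; defaults to the samples seen
#'   in `cov`.
#' @param breadth_min Detection threshold (default 0.75).
#' @param trim_fraction Tail fraction for [tpMean()] (default 0.10).
#' @param mapping_identity Upstream read-mapping identity recorded as
#'   provenance metadata (default 0.90).
#' @return An [AbundanceMatrix-class].
#' @export
buildAbundanceMatrix <- function(cov, votu_lengths, samples = NULL,
                                 breadth_min = 0.75, trim_fraction = 0.10,
                                 mapping_identity = 0.90) {
  lens <- .votu_lengths(votu_lengths)
  unknown <- setdiff(unique(cov$votu_id), names(lens))
  if (length(unknown) > 0)
    .stopf("coverage for unknown vOTU id(s): %s",
           paste(utils::head(unknown, 5), collapse = ", "))
  if (is.null(samples)) samples <- sort(unique(cov$sample_id))
  votus <- sort(names(lens))
  vals <- matrix(0, length(samples), length(votus),
                 dimnames = list(samples, votus))
  det <- matrix(FALSE, length(samples), length(votus),
                dimnames = list(samples, votus))
  if (nrow(cov) > 0) {
    key <- split(seq_len(nrow(cov)), paste(cov$votu_id, cov$sample_id,
                                           sep = "\r"))
    for (k in names(key)) {
      rows <- cov[key[[k]], , drop = FALSE]
      v <- rows$votu_id[1]; s <- rows$sample_id[1]
      if (!s %in% samples) next
      L <- lens[[v]]
      if (max(rows$end) > L)
        .stopf("coverage for %s extends past the contig length", v)
      breadth <- sum((rows$end - rows$start)[rows$depth >= 1]) / L
      if (breadth >= breadth_min) {
        depth <- integer(L)
        for (i in seq_len(nrow(rows)))
          depth[(rows$start[i] + 1):rows$end[i]] <- rows$depth[i]
        vals[s, v] <- tpMean(depth, trim_fraction)
        det[s, v] <- TRUE
      }
    }
  }
  keep <- colSums(det) > 0
  new("AbundanceMatrix", values = vals[, keep, drop = FALSE],
      detection = det[, keep, drop = FALSE],
      params = list(breadth_min = breadth_min,
                    trim_fraction = trim_fraction,
                    mapping_identity = mapping_identity))
}
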