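# Accessor / show / subset methods for the S4 containers.

#' @rdname endovirome-accessors
#' @export
setMethod("seqIds", "ViralSeqSet", function(x) names(x@seqs))

#' @rdname endovirome-accessors
#' @export
setMethod("seqLengths", "ViralSeqSet", function(x) {
  stats::setNames(Biostrings::width(x@seqs), names(x@seqs))
})

#' @rdname endovirome-accessors
#' @export
setMethod("sampleId", "ViralSeqSet", function(x) {
  stats::setNames(x@info$sample_id, names(x@seqs))
})

#' @rdname endovirome-accessors
#' @export
setMethod("qualityTier", "ViralSeqSet", function(x) {
  stats::setNames(x@info$quality_tier, names(x@seqs))
})

#' @rdname endovirome-accessors
#' @export
setMethod("isProvirus", "ViralSeqSet", function(x) {
  stats::setNames(x@info$is_provirus, names(x@seqs))
})

#' @rdname endovirome-accessors
#' @export
setMethod("sequences", "ViralSeqSet", function(x) x@seqs)

#' @export
setMethod("length", "ViralSeqSet", function(x) length(x@seqs))

#' Subset a ViralSeqSet by index, id or logical mask
#' @param x A [ViralSeqSet-class].
#' @param i Index vector (integer, character id, or logical).
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "ViralSeqSet", function(x, i, j, ..., drop = FALSE) {
  new("ViralSeqSet", seqs = x@seqs[i], info = x@info[i, , drop = FALSE])
})

setMethod("show", "ViralSeqSet", function(object) {
  n <- length(object@seqs)
  cat(sprintf("ViralSeqSet with %d contig%s", n, if (n == 1) "" else "s"))
  if (n > 0)
    cat(sprintf(" (%d-%d bp, %d sample%s)",
                min(Biostrings::width(object@seqs)),
                max(Biostrings::width(object@seqs)),
                length(unique(object@info$sample_id)),
                if (length(unique(object@info$sample_id)) == 1) "" else "s"))
  cat("\n")
  tiers <- table(factor(object@info$quality_tier, levels = .QUALITY_TIERS))
  if (n > 0)
    cat("  quality:", paste(sprintf("%s=%d", names(tiers), tiers),
                            collapse = " "), "\n")
})

#' Combine ViralSeqSet objects
#' @param x,... [ViralSeqSet-class] objects.
#' @export
setMethod("c", "ViralSeqSet", function(x, ...) {
  rest <- list(...)
  seqs <- do.call(c, c(list(x@seqs), lapply(rest, function(v) v@seqs)))
  info <- do.call(rbind, c(list(x@info), lapply(rest, function(v) v@info)))
  new("ViralSeqSet", seqs = seqs, info = info)
})

#' @rdname endovirome-accessors
#' @export
setMethod("representatives", "VOTUCatalog", function(x) {
  unique(x@members$representative_id)
})

#' @rdname endovirome-accessors
#' @export
setMethod("clusterMembers", "VOTUCatalog", function(x) {
  split(x@members$member_id, x@members$representative_id)
})

#' @rdname endovirome-accessors
#' @export
setMethod("memberTable", "VOTUCatalog", function(x) x@members)

#' @rdname endovirome-accessors
#' @export
setMethod("filterFlags", "VOTUCatalog", function(x) x@filterFlags)

#' @export
setMethod("length", "VOTUCatalog", function(x) {
  length(unique(x@members$representative_id))
})

setMethod("show", "VOTUCatalog", function(object) {
  cat(sprintf("VOTUCatalog: %d vOTUs from %d sequences (identity >= %.2f, short coverage >= %.2f)\n",
              length(unique(object@members$representative_id)),
              nrow(object@members), object@params$identity,
              object@params$short_cov))
  if (nrow(object@filterFlags) > 0)
    cat(sprintf("  catalog filter applied: %d surviving vOTUs\n",
                length(unique(object@members$representative_id[
                  object@members$member_id %in%
                    object@filterFlags$member_id[object@filterFlags$passed]]))))
})

#' @rdname endovirome-accessors
#' @export
setMethod("abundanceValues", "AbundanceMatrix", function(x) x@values)

#' @rdname endovirome-accessors
#' @export
setMethod("detectionMask", "AbundanceMatrix", function(x) x@detection)

#' @export
setMethod("dim", "AbundanceMatrix", function(x) dim(x@values))

#' @export
setMethod("dimnames", "AbundanceMatrix", function(x) dimnames(x@values))

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf("AbundanceMatrix: %d samples x %d vOTUs (tpmean, trim %.2f/tail, detection breadth >= %.2f)\n",
              nrow(object@values), ncol(object@values),
              object@params$trim_fraction, object@params$breadth_min))
  cat(sprintf("  %.1f%% of cells detected\n",
              100 * mean(object@detection)))
})

#' @rdname endovirome-accessors
#' @export
setMethod("vcMembership", "ViralClusterSet", function(x) x@vcs)

#' @rdname endovirome-accessors
#' @export
setMethod("genomeStatus", "ViralClusterSet", function(x) x@status)

#' @rdname endovirome-accessors
#' @export
setMethod("vcTaxonomy", "ViralClusterSet", function(x) x@vcTaxonomy)

#' @export
setMethod("length", "ViralClusterSet", function(x) length(x@vcs))

setMethod("show", "ViralClusterSet", function(object) {
  cat(sprintf("ViralClusterSet: %d VCs over %d genomes (%d reference)\n",
              length(object@vcs), length(object@genomes),
              length(object@references)))
  if (length(object@status) > 0) {
    st <- table(factor(object@status,
                       levels = c("clustered", "singleton", "outlier",
                                  "overlap")))
    cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = " "),
        "\n")
  }
  if (nrow(object@vcTaxonomy) > 0)
    cat(sprintf("  unique VCs: %d\n",
                sum(object@vcTaxonomy$label == "Unique VC")))
})
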