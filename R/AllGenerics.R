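#' Accessors for endovirome containers
#'
#' Small accessor generics for the package's S4 containers: contig ids and
#' lengths, per-contig annotation, cluster membership, abundance values and
#' detection masks.
#'
#' @param x An endovirome container object.
#' @param ... Passed to methods.
#' @return The requested component; see the methods for details.
#' @name endovirome-accessors
#' @examples
#' vs <- ViralSeqSet(c(a = "ACGT", b = "GGCCTT"), sample_id = "s1")
#' seqIds(vs); seqLengths(vs)
NULL

#' @rdname endovirome-accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))
#' @rdname endovirome-accessors
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))
#' @rdname endovirome-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname endovirome-accessors
#' @export
setGeneric("qualityTier", function(x) standardGeneric("qualityTier"))
#' @rdname endovirome-accessors
#' @export
setGeneric("isProvirus", function(x) standardGeneric("isProvirus"))
#' @rdname endovirome-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname endovirome-accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname endovirome-accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname endovirome-accessors
#' @export
setGeneric("memberTable", function(x) standardGeneric("memberTable"))
#' @rdname endovirome-accessors
#' @export
setGeneric("filterFlags", function(x) standardGeneric("filterFlags"))

#' @rdname endovirome-accessors
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))
#' @rdname endovirome-accessors
#' @export
setGeneric("detectionMask", function(x) standardGeneric("detectionMask"))

#' @rdname endovirome-accessors
#' @export
setGeneric("vcMembership", function(x) standardGeneric("vcMembership"))
#' @rdname endovirome-accessors
#' @export
setGeneric("genomeStatus", function(x) standardGeneric("genomeStatus"))
#' @rdname endovirome-accessors
#' @export
setGeneric("vcTaxonomy", function(x) standardGeneric("vcTaxonomy"))
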