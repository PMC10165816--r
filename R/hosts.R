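# BLAST-consensus phage host prediction: threshold filtering, top-5
# per-rank unanimity, and dual-database merging with MAG priority.

.empty_prediction <- function(votu_id, source) {
  out <- data.frame(votu_id = votu_id, stringsAsFactors = FALSE)
  for (r in .TAX_RANKS) out[[r]] <- NA_character_
  out$source <- source
  out$n_supporting_hits <- 0L
  out
}

# enforce the rank-consistency invariant: once a rank is unassigned,
# everything below it is unassigned too
.truncate_ranks <- function(pred) {
  broken <- FALSE
  for (r in .TAX_RANKS) {
    if (broken) pred[[r]] <- NA_character_
    else if (is.na(pred[[r]])) broken <- TRUE
  }
  pred
}

#' Filter virus-host BLAST hits by the standard thresholds
#'
#' Keeps hits sharing a region of at least 2000 bp with at least 70%
#' identity, bitscore at least 50 and e-value at most 0.001. For hits
#' against the MAG database, the alignment must additionally cover less
#' than 50% of the subject's total length, so partial or entirely viral
#' MAG contigs are not mistaken for hosts. Each hit is judged alone (no
#' HSP merging).
#'
#' @param hits data.frame of hit records (see [readHitTable()]).
#' @param min_aln,min_identity,min_bitscore,max_evalue The thresholds.
#' @param max_mag_cov MAG subject-coverage ceiling (default 0.5,
#'   exclusive).
#' @return The filtered data.frame (possibly zero rows).
#' @export
filterHits <- function(hits, min_aln = 2000L, min_identity = 70,
                       min_bitscore = 50, max_evalue = 0.001,
                       max_mag_cov = 0.5) {
  keep <- hits$aln_length >= min_aln &
    hits$pct_identity >= min_identity &
    hits$bitscore >= min_bitscore &
    hits$evalue <= max_evalue
  is_mag <- hits$db_label == "mag"
  keep[is_mag] <- keep[is_mag] &
    (hits$aln_length[is_mag] / hits$subject_length[is_mag] < max_mag_cov)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-rank consensus host prediction from one query's filtered hits
#'
#' Hits (all for one query against one database) are ranked by bitscore
#' descending, ties by e-value ascending then subject id ascending; only
#' the top 5 are considered. Walking the ranks from domain downward, a
#' rank is assigned iff every considered hit carries the same non-empty
#' name; the first disagreement — an unknown (empty) name counts as a
#' disagreement — stops assignment at that rank and every rank below it.
#'
#' @param hits Filtered hit records sharing one `query_id` and one
#'   `db_label`; zero rows yield an all-unassigned prediction.
#' @param votu_id Used to label an empty prediction when `hits` is empty.
#' @param top_n Number of top hits considered (default 5).
#' @return One-row data.frame: `votu_id`, the seven ranks (`NA` =
#'   unassigned), `source`, `n_supporting_hits`.
#' @export
hostConsensus <- function(hits, votu_id = NULL, top_n = 5L) {
  if (nrow(hits) == 0) {
    if (is.null(votu_id)) .stopf("votu_id needed for an empty prediction")
    return(.empty_prediction(votu_id, "none"))
  }
  if (length(unique(hits$query_id)) != 1)
    .stopf("hostConsensus expects hits for a single query")
  if (length(unique(hits$db_label)) != 1)
    .stopf("hostConsensus expects hits from a single database")
  ord <- order(-hits$bitscore, hits$evalue, hits$subject_id, method = "radix")
  top <- hits[ord[seq_len(min(top_n, nrow(hits)))], , drop = FALSE]
  pred <- .empty_prediction(hits$query_id[1], top$db_label[1])
  pred$n_supporting_hits <- nrow(top)
  for (r in .TAX_RANKS) {
    vals <- top[[r]]
    vals[is.na(vals)] <- ""
    if (length(unique(vals)) == 1 && vals[1] != "") pred[[r]] <- vals[1]
    else break
  }
  .truncate_ranks(pred)
}

#' Merge RefSeq- and MAG-based host predictions
#'
#' Per rank: where both databases assign a name and they disagree, the
#' MAG-based name wins (MAGs come from the same environment and are the
#' more trustworthy host source); where only one database assigns, that
#' name is used. The source is recorded as `merged` when both databases
#' contributed at least one rank. After merging, rank consistency is
#' enforced by truncating below the first unassigned rank.
#'
#' @param refseq_pred,mag_pred One-row predictions from [hostConsensus()]
#'   for the same vOTU.
#' @return One-row merged prediction.
#' @export
mergePredictions <- function(refseq_pred, mag_pred) {
  if (refseq_pred$votu_id != mag_pred$votu_id)
    .stopf("cannot merge predictions for different vOTUs (%s vs %s)",
           refseq_pred$votu_id, mag_pred$votu_id)
  out <- .empty_prediction(refseq_pred$votu_id, "merged")
  used_ref <- FALSE; used_mag <- FALSE
  for (r in .TAX_RANKS) {
    rv <- refseq_pred[[r]]; mv <- mag_pred[[r]]
    if (!is.na(mv)) {
      out[[r]] <- mv
      used_mag <- TRUE
      if (!is.na(rv) && rv == mv) used_ref <- TRUE
    } else if (!is.na(rv)) {
      out[[r]] <- rv
      used_ref <- TRUE
    }
  }
  out$source <- if (used_ref && used_mag) "merged"
    else if (used_mag) "mag" else if (used_ref) "refseq" else "none"
  out$n_supporting_hits <- max(refseq_pred$n_supporting_hits,
                               mag_pred$n_supporting_hits)
  .truncate_ranks(out)
}

#' Predict hosts for all queries in a combined hit table
#'
#' Runs the full procedure: threshold filtering ([filterHits()]),
#' per-database top-5 consensus ([hostConsensus()]) and dual-database
#' merging ([mergePredictions()]).
#'
#' @param hits Combined hit records (both databases).
#' @param votu_ids vOTUs to predict for; defaults to the queries present.
#'   vOTUs with no passing hit get an all-unassigned prediction.
#' @param ... Threshold overrides passed to [filterHits()].
#' @return data.frame with one row per vOTU.
#' @export
predictHosts <- function(hits, votu_ids = NULL, ...) {
  filtered <- filterHits(hits, ...)
  if (is.null(votu_ids))
    votu_ids <- sort(unique(hits$query_id))
  out <- lapply(votu_ids, function(v) {
    sub <- filtered[filtered$query_id == v, , drop = FALSE]
    preds <- lapply(c("refseq", "mag"), function(db) {
      hostConsensus(sub[sub$db_label == db, , drop = FALSE], votu_id = v)
    })
    mergePredictions(preds[[1]], preds[[2]])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize host predictions
#'
#' @param predictions data.frame from [predictHosts()].
#' @return List with `n` (predictions), `n_predicted` and `predicted_pct`
#'   (vOTUs with at least one assigned rank, percentage to two decimals),
#'   `phylum_counts` (named vector over assigned phyla) and `by_source`
#'   (count of predicted vOTUs per source database).
#' @export
summarizeHosts <- function(predictions) {
  n <- nrow(predictions)
  if (n == 0)
    return(list(n = 0L, n_predicted = 0L, predicted_pct = 0,
                phylum_counts = integer(0), by_source = integer(0)))
  has_any <- rowSums(!is.na(as.matrix(predictions[.TAX_RANKS]))) > 0
  phyl <- predictions$phylum[!is.na(predictions$phylum)]
  list(n = as.integer(n), n_predicted = as.integer(sum(has_any)),
       predicted_pct = round(100 * sum(has_any) / n, 2),
       phylum_counts = if (length(phyl))
         sort(table(phyl), decreasing = TRUE) else integer(0),
       by_source = table(predictions$source[has_any]))
}
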