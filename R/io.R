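# Readers/writers for the external formats the pipeline touches.
#
# Coordinate convention: all interval formats are 0-based half-open (BED);
# positions are reported 1-based only in user-facing error messages.

.OUTFMT6 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read predicted viral contigs from a FASTA file
#'
#' Parses a (optionally gzipped) multi-record FASTA of predicted viral
#' contigs into a [ViralSeqSet-class]. Sequences are uppercased; ids are the
#' first whitespace-delimited token of each header and must be unique.
#' Characters outside `ACGTN` are rejected rather than coerced, so upstream
#' corruption surfaces immediately.
#'
#' @param path Path to the FASTA file.
#' @param sample_id Source sample id recorded on every contig (a single
#'   value, or a vector recycled across contigs).
#' @param quality Optional quality table from [readQualityTable()]; contigs
#'   absent from it keep tier `"not_determined"`.
#' @return A [ViralSeqSet-class]. An empty file yields an empty set.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">v1", "ACGTACGT", ">v2", "GGCC"), f)
#' readViralFasta(f)
#' @export
readViralFasta <- function(path, sample_id = NA_character_, quality = NULL) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) {
    vs <- ViralSeqSet(Biostrings::DNAStringSet())
  } else {
    # light structural scan so malformed records get a line number
    first <- nonempty[1]
    if (!startsWith(trimws(lines[first]), ">"))
      .stopf("FASTA parse error at line %d: expected a '>' header", first)
    headers <- which(startsWith(trimws(lines), ">"))
    for (i in seq_along(headers)) {
      h <- headers[i]
      id <- sub("\\s.*$", "", sub("^>", "", trimws(lines[h])))
      if (!nzchar(id))
        .stopf("FASTA parse error at line %d: empty header id", h)
      upto <- if (i < length(headers)) headers[i + 1] - 1 else length(lines)
      body <- lines[seq(h + 1, length.out = max(0, upto - h))]
      if (sum(nchar(trimws(body))) == 0)
        .stopf("FASTA parse error at line %d: record '%s' has an empty sequence",
               h, id)
      bad <- grepl("[^ACGTNacgtn]", trimws(body))
      if (any(bad))
        .stopf("FASTA parse error at line %d: characters outside ACGTN in record '%s'",
               h + which(bad)[1], id)
    }
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
      .stopf("duplicate contig id(s) in %s: %s", path,
             paste(unique(names(seqs)[duplicated(names(seqs))]),
                   collapse = ", "))
    vs <- ViralSeqSet(Biostrings::DNAStringSet(toupper(seqs)),
                      sample_id = sample_id)
  }
  if (!is.null(quality)) vs <- applyQualityTable(vs, quality)
  vs
}

#' Write a ViralSeqSet to FASTA
#'
#' Writes sequences with headers equal to the contig ids, wrapped at a fixed
#' line width, so `writeViralFasta()` followed by [readViralFasta()]
#' round-trips ids and sequence content exactly.
#'
#' @param x A [ViralSeqSet-class].
#' @param path Output path.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
writeViralFasta <- function(x, path, width = 80L) {
  Biostrings::writeXStringSet(sequences(x), path, width = width)
  invisible(path)
}

#' Read a CheckV-style quality summary table
#'
#' Expects a tab-separated table with columns `contig_id`, `checkv_quality`
#' and `provirus`. Quality labels are normalised to the package vocabulary
#' (`complete`, `high`, `medium`, `low`, `not_determined`), accepting the
#' usual CheckV spellings such as `"High-quality"` or `"Not-determined"`.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `contig_id`, `quality_tier`,
#'   `is_provirus`.
#' @export
readQualityTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "checkv_quality", "provirus")
  if (!all(need %in% colnames(df)))
    .stopf("quality table %s must have columns %s", path,
           paste(need, collapse = ", "))
  tier <- tolower(gsub("-quality$", "", gsub(" ", "-", df$checkv_quality)))
  tier <- gsub("-", "_", tier)
  tier[tier == ""] <- "not_determined"
  bad <- !tier %in% .QUALITY_TIERS
  if (any(bad))
    .stopf("unrecognized quality label(s): %s",
           paste(unique(df$checkv_quality[bad]), collapse = ", "))
  data.frame(contig_id = as.character(df$contig_id), quality_tier = tier,
             is_provirus = df$provirus %in% c(TRUE, "Yes", "yes", "TRUE", 1),
             stringsAsFactors = FALSE)
}

#' Attach quality tiers to a ViralSeqSet
#'
#' Contigs absent from the table keep `"not_determined"`.
#'
#' @param x A [ViralSeqSet-class].
#' @param quality data.frame from [readQualityTable()].
#' @return The updated [ViralSeqSet-class].
#' @export
applyQualityTable <- function(x, quality) {
  idx <- match(seqIds(x), quality$contig_id)
  tier <- ifelse(is.na(idx), "not_determined", quality$quality_tier[idx])
  prov <- ifelse(is.na(idx), x@info$is_provirus, quality$is_provirus[idx])
  x@info$quality_tier <- tier
  x@info$is_provirus <- as.logical(prov)
  validObject(x)
  x
}

#' Read a BLAST outfmt-6 hit table with its taxonomy sidecar
#'
#' Reads tab-separated blastn hits in the standard 12-column outfmt-6 layout
#' and joins each hit to its subject's length and 7-rank taxonomy from a
#' sidecar table (TSV columns: `subject_id`, `length`, then
#' domain/phylum/class/order/family/genus/species; empty string = unknown
#' rank). Hits whose subject is missing from the sidecar are dropped with a
#' warning that reports the count.
#'
#' @param path Hit table path (12-column outfmt 6, no header).
#' @param taxonomy_path Sidecar path (9 columns, no header).
#' @param db_label Which database the hits are against: `"refseq"` or
#'   `"mag"`.
#' @return data.frame of hit records: `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `evalue`, `bitscore`, `subject_length`,
#'   `db_label` and the seven rank columns.
#' @export
readHitTable <- function(path, taxonomy_path, db_label = c("refseq", "mag")) {
  db_label <- match.arg(db_label)
  raw <- if (file.size(path) == 0)
    data.frame() else
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
  if (nrow(raw) > 0 && ncol(raw) < length(.OUTFMT6))
    .stopf("hit table %s: expected %d outfmt-6 columns, found %d", path,
           length(.OUTFMT6), ncol(raw))
  if (nrow(raw) == 0) {
    hits <- data.frame(query_id = character(), subject_id = character(),
                       pct_identity = numeric(), aln_length = integer(),
                       evalue = numeric(), bitscore = numeric(),
                       stringsAsFactors = FALSE)
  } else {
    colnames(raw)[seq_along(.OUTFMT6)] <- .OUTFMT6
    num <- function(col) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      if (anyNA(v))
        .stopf("hit table %s: non-numeric '%s' at line %d", path, col,
               which(is.na(v))[1])
      v
    }
    hits <- data.frame(query_id = raw$qseqid, subject_id = raw$sseqid,
                       pct_identity = num("pident"),
                       aln_length = as.integer(num("length")),
                       evalue = num("evalue"), bitscore = num("bitscore"),
                       stringsAsFactors = FALSE)
    if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
      .stopf("hit table %s: percent identity outside [0, 100] at line %d",
             path, which(hits$pct_identity < 0 | hits$pct_identity > 100)[1])
    if (any(hits$aln_length < 0))
      .stopf("hit table %s: negative alignment length", path)
    if (any(hits$evalue < 0))
      .stopf("hit table %s: negative e-value", path)
  }
  tax <- readTaxonomySidecar(taxonomy_path)
  idx <- match(hits$subject_id, tax$subject_id)
  if (anyNA(idx)) {
    n_dropped <- sum(is.na(idx))
    .warnf("%d hit(s) dropped: subject absent from taxonomy sidecar %s",
           n_dropped, taxonomy_path)
    hits <- hits[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  hits$subject_length <- tax$length[idx]
  hits$db_label <- rep(db_label, nrow(hits))
  for (r in .TAX_RANKS) hits[[r]] <- tax[[r]][idx]
  rownames(hits) <- NULL
  hits
}

#' Read a subject-taxonomy sidecar table
#'
#' Fixed 9-column TSV without header: `subject_id`, `length`, then the seven
#' ranks domain..species (empty string = unknown).
#'
#' @param path Sidecar path.
#' @return data.frame with `subject_id`, `length` and one column per rank.
#' @export
readTaxonomySidecar <- function(path) {
  raw <- if (file.size(path) == 0)
    data.frame() else
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
  if (nrow(raw) == 0) {
    out <- data.frame(subject_id = character(), length = integer())
    for (r in .TAX_RANKS) out[[r]] <- character()
    return(out)
  }
  if (ncol(raw) != 2 + length(.TAX_RANKS))
    .stopf("taxonomy sidecar %s: expected %d columns, found %d", path,
           2 + length(.TAX_RANKS), ncol(raw))
  len <- suppressWarnings(as.integer(raw[[2]]))
  if (anyNA(len) || any(len <= 0))
    .stopf("taxonomy sidecar %s: subject length must be a positive integer (line %d)",
           path, which(is.na(len) | len <= 0)[1])
  out <- data.frame(subject_id = raw[[1]], length = len,
                    stringsAsFactors = FALSE)
  for (i in seq_along(.TAX_RANKS)) out[[.TAX_RANKS[i]]] <- raw[[2 + i]]
  out
}

#' Read a BED-like per-contig coverage table
#'
#' Rows are `(contig, start, end, depth)` in 0-based half-open coordinates,
#' as produced by `bedtools genomecov -bga`-style tools. Within each contig,
#' intervals must be non-overlapping; gaps imply depth 0. Rows with zero
#' depth are retained (they carry breadth information explicitly, though
#' omitted gaps are equivalent).
#'
#' @param path Coverage table path (TSV, no header).
#' @param sample_id Sample the table belongs to; if the file has a 5th
#'   column it is used as the per-row sample id instead.
#' @return A coverage data.frame with columns `votu_id`, `sample_id`,
#'   `start`, `end`, `depth`, sorted by contig and start.
#' @export
readCoverageBed <- function(path, sample_id = NA_character_) {
  empty <- data.frame(votu_id = character(), sample_id = character(),
                      start = integer(), end = integer(), depth = integer(),
                      stringsAsFactors = FALSE)
  if (!file.exists(path)) .stopf("coverage file not found: %s", path)
  if (file.size(path) == 0) return(empty)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) return(empty)
  if (ncol(raw) < 4)
    .stopf("coverage table %s: expected at least 4 columns", path)
  cov <- data.frame(
    votu_id = as.character(raw[[1]]),
    sample_id = if (ncol(raw) >= 5) as.character(raw[[5]])
                else rep(as.character(sample_id), nrow(raw)),
    start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
    depth = as.integer(raw[[4]]), stringsAsFactors = FALSE)
  validateCoverage(cov, context = path)
}

#' Validate a coverage data.frame
#'
#' Enforces the interval invariants: `end > start`, depths non-negative, and
#' no overlapping intervals within one `(votu_id, sample_id)` pair.
#'
#' @param cov Coverage data.frame (`votu_id`, `sample_id`, `start`, `end`,
#'   `depth`).
#' @param context Label used in error messages.
#' @return The coverage data.frame sorted by contig, sample and start.
#' @export
validateCoverage <- function(cov, context = "coverage") {
  if (nrow(cov) == 0) return(cov)
  if (anyNA(cov$start) || anyNA(cov$end) || anyNA(cov$depth))
    .stopf("%s: non-numeric interval fields", context)
  if (any(cov$end <= cov$start))
    .stopf("%s: interval with end <= start for contig %s", context,
           cov$votu_id[which(cov$end <= cov$start)[1]])
  if (any(cov$depth < 0))
    .stopf("%s: negative depth", context)
  ord <- order(cov$votu_id, cov$sample_id, cov$start)
  cov <- cov[ord, , drop = FALSE]
  key <- paste(cov$votu_id, cov$sample_id, sep = "\r")
  same <- key[-1] == key[-length(key)]
  overlap <- same & cov$start[-1] < cov$end[-nrow(cov)]
  if (any(overlap))
    .stopf("%s: overlapping intervals for contig %s", context,
           cov$votu_id[which(overlap)[1] + 1])
  rownames(cov) <- NULL
  cov
}

#' Write a coverage data.frame as BED-like TSV
#' @param cov Coverage data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCoverageBed <- function(cov, path) {
  utils::write.table(cov[, c("votu_id", "start", "end", "depth", "sample_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Expand coverage intervals to a per-base depth vector
#'
#' Positions not covered by any interval get depth 0; expanding then
#' re-compressing with [depthToIntervals()] is lossless.
#'
#' @param cov Coverage data.frame.
#' @param votu_id,sample_id Which record to expand.
#' @param length Contig length in bp.
#' @return Integer vector of per-base depths, length `length`.
#' @export
expandCoverage <- function(cov, votu_id, sample_id, length) {
  sel <- cov$votu_id == votu_id & cov$sample_id == sample_id
  sub <- cov[sel, , drop = FALSE]
  if (nrow(sub) > 0 && max(sub$end) > length)
    .stopf("coverage for %s extends past the contig length (%d > %d)",
           votu_id, max(sub$end), length)
  depth <- integer(length)
  for (i in seq_len(nrow(sub)))
    depth[(sub$start[i] + 1):sub$end[i]] <- sub$depth[i]
  depth
}

#' Compress a per-base depth vector into run intervals
#'
#' @param depth Integer vector of per-base depths.
#' @param keep_zero Keep zero-depth runs as explicit rows (default `FALSE`;
#'   gaps imply zero).
#' @return data.frame with `start`, `end`, `depth` in 0-based half-open
#'   coordinates.
#' @export
depthToIntervals <- function(depth, keep_zero = FALSE) {
  if (length(depth) == 0)
    return(data.frame(start = integer(), end = integer(), depth = integer()))
  r <- rle(as.integer(depth))
  end <- cumsum(r$lengths)
  out <- data.frame(start = c(0L, end[-length(end)]), end = end,
                    depth = r$values)
  if (!keep_zero) out <- out[out$depth > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read the sample metadata table
#'
#' CSV with a header row; required columns `sample_id`, `site`, `region`,
#' `rock_type`, `latitude`, `longitude`; optional `altitude_m` and
#' `sun_exposure`. Region and rock-type vocabularies and coordinate ranges
#' are validated.
#'
#' @param path Metadata CSV path.
#' @return data.frame of sample metadata.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "site", "region", "rock_type", "latitude",
            "longitude")
  if (!all(need %in% colnames(df)))
    .stopf("metadata %s must have columns %s", path,
           paste(setdiff(need, colnames(df)), collapse = ", "))
  validateMetadata(df)
}

#' Validate sample metadata
#' @param df Metadata data.frame.
#' @return The validated data.frame (with defaults filled in).
#' @export
validateMetadata <- function(df) {
  if (anyDuplicated(df$sample_id)) .stopf("duplicated sample_id in metadata")
  if (!all(df$region %in% .REGIONS))
    .stopf("unknown region(s): %s",
           paste(unique(setdiff(df$region, .REGIONS)), collapse = ", "))
  if (!all(df$rock_type %in% .ROCK_TYPES))
    .stopf("unknown rock type(s): %s",
           paste(unique(setdiff(df$rock_type, .ROCK_TYPES)), collapse = ", "))
  if (any(df$latitude < -90 | df$latitude > 90))
    .stopf("latitude outside [-90, 90]")
  if (any(df$longitude < -180 | df$longitude > 180))
    .stopf("longitude outside [-180, 180]")
  if (is.null(df$altitude_m)) df$altitude_m <- NA_real_
  if (is.null(df$sun_exposure)) df$sun_exposure <- "unknown"
  if (!all(df$sun_exposure %in% c("north_exposed", "south_shady", "unknown")))
    .stopf("unknown sun_exposure label")
  df
}

#' Read a DRAM-v-style distilled AMG table
#'
#' TSV with header; columns `votu_id`, `gene_id`, `distilled_category`,
#' `distilled_module`. An empty `distilled_category` marks the auxiliary
#' metabolic gene as unclassified.
#'
#' @param path AMG table path.
#' @return data.frame of AMG records.
#' @export
readAMGTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("votu_id", "gene_id", "distilled_category", "distilled_module")
  if (!all(need %in% colnames(df)))
    .stopf("AMG table %s must have columns %s", path,
           paste(need, collapse = ", "))
  df[need]
}

#' Read a genome protein-cluster profile table
#'
#' Long-format TSV with header; columns `genome_id`, `protein_cluster_id`,
#' one row per (genome, protein cluster) occurrence.
#'
#' @param path Profile table path.
#' @return Named list mapping genome id to its character vector of protein
#'   cluster ids.
#' @export
readProfileTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("genome_id", "protein_cluster_id") %in% colnames(df)))
    .stopf("profile table %s must have columns genome_id, protein_cluster_id",
           path)
  lapply(split(df$protein_cluster_id, df$genome_id), unique)
}

#' Read reference genome taxonomy for viral-cluster labeling
#'
#' TSV with header; columns `genome_id` plus the ranks `class`, `order`,
#' `family`, `genus` (empty string = unknown).
#'
#' @param path Reference taxa path.
#' @return data.frame keyed by `genome_id`.
#' @export
readReferenceTaxa <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"genome_id" %in% colnames(df))
    .stopf("reference taxa %s must have a genome_id column", path)
  for (r in .VC_RANKS) if (is.null(df[[r]])) df[[r]] <- ""
  df[c("genome_id", .VC_RANKS)]
}
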