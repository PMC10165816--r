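# End-to-end pipeline: cluster -> abundance/filter -> hosts -> VCs ->
# ecology, with a deterministic plain-text report.

.PIPELINE_DEFAULTS <- list(
  input_dir = NULL, out_dir = NULL,
  identity = 0.95, short_cov = 0.85,
  breadth_min = 0.75, trim_fraction = 0.10, mapping_identity = 0.90,
  min_len = 10000L,
  min_aln = 2000L, min_identity = 70, min_bitscore = 50,
  max_evalue = 0.001, max_mag_cov = 0.5,
  vc_threshold = 1.0, inflation = 2.0,
  universe_size = NULL,
  n_perm = 9999L, seed = 1L,
  log_level = "info")

#' Assemble a pipeline configuration
#'
#' Starts from the standard defaults (95% clustering identity, 85%
#' short-sequence coverage, 75% detection breadth, 10 kbp length filter,
#' 2000 bp / 70% / bitscore 50 / e-value 0.001 host-hit thresholds, 9,999
#' permutations), optionally overlaid with a YAML config file, then with
#' explicit arguments. Unknown keys are rejected.
#'
#' @param path Optional YAML file of settings.
#' @param ... Named overrides of individual settings.
#' @return A named list of class `pipeline_config`.
#' @export
pipelineConfig <- function(path = NULL, ...) {
  cfg <- .PIPELINE_DEFAULTS
  overlay <- function(cfg, vals, origin) {
    unknown <- setdiff(names(vals), names(.PIPELINE_DEFAULTS))
    if (length(unknown) > 0)
      .stopf("unknown config key(s) in %s: %s", origin,
             paste(unknown, collapse = ", "))
    cfg[names(vals)] <- vals
    cfg
  }
  if (!is.null(path)) cfg <- overlay(cfg, yaml::read_yaml(path), path)
  args <- list(...)
  if (length(args) > 0) cfg <- overlay(cfg, args, "arguments")
  structure(cfg, class = "pipeline_config")
}

.pipe_log <- function(con, level, fmt, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), sprintf(fmt, ...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

.stage <- function(name, log_con, expr) {
  tryCatch(expr, error = function(e) {
    .pipe_log(log_con, "error", "stage '%s' failed: %s", name,
              conditionMessage(e))
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

.write_tsv <- function(x, path, rn = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = rn, col.names = if (rn) NA else TRUE)
  invisible(path)
}

#' Run the full virome pipeline on a fixture-format input directory
#'
#' Executes clustering, abundance/detection filtering, host prediction,
#' viral-cluster taxonomy and ecology on the files written by
#' [simulateFixture()] (or real data arranged the same way), writing
#' per-stage TSV outputs and a summary report to `out_dir`. All outputs
#' except the timestamped `run.log` are deterministic given the
#' configuration seed. A stage failure stops with an error naming the
#' stage; outputs of earlier stages are retained.
#'
#' @param config A `pipeline_config` from [pipelineConfig()] with
#'   `input_dir` and `out_dir` set (or the arguments to build one).
#' @param ... Passed to [pipelineConfig()] when `config` is a path or
#'   missing pieces are supplied directly.
#' @return Invisibly, a list with every stage's result objects.
#' @export
runPipeline <- function(config, ...) {
  if (!inherits(config, "pipeline_config"))
    config <- pipelineConfig(config, ...)
  if (is.null(config$input_dir) || is.null(config$out_dir))
    .stopf("config must set input_dir and out_dir")
  ind <- config$input_dir; outd <- config$out_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(outd, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  lg <- function(fmt, ...) .pipe_log(log_con, "info", fmt, ...)
  res <- list(config = config)
  lg("pipeline start (seed %d)", config$seed)

  res$sequences <- .stage("io", log_con, {
    qual <- readQualityTable(file.path(ind, "quality.tsv"))
    readViralFasta(file.path(ind, "contigs.fasta"), quality = qual)
  })
  res$quality <- readQualityTable(file.path(ind, "quality.tsv"))
  res$metadata <- .stage("io", log_con,
                         readSampleMetadata(file.path(ind, "metadata.csv")))
  lg("io: %d contigs, %d samples", length(res$sequences),
     nrow(res$metadata))

  res$catalog <- .stage("cluster", log_con, {
    clusterVOTUs(res$sequences, identity = config$identity,
                 short_cov = config$short_cov)
  })
  lg("cluster: %d vOTUs at identity %.2f / short coverage %.2f",
     length(res$catalog), config$identity, config$short_cov)
  .write_tsv(memberTable(res$catalog), file.path(outd, "catalog.tsv"))

  res$abundance <- .stage("abundance", log_con, {
    cov_path <- file.path(ind, "coverage.bed")
    if (!file.exists(cov_path))
      .stopf("coverage file not found: %s", cov_path)
    cov <- readCoverageBed(cov_path)
    buildAbundanceMatrix(cov, seqLengths(res$sequences),
                         samples = res$metadata$sample_id,
                         breadth_min = config$breadth_min,
                         trim_fraction = config$trim_fraction,
                         mapping_identity = config$mapping_identity)
  })
  lg("abundance: %d samples x %d detected vOTUs (breadth >= %.2f, trim %.2f)",
     nrow(res$abundance@values), ncol(res$abundance@values),
     config$breadth_min, config$trim_fraction)
  .write_tsv(abundanceValues(res$abundance),
             file.path(outd, "abundance.tsv"), rn = TRUE)

  res$filtered <- .stage("filter", log_con, {
    filterCatalog(res$catalog, res$quality,
                  detectionMask(res$abundance), min_len = config$min_len)
  })
  survivors <- representatives(res$filtered)
  lg("filter: %d vOTUs survive length >= %d / quality / detection",
     length(survivors), config$min_len)
  .write_tsv(filterFlags(res$filtered), file.path(outd, "filter_flags.tsv"))

  res$hosts <- .stage("hosts", log_con, {
    hits <- rbind(
      readHitTable(file.path(ind, "hits_refseq.tsv"),
                   file.path(ind, "taxonomy_refseq.tsv"), "refseq"),
      readHitTable(file.path(ind, "hits_mag.tsv"),
                   file.path(ind, "taxonomy_mag.tsv"), "mag"))
    predictHosts(hits, votu_ids = sort(unique(res$catalog@members$representative_id)),
                 min_aln = config$min_aln, min_identity = config$min_identity,
                 min_bitscore = config$min_bitscore,
                 max_evalue = config$max_evalue,
                 max_mag_cov = config$max_mag_cov)
  })
  res$host_summary <- summarizeHosts(res$hosts)
  lg("hosts: %.2f%% of vOTUs with a prediction",
     res$host_summary$predicted_pct)
  .write_tsv(res$hosts, file.path(outd, "hosts.tsv"))

  res$vcs <- .stage("vc", log_con, {
    profiles <- readProfileTable(file.path(ind, "profiles.tsv"))
    ref_taxa <- readReferenceTaxa(file.path(ind, "reference_taxa.tsv"))
    universe <- config$universe_size
    if (is.null(universe))
      universe <- length(unique(unlist(profiles, use.names = FALSE))) + 50L
    buildViralClusters(profiles, universe, ref_taxa,
                       threshold = config$vc_threshold,
                       inflation = config$inflation)
  })
  res$vc_summary <- summarizeVCs(res$vcs)
  lg("vc: %d VCs, %.1f%% unique", res$vc_summary$n_vcs,
     res$vc_summary$unique_pct)
  vc_rows <- data.frame(genome_id = res$vcs@genomes,
                        stringsAsFactors = FALSE)
  vc_of <- rep(NA_character_, nrow(vc_rows))
  for (vc in names(vcMembership(res$vcs)))
    vc_of[vc_rows$genome_id %in% vcMembership(res$vcs)[[vc]]] <- vc
  vc_rows$vc_id <- vc_of
  vc_rows$status <- genomeStatus(res$vcs)[vc_rows$genome_id]
  .write_tsv(vc_rows, file.path(outd, "vcs.tsv"))
  .write_tsv(vcTaxonomy(res$vcs), file.path(outd, "vc_taxonomy.tsv"))

  res$amg_summary <- .stage("amg", log_con, {
    amg_path <- file.path(ind, "amgs.tsv")
    if (file.exists(amg_path)) summarizeAMGs(readAMGTable(amg_path))
    else summarizeAMGs(data.frame(votu_id = character(),
                                  gene_id = character(),
                                  distilled_category = character(),
                                  distilled_module = character()))
  })

  res$ecology <- .stage("ecology", log_con, {
    am <- res$abundance
    keep <- colnames(abundanceValues(am)) %in% survivors
    vals <- abundanceValues(am)[, keep, drop = FALSE]
    det <- detectionMask(am)[, keep, drop = FALSE]
    amf <- new("AbundanceMatrix", values = vals, detection = det,
               params = am@params)
    dmat <- suppressWarnings(hellingerDistance(amf))
    ord <- pcoaOrdination(dmat)
    meta <- res$metadata
    terms <- c("site", "rock_type")
    terms <- terms[vapply(terms, function(t)
      length(unique(meta[[t]])) >= 2, logical(1))]
    perm_t <- permanova(dmat, meta, terms = terms, n_perm = config$n_perm,
                        mode = "terms", seed = config$seed)
    perm_m <- if (length(terms) > 1)
      permanova(dmat, meta, terms = terms, n_perm = config$n_perm,
                mode = "margin", seed = config$seed) else NULL
    disp <- betadisperPermutest(dmat, stats::setNames(meta$site,
                                                      meta$sample_id),
                                n_perm = config$n_perm, seed = config$seed)
    occupancy <- occupancySummary(amf, meta)
    # distance-decay: sandstone samples outside the peninsula, as in the
    # survey design; fall back to all samples if the subset is too small
    sel <- meta$rock_type == "sandstone" &
      meta$region != "antarctic_peninsula"
    sub_ids <- meta$sample_id[sel]
    use_all <- length(sub_ids) < 4 ||
      length(unique(meta$site[sel])) < 2
    ids <- if (use_all) meta$sample_id else sub_ids
    meta_sub <- meta[meta$sample_id %in% ids, , drop = FALSE]
    dsub <- as_dist_matrix(dmat)[meta_sub$sample_id, meta_sub$sample_id]
    gsub <- geoDistanceMatrix(meta_sub)
    mant <- mantelTest(dsub, gsub, n_perm = config$n_perm,
                       seed = config$seed)
    mant_nz <- tryCatch(
      mantelTest(dsub, gsub, n_perm = config$n_perm,
                 exclude_zero_geo = TRUE, seed = config$seed),
      error = function(e) NULL)
    list(matrix = amf, distance = dmat, pcoa = ord,
         permanova_terms = perm_t, permanova_margin = perm_m,
         betadisper = disp, occupancy = occupancy, mantel = mant,
         mantel_no_zero = mant_nz, mantel_all_samples = use_all)
  })
  lg("ecology: PERMANOVA + dispersion + Mantel complete")
  .write_tsv(as.matrix(res$ecology$distance), file.path(outd, "distance.tsv"),
             rn = TRUE)
  .write_tsv(res$ecology$pcoa$coordinates, file.path(outd, "pcoa.tsv"),
             rn = TRUE)
  .write_tsv(as.data.frame(res$ecology$permanova_terms),
             file.path(outd, "permanova_terms.tsv"), rn = TRUE)
  if (!is.null(res$ecology$permanova_margin))
    .write_tsv(as.data.frame(res$ecology$permanova_margin),
               file.path(outd, "permanova_margin.tsv"), rn = TRUE)

  writeLines(.pipeline_report(res), file.path(outd, "report.txt"))
  lg("pipeline done; report at %s", file.path(outd, "report.txt"))
  invisible(res)
}

.fmt_or_na <- function(x, fmt = "%.2f") {
  if (is.null(x) || is.na(x)) "NA" else sprintf(fmt, x)
}

.pipeline_report <- function(res) {
  cfg <- res$config
  qual <- summarizeQuality(res$catalog, res$quality)
  eco <- res$ecology
  occ <- eco$occupancy
  amg <- res$amg_summary
  hs <- res$host_summary
  vs <- res$vc_summary
  pt <- eco$permanova_terms
  lines <- c(
    "Endolith virome pipeline report",
    "===============================",
    "",
    sprintf("Parameters: identity=%.2f short_cov=%.2f breadth_min=%.2f trim=%.2f min_len=%d",
            cfg$identity, cfg$short_cov, cfg$breadth_min,
            cfg$trim_fraction, cfg$min_len),
    sprintf("            host thresholds: aln>=%d id>=%g bits>=%g e<=%g mag_cov<%g",
            cfg$min_aln, cfg$min_identity, cfg$min_bitscore,
            cfg$max_evalue, cfg$max_mag_cov),
    sprintf("            permutations=%d seed=%d", cfg$n_perm, cfg$seed),
    "",
    "Catalog",
    "-------",
    sprintf("  input sequences: %d", length(res$sequences)),
    sprintf("  vOTUs: %d", length(res$catalog)),
    sprintf("  surviving vOTUs after length/quality/detection filter: %d",
            length(res$filtered)),
    sprintf("  quality tiers (members): %s",
            paste(sprintf("%s=%d", names(qual), qual), collapse = " ")),
    "",
    "Hosts",
    "-----",
    sprintf("  vOTUs with a host prediction: %d / %d (%.2f%%)",
            hs$n_predicted, hs$n, hs$predicted_pct),
    if (length(hs$phylum_counts) > 0)
      sprintf("  top predicted phyla: %s",
              paste(sprintf("%s=%d", names(hs$phylum_counts),
                            hs$phylum_counts), collapse = " "))
    else "  top predicted phyla: none",
    "",
    "Viral clusters",
    "--------------",
    sprintf("  VCs: %d (with references: %d, unique: %d = %s%%)",
            vs$n_vcs, vs$n_with_references, vs$n_unique,
            .fmt_or_na(vs$unique_pct, "%.1f")),
    sprintf("  genome status: %s",
            paste(sprintf("%s=%d", names(table(genomeStatus(res$vcs))),
                          table(genomeStatus(res$vcs))), collapse = " ")),
    "",
    "AMGs",
    "----",
    sprintf("  records: %d, unclassified: %d (%s%%)", amg$total,
            amg$n_unclassified, .fmt_or_na(amg$unclassified_pct, "%.1f")),
    "",
    "Ecology",
    "-------",
    sprintf("  occupancy: %d vOTUs detected; >1 site %.2f%%; >=2 regions %.2f%%; all regions %.2f%%",
            occ$n_votus, occ$multi_site_pct, occ$multi_region_pct,
            occ$all_regions_pct),
    "  PERMANOVA (by = terms):",
    paste0("    ", utils::capture.output(print.data.frame(
      as.data.frame(pt), digits = 4))),
    sprintf("  dispersion test: F = %.4f, p = %.4g", eco$betadisper$F,
            eco$betadisper$p),
    sprintf("  Mantel%s: r = %s, p = %s",
            if (eco$mantel_all_samples) " (all samples)"
            else " (sandstone, peninsula excluded)",
            .fmt_or_na(eco$mantel$r, "%.4f"),
            .fmt_or_na(eco$mantel$p, "%.4g")),
    if (!is.null(eco$mantel_no_zero) && !eco$mantel_no_zero$constant)
      sprintf("  Mantel excluding zero-distance pairs: r = %s, p = %s",
              .fmt_or_na(eco$mantel_no_zero$r, "%.4f"),
              .fmt_or_na(eco$mantel_no_zero$p, "%.4g"))
    else "  Mantel excluding zero-distance pairs: not computed")
  unlist(lines)
}
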