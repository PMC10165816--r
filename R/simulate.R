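# Synthetic-data generators with planted ground truth.
#
# Every generator is deterministic given config$seed and leaves the caller's
# RNG stream untouched. Truth tables carry enough information to score all
# downstream stages (cluster recovery, host recovery, VC recovery,
# distance-decay recovery) without re-reading sequences.

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic-data generators, emulating a
#' multi-site endolith virome survey: mutated viral populations with known
#' cluster membership, spatially autocorrelated communities with a tunable
#' distance-decay, planted BLAST hosts and planted gene-sharing clusters.
#'
#' @param seed Integer RNG seed; full determinism across all generators.
#' @param n_ancestors Number of ancestral viral genomes.
#' @param genome_length_range Two-element bp range `(min, max)` for ancestor
#'   lengths.
#' @param divergence_levels Per-site substitution probabilities (each in
#'   `[0, 0.5)`) at which descendants are generated; expected nucleotide
#'   identity of a descendant to its ancestor is `1 - divergence`.
#' @param descendants_per_level Descendants per ancestor at each level.
#' @param n_sites Number of collection sites.
#' @param samples_per_site Metagenomes per site.
#' @param site_coords Optional matrix/data.frame of site `(lat, lon)`; the
#'   default interpolates a latitudinal transect between the survey's two
#'   endpoint coordinates (-62.10008, -58.51664) and (-77.874, 160.739).
#' @param decay_rate Community-similarity decay per km: a vOTU's presence
#'   probability at a site is `presence_home * exp(-decay_rate * d_km)` from
#'   its home site. Default 0.01/km (e-folding distance 100 km).
#' @param presence_home Presence probability at the home site (default 0.9).
#' @param depth_mean Mean read depth of a present vOTU (default 10x).
#' @param breadth_target Fraction of a present vOTU's length that is
#'   covered (contiguous; covered positions always have depth >= 1).
#' @param depth_window Width (bp) of the piecewise-constant depth windows
#'   used to emulate read-pileup smoothness (default 100).
#' @param host_identity Percent identity of planted virus-host matches.
#' @param host_segment_length Alignment length (bp) of planted matches.
#' @param share_fraction Fraction of a genome's protein clusters shared by
#'   all members of its planted viral cluster (default 0.6).
#' @param profile_size Protein clusters per genome profile (default 25).
#' @param amg_unclassified_frac Fraction of simulated auxiliary metabolic
#'   genes left without a distilled category (default 0.4).
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- simConfig(seed = 1, n_ancestors = 5, divergence_levels = 0.02)
#' pop <- generatePopulation(cfg)
#' length(pop$sequences)
#' @export
simConfig <- function(seed = 1L,
                      n_ancestors = 20L,
                      genome_length_range = c(5000L, 20000L),
                      divergence_levels = c(0.02, 0.10),
                      descendants_per_level = 3L,
                      n_sites = 6L,
                      samples_per_site = 4L,
                      site_coords = NULL,
                      decay_rate = 0.01,
                      presence_home = 0.9,
                      depth_mean = 10,
                      breadth_target = 0.9,
                      depth_window = 100L,
                      host_identity = 85,
                      host_segment_length = 3000L,
                      share_fraction = 0.6,
                      profile_size = 25L,
                      amg_unclassified_frac = 0.4) {
  cfg <- list(seed = as.integer(seed), n_ancestors = as.integer(n_ancestors),
              genome_length_range = as.integer(genome_length_range),
              divergence_levels = as.numeric(divergence_levels),
              descendants_per_level = as.integer(descendants_per_level),
              n_sites = as.integer(n_sites),
              samples_per_site = as.integer(samples_per_site),
              site_coords = site_coords, decay_rate = as.numeric(decay_rate),
              presence_home = as.numeric(presence_home),
              depth_mean = as.numeric(depth_mean),
              breadth_target = as.numeric(breadth_target),
              depth_window = as.integer(depth_window),
              host_identity = as.numeric(host_identity),
              host_segment_length = as.integer(host_segment_length),
              share_fraction = as.numeric(share_fraction),
              profile_size = as.integer(profile_size),
              amg_unclassified_frac = as.numeric(amg_unclassified_frac))
  counts <- c("n_ancestors", "descendants_per_level", "n_sites",
              "samples_per_site", "profile_size", "depth_window")
  for (f in counts)
    if (cfg[[f]] < 1L) .stopf("config field %s must be >= 1", f)
  if (length(cfg$genome_length_range) != 2 ||
      cfg$genome_length_range[1] > cfg$genome_length_range[2] ||
      cfg$genome_length_range[1] < 1)
    .stopf("genome_length_range must be an increasing positive pair")
  if (any(cfg$divergence_levels < 0 | cfg$divergence_levels >= 0.5))
    .stopf("divergence levels must lie in [0, 0.5)")
  if (cfg$decay_rate < 0) .stopf("decay_rate must be >= 0")
  if (cfg$presence_home <= 0 || cfg$presence_home > 1)
    .stopf("presence_home must lie in (0, 1]")
  if (cfg$breadth_target <= 0 || cfg$breadth_target > 1)
    .stopf("breadth_target must lie in (0, 1]")
  if (cfg$host_identity <= 0 || cfg$host_identity > 100)
    .stopf("host_identity must lie in (0, 100]")
  if (cfg$share_fraction < 0 || cfg$share_fraction > 1)
    .stopf("share_fraction must lie in [0, 1]")
  if (!is.null(site_coords)) {
    sc <- as.matrix(site_coords)
    if (nrow(sc) != cfg$n_sites || ncol(sc) != 2)
      .stopf("site_coords must be an n_sites x 2 (lat, lon) matrix")
    cfg$site_coords <- sc
  }
  class(cfg) <- "sim_config"
  cfg
}

.random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.mutate_genome <- function(seq_chars, divergence) {
  hit <- which(stats::runif(length(seq_chars)) < divergence)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      seq_chars[i] <- sample(setdiff(bases, seq_chars[i]), 1)
    }
  }
  list(seq = seq_chars, n_subs = length(hit))
}

#' Generate a mutated viral population with known cluster membership
#'
#' Draws random ancestral genomes and, for each ancestor and each
#' divergence level, descendants created by i.i.d. per-site substitution
#' (no indels by default, so the realized nucleotide identity of a
#' descendant to its ancestor is exactly `1 - substitutions/length`).
#' Ancestors drawn at random are mutually unrelated (~25% background
#' identity), so the ancestor partition is the planted vOTU truth.
#'
#' @param config A [simConfig()] object.
#' @return List with `sequences` (a [ViralSeqSet-class]) and `truth`, a
#'   data.frame with `seq_id`, `ancestor_id`, `divergence` and
#'   `realized_identity` (1 for the ancestors themselves).
#' @export
generatePopulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lens <- sample(seq(config$genome_length_range[1],
                       config$genome_length_range[2]),
                   config$n_ancestors, replace = TRUE)
    anc_ids <- sprintf("anc%03d", seq_len(config$n_ancestors))
    seqs <- character(0); ids <- character(0)
    truth <- vector("list", 0)
    for (a in seq_len(config$n_ancestors)) {
      anc_chars <- sample(c("A", "C", "G", "T"), lens[a], replace = TRUE)
      seqs <- c(seqs, paste(anc_chars, collapse = ""))
      ids <- c(ids, anc_ids[a])
      truth[[length(truth) + 1]] <- data.frame(
        seq_id = anc_ids[a], ancestor_id = anc_ids[a], divergence = 0,
        realized_identity = 1, stringsAsFactors = FALSE)
      for (d in config$divergence_levels) {
        for (j in seq_len(config$descendants_per_level)) {
          mut <- .mutate_genome(anc_chars, d)
          did <- sprintf("%s_div%03.0f_%d", anc_ids[a], d * 1000, j)
          seqs <- c(seqs, paste(mut$seq, collapse = ""))
          ids <- c(ids, did)
          truth[[length(truth) + 1]] <- data.frame(
            seq_id = did, ancestor_id = anc_ids[a], divergence = d,
            realized_identity = 1 - mut$n_subs / lens[a],
            stringsAsFactors = FALSE)
        }
      }
    }
    sset <- Biostrings::DNAStringSet(seqs)
    names(sset) <- ids
    list(sequences = ViralSeqSet(sset, sample_id = "sim"),
         truth = do.call(rbind, truth))
  })
}

.default_site_coords <- function(n_sites) {
  cbind(lat = seq(-62.10008, -77.874, length.out = n_sites),
        lon = seq(-58.51664, 160.739, length.out = n_sites))
}

.region_for_lat <- function(lat) {
  ifelse(lat >= -66, "antarctic_peninsula",
         ifelse(lat >= -76, "northern_victoria_land",
                "southern_victoria_land"))
}

#' Generate sample metadata for a multi-site survey
#'
#' Sites lie on a latitudinal transect (default: linear interpolation of
#' the survey's endpoint coordinates); regions are assigned by latitude
#' band and rock types are drawn with the survey's sandstone-dominated
#' proportions (141:43:5:2).
#'
#' @param config A [simConfig()] object.
#' @return Metadata data.frame (one row per metagenome) with columns
#'   `sample_id`, `site`, `region`, `rock_type`, `latitude`, `longitude`,
#'   `altitude_m`, `sun_exposure`.
#' @export
generateSampleMetadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    coords <- if (is.null(config$site_coords))
      .default_site_coords(config$n_sites) else config$site_coords
    n <- config$n_sites * config$samples_per_site
    site_idx <- rep(seq_len(config$n_sites), each = config$samples_per_site)
    df <- data.frame(
      sample_id = sprintf("s%02d_%02d", site_idx,
                          rep(seq_len(config$samples_per_site),
                              config$n_sites)),
      site = sprintf("site%02d", site_idx),
      region = .region_for_lat(coords[site_idx, 1]),
      rock_type = sample(.ROCK_TYPES, n, replace = TRUE,
                         prob = c(141, 43, 5, 2) / 191),
      latitude = coords[site_idx, 1], longitude = coords[site_idx, 2],
      altitude_m = round(stats::runif(n, 0, 3100)),
      sun_exposure = sample(c("north_exposed", "south_shady"), n,
                            replace = TRUE),
      stringsAsFactors = FALSE)
    validateMetadata(df)
  })
}

.votu_lengths <- function(votus) {
  if (is(votus, "ViralSeqSet")) return(seqLengths(votus))
  if (is.numeric(votus) && !is.null(names(votus)))
    return(stats::setNames(as.integer(votus), names(votus)))
  .stopf("votus must be a ViralSeqSet or a named length vector")
}

#' Generate coverage records with a planted distance-decay
#'
#' Each vOTU is anchored at a random home site; its presence probability in
#' a sample decays as `presence_home * exp(-decay_rate * d_km)` with
#' great-circle distance from home, giving communities a known, tunable
#' distance-decay. A present vOTU is covered over one contiguous segment of
#' `breadth_target` of its length; covered positions have depth
#' `1 + Poisson` so realized breadth equals the target exactly. Per-vOTU
#' abundance is scaled by a log-normal factor (meanlog 1, sdlog 1,
#' normalised to mean 1).
#'
#' @param config A [simConfig()] object.
#' @param votus A [ViralSeqSet-class] or named integer vector of vOTU
#'   lengths.
#' @param metadata Sample metadata from [generateSampleMetadata()].
#' @return List with `coverage` (data.frame of depth intervals), `truth`
#'   (data.frame `votu_id`, `sample_id`, `present`) and `home_sites`
#'   (named character vector).
#' @export
generateCoverage <- function(config, votus, metadata) {
  stopifnot(inherits(config, "sim_config"))
  lens <- .votu_lengths(votus)
  if (length(lens) == 0) .stopf("votus must be non-empty")
  with_seed(config$seed + 2L, {
    sites <- unique(metadata$site)
    site_coord <- unique(metadata[, c("site", "latitude", "longitude")])
    home <- sample(sites, length(lens), replace = TRUE)
    names(home) <- names(lens)
    dist_km <- outer(seq_along(sites), seq_along(sites), function(i, j) {
      geoDistance(as.matrix(site_coord[i, c("latitude", "longitude")]),
                  as.matrix(site_coord[j, c("latitude", "longitude")]))
    })
    dimnames(dist_km) <- list(site_coord$site, site_coord$site)
    cov <- vector("list", 0)
    truth <- vector("list", 0)
    lognorm_scale <- exp(1 + 0.5)  # mean of lognormal(1, 1)
    for (v in names(lens)) {
      L <- lens[[v]]
      p_site <- config$presence_home *
        exp(-config$decay_rate * dist_km[home[[v]], metadata$site])
      present <- stats::runif(nrow(metadata)) < p_site
      truth[[length(truth) + 1]] <- data.frame(
        votu_id = v, sample_id = metadata$sample_id, present = present,
        stringsAsFactors = FALSE)
      for (k in which(present)) {
        lf <- stats::rlnorm(1, meanlog = 1, sdlog = 1) / lognorm_scale
        lambda <- max(config$depth_mean * lf - 1, 0)
        cov_len <- max(1L, round(config$breadth_target * L))
        start <- sample.int(L - cov_len + 1L, 1L) - 1L
        n_win <- ceiling(cov_len / config$depth_window)
        win_depth <- 1L + stats::rpois(n_win, lambda)
        depths <- rep(win_depth, each = config$depth_window)[seq_len(cov_len)]
        iv <- depthToIntervals(depths)
        if (nrow(iv) > 0)
          cov[[length(cov) + 1]] <- data.frame(
            votu_id = v, sample_id = metadata$sample_id[k],
            start = iv$start + start, end = iv$end + start, depth = iv$depth,
            stringsAsFactors = FALSE)
      }
    }
    coverage <- if (length(cov)) do.call(rbind, cov) else
      data.frame(votu_id = character(), sample_id = character(),
                 start = integer(), end = integer(), depth = integer(),
                 stringsAsFactors = FALSE)
    list(coverage = validateCoverage(coverage),
         truth = do.call(rbind, truth), home_sites = home)
  })
}

.HOST_PHYLA <- c("Proteobacteria", "Actinobacteriota", "Chloroflexota",
                 "Bacteroidota", "Cyanobacteria", "Acidobacteriota")

.make_host_taxa <- function(n_hosts) {
  phyla <- rep_len(.HOST_PHYLA, n_hosts)
  data.frame(
    host_id = sprintf("host%02d", seq_len(n_hosts)),
    domain = "Bacteria", phylum = phyla,
    class = paste0(phyla, "ia"), order = sprintf("Order_%02d", seq_len(n_hosts)),
    family = sprintf("Family_%02d", seq_len(n_hosts)),
    genus = sprintf("Genus_%02d", seq_len(n_hosts)),
    species = sprintf("Genus_%02d species_%02d", seq_len(n_hosts),
                      seq_len(n_hosts)),
    stringsAsFactors = FALSE)
}

#' Generate BLAST-style hit tables with planted hosts and decoys
#'
#' For a chosen subset of vOTUs, emits hits to a planted true host at
#' `host_identity` percent identity over `host_segment_length` bp in both
#' the RefSeq-style and MAG-style databases, plus decoy hits that each
#' violate exactly one filtering rule (alignment < 2000 bp, identity < 70%,
#' bitscore < 50, e-value > 0.001, or MAG hits covering >= 50% of the
#' subject). Decoys carry a wrong-phylum taxonomy, so any decoy leaking
#' through the filter is visible as a precision loss. Optionally plants a
#' RefSeq/MAG disagreement at family rank and below for selected vOTUs; the
#' truth table records the MAG-side taxonomy for those (the merge rule's
#' expected winner).
#'
#' @param config A [simConfig()] object.
#' @param votus A [ViralSeqSet-class] or named length vector; hosts are
#'   planted for `target_votus`.
#' @param n_hosts Number of distinct host genomes (0 = empty table).
#' @param target_votus vOTU ids to receive planted hosts; default the first
#'   half (rounded up) of the vOTUs.
#' @param conflict_votus Subset of `target_votus` for which RefSeq and MAG
#'   databases disagree at family/genus/species.
#' @param decoys Emit the below-threshold decoy hits (default `TRUE`).
#' @return List with `hits` (data.frame in [readHitTable()] shape, both
#'   databases combined) and `truth` (data.frame `votu_id`, `host_id`, the
#'   seven expected merged ranks).
#' @export
generateHitTable <- function(config, votus, n_hosts,
                             target_votus = NULL, conflict_votus = character(),
                             decoys = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  lens <- .votu_lengths(votus)
  empty_hits <- data.frame(query_id = character(), subject_id = character(),
                           pct_identity = numeric(), aln_length = integer(),
                           evalue = numeric(), bitscore = numeric(),
                           subject_length = integer(), db_label = character(),
                           stringsAsFactors = FALSE)
  for (r in .TAX_RANKS) empty_hits[[r]] <- character()
  if (n_hosts == 0)
    return(list(hits = empty_hits,
                truth = cbind(data.frame(votu_id = character(),
                                         host_id = character(),
                                         stringsAsFactors = FALSE),
                              empty_hits[.TAX_RANKS])))
  with_seed(config$seed + 3L, {
    taxa <- .make_host_taxa(n_hosts)
    if (is.null(target_votus))
      target_votus <- names(lens)[seq_len(ceiling(length(lens) / 2))]
    assign_host <- taxa$host_id[rep_len(seq_len(n_hosts),
                                        length(target_votus))]
    names(assign_host) <- target_votus
    seg <- config$host_segment_length
    rows <- vector("list", 0)
    truth <- vector("list", 0)
    add_hit <- function(q, subj, pid, aln, ev, bits, slen, db, tax) {
      row <- data.frame(query_id = q, subject_id = subj, pct_identity = pid,
                        aln_length = as.integer(aln), evalue = ev,
                        bitscore = bits, subject_length = as.integer(slen),
                        db_label = db, stringsAsFactors = FALSE)
      for (r in .TAX_RANKS) row[[r]] <- tax[[r]]
      rows[[length(rows) + 1]] <<- row
    }
    for (q in target_votus) {
      h <- assign_host[[q]]
      tax <- taxa[taxa$host_id == h, ]
      conflict <- q %in% conflict_votus
      mag_tax <- tax
      if (conflict) {
        mag_tax$family <- paste0(tax$family, "_mag")
        mag_tax$genus <- paste0(tax$genus, "_mag")
        mag_tax$species <- paste0(tax$species, "_mag")
      }
      for (db in c("refseq", "mag")) {
        db_tax <- if (db == "mag") mag_tax else tax
        # conflicting MAG lineages come from a distinct MAG subject, so a
        # subject's taxonomy is single-valued (as in a real database)
        subj <- sprintf("%s_%s%s", db, h,
                        if (conflict && db == "mag") "_alt" else "")
        # MAG subjects sized so planted hits cover 25% (< 50% rule passes)
        slen <- if (db == "mag") 4L * seg else 3000000L
        for (j in 1:3)
          add_hit(q, subj, config$host_identity, seg, 1e-50 * j,
                  round(1.8 * seg * config$host_identity / 100) - j, slen,
                  db, db_tax)
        if (decoys) {
          decoy_tax <- tax
          decoy_tax$phylum <- "DecoyPhylum"
          decoy_tax$class <- "DecoyClass"; decoy_tax$order <- "DecoyOrder"
          decoy_tax$family <- "DecoyFamily"; decoy_tax$genus <- "DecoyGenus"
          decoy_tax$species <- "Decoy species"
          dsub <- sprintf("%s_decoy_%s", db, q)
          add_hit(q, dsub, 95, 1500, 1e-40, 800, slen, db, decoy_tax)
          add_hit(q, dsub, 55, 2500, 1e-40, 800, slen, db, decoy_tax)
          add_hit(q, dsub, 95, 2500, 1e-40, 40, slen, db, decoy_tax)
          add_hit(q, dsub, 95, 2500, 0.01, 800, slen, db, decoy_tax)
          if (db == "mag")  # covers 60% of the MAG subject
            add_hit(q, dsub, 95, round(0.6 * slen), 1e-40, 800, slen, db,
                    decoy_tax)
        }
      }
      tr <- data.frame(votu_id = q, host_id = h, stringsAsFactors = FALSE)
      for (r in .TAX_RANKS) tr[[r]] <- mag_tax[[r]]
      truth[[length(truth) + 1]] <- tr
    }
    list(hits = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Generate protein-cluster profiles with planted viral clusters
#'
#' Genomes planted in the same viral cluster (VC) draw `share_fraction` of
#' their protein clusters from a VC-specific core shared by every member
#' (with `share_fraction = 1` profiles are identical); the remainder are
#' genome-private. Planted singletons carry only private clusters and so
#' share nothing with any other genome. Reference genomes are added to the
#' first VCs (up to two per VC) and carry class/family taxonomy labels
#' (same family within a VC, distinct genera).
#'
#' @param config A [simConfig()] object.
#' @param votus A [ViralSeqSet-class] or a character vector of genome ids.
#' @param n_reference_genomes Number of labeled reference genomes.
#' @param vc_size Planted VC size over the input genomes (default 3).
#' @param n_singletons How many trailing genomes are planted singletons.
#' @return List with `profiles` (named list genome -> protein-cluster ids),
#'   `universe_size`, `reference_taxa` (data.frame) and `truth`
#'   (data.frame `genome_id`, `vc_id` (`NA` for singletons),
#'   `is_reference`).
#' @export
generateProteinProfiles <- function(config, votus, n_reference_genomes = 4L,
                                    vc_size = 3L, n_singletons = 2L) {
  stopifnot(inherits(config, "sim_config"))
  ids <- if (is(votus, "ViralSeqSet")) seqIds(votus) else as.character(votus)
  if (length(ids) <= n_singletons)
    .stopf("need more genomes than planted singletons")
  with_seed(config$seed + 4L, {
    n_cluster_genomes <- length(ids) - n_singletons
    grouped <- ids[seq_len(n_cluster_genomes)]
    singles <- ids[seq_len(n_singletons) + n_cluster_genomes]
    vc_of <- ceiling(seq_along(grouped) / vc_size)
    n_vcs <- max(vc_of)
    refs <- if (n_reference_genomes > 0)
      sprintf("ref_g%02d", seq_len(n_reference_genomes)) else character(0)
    ref_vc <- if (n_reference_genomes > 0)
      rep(seq_len(max(1, ceiling(n_reference_genomes / 2))),
          each = 2)[seq_len(n_reference_genomes)] else integer(0)
    ref_vc <- pmin(ref_vc, n_vcs)
    m <- config$profile_size
    n_core <- round(config$share_fraction * m)
    next_id <- 1L
    take <- function(k) {
      out <- sprintf("PC%06d", seq(next_id, length.out = k))
      next_id <<- next_id + k
      out
    }
    cores <- lapply(seq_len(n_vcs), function(i) take(n_core))
    profiles <- list()
    truth <- vector("list", 0)
    add_genome <- function(g, vc, is_ref) {
      profile <- if (is.na(vc)) take(m) else c(cores[[vc]], take(m - n_core))
      profiles[[g]] <<- profile
      truth[[length(truth) + 1]] <<- data.frame(
        genome_id = g, vc_id = if (is.na(vc)) NA_character_ else
          sprintf("planted_vc%02d", vc),
        is_reference = is_ref, stringsAsFactors = FALSE)
    }
    for (i in seq_along(grouped)) add_genome(grouped[i], vc_of[i], FALSE)
    for (g in singles) add_genome(g, NA, FALSE)
    for (i in seq_along(refs)) add_genome(refs[i], ref_vc[i], TRUE)
    reference_taxa <- data.frame(
      genome_id = refs, class = rep("Caudoviricetes", length(refs)),
      order = sprintf("RefOrder_%02d", ref_vc),
      family = sprintf("RefFamily_%02d", ref_vc),
      genus = sprintf("RefGenus_%02d", seq_along(refs)),
      stringsAsFactors = FALSE)
    list(profiles = profiles, universe_size = next_id - 1L + 50L,
         reference_taxa = reference_taxa, truth = do.call(rbind, truth))
  })
}

#' Generate a distilled AMG annotation table
#'
#' Simulated auxiliary metabolic genes drawn per vOTU; a configurable
#' fraction is left without a distilled category (unclassified).
#'
#' @param config A [simConfig()] object.
#' @param votu_ids Character vector of vOTU ids.
#' @param genes_per_votu Mean number of AMGs per vOTU (Poisson).
#' @return data.frame of AMG records (`votu_id`, `gene_id`,
#'   `distilled_category`, `distilled_module`).
#' @export
generateAMGTable <- function(config, votu_ids, genes_per_votu = 2) {
  stopifnot(inherits(config, "sim_config"))
  cats <- data.frame(
    category = c("carbon utilization", "energy", "organic nitrogen",
                 "transporters", "MISC"),
    module = c("glycoside hydrolase", "photosynthesis",
               "methionine degradation", "ABC transporter", "misc"),
    stringsAsFactors = FALSE)
  with_seed(config$seed + 5L, {
    n_genes <- stats::rpois(length(votu_ids), genes_per_votu)
    rows <- vector("list", 0)
    for (i in seq_along(votu_ids)) {
      if (n_genes[i] == 0) next
      ci <- sample.int(nrow(cats), n_genes[i], replace = TRUE)
      unclass <- stats::runif(n_genes[i]) < config$amg_unclassified_frac
      rows[[length(rows) + 1]] <- data.frame(
        votu_id = votu_ids[i],
        gene_id = sprintf("%s_gene%02d", votu_ids[i], seq_len(n_genes[i])),
        distilled_category = ifelse(unclass, "", cats$category[ci]),
        distilled_module = ifelse(unclass, "", cats$module[ci]),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(votu_id = character(), gene_id = character(),
                 distilled_category = character(),
                 distilled_module = character(), stringsAsFactors = FALSE)
  })
}

#' Materialize a complete synthetic fixture directory
#'
#' Writes every input the pipeline reads — contig FASTA, quality table,
#' sample metadata CSV, coverage BED, hit tables with taxonomy sidecars,
#' protein-cluster profiles with reference taxa, and an AMG table —
#' together with the generators' truth tables under `truth/`. Coverage,
#' hits and profiles are generated for the planted vOTU representatives
#' (ancestors, plus any descendant whose realized identity to its ancestor
#' falls below the 95% clustering threshold).
#'
#' @param config A [simConfig()] object.
#' @param dir Output directory (created if needed).
#' @param n_hosts Hosts planted in the hit tables.
#' @param conflict_votus Passed to [generateHitTable()].
#' @param n_reference_genomes,vc_size,n_singletons Passed to
#'   [generateProteinProfiles()]; the default plants references in only
#'   some VCs, leaving the rest as unique VCs.
#' @return `dir`, invisibly; side effect: files written.
#' @export
simulateFixture <- function(config, dir, n_hosts = 4L,
                            conflict_votus = character(),
                            n_reference_genomes = 2L, vc_size = 3L,
                            n_singletons = 2L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  pop <- generatePopulation(config)
  meta <- generateSampleMetadata(config)
  # planted vOTU representatives: ancestors + descendants below threshold
  reps <- pop$truth$seq_id[pop$truth$divergence == 0 |
                             pop$truth$realized_identity < 0.95]
  rep_set <- pop$sequences[reps]
  covr <- generateCoverage(config, rep_set, meta)
  hits <- generateHitTable(config, rep_set, n_hosts = n_hosts,
                           conflict_votus = conflict_votus)
  prof <- generateProteinProfiles(config, rep_set,
                                  n_reference_genomes = n_reference_genomes,
                                  vc_size = vc_size,
                                  n_singletons = n_singletons)
  amgs <- generateAMGTable(config, seqIds(rep_set))

  writeViralFasta(pop$sequences, file.path(dir, "contigs.fasta"))
  # planted quality tiers: representatives informative, a sprinkling
  # of not_determined to exercise the quality filter
  tiers <- with_seed(config$seed + 6L, {
    sample(c("complete", "high", "medium", "low", "not_determined"),
           length(pop$sequences), replace = TRUE,
           prob = c(0.05, 0.1, 0.2, 0.55, 0.1))
  })
  qual <- data.frame(contig_id = seqIds(pop$sequences),
                     checkv_quality = c(complete = "Complete",
                                        high = "High-quality",
                                        medium = "Medium-quality",
                                        low = "Low-quality",
                                        not_determined = "Not-determined")[tiers],
                     provirus = "No", stringsAsFactors = FALSE)
  utils::write.table(qual, file.path(dir, "quality.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  writeCoverageBed(covr$coverage, file.path(dir, "coverage.bed"))
  for (db in c("refseq", "mag")) {
    sub <- hits$hits[hits$hits$db_label == db, , drop = FALSE]
    out6 <- data.frame(sub$query_id, sub$subject_id, sub$pct_identity,
                       sub$aln_length, 0L, 0L, 1L, sub$aln_length, 1L,
                       sub$aln_length, sub$evalue, sub$bitscore)
    utils::write.table(out6, file.path(dir, sprintf("hits_%s.tsv", db)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    side <- unique(data.frame(sub$subject_id, sub$subject_length,
                              sub$domain, sub$phylum, sub$class, sub$order,
                              sub$family, sub$genus, sub$species,
                              stringsAsFactors = FALSE))
    utils::write.table(side, file.path(dir, sprintf("taxonomy_%s.tsv", db)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  prof_long <- data.frame(
    genome_id = rep(names(prof$profiles), lengths(prof$profiles)),
    protein_cluster_id = unlist(prof$profiles, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(prof_long, file.path(dir, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(prof$reference_taxa, file.path(dir, "reference_taxa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(amgs, file.path(dir, "amgs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tw <- function(x, f) utils::write.table(
    x, file.path(dir, "truth", f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tw(pop$truth, "population.tsv")
  tw(covr$truth, "occupancy.tsv")
  tw(data.frame(votu_id = names(covr$home_sites),
                home_site = unname(covr$home_sites)), "home_sites.tsv")
  tw(hits$truth, "hosts.tsv")
  tw(prof$truth, "vcs.tsv")
  writeLines(sprintf("universe_size\t%d", prof$universe_size),
             file.path(dir, "truth", "universe.tsv"))
  invisible(dir)
}
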