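# Small fixture builders shared across test files.

random_dna <- function(len, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# A single hit-record row in the shape readHitTable() produces.
hit_row <- function(query = "v1", subject = "h1", pid = 80, aln = 2500,
                    evalue = 1e-30, bits = 900, slen = 3e6, db = "refseq",
                    domain = "Bacteria", phylum = "Proteobacteria",
                    class = "Gammaproteobacteria", order = "Ord1",
                    family = "Fam1", genus = "Gen1",
                    species = "Gen1 sp1") {
  data.frame(query_id = query, subject_id = subject, pct_identity = pid,
             aln_length = as.integer(aln), evalue = evalue, bitscore = bits,
             subject_length = as.integer(slen), db_label = db,
             domain = domain, phylum = phylum, class = class, order = order,
             family = family, genus = genus, species = species,
             stringsAsFactors = FALSE)
}

# Uniform-depth coverage over a fraction of a contig, starting at 0.
cov_rows <- function(votu, sample, length, breadth, depth = 5L) {
  data.frame(votu_id = votu, sample_id = sample, start = 0L,
             end = as.integer(round(breadth * length)),
             depth = as.integer(depth), stringsAsFactors = FALSE)
}

# Minimal metadata for n_sites sites x k samples, evenly spaced along a
# 1-degree latitude grid (about 111 km between neighbours).
toy_metadata <- function(n_sites = 2, per_site = 2, regions = NULL,
                         rock = "sandstone", lat0 = -70) {
  site_idx <- rep(seq_len(n_sites), each = per_site)
  if (is.null(regions))
    regions <- rep("northern_victoria_land", n_sites)
  data.frame(
    sample_id = sprintf("s%02d_%02d", site_idx,
                        rep(seq_len(per_site), n_sites)),
    site = sprintf("site%02d", site_idx),
    region = regions[site_idx],
    rock_type = rep_len(rock, n_sites * per_site),
    latitude = lat0 - (site_idx - 1), longitude = 160,
    altitude_m = 100, sun_exposure = "unknown",
    stringsAsFactors = FALSE)
}
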