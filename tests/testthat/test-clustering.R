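# Greedy vOTU clustering: engine vs exact-DP oracle, truth recovery,
# ordering invariance, catalog filtering and summaries.

test_that("alignment identity agrees with the exact-DP oracle", {
  withr::with_seed(17, {
    base <- random_dna(240)
    mutate <- function(s, d) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(ch)) < d)
      for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
      paste(ch, collapse = "")
    }
    cases <- list(
      c(base, base),                     # identical
      c(base, mutate(base, 0.02)),
      c(base, mutate(base, 0.10)),
      c(base, substr(mutate(base, 0.03), 30, 220)),  # partial overlap
      c(base, random_dna(240))           # unrelated
    )
    for (cs in cases) {
      got <- alignmentIdentity(cs[1], cs[2])
      want <- sw_oracle(cs[1], cs[2])
      expect_equal(got$score, want$score, tolerance = 1e-9)
      expect_lt(abs(got$identity - want$identity), 0.005)
    }
  })
})

test_that("clustering basics: single sequence, tie-break, N exclusion", {
  one <- ViralSeqSet(c(x = random_dna(300, seed = 1)))
  cat1 <- clusterVOTUs(one)
  expect_equal(representatives(cat1), "x")

  s <- random_dna(1000, seed = 2)
  two <- ViralSeqSet(c(b = s, a = s))
  cat2 <- clusterVOTUs(two)
  expect_equal(representatives(cat2), "a")  # lexicographic tie-break
  expect_equal(sort(clusterMembers(cat2)$a), c("a", "b"))

  noisy <- ViralSeqSet(c(good = random_dna(200, seed = 3),
                         bad = paste(rep("N", 200), collapse = "")))
  expect_warning(cat3 <- clusterVOTUs(noisy), "50% N")
  expect_equal(representatives(cat3), "good")

  expect_equal(length(clusterVOTUs(ViralSeqSet(Biostrings::DNAStringSet()))),
               0L)
})

test_that("population fixtures are recovered exactly and match brute force", {
  cfg <- simConfig(seed = 33, n_ancestors = 5, divergence_levels = 0.02,
                   descendants_per_level = 3,
                   genome_length_range = c(600, 900))
  pop <- generatePopulation(cfg)
  cat_ <- clusterVOTUs(pop$sequences)
  got <- memberTable(cat_)
  truth_of <- stats::setNames(pop$truth$ancestor_id, pop$truth$seq_id)
  expect_equal(length(cat_), 5L)
  # cluster co-membership equals truth co-membership
  expect_true(all(truth_of[got$member_id] ==
                    truth_of[got$representative_id]))
  # brute-force all-pairs + same greedy order gives the identical partition
  bf <- brute_force_clusters(pop$sequences)
  expect_identical(stats::setNames(got$representative_id, got$member_id)[names(bf)],
                   bf)
})

test_that("partition is invariant to input order; members verify against reps", {
  cfg <- simConfig(seed = 34, n_ancestors = 4, divergence_levels = c(0.02),
                   descendants_per_level = 2,
                   genome_length_range = c(500, 700))
  pop <- generatePopulation(cfg)
  cat_a <- clusterVOTUs(pop$sequences)
  perm <- withr::with_seed(1, sample(length(pop$sequences)))
  cat_b <- clusterVOTUs(pop$sequences[perm])
  ord <- function(cc) {
    m <- memberTable(cc)[, c("member_id", "representative_id")]
    m[order(m$member_id), ]
  }
  expect_equal(ord(cat_a), ord(cat_b), ignore_attr = TRUE)

  # member validity: every member satisfies the criterion against its rep
  seqs <- as.character(sequences(pop$sequences))
  m <- memberTable(cat_a)
  for (i in which(m$member_id != m$representative_id)) {
    al <- alignmentIdentity(seqs[[m$representative_id[i]]],
                            seqs[[m$member_id[i]]])
    expect_gte(al$identity, 0.95)
    expect_gte(al$coverage_shorter, 0.85)
  }
  # representative non-redundancy: no representative pair meets it
  reps <- representatives(cat_a)
  for (i in seq_along(reps)) for (j in seq_len(i - 1)) {
    al <- alignmentIdentity(seqs[[reps[j]]], seqs[[reps[i]]])
    expect_false(al$identity >= 0.95 && al$coverage_shorter >= 0.85)
  }
})

test_that("catalog filter applies length, quality and detection rules", {
  seqs <- c(v_short = random_dna(500, seed = 41),
            v_nd = random_dna(1500, seed = 42),
            v_faint = random_dna(1500, seed = 43),
            v_ok = random_dna(1500, seed = 44))
  cat_ <- clusterVOTUs(ViralSeqSet(seqs))
  expect_equal(length(cat_), 4L)
  quality <- data.frame(
    contig_id = c("v_short", "v_nd", "v_faint", "v_ok"),
    quality_tier = c("low", "not_determined", "medium", "high"),
    stringsAsFactors = FALSE)
  det <- matrix(TRUE, 1, 4,
                dimnames = list("s1", c("v_short", "v_nd", "v_faint", "v_ok")))
  det[, "v_faint"] <- FALSE
  filt <- filterCatalog(cat_, quality, det, min_len = 1000L)
  expect_equal(representatives(filt), "v_ok")
  fl <- filterFlags(filt)
  expect_false(fl$passed_length[fl$member_id == "v_short"])
  expect_false(fl$passed_quality[fl$member_id == "v_nd"])
  expect_false(fl$passed_detection[fl$member_id == "v_faint"])
  expect_true(fl$passed[fl$member_id == "v_ok"])

  # absent from the quality table: treated as not_determined with warning
  expect_warning(
    filt2 <- filterCatalog(cat_, quality[-4, ], det, min_len = 1000L),
    "not_determined")
  expect_equal(length(filt2), 0L)

  empty <- clusterVOTUs(ViralSeqSet(Biostrings::DNAStringSet()))
  expect_equal(length(filterCatalog(empty, quality, det)), 0L)
})

test_that("AMG and quality summaries compute counts and fractions", {
  amgs <- data.frame(votu_id = "v", gene_id = paste0("g", 1:5),
                     distilled_category = c("energy", "", "", "carbon",
                                            "carbon"),
                     distilled_module = "", stringsAsFactors = FALSE)
  s <- summarizeAMGs(amgs)
  expect_equal(s$unclassified_pct, 40.0)
  expect_equal(s$counts[["carbon"]], 2L)
  expect_equal(summarizeAMGs(amgs[amgs$distilled_category != "", ])$unclassified_pct,
               0.0)
  expect_true(is.na(summarizeAMGs(amgs[0, ])$unclassified_pct))

  seqs <- ViralSeqSet(c(a = random_dna(200, seed = 8),
                        b = random_dna(200, seed = 9),
                        c = random_dna(200, seed = 10)))
  cat_ <- clusterVOTUs(seqs)
  qual <- data.frame(contig_id = c("a", "b"),
                     quality_tier = c("complete", "low"),
                     stringsAsFactors = FALSE)
  qsum <- summarizeQuality(cat_, qual)
  expect_equal(qsum[["complete"]], 1L)
  expect_equal(qsum[["low"]], 1L)
  expect_equal(qsum[["not_determined"]], 1L)
})
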