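# Host prediction: thresholds, top-5 unanimity, database merging and
# recovery of planted hosts.

test_that("hit filtering applies the alignment thresholds and the MAG rule", {
  hits <- rbind(
    hit_row(pid = 75, aln = 2500, bits = 900, evalue = 1e-30),   # kept
    hit_row(pid = 95, aln = 1500, bits = 900, evalue = 0),       # short
    hit_row(pid = 65, aln = 2500, bits = 900, evalue = 1e-30),   # low id
    hit_row(pid = 95, aln = 2500, bits = 40, evalue = 1e-30),    # low bits
    hit_row(pid = 95, aln = 2500, bits = 900, evalue = 0.01),    # high e
    hit_row(pid = 95, aln = 3000, bits = 900, slen = 5000, db = "mag"),
    hit_row(pid = 95, aln = 2400, bits = 900, slen = 5000, db = "mag"))
  f <- filterHits(hits)
  expect_equal(nrow(f), 2L)
  expect_equal(f$aln_length, c(2500L, 2400L))  # mag 3000/5000 = 60% dropped
  expect_equal(nrow(filterHits(hits[0, ])), 0L)
  # boundary values are inclusive where the rule says ">=" / "<="
  edge <- hit_row(pid = 70, aln = 2000, bits = 50, evalue = 0.001)
  expect_equal(nrow(filterHits(edge)), 1L)
})

test_that("consensus assigns ranks by unanimity of the top five hits", {
  # all genus-unanimous, three species names: genus assigned, species not
  hits <- do.call(rbind, lapply(1:5, function(i)
    hit_row(subject = sprintf("h%d", i), bits = 900 - i,
            genus = "Friedmanniella",
            species = sprintf("Friedmanniella sp%d", ((i - 1) %% 3) + 1))))
  p <- hostConsensus(hits)
  expect_equal(p$genus, "Friedmanniella")
  expect_true(is.na(p$species))
  expect_equal(p$n_supporting_hits, 5L)

  # a single hit carries its full taxonomy
  p1 <- hostConsensus(hit_row())
  expect_equal(p1$species, "Gen1 sp1")

  # sixth-ranked disagreement is ignored: only the top five count
  hits6 <- rbind(hits, hit_row(subject = "h6", bits = 1,
                               phylum = "OtherPhylum"))
  expect_equal(hostConsensus(hits6)$phylum, "Proteobacteria")

  # empty rank name breaks unanimity at that rank and below
  hitsE <- rbind(hit_row(subject = "h1"), hit_row(subject = "h2", class = ""))
  pE <- hostConsensus(hitsE)
  expect_equal(pE$phylum, "Proteobacteria")
  expect_true(all(is.na(pE[c("class", "order", "family", "genus",
                             "species")])))

  # empty input: all ranks unassigned
  p0 <- hostConsensus(hit_row()[0, ], votu_id = "vx")
  expect_true(all(is.na(p0[unlist(strsplit("domain phylum class order family genus species", " "))])))
  expect_equal(p0$n_supporting_hits, 0L)
})

test_that("consensus is invariant to hit order (total order on hits)", {
  hits <- do.call(rbind, lapply(1:7, function(i)
    hit_row(subject = sprintf("h%d", i), bits = c(900, 900, 880, 870, 860,
                                                  850, 840)[i],
            evalue = c(1e-30, 1e-40, 1e-30, 1e-30, 1e-30, 1e-30, 1e-30)[i],
            genus = if (i <= 5) "GenA" else "GenB",
            species = paste("sp", i))))
  perms <- list(1:7, 7:1, c(4, 2, 6, 1, 7, 3, 5))
  preds <- lapply(perms, function(p) hostConsensus(hits[p, ]))
  expect_identical(preds[[1]], preds[[2]])
  expect_identical(preds[[1]], preds[[3]])
})

test_that("merging prefers MAG on disagreement and keeps rank consistency", {
  ref <- hostConsensus(hit_row(family = "A", genus = "gA",
                               species = "gA s"))
  mag <- hostConsensus(hit_row(family = "B", genus = "gB", species = "gB s",
                               db = "mag", slen = 50000))
  m <- mergePredictions(ref, mag)
  expect_equal(m$family, "B")
  expect_equal(m$source, "merged")

  # single-source rank: taken from whichever database assigned it
  ref2 <- hostConsensus(rbind(hit_row(subject = "x", class = "C1"),
                              hit_row(subject = "y", class = "C1",
                                      order = "")))
  mag2 <- hostConsensus(hit_row(db = "mag", slen = 50000)[0, ], votu_id = "v1")
  m2 <- mergePredictions(ref2, mag2)
  expect_equal(m2$class, "C1")
  expect_true(is.na(m2$order))
  expect_equal(m2$source, "refseq")

  both0 <- mergePredictions(hostConsensus(hit_row()[0, ], votu_id = "v9"),
                            hostConsensus(hit_row()[0, ], votu_id = "v9"))
  expect_true(all(is.na(both0[c("domain", "phylum", "species")])))
  expect_equal(both0$source, "none")

  expect_error(mergePredictions(hostConsensus(hit_row()[0, ], votu_id = "a"),
                                hostConsensus(hit_row()[0, ], votu_id = "b")),
               "different vOTUs")

  # rank consistency holds on every emitted prediction
  for (p in list(m, m2, both0)) {
    ranks <- is.na(unlist(p[c("domain", "phylum", "class", "order",
                              "family", "genus", "species")]))
    if (any(ranks)) expect_true(all(ranks[which(ranks)[1]:7]))
  }
})

test_that("planted hosts are recovered with precision 1 at assigned ranks", {
  cfg <- simConfig(seed = 61, host_identity = 85, host_segment_length = 3000)
  lens <- stats::setNames(rep(10000L, 6), sprintf("v%d", 1:6))
  ht <- generateHitTable(cfg, lens, n_hosts = 4, conflict_votus = "v2")
  preds <- predictHosts(ht$hits)
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  for (i in seq_len(nrow(ht$truth))) {
    p <- preds[preds$votu_id == ht$truth$votu_id[i], ]
    expect_equal(nrow(p), 1L)
    for (r in ranks) {
      if (!is.na(p[[r]])) expect_equal(p[[r]], ht$truth[[r]][i])
    }
    # every planted vOTU gets at least a phylum call
    expect_false(is.na(p$phylum))
  }
  # the RefSeq/MAG conflict resolves to the MAG-side value
  expect_equal(preds$family[preds$votu_id == "v2"],
               ht$truth$family[ht$truth$votu_id == "v2"])
  expect_match(preds$family[preds$votu_id == "v2"], "_mag$")
})

test_that("host summary reports counts, fraction and phylum table", {
  preds <- predictHosts(rbind(hit_row(query = "v1"),
                              hit_row(query = "v2", pid = 60),
                              hit_row(query = "v3", pid = 60),
                              hit_row(query = "v4", pid = 60)))
  s <- summarizeHosts(preds)
  expect_equal(s$n, 4L)
  expect_equal(s$predicted_pct, 25.00)
  expect_equal(unname(s$phylum_counts["Proteobacteria"]), 1L)
  s0 <- summarizeHosts(preds[0, ])
  expect_equal(s0$predicted_pct, 0)
})
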