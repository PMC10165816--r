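# Gene-sharing network: hypergeometric weights vs exact tail-sum oracle,
# Markov clustering, status partition and VC taxonomy.

test_that("edge weights match the exact hypergeometric tail oracle", {
  # worked case: N=100, n=10, m=12, shared=8
  profiles <- list(g1 = sprintf("PC%03d", 1:10),
                   g2 = sprintf("PC%03d", c(1:8, 90:93)))
  g <- edgeWeights(profiles, universe_size = 100)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$shared, 8L)
  want <- -hyper_tail_oracle(8, 10, 12, 100) / log(10)
  expect_equal(g$edges$weight, want, tolerance = 1e-12)

  # grid: relative error below 1e-9, except where the tail probability is
  # within double-precision rounding of 1 (weight ~ 1e-12 or less, zero in
  # any practical sense), where only absolute agreement is meaningful
  withr::with_seed(71, {
    for (N in c(50, 100, 1000)) {
      for (rep in 1:10) {
        n <- sample(2:(N / 2), 1); m <- sample(2:(N / 2), 1)
        a <- sample(seq_len(min(n, m)), 1)
        got <- -stats::phyper(a - 1, m, N - m, n, lower.tail = FALSE,
                              log.p = TRUE) / log(10)
        want <- -hyper_tail_oracle(a, n, m, N) / log(10)
        err <- abs(got - want)
        expect_true(err / abs(want) < 1e-9 || err < 1e-12)
      }
    }
  })

  # no sharing: no edge; identical large profiles: enormous weight
  g0 <- edgeWeights(list(a = c("PC1"), b = c("PC2")), 100)
  expect_equal(nrow(g0$edges), 0L)
  gid <- edgeWeights(list(a = sprintf("PC%d", 1:20),
                          b = sprintf("PC%d", 1:20)), 10000)
  expect_gt(gid$edges$weight, 40)
  expect_error(edgeWeights(list(a = sprintf("PC%d", 1:20)), 10),
               "universe_size")
})

test_that("edge weights are symmetric in genome order", {
  profiles <- list(b = sprintf("PC%d", 1:12), a = sprintf("PC%d", 5:20))
  g1 <- edgeWeights(profiles, 200)
  g2 <- edgeWeights(rev(profiles), 200)
  expect_equal(g1$edges$weight, g2$edges$weight)
  expect_equal(g1$edges[c("from", "to")], g2$edges[c("from", "to")])
})

test_that("graph clustering recovers disjoint cliques and planted VCs", {
  # two disjoint cliques of three
  mk <- function(core, tag) {
    stats::setNames(lapply(1:3, function(i)
      c(core, sprintf("%s_priv%d_%d", tag, i, 1:5))),
      sprintf("%s%d", tag, 1:3))
  }
  profiles <- c(mk(sprintf("coreA%d", 1:15), "a"),
                mk(sprintf("coreB%d", 1:15), "b"))
  cs <- clusterGraph(edgeWeights(profiles, 500))
  expect_equal(length(cs), 2L)
  expect_setequal(vcMembership(cs)[[1]], c("a1", "a2", "a3"))
  expect_setequal(vcMembership(cs)[[2]], c("b1", "b2", "b3"))

  # planted-VC profiles from the generator equal the truth partition
  cfg <- simConfig(seed = 81, share_fraction = 0.6, profile_size = 25)
  ids <- sprintf("v%02d", 1:11)
  pr <- generateProteinProfiles(cfg, ids, n_reference_genomes = 4,
                                vc_size = 3, n_singletons = 2)
  cs2 <- clusterGraph(edgeWeights(pr$profiles, pr$universe_size))
  truth_vcs <- split(pr$truth$genome_id, pr$truth$vc_id)
  got_vcs <- unname(lapply(vcMembership(cs2), sort))
  expect_setequal(lapply(unname(truth_vcs), sort), got_vcs)

  # a single genome with no edges yields no VC
  cs3 <- clusterGraph(edgeWeights(list(solo = c("PC1", "PC2")), 100))
  expect_equal(length(cs3), 0L)

  # determinism across runs
  cs4 <- clusterGraph(edgeWeights(pr$profiles, pr$universe_size))
  expect_identical(vcMembership(cs2), vcMembership(cs4))
})

test_that("status labels partition genomes into the four classes", {
  # hand-built graph: VC1 = {a1,a2}, VC2 = {b1,b2}; x overlaps both VCs;
  # y has one weak (non-significant) edge; z is isolated.
  genomes <- c("a1", "a2", "b1", "b2", "x", "y", "z")
  edges <- data.frame(
    from = c("a1", "b1", "x", "x", "y"),
    to = c("a2", "b2", "a1", "b1", "a2"),
    shared = 5L,
    weight = c(10, 10, 5, 5, 0.5),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  graph <- structure(list(edges = edges, genomes = genomes, threshold = 1,
                          universe_size = 1000),
                     class = "gene_sharing_graph")
  cs <- new("ViralClusterSet", edges = edges,
            vcs = list(VC_1 = c("a1", "a2"), VC_2 = c("b1", "b2")),
            status = character(0), vcTaxonomy = data.frame(),
            genomes = genomes, references = character(0))
  cs <- assignStatus(cs, graph)
  st <- genomeStatus(cs)
  expect_equal(unname(st[c("a1", "a2", "b1", "b2")]), rep("clustered", 4))
  expect_equal(unname(st[["x"]]), "overlap")
  expect_equal(unname(st[["y"]]), "outlier")
  expect_equal(unname(st[["z"]]), "singleton")
  expect_setequal(names(st), genomes)  # total, mutually exclusive
})

test_that("VC taxonomy follows per-rank reference unanimity", {
  cs <- new("ViralClusterSet", edges = data.frame(),
            vcs = list(VC_1 = c("v1", "v2"),
                       VC_2 = c("v3", "r1", "r2"),
                       VC_3 = c("v4", "r3", "r4")),
            status = character(0), vcTaxonomy = data.frame(),
            genomes = c(sprintf("v%d", 1:4), sprintf("r%d", 1:4)),
            references = character(0))
  ref_taxa <- data.frame(
    genome_id = sprintf("r%d", 1:4),
    class = c("Caudoviricetes", "Caudoviricetes", "ClassA", "ClassB"),
    order = c("O1", "O1", "OA", "OB"),
    family = c("FamX", "FamY", "FA", "FB"),
    genus = c("G1", "G2", "GA", "GB"),
    stringsAsFactors = FALSE)
  cs <- assignVCTaxonomy(cs, ref_taxa)
  tax <- vcTaxonomy(cs)
  expect_equal(tax$label[tax$vc_id == "VC_1"], "Unique VC")
  # class unanimity despite family disagreement
  expect_equal(tax$class[tax$vc_id == "VC_2"], "Caudoviricetes")
  expect_true(is.na(tax$family[tax$vc_id == "VC_2"]))
  expect_equal(tax$label[tax$vc_id == "VC_2"], "O1")  # deepest assigned
  # references disagreeing at every rank
  expect_equal(tax$label[tax$vc_id == "VC_3"], "Mixed")

  s <- summarizeVCs(cs)
  expect_equal(s$n_vcs, 3L)
  expect_equal(s$n_unique, 1L)
  expect_equal(s$unique_pct, 33.3)

  cs0 <- new("ViralClusterSet", edges = data.frame(), vcs = list(),
             status = character(0), vcTaxonomy = data.frame(),
             genomes = character(0), references = character(0))
  expect_equal(summarizeVCs(cs0)$n_vcs, 0L)
})

test_that("end-to-end viral clusters match the generator's truth", {
  cfg <- simConfig(seed = 91, share_fraction = 0.6)
  ids <- sprintf("v%02d", 1:14)
  pr <- generateProteinProfiles(cfg, ids, n_reference_genomes = 4,
                                vc_size = 3, n_singletons = 2)
  cs <- buildViralClusters(pr$profiles, pr$universe_size,
                           pr$reference_taxa)
  truth <- pr$truth
  # singleton genomes are labeled singleton; clustered genomes clustered
  st <- genomeStatus(cs)
  expect_true(all(st[truth$genome_id[is.na(truth$vc_id)]] == "singleton"))
  expect_true(all(st[truth$genome_id[!is.na(truth$vc_id)]] == "clustered"))
  # VCs with references get the shared reference family; others Unique VC
  tax <- vcTaxonomy(cs)
  with_refs <- vapply(vcMembership(cs), function(mm)
    any(mm %in% pr$reference_taxa$genome_id), logical(1))
  expect_equal(sum(tax$label == "Unique VC"), sum(!with_refs))
  expect_true(all(tax$class[with_refs[tax$vc_id]] == "Caudoviricetes"))
  s <- summarizeVCs(cs)
  expect_equal(s$n_vcs, length(vcMembership(cs)))
  expect_equal(s$n_unique + s$n_with_references, s$n_vcs)
})
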