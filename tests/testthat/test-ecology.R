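# Ecology statistics from first principles, cross-checked against vegan,
# cmdscale and geosphere, with exhaustive permutation oracles.

test_that("Hellinger transform and distance match hand values and bounds", {
  expect_equal(hellingerTransform(rbind(c(4, 0, 0)))[1, ], c(1, 0, 0))
  h <- hellingerTransform(rbind(c(1, 3)))
  expect_equal(h[1, ], c(0.5, 0.8660254), tolerance = 1e-7)
  expect_warning(hz <- hellingerTransform(rbind(a = c(0, 0), b = c(1, 1))),
                 "all-zero")
  expect_equal(hz["a", ], c(0, 0))
  expect_error(hellingerTransform(rbind(c(-1, 2))), "non-negative")

  d <- hellingerDistance(rbind(a = c(1, 3), b = c(3, 1)))
  expect_equal(as.numeric(d), 0.5176381, tolerance = 1e-7)
  expect_equal(as.numeric(hellingerDistance(rbind(c(1, 2), c(1, 2)))), 0)
  expect_equal(as.numeric(hellingerDistance(rbind(c(5, 0), c(0, 7)))),
               sqrt(2))

  withr::with_seed(101, {
    m <- matrix(stats::rpois(60, 4), 6)
    h2 <- hellingerTransform(m)
    expect_equal(rowSums(h2^2), rep(1, 6))
    dm <- as.matrix(hellingerDistance(m))
    expect_true(all(dm <= sqrt(2) + 1e-12))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
    skip_if_not_installed("vegan")
    expect_equal(unname(h2),
                 unname(as.matrix(vegan::decostand(m, "hellinger"))),
                 tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("PCoA reproduces Euclidean geometry and flags negative axes", {
  # three collinear points: one informative axis
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  ord <- pcoaOrdination(d)
  expect_equal(ord$eigenvalues[1] / sum(ord$eigenvalues[ord$eigenvalues > 0]),
               1, tolerance = 1e-9)
  expect_equal(ncol(ord$coordinates), 1L)

  z <- matrix(0, 3, 3)
  ordz <- pcoaOrdination(z)
  expect_equal(ncol(ordz$coordinates), 0L)
  expect_equal(ordz$eigenvalues, rep(0, 3))

  withr::with_seed(103, {
    x <- matrix(stats::rnorm(40), 8)
    d8 <- as.matrix(stats::dist(x))
    ord8 <- pcoaOrdination(d8)
    expect_equal(as.matrix(stats::dist(ord8$coordinates)), d8,
                 ignore_attr = TRUE, tolerance = 1e-8)
    cmd <- stats::cmdscale(d8, k = 5, eig = TRUE)
    expect_equal(ord8$eigenvalues[1:5], cmd$eig[1:5], tolerance = 1e-8)
    # non-Euclidean input reports negative eigenvalues
    dn <- d8; dn[1, 2] <- dn[2, 1] <- max(d8) * 1.5
    expect_gt(length(pcoaOrdination(dn)$negative_eigenvalues), 0)
  })
  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA partitions SS exactly and matches vegan on fixtures", {
  withr::with_seed(107, {
    meta <- toy_metadata(n_sites = 3, per_site = 4)
    meta$rock_type <- rep(c("sandstone", "granite"), 6)
    x <- matrix(stats::rpois(12 * 20, 3) +
                  rep(c(0, 2, 4), each = 4), 12)
    rownames(x) <- meta$sample_id
    d <- hellingerDistance(x)
    res <- permanova(d, meta, terms = c("site", "rock_type"),
                     n_perm = 499, seed = 1)
    # additivity of the sequential decomposition
    expect_equal(sum(res$SumOfSqs[1:3]), res$SumOfSqs[4], tolerance = 1e-8)
    expect_true(all(res$`Pr..F.`[1:2] >= 1 / 500 &
                      res$`Pr..F.`[1:2] <= 1))
    skip_if_not_installed("vegan")
    veg <- vegan::adonis2(d ~ site + rock_type, data = meta,
                          permutations = 499, by = "terms")
    expect_equal(res$SumOfSqs, veg$SumOfSqs, tolerance = 1e-8)
    expect_equal(res$F[1:2], veg$F[1:2], tolerance = 1e-8)
    expect_equal(res$R2, veg$R2, tolerance = 1e-8)
    vegm <- vegan::adonis2(d ~ site + rock_type, data = meta,
                           permutations = 499, by = "margin")
    resm <- permanova(d, meta, terms = c("site", "rock_type"),
                      n_perm = 499, mode = "margin", seed = 1)
    expect_equal(resm$SumOfSqs[1:2], vegm$SumOfSqs[1:2], tolerance = 1e-8)
    expect_equal(resm$F[1:2], vegm$F[1:2], tolerance = 1e-8)
  })
})

test_that("balanced orthogonal designs give equal sequential and marginal SS", {
  withr::with_seed(109, {
    meta <- toy_metadata(n_sites = 2, per_site = 4)
    meta$rock_type <- rep(c("sandstone", "granite"), 4)  # balanced 2x2
    x <- matrix(stats::rnorm(8 * 6), 8)
    rownames(x) <- meta$sample_id
    d <- stats::dist(x)
    st <- permanova(d, meta, terms = c("site", "rock_type"), n_perm = 99,
                    seed = 2)
    mg <- permanova(d, meta, terms = c("site", "rock_type"), n_perm = 99,
                    mode = "margin", seed = 2)
    expect_equal(st$SumOfSqs[1:2], mg$SumOfSqs[1:2], tolerance = 1e-8)
  })
})

test_that("PERMANOVA input contracts: levels, coverage, determinism", {
  meta <- toy_metadata(n_sites = 1, per_site = 4)
  d <- stats::dist(matrix(stats::rnorm(20), 4))
  attr(d, "Labels") <- meta$sample_id
  expect_error(permanova(d, meta, terms = "site"), "fewer than 2 levels")
  meta2 <- toy_metadata(n_sites = 2, per_site = 2)
  expect_error(permanova(d, meta2[1:2, ], terms = "site"), "cover")
  meta4 <- toy_metadata(2, 2)
  x4 <- matrix(stats::rnorm(16), 4)
  rownames(x4) <- meta4$sample_id
  expect_error(permanova(stats::dist(x4), meta4,
                         terms = "altitude_missing"),
               "lacks term")
  withr::with_seed(3, {
    meta3 <- toy_metadata(n_sites = 2, per_site = 5)
    x <- matrix(stats::rnorm(10 * 4), 10)
    rownames(x) <- meta3$sample_id
    d3 <- stats::dist(x)
    r1 <- permanova(d3, meta3, terms = "site", n_perm = 199, seed = 11)
    r2 <- permanova(d3, meta3, terms = "site", n_perm = 199, seed = 11)
    expect_identical(r1$`Pr..F.`, r2$`Pr..F.`)
  })
})

test_that("exhaustive PERMANOVA equals the enumeration oracle", {
  withr::with_seed(113, {
    meta <- toy_metadata(n_sites = 2, per_site = 3)
    x <- matrix(stats::rnorm(6 * 4), 6) + rep(c(0, 1.5), each = 3)
    rownames(x) <- meta$sample_id
    d <- stats::dist(x)
    res <- permanova(d, meta, terms = "site", n_perm = 100000)
    expect_true(attr(res, "exhaustive"))
    dm <- as.matrix(d)
    expect_equal(res$F[1], permanova_F_oracle(dm, meta$site),
                 tolerance = 1e-9)
    expect_equal(res$`Pr..F.`[1], permanova_p_oracle(dm, meta$site),
                 tolerance = 1e-12)
  })
})

test_that("dispersion test: degenerate groups, translated clouds, power", {
  withr::with_seed(127, {
    # translated identical clouds: dispersions equal
    base <- matrix(stats::rnorm(12), 6)
    x <- rbind(base, sweep(base, 2, c(10, 10), "+"))
    rownames(x) <- sprintf("s%02d", 1:12)
    d <- stats::dist(x)
    grp <- rep(c("g1", "g2"), each = 6)
    r <- betadisperPermutest(d, grp, n_perm = 199, seed = 5)
    expect_equal(unname(r$group_means[1]), unname(r$group_means[2]),
                 tolerance = 1e-6)
    expect_gt(r$p, 0.5)

    # strongly unequal dispersions are detected
    y <- rbind(matrix(stats::rnorm(20, sd = 1), 10),
               matrix(stats::rnorm(20, sd = 4), 10))
    rownames(y) <- sprintf("t%02d", 1:20)
    r2 <- betadisperPermutest(stats::dist(y), rep(c("a", "b"), each = 10),
                              n_perm = 199, seed = 6)
    expect_lt(r2$p, 0.05)

    # single-sample group: zero dispersion with a warning
    expect_warning(
      r3 <- betadisperPermutest(stats::dist(y[1:5, ]),
                                c("a", "a", "a", "a", "b"),
                                n_perm = 99, seed = 7),
      "single sample")
    expect_equal(unname(r3$distances[5]), 0)
  })
})

test_that("haversine distances match the closed forms and geosphere", {
  expect_equal(geoDistance(c(0, 0), c(0, 0)), 0)
  expect_equal(geoDistance(c(0, 0), c(0, 1)), 111.3195, tolerance = 1e-4)
  expect_equal(geoDistance(c(0, 0), c(0, 180)), pi * 6378.137,
               tolerance = 1e-4)
  expect_equal(geoDistance(c(-70, 100), c(-75, 140)),
               geoDistance(c(-75, 140), c(-70, 100)))
  skip_if_not_installed("geosphere")
  withr::with_seed(131, {
    for (i in 1:10) {
      a <- c(stats::runif(1, -89, 89), stats::runif(1, -179, 179))
      b <- c(stats::runif(1, -89, 89), stats::runif(1, -179, 179))
      expect_equal(geoDistance(a, b),
                   geosphere::distHaversine(rev(a), rev(b)) / 1000,
                   tolerance = 1e-9)
    }
  })
})

test_that("Mantel: identity case, exhaustive oracle, vegan agreement", {
  withr::with_seed(137, {
    meta <- toy_metadata(n_sites = 5, per_site = 1)
    g <- geoDistanceMatrix(meta)
    expect_equal(mantelTest(g, g, n_perm = 1000)$r, 1.0)

    x <- matrix(stats::rnorm(5 * 6), 5)
    rownames(x) <- meta$sample_id
    cmat <- as.matrix(stats::dist(x))
    res <- mantelTest(cmat, g, n_perm = 100000)
    expect_true(res$exhaustive)
    orc <- mantel_p_oracle(cmat, g)
    expect_equal(res$r, orc$r, tolerance = 1e-12)
    expect_equal(res$p, orc$p, tolerance = 1e-12)

    skip_if_not_installed("vegan")
    veg <- vegan::mantel(cmat, g, method = "spearman", permutations = 999)
    expect_equal(res$r, unname(veg$statistic), tolerance = 1e-12)
  })
})

test_that("Mantel zero-distance exclusion masks within-site pairs", {
  withr::with_seed(139, {
    meta <- toy_metadata(n_sites = 3, per_site = 2)
    g <- geoDistanceMatrix(meta)
    x <- matrix(stats::rnorm(6 * 5), 6)
    rownames(x) <- meta$sample_id
    cmat <- as.matrix(stats::dist(x))
    full <- mantelTest(cmat, g, n_perm = 499, seed = 1)
    masked <- mantelTest(cmat, g, n_perm = 499, exclude_zero_geo = TRUE,
                         seed = 1)
    lower <- lower.tri(g)
    keep <- g[lower] > 0
    want_r <- stats::cor(rank(g[lower][keep]), rank(cmat[lower][keep]))
    expect_equal(masked$r, want_r, tolerance = 1e-12)
    expect_true(masked$excluded_zero_pairs)
    expect_false(isTRUE(all.equal(full$r, masked$r)))

    expect_warning(
      const <- mantelTest(matrix(0, 6, 6,
                                 dimnames = dimnames(g)) + 1 - diag(6), g,
                          n_perm = 99),
      "constant")
    expect_true(const$constant)
    expect_true(is.na(const$r))
  })
})

test_that("synthetic distance decay is recovered by the Mantel test", {
  coords <- cbind(seq(-70, -73, length.out = 4), 160)
  cfg <- simConfig(seed = 149, n_sites = 4, samples_per_site = 5,
                   site_coords = coords, decay_rate = 0.01)
  lens <- stats::setNames(rep(400L, 30), sprintf("v%02d", 1:30))
  meta <- generateSampleMetadata(cfg)
  covr <- generateCoverage(cfg, lens, meta)
  am <- buildAbundanceMatrix(covr$coverage, lens, samples = meta$sample_id)
  d <- suppressWarnings(hellingerDistance(am))
  res <- mantelTest(as.matrix(d), geoDistanceMatrix(meta), n_perm = 999,
                    seed = 2)
  expect_gt(res$r, 0)
  expect_lt(res$p, 0.05)
})

test_that("occupancy fractions follow the planted toy mask", {
  meta <- toy_metadata(n_sites = 2, per_site = 2,
                       regions = c("antarctic_peninsula",
                                   "northern_victoria_land"))
  det <- matrix(FALSE, 4, 3,
                dimnames = list(meta$sample_id, c("v1", "v2", "v3")))
  det["s01_01", "v1"] <- TRUE                      # one site, one region
  det[c("s01_01", "s02_01"), "v2"] <- TRUE         # both sites and regions
  det[c("s01_01", "s01_02"), "v3"] <- TRUE         # one site, two samples
  occ <- occupancySummary(det, meta)
  expect_equal(occ$n_votus, 3L)
  expect_equal(occ$multi_site_pct, round(100 / 3, 2))
  expect_equal(occ$multi_region_pct, round(100 / 3, 2))
  expect_equal(occ$all_regions_pct, round(100 / 3, 2))
  expect_warning(occ0 <- occupancySummary(det & FALSE, meta), "empty")
  expect_equal(occ0$multi_site_pct, 0)
})

test_that("sample subsetting filters rows and drops undetected vOTUs", {
  meta <- toy_metadata(n_sites = 2, per_site = 2)
  meta$rock_type <- c("sandstone", "sandstone", "granite", "granite")
  vals <- matrix(c(5, 0, 0, 0,
                   2, 3, 0, 0,
                   0, 0, 4, 4), 4, 3,
                 dimnames = list(meta$sample_id, c("v1", "v2", "v3")))
  am <- new("AbundanceMatrix", values = vals, detection = vals > 0,
            params = list(breadth_min = 0.75, trim_fraction = 0.1,
                          mapping_identity = 0.9))
  sand <- subsetSamples(am, meta, function(m) m$rock_type == "sandstone")
  expect_equal(rownames(abundanceValues(sand)), meta$sample_id[1:2])
  expect_setequal(colnames(abundanceValues(sand)), c("v1", "v2"))
  expect_warning(none <- subsetSamples(am, meta, rep(FALSE, 4)), "no samples")
  expect_equal(nrow(abundanceValues(none)), 0L)
})
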