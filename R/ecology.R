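# Beta-diversity, ordination, permutation tests, geographic distance and
# distance-decay analysis, implemented from first principles.
#
# Permutation convention throughout: free permutation of sample labels (no
# strata), one-sided "greater" alternative, p = (#{stat_perm >= stat_obs} +
# 1) / (n_perm + 1). When n! <= n_perm the full permutation set is
# enumerated instead and p = #{stat_perm >= stat_obs} / n! (the identity
# permutation is among them, so p = 0 remains impossible).

.EARTH_RADIUS_KM <- 6378.137

#' Hellinger transformation of an abundance matrix
#'
#' Per sample (row): `h_ij = sqrt(x_ij / row_sum)`. Rows summing to zero
#' are left as zeros with a warning. Nonzero transformed rows have unit
#' sum of squares, so their Euclidean distances are Hellinger distances,
#' bounded by `sqrt(2)`.
#'
#' @param mat Non-negative numeric matrix, samples as rows (or an
#'   [AbundanceMatrix-class]).
#' @return Transformed numeric matrix of the same shape.
#' @examples
#' hellingerTransform(rbind(a = c(1, 3), b = c(3, 1)))
#' @export
hellingerTransform <- function(mat) {
  if (is(mat, "AbundanceMatrix")) mat <- abundanceValues(mat)
  if (any(mat < 0)) .stopf("abundance values must be non-negative")
  rs <- rowSums(mat)
  zero <- rs == 0
  if (any(zero)) {
    .warnf("%d all-zero row(s) left untransformed", sum(zero))
    rs[zero] <- 1
  }
  sqrt(sweep(mat, 1, rs, "/"))
}

#' Hellinger distance matrix
#'
#' Euclidean distance between Hellinger-transformed sample rows.
#'
#' @param mat Non-negative matrix (samples x taxa) or
#'   [AbundanceMatrix-class].
#' @return A `dist` object labeled by sample.
#' @export
hellingerDistance <- function(mat) {
  stats::dist(hellingerTransform(mat), method = "euclidean")
}

#' Principal-coordinate analysis (classical metric scaling)
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Axes are ordered by descending eigenvalue; coordinates are returned for
#' positive-eigenvalue axes only, while negative eigenvalues (from
#' non-Euclidean distances) are reported alongside.
#'
#' @param d Distance matrix (`dist` or symmetric matrix).
#' @return List: `coordinates` (samples x positive axes, columns
#'   `Axis.1`, ...), `eigenvalues` (all, descending), `prop_explained`
#'   (per positive axis, of the positive total), `negative_eigenvalues`.
#' @export
pcoaOrdination <- function(d) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  G <- .gower_center(m)
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values), 1) * 1e-9
  pos <- eig$values > tol
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  rownames(coords) <- rownames(m)
  if (ncol(coords) > 0)
    colnames(coords) <- sprintf("Axis.%d", seq_len(ncol(coords)))
  pos_total <- sum(eig$values[pos])
  list(coordinates = coords, eigenvalues = eig$values,
       prop_explained = if (pos_total > 0) eig$values[pos] / pos_total
                        else numeric(0),
       negative_eigenvalues = eig$values[eig$values < -tol])
}

# Gower-centered inner-product matrix from a distance matrix.
.gower_center <- function(m) {
  A <- -0.5 * m^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# Hat (projection) matrix of a design, rank-revealing.
.hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  list(H = tcrossprod(Q), rank = q$rank)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' McArdle-Anderson partitioning of a distance matrix's sum of squares
#' among factors, with pseudo-F tested by free permutation of sample
#' labels. `mode = "terms"` gives sequential (Type I) sums of squares in
#' formula order; `mode = "margin"` adjusts each term for all others. In
#' both modes the denominator is the residual mean square of the full
#' model. Aliased design columns are dropped with a warning; a term that
#' is fully aliased is an error naming the term. Deterministic given
#' `seed`; when `n!` does not exceed `n_perm` the permutation distribution
#' is enumerated exhaustively.
#'
#' @param d Distance matrix (`dist` or symmetric matrix) labeled by
#'   sample.
#' @param metadata data.frame with a `sample_id` column covering all
#'   samples of `d`, plus the term columns.
#' @param terms Character vector of metadata columns (default
#'   `c("site", "rock_type")`, the `Distance ~ Site + Rock type` model).
#' @param n_perm Number of permutations (default 9999).
#' @param mode `"terms"` (sequential) or `"margin"`.
#' @param seed Optional integer seed for the permutations.
#' @return A `permanova_result`: data.frame with `Df`, `SumOfSqs`, `R2`,
#'   `F`, `Pr..F.` rows for each term plus `Residual` and `Total`;
#'   attributes `mode`, `n_perm`, `exhaustive`.
#' @export
permanova <- function(d, metadata, terms = c("site", "rock_type"),
                      n_perm = 9999L, mode = c("terms", "margin"),
                      seed = NULL) {
  mode <- match.arg(mode)
  m <- as_dist_matrix(d)
  n <- nrow(m)
  idx <- match(rownames(m), metadata$sample_id)
  if (anyNA(idx)) .stopf("metadata must cover all samples of the distance matrix")
  meta <- metadata[idx, , drop = FALSE]
  for (term in terms) {
    if (is.null(meta[[term]])) .stopf("metadata lacks term column '%s'", term)
    if (length(unique(meta[[term]])) < 2)
      .stopf("term '%s' has fewer than 2 levels", term)
  }
  G <- .gower_center(m)
  ss_total <- sum(diag(G))
  # cumulative designs, treatment contrasts, alphabetical reference level
  design_cols <- lapply(terms, function(term) {
    f <- factor(meta[[term]], levels = sort(unique(as.character(meta[[term]]))))
    stats::model.matrix(~f)[, -1, drop = FALSE]
  })
  X0 <- matrix(1, n, 1)
  cum <- vector("list", length(terms) + 1)
  cum[[1]] <- .hat_matrix(X0)
  X <- X0
  for (k in seq_along(terms)) {
    X <- cbind(X, design_cols[[k]])
    cum[[k + 1]] <- .hat_matrix(X)
  }
  full <- cum[[length(cum)]]
  expected_rank <- 1 + sum(vapply(design_cols, ncol, integer(1)))
  if (full$rank < expected_rank)
    .warnf("rank-deficient design: %d aliased column(s) dropped",
           expected_rank - full$rank)
  df_term <- diff(vapply(cum, `[[`, integer(1), "rank"))
  if (any(df_term == 0) && mode == "terms")
    .stopf("term '%s' is fully aliased", terms[which(df_term == 0)[1]])
  df_res <- n - full$rank
  if (df_res <= 0) .stopf("no residual degrees of freedom")
  if (mode == "terms") {
    # SS via differences of cumulative projections
    stat_mats <- lapply(seq_along(terms), function(k)
      cum[[k + 1]]$H - cum[[k]]$H)
    dfs <- df_term
  } else {
    # marginal: full minus the design omitting term k
    stat_mats <- vector("list", length(terms))
    dfs <- integer(length(terms))
    for (k in seq_along(terms)) {
      Xk <- do.call(cbind, c(list(X0), design_cols[-k]))
      hk <- .hat_matrix(Xk)
      dfs[k] <- full$rank - hk$rank
      if (dfs[k] == 0) .stopf("term '%s' is fully aliased", terms[k])
      stat_mats[[k]] <- full$H - hk$H
    }
  }
  compute_F <- function(Gp) {
    ss <- vapply(stat_mats, function(Hd) sum(Hd * Gp), numeric(1))
    ss_res <- sum(diag(Gp)) - sum(full$H * Gp)
    list(ss = ss, ss_res = ss_res,
         F = (ss / dfs) / (ss_res / df_res))
  }
  obs <- compute_F(G)
  exhaustive <- factorial(n) <= n_perm
  count <- numeric(length(terms))
  if (exhaustive) {
    perms <- all_permutations(n)
    for (r in seq_len(nrow(perms))) {
      Fp <- compute_F(G[perms[r, ], perms[r, ]])$F
      count <- count + (Fp >= obs$F - 1e-12)
    }
    pvals <- count / nrow(perms)
    n_used <- nrow(perms)
  } else {
    with_seed(seed, {
      for (r in seq_len(n_perm)) {
        p <- sample.int(n)
        Fp <- compute_F(G[p, p])$F
        count <- count + (Fp >= obs$F - 1e-12)
      }
    })
    pvals <- (count + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  tab <- data.frame(
    Df = c(dfs, df_res, n - 1),
    SumOfSqs = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$F, NA, NA),
    `Pr..F.` = c(pvals, NA, NA),
    row.names = c(terms, "Residual", "Total"), check.names = FALSE)
  structure(tab, class = c("permanova_result", "data.frame"),
            mode = mode, n_perm = n_used, exhaustive = exhaustive)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (by = %s, %s%d permutations)\n",
              attr(x, "mode"),
              if (attr(x, "exhaustive")) "exhaustive, " else "",
              attr(x, "n_perm")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Homogeneity of multivariate dispersions with permutation test
#'
#' Embeds the samples by principal coordinates (keeping negative-eigenvalue
#' axes as imaginary coordinates), measures each sample's distance to its
#' group's spatial median — squared real-axis distance minus squared
#' imaginary-axis distance, floored at zero — and tests the one-way F
#' statistic on those distances by permuting them freely across samples.
#' Groups of one sample have dispersion zero and trigger a warning.
#'
#' @param d Distance matrix labeled by sample.
#' @param grouping Factor (or character) of group labels, aligned to the
#'   samples of `d`, or a named vector matched by name.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return A `betadisper_result` list: `distances` (per sample),
#'   `group_means`, `F`, `p`, `n_perm`.
#' @export
betadisperPermutest <- function(d, grouping, n_perm = 9999L, seed = NULL) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  if (!is.null(names(grouping))) grouping <- grouping[rownames(m)]
  if (length(grouping) != n)
    .stopf("grouping must align with the distance matrix")
  grouping <- factor(as.character(grouping))
  if (any(table(grouping) == 1))
    .warnf("group(s) with a single sample have dispersion 0")
  eig <- eigen(.gower_center(m), symmetric = TRUE)
  tol <- max(abs(eig$values), 1) * 1e-9
  pos <- eig$values > tol; neg <- eig$values < -tol
  Xr <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  Xi <- eig$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-eig$values[neg]), sum(neg))
  dists <- numeric(n)
  for (g in levels(grouping)) {
    sel <- which(grouping == g)
    mr <- .spatial_median(Xr[sel, , drop = FALSE])
    mi <- .spatial_median(Xi[sel, , drop = FALSE])
    d2 <- rowSums(sweep(Xr[sel, , drop = FALSE], 2, mr)^2)
    if (ncol(Xi) > 0)
      d2 <- d2 - rowSums(sweep(Xi[sel, , drop = FALSE], 2, mi)^2)
    dists[sel] <- sqrt(pmax(d2, 0))
  }
  names(dists) <- rownames(m)
  anova_F <- function(y) {
    gm <- tapply(y, grouping, mean)
    ssb <- sum(table(grouping) * (gm - mean(y))^2)
    ssw <- sum((y - gm[grouping])^2)
    dfb <- nlevels(grouping) - 1
    dfw <- n - nlevels(grouping)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / dfb) / (ssw / dfw)
  }
  F_obs <- anova_F(dists)
  exhaustive <- factorial(n) <= n_perm
  if (exhaustive) {
    perms <- all_permutations(n)
    count <- sum(apply(perms, 1, function(p) anova_F(dists[p])) >=
                   F_obs - 1e-12)
    p_val <- count / nrow(perms)
    n_used <- nrow(perms)
  } else {
    count <- 0
    with_seed(seed, {
      for (r in seq_len(n_perm))
        if (anova_F(dists[sample.int(n)]) >= F_obs - 1e-12)
          count <- count + 1
    })
    p_val <- (count + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(distances = dists,
                 group_means = tapply(dists, grouping, mean),
                 F = F_obs, p = p_val, n_perm = n_used),
            class = "betadisper_result")
}

#' @export
print.betadisper_result <- function(x, ...) {
  cat(sprintf("Multivariate dispersion test: F = %.4f, p = %.4g (%d permutations)\n",
              x$F, x$p, x$n_perm))
  cat("Group mean distances to spatial median:\n")
  print(round(x$group_means, 4))
  invisible(x)
}

# L1-optimal (spatial) median of the rows of X, by convex minimization of
# the summed Euclidean distances. Zero columns / single rows short-circuit.
.spatial_median <- function(X) {
  if (ncol(X) == 0) return(numeric(0))
  if (nrow(X) == 1) return(drop(X[1, ]))
  start <- colMeans(X)
  obj <- function(mu) sum(sqrt(rowSums(sweep(X, 2, mu)^2) + 1e-24))
  stats::optim(start, obj, method = "BFGS",
               control = list(reltol = 1e-12, maxit = 500))$par
}

#' Great-circle (haversine) distance in kilometers
#'
#' Earth radius 6,378,137 m (the equatorial radius used by the common
#' geographic libraries), so one degree of longitude at the equator is
#' 111.3195 km.
#'
#' @param coord_a,coord_b Coordinates as `c(lat, lon)` in decimal degrees,
#'   or matrices/data.frames with two columns (lat, lon); recycled
#'   row-wise.
#' @return Distance(s) in km.
#' @examples
#' geoDistance(c(0, 0), c(0, 1))  # 111.3195
#' @export
geoDistance <- function(coord_a, coord_b) {
  a <- matrix(as.numeric(as.matrix(coord_a)), ncol = 2)
  b <- matrix(as.numeric(as.matrix(coord_b)), ncol = 2)
  la1 <- a[, 1] * pi / 180; lo1 <- a[, 2] * pi / 180
  la2 <- b[, 1] * pi / 180; lo2 <- b[, 2] * pi / 180
  h <- sin((la2 - la1) / 2)^2 + cos(la1) * cos(la2) * sin((lo2 - lo1) / 2)^2
  2 * .EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
}

#' Pairwise geographic distances between samples
#'
#' @param metadata Metadata data.frame with `sample_id`, `latitude`,
#'   `longitude`.
#' @return Symmetric km matrix labeled by sample id.
#' @export
geoDistanceMatrix <- function(metadata) {
  n <- nrow(metadata)
  coords <- as.matrix(metadata[, c("latitude", "longitude")])
  m <- matrix(0, n, n, dimnames = list(metadata$sample_id,
                                       metadata$sample_id))
  for (i in seq_len(n))
    m[i, ] <- geoDistance(coords[rep(i, n), , drop = FALSE], coords)
  (m + t(m)) / 2
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default, average ranks for ties) between the
#' lower triangles of a community and a geographic distance matrix, tested
#' one-sided ("greater") by jointly permuting rows and columns of the
#' community matrix. With `exclude_zero_geo = TRUE`, sample pairs at zero
#' geographic distance (same site) are masked out; the mask is defined by
#' the unpermuted geographic matrix and applied after each permutation of
#' the community matrix, since the geographic structure is fixed.
#'
#' @param community_dist,geo_dist Distance matrices (`dist` or symmetric
#'   matrix) over the same samples; at least 4 samples.
#' @param method `"spearman"` or `"pearson"`.
#' @param n_perm Number of permutations (default 9999).
#' @param exclude_zero_geo Mask zero-geographic-distance pairs.
#' @param seed Optional integer seed.
#' @return A `mantel_result` list: `r`, `p`, `n_perm`, `n`,
#'   `excluded_zero_pairs`, `exhaustive`, `constant` (TRUE when a distance
#'   vector was constant and `r` is undefined).
#' @export
mantelTest <- function(community_dist, geo_dist, method = c("spearman",
                                                            "pearson"),
                       n_perm = 9999L, exclude_zero_geo = FALSE,
                       seed = NULL) {
  method <- match.arg(method)
  C <- as_dist_matrix(community_dist, "community distance matrix")
  Gm <- as_dist_matrix(geo_dist, "geographic distance matrix")
  if (!identical(rownames(C), rownames(Gm))) {
    if (!setequal(rownames(C), rownames(Gm)))
      .stopf("distance matrices must share sample labels")
    Gm <- Gm[rownames(C), rownames(C)]
  }
  n <- nrow(C)
  if (n < 4) .stopf("Mantel test needs at least 4 samples")
  lower <- lower.tri(C)
  mask <- if (exclude_zero_geo) Gm[lower] > 0 else rep(TRUE, sum(lower))
  if (sum(mask) < 3) .stopf("too few non-masked pairs for a Mantel test")
  gv <- Gm[lower][mask]
  gv_stat <- if (method == "spearman") avg_rank(gv) else gv
  clow <- C[lower]
  # pair-index map: entry (i, j) holds the lower-triangle position of the
  # unordered pair, so a joint row/column permutation of C reduces to an
  # integer reindexing of the original lower-triangle vector
  n_pairs <- sum(lower)
  pairM <- matrix(0L, n, n)
  pairM[lower] <- seq_len(n_pairs)
  pairM <- pairM + t(pairM)
  crank <- if (method == "spearman") avg_rank(clow) else clow
  corr <- function(idx) {
    cv <- if (method == "spearman" && !exclude_zero_geo)
      crank[idx] else clow[idx]
    if (exclude_zero_geo) cv <- cv[mask]
    if (stats::sd(cv) == 0 || stats::sd(gv) == 0) return(NA_real_)
    if (method == "spearman" && exclude_zero_geo) cv <- avg_rank(cv)
    stats::cor(gv_stat, cv)
  }
  r_obs <- corr(seq_len(n_pairs))
  if (is.na(r_obs)) {
    .warnf("constant distance vector: Mantel r undefined")
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = 0L, n = n,
                          excluded_zero_pairs = exclude_zero_geo,
                          exhaustive = FALSE, constant = TRUE),
                     class = "mantel_result"))
  }
  perm_r <- function(p) corr(pairM[p, p][lower])
  exhaustive <- factorial(n) <= n_perm
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, perm_r)
    p_val <- mean(rs >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    count <- 0
    with_seed(seed, {
      for (k in seq_len(n_perm))
        if (perm_r(sample.int(n)) >= r_obs - 1e-12) count <- count + 1
    })
    p_val <- (count + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p_val, n_perm = n_used, n = n,
                 excluded_zero_pairs = exclude_zero_geo,
                 exhaustive = exhaustive, constant = FALSE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (x$constant) {
    cat("Mantel test: r undefined (constant distance vector)\n")
  } else {
    cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s%d permutations, n = %d%s)\n",
                x$r, x$p, if (x$exhaustive) "exhaustive, " else "",
                x$n_perm, x$n,
                if (x$excluded_zero_pairs) ", zero-distance pairs excluded"
                else ""))
  }
  invisible(x)
}

#' Occupancy of vOTUs across sites and regions
#'
#' Joins a detection mask to sample metadata and reports, over the vOTUs
#' detected anywhere, the fractions detected at more than one site, in two
#' or more geographic regions, and in all regions.
#'
#' @param detection Logical samples-x-vOTUs matrix (rows labeled by sample
#'   id), or an [AbundanceMatrix-class].
#' @param metadata Metadata data.frame covering the samples.
#' @return List: `n_votus` (detected anywhere), `multi_site_pct`,
#'   `multi_region_pct`, `all_regions_pct` (percentages to two decimals)
#'   plus the underlying counts.
#' @export
occupancySummary <- function(detection, metadata) {
  if (is(detection, "AbundanceMatrix")) detection <- detectionMask(detection)
  idx <- match(rownames(detection), metadata$sample_id)
  if (anyNA(idx)) .stopf("metadata must cover all samples")
  site <- metadata$site[idx]
  region <- metadata$region[idx]
  n_regions_total <- length(unique(region))
  anywhere <- colSums(detection) > 0
  if (!any(anywhere)) {
    .warnf("empty detection mask: occupancy fractions are 0")
    return(list(n_votus = 0L, n_multi_site = 0L, n_multi_region = 0L,
                n_all_regions = 0L, multi_site_pct = 0,
                multi_region_pct = 0, all_regions_pct = 0))
  }
  det <- detection[, anywhere, drop = FALSE]
  n_sites <- apply(det, 2, function(col) length(unique(site[col])))
  n_regs <- apply(det, 2, function(col) length(unique(region[col])))
  nv <- ncol(det)
  list(n_votus = as.integer(nv),
       n_multi_site = as.integer(sum(n_sites > 1)),
       n_multi_region = as.integer(sum(n_regs >= 2)),
       n_all_regions = as.integer(sum(n_regs == n_regions_total)),
       multi_site_pct = round(100 * sum(n_sites > 1) / nv, 2),
       multi_region_pct = round(100 * sum(n_regs >= 2) / nv, 2),
       all_regions_pct = round(100 * sum(n_regs == n_regions_total) / nv, 2))
}

#' Subset an abundance matrix by a metadata predicate
#'
#' Keeps the samples for which the predicate holds and drops vOTUs
#' detected in no remaining sample (e.g. restricting to sandstone samples
#' before a distance-decay analysis).
#'
#' @param x An [AbundanceMatrix-class].
#' @param metadata Metadata data.frame covering the samples.
#' @param predicate Either a logical vector over metadata rows or a
#'   function of the metadata data.frame returning one.
#' @return The subset [AbundanceMatrix-class]; empty selections warn.
#' @examples
#' \dontrun{subsetSamples(am, meta, function(m) m$rock_type == "sandstone")}
#' @export
subsetSamples <- function(x, metadata, predicate) {
  stopifnot(is(x, "AbundanceMatrix"))
  keep_meta <- if (is.function(predicate)) predicate(metadata) else predicate
  if (!is.logical(keep_meta) || length(keep_meta) != nrow(metadata))
    .stopf("predicate must yield one logical per metadata row")
  keep_samples <- metadata$sample_id[keep_meta]
  sel <- rownames(abundanceValues(x)) %in% keep_samples
  if (!any(sel)) .warnf("predicate matched no samples")
  vals <- abundanceValues(x)[sel, , drop = FALSE]
  det <- detectionMask(x)[sel, , drop = FALSE]
  keep_votus <- colSums(det) > 0
  new("AbundanceMatrix", values = vals[, keep_votus, drop = FALSE],
      detection = det[, keep_votus, drop = FALSE], params = x@params)
}
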