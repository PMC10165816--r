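# Independent oracles used across the suite.

# Pure-R Gotoh local alignment (affine gaps, same scoring scheme as the
# package's alignment engine: match 2, mismatch -3, gap open 5, extend 2,
# a gap of length L costing open + L * ext). Full O(nm) dynamic
# programming with traceback; intended for sequences of a few hundred bp.
# Returns identity = matches / alignment columns and the aligned span on
# the shorter sequence.
sw_oracle <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  if (length(A) < length(B)) { tmp <- A; A <- B; B <- tmp }
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in A (move along B)
  F_ <- matrix(NEG, n + 1, m + 1) # gap in B (move along A)
  ptr <- matrix(0L, n + 1, m + 1) # 1 diag, 2 from E, 3 from F
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F_[i, j] <- max(H[i - 1, j] - open - ext, F_[i - 1, j] - ext)
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      diag <- H[i - 1, j - 1] + s
      h <- max(0, diag, E[i, j], F_[i, j])
      H[i, j] <- h
      ptr[i, j] <- if (h == 0) 0L else if (h == diag) 1L else
        if (h == E[i, j]) 2L else 3L
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best == 0)
    return(list(identity = 0, coverage_shorter = 0, score = 0))
  i <- bi; j <- bj
  matches <- 0L; cols <- 0L
  j_end <- bj - 1L
  while (i > 1 && j > 1 && H[i, j] > 0) {
    p <- ptr[i, j]
    if (p == 1L) {
      cols <- cols + 1L
      if (A[i - 1] == B[j - 1] && A[i - 1] != "N") matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      # walk the whole horizontal gap (gap in A)
      k <- 1L
      while (E[i, j] != H[i, j - k] - open - ext * k) k <- k + 1L
      cols <- cols + k
      j <- j - k
    } else {
      k <- 1L
      while (F_[i, j] != H[i - k, j] - open - ext * k) k <- k + 1L
      cols <- cols + k
      i <- i - k
    }
  }
  list(identity = matches / cols,
       coverage_shorter = (j_end - (j - 1)) / m,
       score = best)
}

# Brute-force reference clustering: precompute all pairwise alignments
# with the package engine (no prescreen), then apply the same greedy
# longest-first / first-matching-representative rule.
brute_force_clusters <- function(vset, identity = 0.95, short_cov = 0.85) {
  lens <- seqLengths(vset)
  ord <- order(-lens, names(lens), method = "radix")
  ids <- names(lens)[ord]
  seqs <- as.character(sequences(vset))[ids]
  k <- length(ids)
  idm <- matrix(0, k, k, dimnames = list(ids, ids))
  cvm <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j >= i) next
    al <- alignmentIdentity(seqs[[j]], seqs[[i]])  # j is longer (earlier)
    idm[ids[j], ids[i]] <- al$identity
    cvm[ids[j], ids[i]] <- al$coverage_shorter
  }
  reps <- character(0)
  assign <- stats::setNames(character(k), ids)
  for (id in ids) {
    hit <- NA_character_
    for (r in reps) {
      if (idm[r, id] >= identity && cvm[r, id] >= short_cov) {
        hit <- r; break
      }
    }
    if (is.na(hit)) { reps <- c(reps, id); assign[id] <- id }
    else assign[id] <- hit
  }
  assign
}

# Exact log-space hypergeometric upper-tail sum via binomial coefficients:
# P(X >= a) with X ~ Hypergeometric(N, m, n).
hyper_tail_oracle <- function(a, n, m, N) {
  ks <- a:min(n, m)
  logt <- lchoose(m, ks) + lchoose(N - m, n - ks) - lchoose(N, n)
  mx <- max(logt)
  mx + log(sum(exp(logt - mx)))
}

# Closed-form one-factor PERMANOVA pseudo-F from a distance matrix and a
# grouping, via within/total sums of squared distances (no projections).
permanova_F_oracle <- function(dmat, grouping) {
  n <- nrow(dmat)
  ss_total <- sum(dmat[lower.tri(dmat)]^2) / n
  ss_within <- 0
  for (g in unique(grouping)) {
    sel <- which(grouping == g)
    sub <- dmat[sel, sel, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(sel)
  }
  a <- length(unique(grouping))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# Exhaustive one-factor PERMANOVA p-value over all n! relabelings.
permanova_p_oracle <- function(dmat, grouping) {
  n <- nrow(dmat)
  perms <- endovirome_all_perms(n)
  F_obs <- permanova_F_oracle(dmat, grouping)
  Fs <- apply(perms, 1, function(p) permanova_F_oracle(dmat, grouping[p]))
  mean(Fs >= F_obs - 1e-12)
}

# Exhaustive Mantel p-value (Spearman, one-sided greater).
mantel_p_oracle <- function(cmat, gmat) {
  n <- nrow(cmat)
  lower <- lower.tri(cmat)
  gv <- gmat[lower]
  r_of <- function(p) stats::cor(cmat[p, p][lower], gv, method = "spearman")
  perms <- endovirome_all_perms(n)
  rs <- apply(perms, 1, r_of)
  r_obs <- r_of(seq_len(n))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# Minimal permutation enumerator (lexicographic), independent of the
# package's internal helper.
endovirome_all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- endovirome_all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- setdiff(seq_len(n), first)
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}
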