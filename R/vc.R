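# Simplified gene-sharing network: hypergeometric edge significance,
# Markov clustering into viral clusters (VCs), per-genome status labels,
# and VC-membership taxonomy.

#' Gene-sharing edge weights by hypergeometric significance
#'
#' For every genome pair sharing at least one protein cluster, the edge
#' weight is `-log10 P(X >= a)` where `X` is hypergeometric: the number of
#' clusters shared by chance between profiles of sizes `n` and `m` drawn
#' from a universe of `universe_size` protein clusters, and `a` the
#' observed overlap. Computed in log space, so extreme overlaps do not
#' underflow. Edges with weight below `threshold` are kept in the edge
#' table but flagged non-significant; only significant edges enter the
#' clustering.
#'
#' @param profiles Named list mapping genome id to its character vector of
#'   protein-cluster ids (see [readProfileTable()]).
#' @param universe_size Total number of protein clusters; must be at least
#'   every profile's size.
#' @param threshold Significance threshold on the weight (default 1.0,
#'   i.e. P <= 0.1).
#' @return List of class `gene_sharing_graph`: `edges` (data.frame `from`,
#'   `to`, `shared`, `weight`, `significant`), `genomes`, `threshold`,
#'   `universe_size`.
#' @export
edgeWeights <- function(profiles, universe_size, threshold = 1.0) {
  genomes <- sort(names(profiles))
  sizes <- lengths(profiles[genomes])
  if (any(sizes > universe_size))
    .stopf("universe_size (%d) smaller than a genome's cluster count (%d)",
           universe_size, max(sizes))
  rows <- vector("list", 0)
  for (i in seq_along(genomes)) {
    for (j in seq_len(i - 1L)) {
      a <- length(intersect(profiles[[genomes[i]]], profiles[[genomes[j]]]))
      if (a == 0) next
      n <- sizes[[i]]; m <- sizes[[j]]
      logp <- stats::phyper(a - 1, m, universe_size - m, n,
                            lower.tail = FALSE, log.p = TRUE)
      w <- -logp / log(10)
      rows[[length(rows) + 1]] <- data.frame(
        from = genomes[j], to = genomes[i], shared = a, weight = w,
        significant = w >= threshold, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), to = character(), shared = integer(),
               weight = numeric(), significant = logical(),
               stringsAsFactors = FALSE)
  structure(list(edges = edges, genomes = genomes, threshold = threshold,
                 universe_size = universe_size),
            class = "gene_sharing_graph")
}

# Markov clustering (expansion 2, configurable inflation) on a weighted
# undirected graph given as an edge data.frame over `nodes`. Deterministic:
# nodes are processed in sorted order and convergence is by a fixed
# tolerance. Returns a list of character clusters.
.mcl <- function(edges, nodes, inflation = 2.0, tol = 1e-8,
                 max_iter = 200L) {
  nodes <- sort(nodes)
  k <- length(nodes)
  if (k == 0) return(list())
  M <- matrix(0, k, k, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    fi <- match(edges$from, nodes); ti <- match(edges$to, nodes)
    for (e in seq_len(nrow(edges))) {
      M[fi[e], ti[e]] <- edges$weight[e]
      M[ti[e], fi[e]] <- edges$weight[e]
    }
  }
  # self-loops at each node's maximum incident weight (MCL convention)
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2, colSums(M), "/")
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M                      # expansion
    M <- M^inflation                  # inflation
    M[M < 1e-14] <- 0
    M <- sweep(M, 2, colSums(M), "/")
    if (max(abs(M - prev)) < tol) break
  }
  # clusters: connected components of the attractor relation
  adj <- M >= 1e-6
  adj <- adj | t(adj)
  comp <- rep(NA_integer_, k)
  cid <- 0L
  for (s in seq_len(k)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  unname(split(nodes, comp))
}

#' Cluster the gene-sharing graph into viral clusters
#'
#' Runs Markov-flow clustering (expansion 2, configurable inflation,
#' convergence tolerance 1e-8, deterministic sorted iteration order) on the
#' significant edges of a gene-sharing graph. Graph components that end up
#' as single genomes are not VCs; those genomes are left unclustered for
#' [assignStatus()] to label.
#'
#' @param graph A `gene_sharing_graph` from [edgeWeights()].
#' @param inflation MCL inflation (default 2.0).
#' @return A [ViralClusterSet-class] with VC membership filled in and
#'   statuses unset (see [assignStatus()]).
#' @export
clusterGraph <- function(graph, inflation = 2.0) {
  stopifnot(inherits(graph, "gene_sharing_graph"))
  sig <- graph$edges[graph$edges$significant, , drop = FALSE]
  nodes <- sort(unique(c(sig$from, sig$to)))
  clusters <- .mcl(sig, nodes, inflation = inflation)
  clusters <- clusters[lengths(clusters) >= 2]
  clusters <- clusters[order(vapply(clusters, min, character(1)))]
  vcs <- stats::setNames(clusters,
                         sprintf("VC_%d", seq_along(clusters)))
  new("ViralClusterSet", edges = graph$edges, vcs = vcs,
      status = character(0), vcTaxonomy = data.frame(),
      genomes = graph$genomes, references = character(0))
}

#' Label every genome's clustering status
#'
#' Applies the usual gene-sharing-network vocabulary: `clustered` (in a
#' VC); `singleton` (no gene-sharing edges at all); `overlap` (significant
#' edges to members of two or more distinct VCs, without being in a VC
#' itself); `outlier` (has edges — possibly only weak ones — but cannot be
#' placed in a VC and is not an overlap). The four statuses partition the
#' genomes.
#'
#' @param cluster_set A [ViralClusterSet-class] from [clusterGraph()].
#' @param graph The `gene_sharing_graph` the clusters came from.
#' @return The cluster set with `status` filled in.
#' @export
assignStatus <- function(cluster_set, graph) {
  stopifnot(is(cluster_set, "ViralClusterSet"))
  genomes <- cluster_set@genomes
  vc_of <- rep(NA_character_, length(genomes))
  names(vc_of) <- genomes
  for (vc in names(cluster_set@vcs))
    vc_of[cluster_set@vcs[[vc]]] <- vc
  edges <- graph$edges
  status <- stats::setNames(rep("outlier", length(genomes)), genomes)
  has_edge <- genomes %in% c(edges$from, edges$to)
  status[!has_edge] <- "singleton"
  status[!is.na(vc_of)] <- "clustered"
  sig <- edges[edges$significant, , drop = FALSE]
  for (g in genomes[is.na(vc_of) & has_edge]) {
    nb <- c(sig$to[sig$from == g], sig$from[sig$to == g])
    vcs_touched <- unique(stats::na.omit(vc_of[nb]))
    if (length(vcs_touched) >= 2) status[g] <- "overlap"
  }
  cluster_set@status <- status
  validObject(cluster_set)
  cluster_set
}

#' Assign taxonomy to viral clusters from reference members
#'
#' Per VC and per rank (class, order, family, genus — each rank evaluated
#' independently, so a class can be assigned even when families disagree):
#' if the VC contains at least one reference genome and all its references
#' carry the same non-empty name at that rank, the VC gets that name. A VC
#' whose references disagree at every rank is labeled `Mixed`; a VC with
#' no references is a `Unique VC` (a putatively novel genus). Otherwise
#' the label is the name at the deepest assigned rank.
#'
#' @param cluster_set A [ViralClusterSet-class].
#' @param reference_taxa data.frame from [readReferenceTaxa()]; its
#'   `genome_id`s define which genomes count as references.
#' @return The cluster set with `vcTaxonomy` and `references` filled in.
#' @export
assignVCTaxonomy <- function(cluster_set, reference_taxa) {
  stopifnot(is(cluster_set, "ViralClusterSet"))
  refs <- reference_taxa$genome_id
  rows <- vector("list", 0)
  for (vc in names(cluster_set@vcs)) {
    members <- cluster_set@vcs[[vc]]
    vrefs <- intersect(members, refs)
    row <- data.frame(vc_id = vc, stringsAsFactors = FALSE)
    for (r in .VC_RANKS) row[[r]] <- NA_character_
    if (length(vrefs) == 0) {
      row$label <- "Unique VC"
    } else {
      tax <- reference_taxa[match(vrefs, reference_taxa$genome_id), ,
                            drop = FALSE]
      assigned_any <- FALSE
      for (r in .VC_RANKS) {
        vals <- tax[[r]]
        vals[is.na(vals)] <- ""
        if (length(unique(vals)) == 1 && vals[1] != "") {
          row[[r]] <- vals[1]
          assigned_any <- TRUE
        }
      }
      if (!assigned_any) row$label <- "Mixed"
      else {
        deepest <- rev(.VC_RANKS)[which(!is.na(
          unlist(row[rev(.VC_RANKS)])))[1]]
        row$label <- row[[deepest]]
      }
    }
    rows[[length(rows) + 1]] <- row
  }
  cluster_set@vcTaxonomy <- if (length(rows)) do.call(rbind, rows) else
    data.frame(vc_id = character(), label = character(),
               stringsAsFactors = FALSE)
  cluster_set@references <- refs
  cluster_set
}

#' Count viral clusters by reference content
#'
#' @param cluster_set A [ViralClusterSet-class] with taxonomy assigned.
#' @return List: `n_vcs`, `n_with_references`, `n_unique`, `unique_pct`
#'   and `with_references_pct` (one decimal; `NA` when there are no VCs).
#' @export
summarizeVCs <- function(cluster_set) {
  stopifnot(is(cluster_set, "ViralClusterSet"))
  tax <- cluster_set@vcTaxonomy
  n <- length(cluster_set@vcs)
  if (n == 0 || nrow(tax) == 0)
    return(list(n_vcs = 0L, n_with_references = 0L, n_unique = 0L,
                unique_pct = NA_real_, with_references_pct = NA_real_))
  n_unique <- sum(tax$label == "Unique VC")
  list(n_vcs = as.integer(n),
       n_with_references = as.integer(n - n_unique),
       n_unique = as.integer(n_unique),
       unique_pct = round(100 * n_unique / n, 1),
       with_references_pct = round(100 * (n - n_unique) / n, 1))
}

#' Build viral clusters end to end
#'
#' Convenience wrapper: [edgeWeights()] then [clusterGraph()],
#' [assignStatus()] and [assignVCTaxonomy()].
#'
#' @param profiles Named list of protein-cluster profiles.
#' @param universe_size Protein-cluster universe size.
#' @param reference_taxa Reference taxonomy data.frame.
#' @param threshold,inflation Tuning knobs (defaults 1.0 and 2.0).
#' @return A fully annotated [ViralClusterSet-class].
#' @export
buildViralClusters <- function(profiles, universe_size, reference_taxa,
                               threshold = 1.0, inflation = 2.0) {
  graph <- edgeWeights(profiles, universe_size, threshold = threshold)
  cs <- clusterGraph(graph, inflation = inflation)
  cs <- assignStatus(cs, graph)
  assignVCTaxonomy(cs, reference_taxa)
}
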