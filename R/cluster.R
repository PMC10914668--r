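# Cluster: drug-drug Pearson correlation of adjusted fingerprints, weighted
# graph construction, and Louvain modularity partitioning.

#' Drug-drug Pearson correlation of receptor fingerprints
#'
#' Each drug's adjusted affinity vector across receptors is Pearson
#' correlated with every other drug's; a high coefficient means two drugs
#' share a similar receptor profile. Because correlation is location/scale
#' invariant per drug, it also absorbs overall potency differences between
#' compounds (similar in effect to normalizing by D2 affinity).
#'
#' @param x complete `adjusted_matrix` (impute first) or numeric matrix
#'   without missing values.
#' @return a `similarity_matrix`: symmetric n x n correlation matrix with
#'   unit diagonal.
#' @export
correlation_matrix <- function(x) {
  V <- as_values(x)
  if (anyNA(V))
    stop("correlation_matrix: matrix has missing values; impute first")
  sds <- apply(V, 1, sd)
  if (any(sds == 0))
    stop("correlation_matrix: zero variance across receptors for drug(s): ",
         paste(rownames(V)[sds == 0], collapse = ", "))
  C <- cor(t(V))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(list(drugs = rownames(V), values = C),
            class = "similarity_matrix")
}

#' Construct a similarity matrix from a square correlation-like matrix
#'
#' @param values symmetric numeric matrix with unit diagonal and entries in
#'   `[-1, 1]`, drugs as dimnames.
#' @return a `similarity_matrix`.
#' @export
similarity_matrix <- function(values) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            max(abs(values - t(values))) < 1e-12,
            all(abs(diag(values) - 1) < 1e-12),
            all(values >= -1 - 1e-12 & values <= 1 + 1e-12))
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) <- sprintf("drug%02d", seq_len(nrow(values)))
  structure(list(drugs = rownames(values), values = values),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$values[lower.tri(x$values)]
  cat(sprintf("similarity matrix: %d drugs, off-diagonal r in [%.3f, %.3f]\n",
              length(x$drugs), min(off), max(off)))
  invisible(x)
}

#' Build the weighted drug graph from a similarity matrix
#'
#' Modularity-based community detection expects non-negative weights, while
#' Pearson correlations can be negative; a policy maps correlations to
#' weights: `clip_zero` (default; negative similarities carry no attractive
#' force), `shift_min` (subtract the minimum off-diagonal correlation) or
#' `abs`. No self-loops.
#'
#' @param sim a `similarity_matrix`.
#' @param negative_policy one of `"clip_zero"`, `"shift_min"`, `"abs"`.
#' @return a `drug_graph`: list with the weight matrix, the policy label and
#'   an `igraph` carrier graph.
#' @export
build_graph <- function(sim, negative_policy = c("clip_zero", "shift_min", "abs")) {
  negative_policy <- match.arg(negative_policy)
  stopifnot(inherits(sim, "similarity_matrix"))
  W <- sim$values
  diag(W) <- 0
  W <- switch(negative_policy,
              clip_zero = pmax(W, 0),
              shift_min = { m <- min(W[row(W) != col(W)]); out <- W - m; diag(out) <- 0; out },
              abs = abs(W))
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  structure(list(drugs = sim$drugs, weights = W,
                 negative_policy = negative_policy, graph = g),
            class = "drug_graph")
}

#' Weighted modularity of a partition
#'
#' Direct evaluation of Q = (1/2m) * sum_ij (A_ij - gamma k_i k_j / 2m)
#' delta(c_i, c_j), including the i = j degree terms, so the all-in-one
#' partition scores exactly 0 at `resolution = 1`. Implemented from the
#' formula (independently of the community-detection backend) so that
#' returned partitions can be re-scored.
#'
#' @param graph a `drug_graph` (or a non-negative symmetric weight matrix
#'   with zero diagonal).
#' @param partition a `partition` object or a membership vector named by
#'   node.
#' @param resolution resolution parameter gamma (1 = classic modularity).
#' @return the modularity value Q.
#' @export
modularity_q <- function(graph, partition, resolution = 1) {
  A <- if (inherits(graph, "drug_graph")) graph$weights else as.matrix(graph)
  memb <- if (inherits(partition, "partition")) partition$assignment else partition
  if (is.null(names(memb)) && length(memb) == nrow(A)) names(memb) <- rownames(A)
  if (!all(rownames(A) %in% names(memb)))
    stop("modularity_q: partition is missing node(s): ",
         paste(setdiff(rownames(A), names(memb)), collapse = ", "))
  memb <- memb[rownames(A)]
  m2 <- sum(A)  # = 2m
  if (m2 <= 0) stop("modularity_q: graph has no positive edge weight")
  k <- rowSums(A)
  same <- outer(memb, memb, `==`)
  sum((A - resolution * outer(k, k) / m2) * same) / m2
}

canonical_relabel <- function(memb) {
  # order clusters by size (desc), ties by lexicographically smallest member
  ids <- unique(memb)
  size <- vapply(ids, function(c) sum(memb == c), integer(1))
  first <- vapply(ids, function(c) min(names(memb)[memb == c]), character(1))
  ord <- ids[order(-size, first)]
  out <- match(memb, ord)
  names(out) <- names(memb)
  out
}

#' Partition the drug graph by Louvain modularity maximization
#'
#' Runs the Louvain local-moving/aggregation heuristic `n_restarts` times
#' over seeded random node orders and keeps the highest-modularity result
#' (ties broken by the lexicographically smallest canonical assignment
#' vector). Cluster ids are relabeled canonically: decreasing size, ties by
#' smallest member name.
#'
#' @param graph a `drug_graph` with at least one positive-weight edge.
#' @param seed integer master seed for the restart protocol.
#' @param resolution modularity resolution (1 = the classic objective).
#' @param n_restarts number of seeded node-order restarts.
#' @return a `partition`: `assignment` (named integer vector, contiguous
#'   ids), `n_clusters`, `modularity` (recomputed with [modularity_q()]),
#'   `seed`, `n_restarts`, `negative_policy`.
#' @export
louvain_partition <- function(graph, seed = 1L, resolution = 1,
                              n_restarts = 100L) {
  stopifnot(inherits(graph, "drug_graph"))
  if (sum(graph$weights) <= 0)
    stop("louvain_partition: graph has no positive-weight edge ",
         "(degenerate under negative policy '", graph$negative_policy, "')")
  g <- graph$graph
  nv <- igraph::vcount(g)
  seeds <- derive_seeds(seed, paste0("restart", seq_len(n_restarts)))
  best_q <- -Inf
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seeds[r])
    perm <- sample.int(nv)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp, resolution = resolution)
    memb <- igraph::membership(cl)[perm]  # back to original vertex order
    names(memb) <- graph$drugs
    memb <- canonical_relabel(memb)
    q <- modularity_q(graph, memb, resolution)
    better <- q > best_q + 1e-12 ||
      (abs(q - best_q) <= 1e-12 && !is.null(best) &&
         paste(memb, collapse = ",") < paste(best, collapse = ","))
    if (better) { best_q <- q; best <- memb }
  }
  structure(list(assignment = best, n_clusters = length(unique(best)),
                 modularity = best_q, seed = seed, n_restarts = n_restarts,
                 resolution = resolution,
                 negative_policy = graph$negative_policy),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d drugs in %d cluster(s), Q = %.4f (policy %s, %d restarts)\n",
              length(x$assignment), x$n_clusters, x$modularity,
              x$negative_policy, x$n_restarts))
  sizes <- table(x$assignment)
  for (cid in names(sizes))
    cat(sprintf("  cluster %s (%d): %s\n", cid, sizes[[cid]],
                paste(names(x$assignment)[x$assignment == as.integer(cid)],
                      collapse = ", ")))
  invisible(x)
}

#' Convert a partition to a grouping scheme
#'
#' @param partition a `partition`.
#' @param name scheme label (default `"derived_clusters"`).
#' @return a `grouping_scheme` usable as a categorical predictor.
#' @export
partition_to_scheme <- function(partition, name = "derived_clusters") {
  grouping_scheme(stats::setNames(paste0("cluster", partition$assignment),
                                  names(partition$assignment)), name)
}
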