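# Shared fixtures and independent oracles used across test files.

# write a small TSV fixture and return its path
write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

make_records <- function(drug, receptor, ki, species = "human",
                         source_id = NA_character_) {
  if (length(drug) == 0L) species <- source_id <- character(0)
  structure(data.frame(drug = drug, receptor = receptor, species = species,
                       ki_nM = ki, source_id = source_id,
                       stringsAsFactors = FALSE),
            class = c("ki_records", "data.frame"))
}

make_clinical <- function(Y) {
  kind <- stats::setNames(rep("side_effect", ncol(Y)), colnames(Y))
  apclust:::new_clinical_profile(Y, kind)
}

make_affinity <- function(values) {
  apclust:::new_affinity_matrix(values)
}

# enumerate all set partitions of n elements as restricted growth strings
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (c in seq_len(maxid + 1L)) rec(c(prefix, c), max(maxid, c))
  }
  rec(1L, 1L)
  out
}

# brute-force maximum-modularity oracle, independent of the Louvain path
brute_force_best_modularity <- function(W) {
  best <- -Inf
  for (pp in enumerate_partitions(nrow(W))) {
    q <- modularity_q(W, stats::setNames(pp, rownames(W)))
    if (q > best) best <- q
  }
  best
}

# principal angle (radians) between the column spans of two bases
max_subspace_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  cosv <- svd(crossprod(qa, qb))$d
  max(acos(pmin(pmax(cosv, -1), 1)))
}

adjusted_rand <- function(a, b) {
  skip_if_not_installed("mclust")
  mclust::adjustedRandIndex(a, b)
}
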