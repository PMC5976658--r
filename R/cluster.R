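#' Functional similarity matrix of synergies
#'
#' Each synergy is represented by its full-movement confusion matrix
#' (72 x 72 for the complete design), reshaped as a vector (5184 elements);
#' functional similarity of two synergies — possibly from different
#' subjects — is the Pearson correlation of these vectors. Pairs involving
#' a zero-variance (degenerate) confusion matrix have undefined
#' correlation; they are recorded as `NA` and treated as maximally distant
#' by the tree builder.
#'
#' @param confusions list of row-stochastic confusion matrices `D`, all of
#'   the same dimension and class ordering (or `decoding_result` objects,
#'   whose `$confusion$D` is taken).
#' @param registry optional data frame describing each synergy (subject,
#'   index, mode); carried through for reporting.
#' @return object of class `functional_similarity`: `r` (symmetric
#'   correlation matrix with unit diagonal), `registry`, `vector_length`.
#' @export
functional_similarity_matrix <- function(confusions, registry = NULL) {
  vecs <- lapply(confusions, function(cm) {
    if (inherits(cm, "decoding_result")) cm <- cm$confusion
    if (inherits(cm, "confusion_matrix")) cm <- cm$D
    as.vector(as.matrix(cm))
  })
  len <- unique(vapply(vecs, length, integer(1)))
  if (length(len) != 1) stop("all confusion matrices must share dimensions")
  n <- length(vecs)
  r <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      if (sd(vecs[[i]]) == 0 || sd(vecs[[j]]) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
      } else {
        r[i, j] <- r[j, i] <- cor(vecs[[i]], vecs[[j]])
      }
    }
  }
  if (is.null(registry)) {
    registry <- data.frame(synergy = seq_len(n))
  }
  structure(list(r = r, registry = registry, vector_length = len),
            class = "functional_similarity")
}

#' Build a complete-linkage tree from functional similarities
#'
#' Correlation is a similarity, so the tree is grown on the distance
#' `d = 1 - r`; undefined similarities are imputed as distance 2 (beyond
#' the maximum attainable), making degenerate synergies singletons.
#' Complete linkage uses the furthest distance between members of two
#' clusters, so merge heights are monotone non-decreasing.
#'
#' @param sim a [functional_similarity_matrix()] object, or directly a
#'   symmetric correlation matrix.
#' @param linkage linkage rule (only `"complete"` is supported, as used
#'   for the synergy trees).
#' @return an [stats::hclust] tree (heights on the `1 - r` scale).
#' @export
build_tree <- function(sim, linkage = "complete") {
  stopifnot(identical(linkage, "complete"))
  r <- if (inherits(sim, "functional_similarity")) sim$r else as.matrix(sim)
  if (nrow(r) < 2) stop("need at least 2 synergies to build a tree")
  d <- 1 - r
  d[is.na(d)] <- 2
  hclust(as.dist(d), method = "complete")
}

#' Cut the synergy tree and summarize the clusters
#'
#' Clusters are the tree components whose internal merge heights lie below
#' `cutoff` (on the `1 - r` distance scale; the reference analysis uses
#' 0.5 for temporal synergies and 0.6 for spatial ones). Components of
#' size one are labelled `"unclustered"` — synergies functionally
#' dissimilar to every other. Each real cluster is summarised by the
#' entrywise average of its members' synergies (meaningful under the
#' unit-norm convention), with per-element dispersion, and by the average
#' of its members' confusion matrices, row-renormalised to stay
#' row-stochastic.
#'
#' @param tree an [stats::hclust] tree from [build_tree()].
#' @param cutoff positive cut height.
#' @param synergies optional list of synergy vectors/matrices (one per
#'   leaf, same order as the similarity matrix) to average.
#' @param confusions optional list of confusion matrices (as in
#'   [functional_similarity_matrix()]) to average.
#' @return list of class `cluster_set`: `assignments` (integer cluster id
#'   or `NA` for unclustered, with a `labels` character rendering),
#'   `n_clusters`, `cutoff`, `tree` and `summaries` (per cluster: members,
#'   `mean_synergy`, `sd_synergy`, `mean_confusion`).
#' @export
cut_and_summarize <- function(tree, cutoff, synergies = NULL,
                              confusions = NULL) {
  stopifnot(inherits(tree, "hclust"), cutoff > 0)
  if (all(tree$height >= cutoff)) {
    warning("cutoff below all merge heights: every synergy is unclustered")
  }
  grp <- cutree(tree, h = cutoff)
  sizes <- table(grp)
  real <- as.integer(names(sizes)[sizes >= 2])
  assignments <- ifelse(grp %in% real, match(grp, real), NA_integer_)
  labels <- ifelse(is.na(assignments), "unclustered",
                   paste0("C", assignments))
  get_D <- function(cm) {
    if (inherits(cm, "decoding_result")) cm <- cm$confusion
    if (inherits(cm, "confusion_matrix")) cm <- cm$D
    as.matrix(cm)
  }
  summaries <- lapply(seq_along(real), function(ci) {
    members <- which(assignments == ci)
    out <- list(cluster = ci, members = members, size = length(members))
    if (!is.null(synergies)) {
      stack <- simplify2array(lapply(members, function(m) synergies[[m]]))
      out$mean_synergy <- apply(stack, seq_len(length(dim(stack)) - 1), mean)
      out$sd_synergy <- apply(stack, seq_len(length(dim(stack)) - 1), sd)
    }
    if (!is.null(confusions)) {
      Dm <- Reduce(`+`, lapply(members, function(m) get_D(confusions[[m]]))) /
        length(members)
      rs <- rowSums(Dm)
      out$mean_confusion <- Dm / ifelse(rs > 0, rs, 1)
    }
    out
  })
  structure(list(assignments = assignments, labels = labels,
                 n_clusters = length(real), cutoff = cutoff, tree = tree,
                 summaries = summaries),
            class = "cluster_set")
}

#' Cluster synergies across subjects by functional similarity
#'
#' One-call wrapper: similarity matrix, complete-linkage tree, cut and
#' summaries.
#'
#' @inheritParams functional_similarity_matrix
#' @inheritParams cut_and_summarize
#' @param cutoff cut height on the `1 - r` scale (0.5 for temporal
#'   synergies, 0.6 for spatial ones in the reference analysis).
#' @return a `cluster_set` (see [cut_and_summarize()]); the similarity
#'   matrix is attached as `$similarity`.
#' @export
cluster_synergies <- function(confusions, cutoff, registry = NULL,
                              synergies = NULL) {
  sim <- functional_similarity_matrix(confusions, registry)
  tree <- build_tree(sim)
  out <- cut_and_summarize(tree, cutoff, synergies = synergies,
                           confusions = confusions)
  out$similarity <- sim
  out
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Functional-similarity clustering (cutoff %.2f): %d cluster(s), %d unclustered\n",
              x$cutoff, x$n_clusters, sum(is.na(x$assignments))))
  for (s in x$summaries) {
    cat(sprintf("  C%d: %d members (%s)\n", s$cluster, s$size,
                paste(s$members, collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.functional_similarity <- function(x, ...) {
  cat(sprintf("Functional similarity of %d synergies (confusion vectors of length %d)\n",
              nrow(x$r), x$vector_length))
  invisible(x)
}
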