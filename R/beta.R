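#' Jaccard dissimilarity matrix
#'
#' Presence/absence Jaccard distance between all sample pairs:
#' \eqn{d(A,B) = 1 - |P_A \cap P_B| / |P_A \cup P_B|} with \eqn{P_X} the set
#' of OTUs with non-zero count in X. Pairs of two empty samples are defined
#' as distance 0 with a warning.
#'
#' @param t an [otu_table] (normally rarefied first).
#' @return symmetric distance matrix over samples.
#' @export
jaccard_matrix <- function(t) {
  pa <- t$counts > 0L
  inter <- tcrossprod(pa * 1)
  size <- rowSums(pa)
  union <- outer(size, size, `+`) - inter
  d <- 1 - inter / union
  if (any(union == 0)) {
    .warnf("empty sample pair(s); their Jaccard distance is defined as 0")
    d[union == 0] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(t$counts), rownames(t$counts))
  d
}

# per-edge descendant-leaf incidence for a rooted tree: edges x leaves
.edge_leaf_incidence <- function(tree) {
  n <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  inc <- matrix(FALSE, nrow(post$edge), n,
                dimnames = list(NULL, post$tip.label))
  below <- vector("list", n + post$Nnode)  # leaf indices under each node
  for (i in seq_len(nrow(post$edge))) {
    child <- post$edge[i, 2L]
    below[[child]] <- if (child <= n) child else below[[child]]
    inc[i, below[[child]]] <- TRUE
    par <- post$edge[i, 1L]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  list(inc = inc, lengths = post$edge.length)
}

.check_unifrac_inputs <- function(t, otu_tree) {
  if (is.null(otu_tree$edge.length))
    .stopf("OTU tree must have branch lengths")
  missing <- setdiff(colnames(t$counts), otu_tree$tip.label)
  if (length(missing))
    .stopf("OTUs missing from the tree: %s", paste(missing, collapse = ", "))
  extra <- setdiff(otu_tree$tip.label, colnames(t$counts))
  if (length(extra))
    otu_tree <- ape::drop.tip(otu_tree, extra)
  otu_tree
}

#' Unweighted UniFrac distance matrix
#'
#' Fraction of tree branch length unique to one of the two communities:
#' \eqn{d(A,B) = \sum_b l_b [A_b \neq B_b] / \sum_b l_b [A_b \lor B_b]},
#' where \eqn{A_b} indicates that branch b has at least one descendant leaf
#' present in sample A. The tree is used as rooted in the input; branches
#' with no present descendant in either sample contribute nothing.
#'
#' @param t an [otu_table]; every OTU must be a leaf of `otu_tree` (extra
#'   leaves are pruned).
#' @param otu_tree rooted `phylo` with branch lengths.
#' @return symmetric distance matrix over samples, entries in \[0, 1\].
#' @export
unweighted_unifrac <- function(t, otu_tree) {
  otu_tree <- .check_unifrac_inputs(t, otu_tree)
  el <- .edge_leaf_incidence(otu_tree)
  pa <- t(t$counts > 0L)[colnames(el$inc), , drop = FALSE]  # leaves x samples
  on_edge <- (el$inc %*% pa) > 0  # edges x samples
  ns <- ncol(pa)
  d <- matrix(0, ns, ns, dimnames = list(colnames(pa), colnames(pa)))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    a <- on_edge[, i]; b <- on_edge[, j]
    union <- sum(el$lengths[a | b])
    if (union == 0)
      .stopf("samples %s and %s span zero branch length", colnames(pa)[i],
             colnames(pa)[j])
    d[i, j] <- d[j, i] <- sum(el$lengths[xor(a, b)]) / union
  }
  d
}

#' Weighted UniFrac distance matrix
#'
#' Abundance-weighted branch-length difference:
#' \eqn{d(A,B) = \sum_b l_b |p_A(b) - p_B(b)|} with \eqn{p_X(b)} the
#' fraction of sample X's reads on leaves descending from branch b. The raw
#' (unnormalized) form is the default; with `normalized = TRUE` the raw
#' value is divided by \eqn{\sum_i r_i (p_A(i) + p_B(i))} over leaves i,
#' where \eqn{r_i} is the leaf's root-to-tip distance — the standard
#' normalization bounding the distance by 1.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized logical; default FALSE (raw).
#' @return symmetric distance matrix over samples.
#' @export
weighted_unifrac <- function(t, otu_tree, normalized = FALSE) {
  otu_tree <- .check_unifrac_inputs(t, otu_tree)
  el <- .edge_leaf_incidence(otu_tree)
  totals <- rowSums(t$counts)
  if (any(totals == 0L))
    .stopf("weighted UniFrac undefined for empty samples: %s",
           paste(rownames(t$counts)[totals == 0L], collapse = ", "))
  rel <- t(t$counts / totals)[colnames(el$inc), , drop = FALSE]
  p_edge <- el$inc %*% rel  # edges x samples
  ns <- ncol(rel)
  d <- matrix(0, ns, ns, dimnames = list(colnames(rel), colnames(rel)))
  root_dist <- colSums(el$inc * el$lengths)  # root-to-leaf distances
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    raw <- sum(el$lengths * abs(p_edge[, i] - p_edge[, j]))
    if (normalized) {
      denom <- sum(root_dist * (rel[, i] + rel[, j]))
      raw <- raw / denom
    }
    d[i, j] <- d[j, i] <- raw
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers \eqn{-d^2/2} and eigendecomposes it. Coordinates are
#' returned for positive eigenvalues only; all eigenvalues (including
#' negative ones) are reported. Axis signs are canonicalized so the first
#' non-zero loading of each axis is positive. No negative-eigenvalue
#' correction is applied unless `correction = "cailliez"`.
#'
#' @param dm symmetric labeled distance matrix.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (descending), `proportion_explained`
#'   (fractions of the positive inertia).
#' @export
pcoa <- function(dm, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  dm <- validate_distance_matrix(dm)
  n <- nrow(dm)
  # k = n-1 axes are requested on purpose; cmdscale warns when some have
  # non-positive eigenvalues, which is routine for non-Euclidean input and
  # reported through `eigenvalues`
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = n - 1L, eig = TRUE,
                    add = correction == "cailliez"))
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-12 & eig > 0)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  for (a in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, a]) > 1e-12)
    if (length(nz) && coords[nz[1L], a] < 0) coords[, a] <- -coords[, a]
  }
  if (ncol(coords) > 0L)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pos_total <- sum(pmax(eig, 0))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = if (pos_total > 0)
                   pmax(eig, 0) / pos_total else rep(0, length(eig))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3L, ncol(x$coordinates))
  cat(sprintf("PCoA: %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat(sprintf("  first %d axes explain %.1f%% of positive inertia\n", k,
              100 * sum(x$proportion_explained[seq_len(k)])))
  invisible(x)
}
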