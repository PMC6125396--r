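#' UPGMA dendrogram from a distance matrix
#'
#' Agglomerative clustering with size-weighted average linkage (the
#' unweighted pair group method with arithmetic mean). The node joining two
#' clusters is placed at half their merge distance, so the dendrogram is
#' ultrametric and, on ultrametric input, reproduces the input distances as
#' cophenetic distances exactly. Ties between equal merge distances are
#' broken deterministically by picking the lexicographically smallest pair
#' of cluster labels (a cluster is labeled by its smallest leaf label).
#'
#' @param dm symmetric labeled distance matrix with at least two labels.
#' @return rooted ultrametric `phylo` tree.
#' @export
upgma <- function(dm) {
  dm <- validate_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 2L) .stopf("need at least two labels")
  labels <- rownames(dm)
  # active clusters: newick fragment, height, size, smallest leaf label
  frag <- as.list(labels)
  height <- rep(0, n)
  size <- rep(1L, n)
  key <- labels
  d <- dm
  active <- seq_len(n)
  while (length(active) > 1L) {
    sub <- d[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    mins <- which(sub == min(sub), arr.ind = TRUE)
    # deterministic tie-break on the (sorted) label pair
    pair_keys <- apply(mins, 1L, function(ij) {
      ks <- sort(c(key[active[ij[1L]]], key[active[ij[2L]]]))
      paste(ks, collapse = "\r")
    })
    pick <- mins[order(pair_keys)[1L], ]
    i <- active[pick[1L]]; j <- active[pick[2L]]
    h <- d[i, j] / 2
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)",
                        frag[[i]], h - height[i], frag[[j]], h - height[j])
    # size-weighted average linkage update
    others <- setdiff(active, c(i, j))
    new_d <- (size[i] * d[i, others] + size[j] * d[j, others]) /
      (size[i] + size[j])
    frag[[i]] <- new_frag
    height[i] <- h
    size[i] <- size[i] + size[j]
    key[i] <- min(key[i], key[j])
    d[i, others] <- new_d
    d[others, i] <- new_d
    active <- setdiff(active, j)
  }
  ape::read.tree(text = paste0(frag[[active]], ";"))
}
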