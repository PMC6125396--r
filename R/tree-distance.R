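#' Non-trivial clusters of a rooted tree
#'
#' The clusters (clades) of a rooted leaf-labeled tree are the leaf sets
#' below its internal nodes. The non-trivial proper clusters — everything
#' except the root's full leaf set and singletons — are what the rooted
#' Robinson-Foulds and Matching Cluster distances compare.
#'
#' @param tree rooted `phylo`.
#' @return list of character vectors (sorted leaf labels), one per
#'   non-trivial proper cluster; empty for a 2-leaf tree.
#' @export
tree_clusters <- function(tree) {
  if (!inherits(tree, "phylo")) .stopf("`tree` must be a phylo object")
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- lapply(parts, function(idx) sort(labs[idx]))
  n <- length(labs)
  keep <- vapply(out, function(s) length(s) > 1L && length(s) < n, logical(1))
  out[keep]
}

.check_same_leaves <- function(t1, t2) {
  l1 <- t1$tip.label
  l2 <- t2$tip.label
  if (!setequal(l1, l2))
    .stopf("leaf sets differ: only in tree 1: {%s}; only in tree 2: {%s}",
           paste(setdiff(l1, l2), collapse = ", "),
           paste(setdiff(l2, l1), collapse = ", "))
  sort(l1)
}

# clusters as integer bitmasks over `leaves` (requires length(leaves) <= 16)
.cluster_masks_phylo <- function(tree, leaves) {
  bits <- bitwShiftL(1L, seq_along(leaves) - 1L)
  names(bits) <- leaves
  vapply(tree_clusters(tree), function(s) {
    m <- 0L
    for (b in bits[s]) m <- bitwOr(m, b)
    m
  }, integer(1))
}

# raw rooted RF between two cluster-mask vectors
.rf_masks <- function(a, b) {
  length(a) + length(b) - 2L * sum(a %in% b)
}

# raw MC between two cluster-mask vectors (padded with empty clusters)
.mc_masks <- function(a, b) {
  k <- max(length(a), length(b))
  if (k == 0L) return(0L)
  a <- c(a, integer(k - length(a)))
  b <- c(b, integer(k - length(b)))
  # column-major k x k cost vector: cost[(j-1)k + i] = |C_i xor C_j|
  costv <- .popcount16()[bitwXor(rep(a, times = k), rep(b, each = k)) + 1L]
  if (k <= 6L) min(rowSums(matrix(costv[.perm_idx(k)], ncol = k)))
  else .hungarian(matrix(costv, k, k))
}

# cached linear-index vector mapping each permutation to cost entries
.perm_idx <- function(k) {
  key <- paste0("permidx", k)
  idx <- .pkg_cache[[key]]
  if (is.null(idx)) {
    p <- .perms(k)
    idx <- as.vector((p - 1L) * k + rep(seq_len(k), each = nrow(p)))
    .pkg_cache[[key]] <- idx
  }
  idx
}

# ---- minimum-cost perfect matching -----------------------------------------

# all permutations of 1..k (cached); used for the small-k fast path
.perms <- function(k) {
  key <- paste0("perms", k)
  p <- .pkg_cache[[key]]
  if (is.null(p)) {
    gen <- function(v) {
      if (length(v) <= 1L) return(matrix(v, 1L))
      do.call(rbind, lapply(seq_along(v), function(i)
        cbind(v[i], gen(v[-i]))))
    }
    p <- gen(seq_len(k))
    # column-major linear index matrix into a k x k cost matrix
    .pkg_cache[[key]] <- p
  }
  p
}

# minimum total cost over perfect matchings of a square cost matrix;
# exhaustive for k <= 6, Hungarian algorithm (O(k^3)) beyond
.min_assignment <- function(cost) {
  k <- nrow(cost)
  if (k <= 6L)
    return(min(rowSums(matrix(cost[.perm_idx(k)], ncol = k))))
  .hungarian(cost)
}

# Hungarian / shortest augmenting path assignment; returns the minimum cost
.hungarian <- function(cost) {
  k <- nrow(cost)
  u <- numeric(k + 1L)        # row potentials, index row+1 (row 0 dummy)
  v <- numeric(k + 1L)        # column potentials, index col+1 (col 0 dummy)
  p <- integer(k + 1L)        # p[j+1]: row matched to column j (0 = none)
  way <- integer(k + 1L)
  for (i in seq_len(k)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, k + 1L)
    used <- rep(FALSE, k + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])          # candidate columns (1-based)
      cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j + 1L]
      minv[free_j[upd] + 1L] <- cur[upd]
      way[free_j[upd] + 1L] <- j0
      j1 <- free_j[which.min(minv[free_j + 1L])]
      delta <- minv[j1 + 1L]
      u[p[used] + 1L] <- u[p[used] + 1L] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assigned <- p[-1L]
  sum(cost[cbind(assigned, seq_len(k))])
}

# ---- public distances ------------------------------------------------------

#' Rooted Robinson-Foulds distance
#'
#' Size of the symmetric difference between the non-trivial cluster sets of
#' two rooted trees on the same leaves. The normalized value divides by
#' `2 * (n - 2)`, the maximum symmetric difference between rooted
#' bifurcating trees on n leaves, and is clamped to \[0, 1\] (trees with
#' multifurcations are accepted; their cluster sets are simply smaller).
#'
#' @param t1,t2 rooted `phylo` trees with identical leaf sets.
#' @return list with integer `raw` and numeric `normalized`.
#' @export
rf_distance <- function(t1, t2) {
  .check_same_leaves(t1, t2)
  c1 <- vapply(tree_clusters(t1), paste, "", collapse = "\r")
  c2 <- vapply(tree_clusters(t2), paste, "", collapse = "\r")
  raw <- length(c1) + length(c2) - 2L * length(intersect(c1, c2))
  n <- length(t1$tip.label)
  denom <- 2L * (n - 2L)
  list(raw = as.integer(raw),
       normalized = if (denom > 0L) min(1, raw / denom) else 0)
}

#' Matching Cluster distance between rooted trees
#'
#' Minimum-weight perfect matching between the two trees' non-trivial
#' cluster sets (padded with empty clusters when their sizes differ, e.g.
#' for multifurcating trees), where the weight of pairing clusters C1, C2
#' is the Hamming distance of their leaf-membership indicators,
#' \eqn{|C_1 \Delta C_2|}. Solved by an optimal assignment algorithm
#' (exhaustive matching enumeration for up to 6 clusters, Hungarian
#' algorithm beyond).
#'
#' The normalized value divides by the metric's maximum over tree pairs
#' with the same number of leaves: the exact enumerated maximum for
#' n <= 7 (cached per session), and the analytic upper bound `n * (n - 2)`
#' for larger trees; `normalizer_kind` records which was used.
#'
#' @param t1,t2 rooted `phylo` trees with identical leaf sets.
#' @return list with integer `raw`, numeric `normalized`, the `normalizer`
#'   used, and `normalizer_kind` (`"exact"` or `"upper_bound"`).
#' @export
mc_distance <- function(t1, t2) {
  leaves <- .check_same_leaves(t1, t2)
  n <- length(leaves)
  raw <- if (n <= 16L) {
    .mc_masks(.cluster_masks_phylo(t1, leaves),
              .cluster_masks_phylo(t2, leaves))
  } else {
    m1 <- .cluster_indicators(t1, leaves)
    m2 <- .cluster_indicators(t2, leaves)
    k <- max(nrow(m1), nrow(m2))
    if (k == 0L) 0L else {
      m1 <- rbind(m1, matrix(0L, k - nrow(m1), n))
      m2 <- rbind(m2, matrix(0L, k - nrow(m2), n))
      cost <- outer(rowSums(m1), rowSums(m2), `+`) - 2 * tcrossprod(m1, m2)
      .min_assignment(cost)
    }
  }
  norm <- .max_mc(n)
  list(raw = as.integer(raw),
       normalized = if (norm$value > 0) raw / norm$value else 0,
       normalizer = norm$value, normalizer_kind = norm$kind)
}

# clusters as a 0/1 indicator matrix (clusters x leaves), any n
.cluster_indicators <- function(tree, leaves) {
  cl <- tree_clusters(tree)
  m <- matrix(0L, length(cl), length(leaves),
              dimnames = list(NULL, leaves))
  for (i in seq_along(cl)) m[i, cl[[i]]] <- 1L
  m
}

# maximum MC distance over pairs of rooted bifurcating topologies on n
# leaves: exact enumeration (shape representatives x all labeled trees) for
# n <= 7, analytic upper bound n*(n-2) beyond
.max_mc <- function(n) {
  if (n <= 2L) return(list(value = 0L, kind = "exact"))
  if (n > 7L) return(list(value = n * (n - 2L), kind = "upper_bound"))
  key <- paste0("maxmc", n)
  val <- .pkg_cache[[key]]
  if (is.null(val)) {
    enum <- .enum_masks(n)
    reps <- which(!duplicated(enum$shapes))
    val <- 0L
    for (r in reps) {
      a <- enum$masks[r, ]
      for (i in seq_len(nrow(enum$masks))) {
        d <- .mc_masks(a, enum$masks[i, ])
        if (d > val) val <- d
      }
    }
    .pkg_cache[[key]] <- val
  }
  list(value = val, kind = "exact")
}
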