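# Labeled rooted bifurcating topologies: uniform sampling and exhaustive
# enumeration, via sequential leaf insertion. A tree on k leaves offers
# 2k - 1 insertion points for leaf k+1 (above any node, or above the root),
# so every labeled topology on n leaves arises from exactly one choice
# sequence and the total count is (2n-3)!!.
#
# Internal representation: parent arrays. Leaves are nodes 1..n, internal
# nodes get ids n+1, n+2, ... in creation order; `root` tracks the current
# root. Only valid for bifurcating trees built here.

.rand_ptree <- function(n) {
  nn <- 2L * n - 1L
  par <- rep(NA_integer_, nn)
  root <- n + 1L
  par[1L] <- root
  par[2L] <- root
  if (n >= 3L) {
    nxt <- n + 2L
    nodes <- c(1L, 2L, root)
    for (k in 3:n) {
      v <- nodes[sample.int(length(nodes), 1L)]
      u <- nxt
      nxt <- nxt + 1L
      if (v == root) {
        par[root] <- u
        root <- u
      } else {
        par[u] <- par[v]
        par[v] <- u
      }
      par[k] <- u
      nodes <- c(nodes, k, u)
    }
  }
  list(par = par, root = root)
}

# cluster bitmasks of the non-root internal nodes (n <= 16)
.ptree_masks <- function(par, root, n) {
  m <- integer(length(par))
  for (i in seq_len(n)) {
    b <- bitwShiftL(1L, i - 1L)
    v <- par[i]
    while (!is.na(v)) {
      m[v] <- bitwOr(m[v], b)
      v <- par[v]
    }
  }
  internals <- setdiff(seq.int(n + 1L, length(par)), root)
  m[internals]
}

# canonical (label-free) shape key, for deduplicating topologies by shape
.ptree_shape <- function(par, root, n) {
  kids <- vector("list", length(par))
  for (v in seq_along(par)) if (!is.na(par[v]))
    kids[[par[v]]] <- c(kids[[par[v]]], v)
  canon <- function(v) {
    if (v <= n) return("L")
    paste0("(", paste(sort(vapply(kids[[v]], canon, "")), collapse = ","), ")")
  }
  canon(root)
}

# parent array -> phylo (ape numbering: tips 1..n, root n+1, preorder edges)
.ptree_to_phylo <- function(par, root, n, labels) {
  kids <- vector("list", length(par))
  for (v in seq_along(par)) if (!is.na(par[v]))
    kids[[par[v]]] <- c(kids[[par[v]]], v)
  newid <- integer(length(par))
  newid[seq_len(n)] <- seq_len(n)
  edge <- matrix(0L, 2L * n - 2L, 2L)
  nid <- n
  erow <- 0L
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v > n) {
      nid <- nid + 1L
      newid[v] <- nid
    }
    if (!is.na(par[v])) {
      erow <- erow + 1L
      edge[erow, ] <- c(newid[par[v]], newid[v])
    }
    if (v > n) stack <- c(stack, rev(kids[[v]]))
  }
  structure(list(edge = edge, tip.label = labels, Nnode = n - 1L),
            class = "phylo")
}

# exhaustive enumeration of parent trees on n leaves
.enum_ptrees <- function(n) {
  if (n == 2L) {
    base <- .rand_ptree(2L)
    return(list(base))
  }
  res <- vector("list", .double_factorial(2L * n - 3L))
  cnt <- 0L
  recurse <- function(par, root, nxt, nodes, k) {
    if (k > n) {
      cnt <<- cnt + 1L
      res[[cnt]] <<- list(par = par, root = root)
      return()
    }
    for (v in nodes) {
      p2 <- par
      r2 <- root
      u <- nxt
      if (v == r2) {
        p2[r2] <- u
        r2 <- u
      } else {
        p2[u] <- p2[v]
        p2[v] <- u
      }
      p2[k] <- u
      recurse(p2, r2, nxt + 1L, c(nodes, k, u), k + 1L)
    }
  }
  nn <- 2L * n - 1L
  par <- rep(NA_integer_, nn)
  par[1L] <- n + 1L
  par[2L] <- n + 1L
  recurse(par, n + 1L, n + 2L, c(1L, 2L, n + 1L), 3L)
  res
}

# cached enumeration as a mask matrix (+ shape keys), n <= 16
.enum_masks <- function(n) {
  key <- paste0("enum", n)
  e <- .pkg_cache[[key]]
  if (is.null(e)) {
    trees <- .enum_ptrees(n)
    masks <- if (n == 2L) matrix(integer(0), 1L, 0L) else
      t(vapply(trees, function(tr)
        .ptree_masks(tr$par, tr$root, n), integer(n - 2L)))
    if (n == 3L) masks <- matrix(masks, length(trees))
    shapes <- vapply(trees, function(tr)
      .ptree_shape(tr$par, tr$root, n), "")
    e <- list(masks = masks, shapes = shapes)
    .pkg_cache[[key]] <- e
  }
  e
}

.double_factorial <- function(k) {
  if (k <= 0L) return(1L)
  prod(seq(k, 1L, by = -2L))
}

#' Number of labeled rooted bifurcating topologies
#'
#' `(2n - 3)!!` topologies exist on n labeled leaves.
#' @param n_leaves number of leaves (>= 2).
#' @return the count, as a double (exact up to n ~ 15).
#' @export
count_topologies <- function(n_leaves) {
  .assert_scalar_int(n_leaves, "n_leaves", lower = 2)
  .double_factorial(2L * n_leaves - 3L)
}

#' Draw a uniform random rooted bifurcating topology
#'
#' Uniform over all `(2n - 3)!!` labeled rooted bifurcating topologies, by
#' sequential random leaf insertion (each new leaf attaches above a
#' uniformly chosen existing node or above the root). Branch lengths are
#' not set.
#'
#' @param leaves character vector of leaf labels (>= 2).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers can draw many topologies under one seed).
#' @return rooted `phylo` without branch lengths.
#' @export
random_topology <- function(leaves, seed = NULL) {
  n <- length(leaves)
  if (n < 2L) .stopf("need at least two leaves")
  if (anyDuplicated(leaves)) .stopf("leaf labels must be unique")
  tr <- local_seed_eval(seed, .rand_ptree(n))
  .ptree_to_phylo(tr$par, tr$root, n, leaves)
}

#' Enumerate all labeled rooted bifurcating topologies
#'
#' Yields each of the `(2n - 3)!!` topologies exactly once. Guarded to
#' n <= 9 leaves (135,135 topologies); beyond that the combinatorial
#' explosion makes enumeration impractical and Monte-Carlo sampling with
#' [random_topology] should be used instead.
#'
#' @param leaves character vector of 2 to 9 leaf labels.
#' @return list of rooted `phylo` trees without branch lengths.
#' @export
enumerate_topologies <- function(leaves) {
  n <- length(leaves)
  if (n < 2L) .stopf("need at least two leaves")
  if (n > 9L)
    .stopf(paste("enumeration is limited to 9 leaves ((2n-3)!! blows up);",
                 "use random_topology() for Monte-Carlo sampling"))
  lapply(.enum_ptrees(n), function(tr)
    .ptree_to_phylo(tr$par, tr$root, n, leaves))
}
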