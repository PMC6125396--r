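#' Host-tree vs dendrogram congruence test with a randomized-topology null
#'
#' Measures the topological distance (rooted Robinson-Foulds or Matching
#' Cluster) between a host phylogeny and a microbiota dendrogram on the same
#' leaves, and asks how often a random rooted bifurcating topology would be
#' at least as congruent: the p-value is the probability, under the uniform
#' topology null, of a distance less than or equal to the observed one (ties
#' count toward the tail, i.e. "equivalent or more congruent").
#'
#' In `monte_carlo` mode the null is sampled (`n_random` uniform draws,
#' default 80,000); in `exact` mode it is the full enumeration of all
#' `(2n-3)!!` topologies (n <= 9); `auto` picks exact when the enumeration
#' is small enough (n <= 8) and Monte-Carlo otherwise. The Monte-Carlo
#' p-value is the plain tail proportion k/N by default; set `add_one` for
#' the conservative (k+1)/(N+1) variant.
#'
#' @param host rooted `phylo` host phylogeny.
#' @param dendrogram rooted `phylo` microbiota dendrogram (same leaf set).
#' @param metric `"rf"` or `"mc"`.
#' @param n_random Monte-Carlo sample size.
#' @param mode `"auto"`, `"monte_carlo"` or `"exact"`.
#' @param seed integer seed for Monte-Carlo sampling.
#' @param add_one use the (k+1)/(N+1) p-value convention (Monte-Carlo only).
#' @return object of class `congruence_result`: list with `metric`,
#'   `observed` (raw), `normalized`, `null_size`, `null_mean`, `null_sd`,
#'   `normalized_by_null_mean` (observed divided by the null mean — the
#'   random-expectation normalization alternative), `p_value`, `mode`,
#'   `seed`, and for MC the `normalizer` used.
#' @export
congruence_test <- function(host, dendrogram, metric = c("rf", "mc"),
                            n_random = 80000L,
                            mode = c("auto", "monte_carlo", "exact"),
                            seed = NULL, add_one = FALSE) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  leaves <- .check_same_leaves(host, dendrogram)
  n <- length(leaves)
  if (mode == "auto") mode <- if (n <= 8L) "exact" else "monte_carlo"
  if (mode == "exact" && n > 9L)
    .stopf("exact mode is limited to 9 leaves; use monte_carlo")
  obs <- if (metric == "rf") rf_distance(host, dendrogram)
         else mc_distance(host, dendrogram)

  null_d <- .null_distances(host, leaves, metric, mode, n_random, seed)
  k <- sum(null_d <= obs$raw)
  p <- if (mode == "monte_carlo" && add_one) (k + 1) / (length(null_d) + 1)
       else k / length(null_d)
  structure(list(metric = toupper(metric),
                 observed = obs$raw,
                 normalized = obs$normalized,
                 normalizer = obs$normalizer %||% 2L * (n - 2L),
                 null_size = length(null_d),
                 null_mean = mean(null_d),
                 null_sd = stats::sd(null_d),
                 normalized_by_null_mean = obs$raw / mean(null_d),
                 p_value = p,
                 mode = mode,
                 n_leaves = n,
                 seed = seed,
                 add_one = add_one),
            class = "congruence_result")
}

# null distribution of distances from `host` to uniform random / enumerated
# topologies, as an integer vector
.null_distances <- function(host, leaves, metric, mode, n_random, seed) {
  n <- length(leaves)
  if (n <= 16L) {
    h <- .cluster_masks_phylo(host, leaves)
    if (mode == "exact") {
      m <- .enum_masks(n)$masks
      if (metric == "rf") {
        shared <- rep(0L, nrow(m))
        for (x in h) shared <- shared + as.integer(rowSums(m == x) > 0L)
        return(ncol(m) + length(h) - 2L * shared)
      }
      return(vapply(seq_len(nrow(m)), function(i)
        as.integer(.mc_masks(h, m[i, ])), integer(1)))
    }
    return(local_seed_eval(seed, {
      vapply(seq_len(n_random), function(i) {
        tr <- .rand_ptree(n)
        cl <- .ptree_masks(tr$par, tr$root, n)
        if (metric == "rf") .rf_masks(h, cl)
        else as.integer(.mc_masks(h, cl))
      }, integer(1))
    }))
  }
  # large-n fallback: generic phylo path
  dist_fun <- if (metric == "rf") function(a, b) rf_distance(a, b)$raw
              else function(a, b) mc_distance(a, b)$raw
  if (mode == "exact") {
    vapply(enumerate_topologies(leaves), function(tr)
      as.integer(dist_fun(host, tr)), integer(1))
  } else {
    local_seed_eval(seed, vapply(seq_len(n_random), function(i)
      as.integer(dist_fun(host, random_topology(leaves))), integer(1)))
  }
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf("Congruence test (%s, %s null)\n", x$metric, x$mode))
  cat(sprintf("  observed distance: %d (normalized %.4f)\n",
              x$observed, x$normalized))
  cat(sprintf("  null: %d topologies, mean %.2f, sd %.2f\n",
              x$null_size, x$null_mean, x$null_sd))
  conv <- if (x$mode == "monte_carlo" && isTRUE(x$add_one))
    "(k+1)/(N+1)" else "k/N"
  cat(sprintf("  p-value [%s]: %.4g\n", conv, x$p_value))
  invisible(x)
}

#' Serialize a congruence result to key: value text
#' @param x a `congruence_result`.
#' @param path optional output path; when NULL the lines are returned.
#' @return character vector of lines, invisibly when written to `path`.
#' @export
format_congruence_result <- function(x, path = NULL) {
  fields <- c("metric", "observed", "normalized", "normalizer", "null_size",
              "null_mean", "null_sd", "normalized_by_null_mean", "p_value",
              "mode", "n_leaves")
  lines <- vapply(fields, function(f)
    sprintf("%s: %s", f, format(x[[f]], digits = 10)), "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
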