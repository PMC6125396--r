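#' Mantel test between two distance matrices
#'
#' Pearson correlation between the upper triangles of two labeled distance
#' matrices over the same objects; significance from simultaneous
#' row/column permutation of the second matrix, one-sided for positive
#' association. The permutation p-value is the plain tail proportion k/N by
#' default (`add_one` switches to (k+1)/(N+1)). A Spearman variant is
#' available via `method`.
#'
#' @param dm1,dm2 symmetric labeled distance matrices with identical label
#'   sets (order may differ; `dm2` is aligned to `dm1`).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param add_one use the (k+1)/(N+1) convention.
#' @return object of class `perm_test`: list with `statistic` (r),
#'   `p_value`, `n_permutations`, `seed`, `tail`, `method`, `convention`.
#' @export
mantel_test <- function(dm1, dm2, n_perm = 9999L, seed = NULL,
                        method = c("pearson", "spearman"), add_one = FALSE) {
  method <- match.arg(method)
  dm1 <- validate_distance_matrix(dm1)
  dm2 <- validate_distance_matrix(dm2)
  if (!setequal(rownames(dm1), rownames(dm2)))
    .stopf("matrix labels differ: %s",
           paste(union(setdiff(rownames(dm1), rownames(dm2)),
                       setdiff(rownames(dm2), rownames(dm1))), collapse = ", "))
  dm2 <- dm2[rownames(dm1), rownames(dm1)]
  ut <- upper.tri(dm1)
  x <- dm1[ut]
  if (stats::sd(x) == 0 || stats::sd(dm2[ut]) == 0)
    .stopf("a distance matrix has zero variance; Mantel r is undefined")
  if (method == "spearman") x <- rank(x)
  stat_for <- function(m2) {
    y <- m2[ut]
    if (method == "spearman") y <- rank(y)
    stats::cor(x, y)
  }
  observed <- stat_for(dm2)
  n <- nrow(dm1)
  perm_stats <- local_seed_eval(seed, vapply(seq_len(n_perm), function(i) {
    pm <- sample.int(n)
    stat_for(dm2[pm, pm])
  }, numeric(1)))
  k <- sum(perm_stats >= observed)
  p <- if (add_one) (k + 1) / (n_perm + 1) else k / n_perm
  .perm_test(statistic = observed, p_value = p, n_permutations = n_perm,
             seed = seed, tail = "one_sided_greater",
             method = paste("Mantel", method),
             convention = if (add_one) "(k+1)/(N+1)" else "k/N",
             null_stats = perm_stats)
}

#' Analysis of similarity (ANOSIM)
#'
#' Clarke's rank-based test of group separation on a distance matrix:
#' \eqn{R = (\bar r_B - \bar r_W) / (M/2)} where \eqn{\bar r_B} and
#' \eqn{\bar r_W} are the mean ranks (average ranks for ties) of
#' between-group and within-group distances and \eqn{M = n(n-1)/2} is the
#' number of pairs. Significance by permuting group labels, one-sided for
#' R >= observed.
#'
#' @param dm symmetric labeled distance matrix.
#' @param groups named character/factor vector mapping each label of `dm`
#'   to its group; at least 2 groups, each with at least 2 members.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param add_one use the (k+1)/(N+1) convention.
#' @return a `perm_test` object (statistic is R).
#' @export
anosim_test <- function(dm, groups, n_perm = 999L, seed = NULL,
                        add_one = FALSE) {
  dm <- validate_distance_matrix(dm)
  if (is.null(names(groups))) {
    if (length(groups) != nrow(dm))
      .stopf("`groups` must be named by the matrix labels")
    names(groups) <- rownames(dm)
  }
  missing <- setdiff(rownames(dm), names(groups))
  if (length(missing))
    .stopf("no group for: %s", paste(missing, collapse = ", "))
  g <- as.character(groups[rownames(dm)])
  sizes <- table(g)
  if (length(sizes) < 2L) .stopf("need at least two groups")
  if (any(sizes < 2L))
    .stopf("group(s) of size 1: %s",
           paste(names(sizes)[sizes < 2L], collapse = ", "))
  ut <- upper.tri(dm)
  r <- rank(dm[ut])  # average ranks for ties
  n <- nrow(dm)
  M <- n * (n - 1) / 2
  stat_for <- function(gg) {
    within <- outer(gg, gg, `==`)[ut]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  observed <- stat_for(g)
  perm_stats <- local_seed_eval(seed, vapply(seq_len(n_perm), function(i)
    stat_for(g[sample.int(n)]), numeric(1)))
  k <- sum(perm_stats >= observed)
  p <- if (add_one) (k + 1) / (n_perm + 1) else k / n_perm
  .perm_test(statistic = observed, p_value = p, n_permutations = n_perm,
             seed = seed, tail = "one_sided_greater", method = "ANOSIM",
             convention = if (add_one) "(k+1)/(N+1)" else "k/N",
             null_stats = perm_stats)
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects F test with (k-1, N-k) degrees of freedom and a
#' parametric p-value from the F distribution.
#'
#' @param samples_by_group named list of numeric vectors (>= 2 groups, each
#'   with >= 2 values).
#' @return list with `statistic` (F), `df`, `p_value`, `method`.
#' @export
one_way_anova <- function(samples_by_group) {
  if (length(samples_by_group) < 2L) .stopf("need at least two groups")
  if (any(lengths(samples_by_group) < 2L))
    .stopf("every group needs at least two values")
  ssw <- sum(vapply(samples_by_group,
                    function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0)
    .stopf("F is undefined (zero within-group variance everywhere)")
  values <- unlist(samples_by_group, use.names = FALSE)
  g <- factor(rep(names(samples_by_group), lengths(samples_by_group)))
  fit <- stats::anova(stats::lm(values ~ g))
  f <- fit[["F value"]][1L]
  list(statistic = f, df = c(fit$Df[1L], fit$Df[2L]),
       p_value = fit[["Pr(>F)"]][1L], method = "one-way ANOVA")
}

.perm_test <- function(...) {
  structure(list(...), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s permutation test\n", x$method))
  cat(sprintf("  statistic: %.4f\n", x$statistic))
  cat(sprintf("  p-value [%s, %s, %d permutations]: %.4g\n",
              x$convention, x$tail, x$n_permutations, x$p_value))
  invisible(x)
}
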