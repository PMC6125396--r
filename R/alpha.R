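#' Alpha-diversity indices per sample
#'
#' Computes, for each sample: observed OTUs \eqn{S_{obs}}, bias-corrected
#' Chao1 \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))} (with \eqn{F_1, F_2} the
#' singleton and doubleton OTU counts), Shannon entropy in bits
#' \eqn{H = -\sum p_i \log_2 p_i}, Simpson diversity \eqn{1 - \sum p_i^2},
#' equitability \eqn{H / \log_2 S_{obs}}, and Good's coverage
#' \eqn{1 - F_1 / N}. Logarithm base 2 follows the legacy-QIIME convention;
#' with it, Shannon values for communities of 1,200-1,900 OTUs land in the
#' 7.5-9.5 range typical of ruminant fecal microbiota.
#'
#' Empty samples yield `NA` for every index rather than zero.
#'
#' @param t an [otu_table] with integer counts (Chao1 and coverage rely on
#'   singleton counts, so the table should not be rescaled).
#' @return data.frame with one row per sample and columns `sample_id`,
#'   `observed_otus`, `chao1`, `shannon`, `simpson`, `equitability`,
#'   `goods_coverage`.
#' @export
alpha_diversity <- function(t) {
  res <- lapply(seq_len(nrow(t$counts)), function(i) {
    n <- t$counts[i, ]
    N <- sum(n)
    if (N == 0L)
      return(data.frame(observed_otus = NA_integer_, chao1 = NA_real_,
                        shannon = NA_real_, simpson = NA_real_,
                        equitability = NA_real_, goods_coverage = NA_real_))
    present <- n[n > 0L]
    s_obs <- length(present)
    f1 <- sum(present == 1L)
    f2 <- sum(present == 2L)
    p <- present / N
    h <- -sum(p * log2(p))
    data.frame(
      observed_otus = s_obs,
      chao1 = s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)),
      shannon = h,
      simpson = 1 - sum(p^2),
      equitability = if (s_obs > 1L) h / log2(s_obs) else NA_real_,
      goods_coverage = 1 - f1 / N)
  })
  cbind(data.frame(sample_id = rownames(t$counts),
                   stringsAsFactors = FALSE),
        do.call(rbind, res))
}

#' Rarefaction curve of Good's coverage
#'
#' For each sample and each depth, subsamples without replacement `reps`
#' times and reports the mean Good's coverage of the subsamples. Used to
#' check that sequencing depth saturates the community.
#'
#' @param t an [otu_table].
#' @param depths strictly increasing positive integers, each no larger than
#'   every sample's total.
#' @param reps number of independent rarefactions per depth (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `depth`, `goods_coverage`.
#' @export
rarefaction_curve <- function(t, depths, reps = 10L, seed = 1L) {
  if (length(depths) == 0L || any(depths <= 0) || any(diff(depths) <= 0))
    .stopf("`depths` must be strictly increasing positive integers")
  .assert_scalar_int(reps, "reps", lower = 1)
  totals <- rowSums(t$counts)
  if (any(max(depths) > totals))
    .stopf("depth %d exceeds the total of sample(s): %s", max(depths),
           paste(rownames(t$counts)[totals < max(depths)], collapse = ", "))
  local_seed_eval(seed, {
    grid <- expand.grid(sample_id = rownames(t$counts), depth = depths,
                        stringsAsFactors = FALSE)
    grid$goods_coverage <- mapply(function(sid, d) {
      row <- t$counts[sid, ]
      pool <- rep.int(seq_along(row), row)
      mean(vapply(seq_len(reps), function(r) {
        sub <- tabulate(pool[sample.int(length(pool), d)], length(row))
        1 - sum(sub == 1L) / d
      }, numeric(1)))
    }, grid$sample_id, grid$depth)
    grid
  })
}
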