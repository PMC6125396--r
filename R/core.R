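#' Core (shared) OTUs per group of replicate samples
#'
#' The core microbiota of a group is the set of OTUs present (count >= 1) in
#' every sample of the group. Two summary fractions are reported:
#' `shared_otu_pct`, the core as a percentage of the group's total distinct
#' OTUs, and `shared_seq_pct_*`, the percentage of each sample's reads
#' falling in core OTUs, summarized as mean and SD across the group's
#' samples.
#'
#' @param t an [otu_table].
#' @param group_by metadata column defining groups (default `host_species`).
#' @return data.frame with one row per group: `group`, `n_samples`,
#'   `n_core_otus`, `n_total_otus`, `shared_otu_pct`, `shared_seq_pct_mean`,
#'   `shared_seq_pct_sd`, plus a list column `core_otu_ids`.
#' @export
core_otus <- function(t, group_by = "host_species") {
  if (!group_by %in% names(t$metadata))
    .stopf("metadata has no column '%s'", group_by)
  groups <- split(rownames(t$counts), t$metadata[[group_by]])
  rows <- lapply(names(groups), function(g) {
    sids <- groups[[g]]
    sub <- t$counts[sids, , drop = FALSE]
    if (length(sids) == 1L)
      .warnf("group '%s' has a single sample; its core is its OTU set", g)
    present <- sub > 0L
    core <- colnames(sub)[colSums(present) == length(sids)]
    total <- colnames(sub)[colSums(present) > 0L]
    seq_pct <- 100 * rowSums(sub[, core, drop = FALSE]) / rowSums(sub)
    data.frame(group = g, n_samples = length(sids),
               n_core_otus = length(core), n_total_otus = length(total),
               shared_otu_pct = if (length(total)) 100 * length(core) /
                 length(total) else 0,
               shared_seq_pct_mean = mean(seq_pct),
               shared_seq_pct_sd = stats::sd(seq_pct),
               core_otu_ids = I(list(core)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exclusive intersection counts over a family of OTU sets
#'
#' For every non-empty subset of the groups, counts the elements present in
#' exactly those groups (the numbers behind an UpSet plot). The counts over
#' all signatures partition the union of the sets.
#'
#' @param groups named list of character vectors (e.g. per-species core OTU
#'   sets); at least two groups.
#' @return data.frame with one logical membership column per group, a
#'   `signature` string (`+`-joined member groups), and `count`. Rows are
#'   ordered by subset size then by signature.
#' @export
intersection_counts <- function(groups) {
  if (length(groups) < 2L) .stopf("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    .stopf("groups must be named")
  gn <- names(groups)
  universe <- unique(unlist(groups, use.names = FALSE))
  member <- vapply(groups, function(g) universe %in% g,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, gn))
  sig_of <- apply(member, 1L, function(r) paste(gn[r], collapse = "+"))
  combos <- unlist(lapply(seq_along(gn), function(k)
    utils::combn(gn, k, paste, collapse = "+")), use.names = FALSE)
  counts <- as.integer(table(factor(sig_of, levels = combos)))
  mem <- t(vapply(strsplit(combos, "+", fixed = TRUE),
                  function(s) gn %in% s, logical(length(gn))))
  colnames(mem) <- gn
  out <- data.frame(mem, signature = combos, count = counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out[order(rowSums(mem), out$signature), , drop = FALSE]
}

#' Spearman co-occurrence of selected genera within each host species
#'
#' Aggregates the table to genus-level relative abundances, then, per host
#' species (across that species' replicate samples), computes pairwise
#' Spearman rank correlations between the requested genera. Ties get average
#' ranks; two-sided p-values are exact for small n without ties (via
#' [stats::cor.test]) and t-approximate otherwise. Pairs involving a
#' constant abundance vector are reported as `NA`.
#'
#' @param t an [otu_table].
#' @param taxa character vector of genus names (matched against the genus
#'   rank of the taxonomy, including `unclassified_*` pools).
#' @param group_by metadata column defining groups (default `host_species`).
#' @return named list (one element per group) of lists with symmetric
#'   matrices `rho` and `p_value` over `taxa`.
#' @export
cooccurrence_spearman <- function(t, taxa, group_by = "host_species") {
  rel <- aggregate_by_rank(t, "genus")
  missing <- setdiff(taxa, colnames(rel))
  if (length(missing))
    .stopf("genera not found in taxonomy: %s", paste(missing, collapse = ", "))
  groups <- split(rownames(t$counts), t$metadata[[group_by]])
  lapply(groups, function(sids) {
    sub <- rel[sids, taxa, drop = FALSE]
    k <- length(taxa)
    rho <- matrix(NA_real_, k, k, dimnames = list(taxa, taxa))
    pv <- rho
    diag(rho) <- 1
    diag(pv) <- 0
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      x <- sub[, i]; y <- sub[, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = NULL))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
    list(rho = rho, p_value = pv)
  })
}
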