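#' Remove singleton OTUs
#'
#' Drops every OTU whose total count across all samples equals one. Counts
#' of the remaining OTUs are untouched.
#'
#' @param t an [otu_table].
#' @return a filtered [otu_table] (possibly with zero OTUs).
#' @export
filter_singletons <- function(t) {
  keep <- colSums(t$counts) != 1L
  .subset_table(t, otus = which(keep))
}

#' Rarefy an OTU table to a fixed depth
#'
#' Each sample is subsampled without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples with fewer than `depth`
#' reads are dropped with a warning rather than padded. The draw is
#' deterministic given `seed`.
#'
#' @param t an [otu_table].
#' @param depth target reads per sample (positive integer).
#' @param seed integer seed; required, no hidden global state.
#' @param prune_empty drop OTUs whose total count becomes zero (default TRUE)
#'   so presence/absence metrics downstream see the rarefied support.
#' @return rarefied [otu_table]; every remaining row sums to `depth`.
#' @export
rarefy <- function(t, depth, seed, prune_empty = TRUE) {
  .assert_scalar_int(depth, "depth", lower = 1)
  totals <- rowSums(t$counts)
  drop <- totals < depth
  if (any(drop)) {
    .warnf("dropping %d sample(s) below depth %d: %s", sum(drop), depth,
           paste(rownames(t$counts)[drop], collapse = ", "))
    t <- .subset_table(t, samples = which(!drop))
    totals <- totals[!drop]
  }
  if (nrow(t$counts) == 0L) .stopf("no sample reaches depth %d", depth)
  counts <- local_seed_eval(seed, {
    out <- t$counts
    for (i in seq_len(nrow(out))) {
      row <- out[i, ]
      if (sum(row) == depth) next
      pool <- rep.int(seq_along(row), row)
      drawn <- pool[sample.int(length(pool), depth)]
      out[i, ] <- tabulate(drawn, nbins = length(row))
    }
    out
  })
  res <- otu_table(counts, t$taxonomy, t$metadata)
  if (prune_empty) res <- .subset_table(res, otus = which(colSums(counts) > 0L))
  res
}

# rank names in lineage order
.tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")

# split "k__Bacteria; p__Firmicutes; ..." (or plain 7-field) lineages into a
# matrix of clean rank values; empty / "unclassified" / bare prefixes -> NA
.parse_taxonomy <- function(lineages) {
  parts <- strsplit(lineages, ";", fixed = TRUE)
  m <- matrix(NA_character_, length(lineages), 7L,
              dimnames = list(names(lineages), .tax_ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[a-z]__", "", p)
    p[p == "" | tolower(p) %in% c("unclassified", "unassigned", "na")] <-
      NA_character_
    n <- min(length(p), 7L)
    if (n > 0L) m[i, seq_len(n)] <- p[seq_len(n)]
  }
  m
}

# label OTUs at `rank`; unassigned pooled as "unclassified_<deepest parent>"
.rank_labels <- function(t, rank) {
  ri <- match(rank, .tax_ranks)
  if (is.na(ri)) .stopf("unknown taxonomic rank '%s'", rank)
  tm <- .parse_taxonomy(t$taxonomy)
  lab <- tm[, ri]
  una <- is.na(lab)
  if (any(una)) {
    parent <- apply(tm[una, seq_len(ri), drop = FALSE], 1L, function(r) {
      known <- which(!is.na(r))
      if (length(known)) r[max(known)] else "Root"
    })
    lab[una] <- paste0("unclassified_", parent)
  }
  stats::setNames(lab, colnames(t$counts))
}

#' Aggregate an OTU table to relative abundances at a taxonomic rank
#'
#' OTUs unassigned at `rank` are pooled into `unclassified_<parent>` columns
#' named after their deepest assigned ancestor. Output columns are ordered by
#' grand-mean relative abundance, descending; each row sums to one.
#'
#' @param t an [otu_table].
#' @param rank one of kingdom, phylum, class, order, family, genus.
#' @return numeric matrix, samples x taxa, of relative abundances.
#' @export
aggregate_by_rank <- function(t, rank) {
  if (!rank %in% .tax_ranks[1:6])
    .stopf("unknown taxonomic rank '%s' (use %s)", rank,
           paste(.tax_ranks[1:6], collapse = ", "))
  lab <- .rank_labels(t, rank)
  totals <- rowSums(t$counts)
  if (any(totals == 0L)) .stopf("cannot aggregate empty samples: %s",
    paste(rownames(t$counts)[totals == 0L], collapse = ", "))
  agg <- t(rowsum(t(t$counts), lab))
  rel <- agg / totals
  rel[, order(colMeans(rel), decreasing = TRUE), drop = FALSE]
}
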