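# Fixtures are built in code; oracles here are deliberately independent of
# the package's own implementation paths (explicit set arithmetic and
# factorial enumeration instead of bitmasks / assignment algorithms).

make_table <- function(counts, taxonomy = NULL, species = NULL) {
  if (is.null(species)) species <- rownames(counts)
  md <- data.frame(sample_id = rownames(counts), host_species = species,
                   stringsAsFactors = FALSE)
  otu_table(counts, taxonomy, md)
}

tiny_table <- function() {
  m <- matrix(c(5L, 1L, 0L, 2L,
                3L, 0L, 4L, 2L,
                0L, 2L, 6L, 2L), 3, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), paste0("o", 1:4)))
  tax <- stats::setNames(c(
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Ruminococcaceae;g__Ruminococcus;s__",
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__;g__;s__",
    "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides;s__",
    "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__S24-7;g__;s__"),
    paste0("o", 1:4))
  make_table(m, tax, species = c("spA", "spA", "spB"))
}

rand_table <- function(n_samples, n_otus, seed, max_count = 20L) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, 2), n_samples, n_otus,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("o", seq_len(n_otus))))
  storage.mode(m) <- "integer"
  make_table(m)
}

# simulated-study fixture on disk + a run_analysis config for it
write_fixture <- function(dir, with_otu_tree = TRUE, n_otus = 300L,
                          depth = 800L, seed = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  host <- reference_host_tree(7)
  cfg <- simulation_config(n_otus = n_otus, depth = depth,
                           replicate_dropout = 0, abundance_sigma = 0.5,
                           seed = seed)
  tab <- simulate_microbiota(host, cfg)
  write_otu_table(tab, file.path(dir, "otus.tsv"),
                  file.path(dir, "metadata.tsv"))
  ape::write.tree(host, file.path(dir, "host.nwk"))
  config <- list(otu_table = file.path(dir, "otus.tsv"),
                 metadata = file.path(dir, "metadata.tsv"),
                 host_tree = file.path(dir, "host.nwk"),
                 depth = 500L, seed = 11L,
                 mantel_permutations = 499L, anosim_permutations = 99L,
                 congruence_mode = "exact")
  if (with_otu_tree) {
    set.seed(1)
    otu_tree <- ape::rcoal(n_otus, tip.label = otu_ids(tab))
    ape::write.tree(otu_tree, file.path(dir, "otu_tree.nwk"))
    config$otu_tree <- file.path(dir, "otu_tree.nwk")
  }
  config
}

# ---- independent slow oracles for tree distances ---------------------------

# clusters by explicit recursion over the phylo edge list
slow_clusters <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  below <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    sort(unique(unlist(lapply(kids[[as.character(v)]], below))))
  }
  internal <- unique(tree$edge[, 1L])
  out <- lapply(internal, below)
  out[vapply(out, function(s) length(s) > 1L && length(s) < n, logical(1))]
}

slow_rf <- function(t1, t2) {
  a <- vapply(slow_clusters(t1), paste, "", collapse = "|")
  b <- vapply(slow_clusters(t2), paste, "", collapse = "|")
  length(setdiff(a, b)) + length(setdiff(b, a))
}

all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) for (pos in seq_len(k))
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

# MC by factorial enumeration of matchings on label-set clusters
slow_mc <- function(t1, t2) {
  a <- slow_clusters(t1)
  b <- slow_clusters(t2)
  k <- max(length(a), length(b))
  if (k == 0L) return(0L)
  while (length(a) < k) a[[length(a) + 1L]] <- character(0)
  while (length(b) < k) b[[length(b) + 1L]] <- character(0)
  best <- Inf
  for (p in all_perms(k)) {
    tot <- 0L
    for (i in seq_len(k)) {
      x <- a[[i]]; y <- b[[p[i]]]
      tot <- tot + length(setdiff(x, y)) + length(setdiff(y, x))
    }
    if (tot < best) best <- tot
  }
  best
}

# distances between two samples' rows by direct definition
slow_jaccard <- function(x, y) {
  px <- which(x > 0); py <- which(y > 0)
  1 - length(intersect(px, py)) / length(union(px, py))
}
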