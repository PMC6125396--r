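#' Configuration for the host-microbiome codivergence simulator
#'
#' Bundles every knob of [simulate_microbiota]. Defaults mirror a
#' zoo-collection cross-sectional design: 7 host species with 3 replicate
#' fecal samples each, a few thousand OTUs, and 9,683 reads per sample
#' (a typical post-rarefaction depth for 16S MiSeq data).
#'
#' @param n_species number of host species (default 7).
#' @param n_replicates replicate samples per species (default 3).
#' @param n_otus number of OTUs in the regional pool (default 2000).
#' @param depth reads per sample (default 9683).
#' @param signal_strength phylosymbiosis dial s in \[0, 1\]: each OTU keeps
#'   its tree-evolved presence pattern with probability s and has it
#'   shuffled across species otherwise; s = 1 is pure codivergence, s = 0 an
#'   exact no-signal null.
#' @param gain_rate,loss_rate per-unit-branch-length rates of the two-state
#'   presence process along the host tree (defaults 0.25, 0.25; tree height
#'   is 1). Moderate turnover keeps deep splits away from saturation: with
#'   total rate 0.5 the expected state-flip probability across the full tree
#'   height is about 0.2, so both shallow and deep host splits leave a
#'   resolvable imprint on presence/absence dissimilarity.
#' @param abundance_sigma log-normal SD of the species-by-OTU abundance
#'   effects (default 1).
#' @param replicate_dropout probability that a species-level OTU is missing
#'   from any one replicate (default 0.05).
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 7L, n_replicates = 3L,
                              n_otus = 2000L, depth = 9683L,
                              signal_strength = 1, gain_rate = 0.25,
                              loss_rate = 0.25, abundance_sigma = 1,
                              replicate_dropout = 0.05, seed = 1L) {
  .assert_scalar_int(n_species, "n_species", lower = 2)
  .assert_scalar_int(n_replicates, "n_replicates", lower = 1)
  .assert_scalar_int(n_otus, "n_otus", lower = 1)
  .assert_scalar_int(depth, "depth", lower = 1)
  if (signal_strength < 0 || signal_strength > 1)
    .stopf("signal_strength must be in [0, 1]")
  if (gain_rate < 0 || loss_rate < 0) .stopf("rates must be >= 0")
  if (replicate_dropout < 0 || replicate_dropout > 1)
    .stopf("replicate_dropout must be in [0, 1]")
  structure(list(n_species = as.integer(n_species),
                 n_replicates = as.integer(n_replicates),
                 n_otus = as.integer(n_otus), depth = as.integer(depth),
                 signal_strength = signal_strength, gain_rate = gain_rate,
                 loss_rate = loss_rate, abundance_sigma = abundance_sigma,
                 replicate_dropout = replicate_dropout,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a host phylogeny
#'
#' Pure-birth (Yule) tree rescaled to unit total height, with leaves
#' labeled `sp1..spN`. Ultrametric by construction.
#'
#' @param n_species number of leaves (>= 2).
#' @param seed integer seed.
#' @return rooted ultrametric `phylo`.
#' @export
simulate_host_tree <- function(n_species, seed = 1L) {
  .assert_scalar_int(n_species, "n_species", lower = 2)
  tree <- local_seed_eval(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length / max(depths)
  tree$tip.label <- paste0("sp", seq_len(n_species))
  tree
}

#' Reference host phylogeny for simulation studies
#'
#' A fixed, well-resolved host tree for benchmarking: the first Yule draw
#' (seeds 1, 2, ...) whose internal branches are all at least `min_branch`
#' and whose internal-node heights are pairwise separated by at least
#' `min_height_gap` (in units of the unit tree height). The conditioning
#' emulates a well-supported host phylogeny — merge levels too close
#' together are unresolvable by any dissimilarity-based dendrogram, so an
#' unconditioned random tree would confound method error with an
#' unidentifiable truth.
#'
#' @param n_species number of leaves (default 7).
#' @param min_branch minimum internal branch length (default 0.05).
#' @param min_height_gap minimum separation between internal node heights
#'   (default 0.12).
#' @param max_seeds give up after this many candidate seeds.
#' @return rooted ultrametric `phylo`; the accepted seed is stored in
#'   `attr(tree, "seed")`.
#' @export
reference_host_tree <- function(n_species = 7L, min_branch = 0.05,
                                min_height_gap = 0.12, max_seeds = 1000L) {
  for (s in seq_len(max_seeds)) {
    tree <- simulate_host_tree(n_species, seed = s)
    internal <- tree$edge[, 2L] > n_species
    depths <- ape::node.depth.edgelength(tree)
    heights <- max(depths) - depths[-seq_len(n_species)]
    if (min(tree$edge.length[internal]) >= min_branch &&
        min(diff(sort(heights))) >= min_height_gap) {
      attr(tree, "seed") <- s
      return(tree)
    }
  }
  .stopf("no qualifying tree in %d seeds; relax the thresholds", max_seeds)
}

# transition of the 2-state (absent=0/present=1) process over branch t
.presence_step <- function(state, t, gain, loss) {
  rate <- gain + loss
  if (rate == 0) return(state)
  pi1 <- gain / rate
  decay <- exp(-rate * t)
  p1 <- ifelse(state == 1L, pi1 + (1 - pi1) * decay, pi1 * (1 - decay))
  as.integer(stats::runif(length(state)) < p1)
}

# synthetic 7-rank lineages: a small nested hierarchy with some unassigned
# family/genus levels, so rank aggregation has realistic structure
.synthetic_taxonomy <- function(n_otus) {
  phyla <- sprintf("Phylum%02d", sample.int(6L, n_otus, replace = TRUE,
                                            prob = c(.35, .3, .15, .1, .06, .04)))
  classes <- paste0(sub("Phylum", "Class", phyla), "_",
                    sample.int(2L, n_otus, replace = TRUE))
  orders <- paste0(sub("Class", "Order", classes), "_",
                   sample.int(2L, n_otus, replace = TRUE))
  families <- paste0(sub("Order", "Family", orders), "_",
                     sample.int(3L, n_otus, replace = TRUE))
  genera <- paste0(sub("Family", "Genus", families), "_",
                   sample.int(3L, n_otus, replace = TRUE))
  families[stats::runif(n_otus) < 0.1] <- ""
  genera[stats::runif(n_otus) < 0.3] <- ""
  sprintf("k__Bacteria;p__%s;c__%s;o__%s;f__%s;g__%s;s__",
          phyla, classes, orders, families, genera)
}

#' Simulate host-structured fecal microbiota along a host tree
#'
#' Generates an OTU table whose between-species structure carries a tunable
#' phylosymbiosis signal: (i) each OTU's species-level presence evolves
#' along the host tree under a two-state gain/loss Markov process started
#' at stationarity; (ii) with probability `1 - s` the evolved presence
#' pattern is shuffled across species, destroying the host structure;
#' (iii) species-level expected abundances combine a shared per-OTU
#' log-normal baseline with species-by-OTU log-normal effects of SD
#' `abundance_sigma`; (iv) each replicate inherits its species profile,
#' loses each OTU independently with probability `replicate_dropout`, and
#' draws exactly `depth` reads multinomially. Samples are named
#' `<species>_r<replicate>`; metadata derives `tribe` from the root split
#' of the host tree and `genus` from sister-species cherries.
#'
#' @param host rooted `phylo` (leaves become host species names).
#' @param cfg a [simulation_config]; its `n_species` is overridden by the
#'   host tree's leaf count.
#' @return an [otu_table] with synthetic taxonomy.
#' @export
simulate_microbiota <- function(host, cfg = simulation_config()) {
  if (!inherits(cfg, "simulation_config"))
    .stopf("`cfg` must be a simulation_config")
  species <- host$tip.label
  ns <- length(species)
  local_seed_eval(cfg$seed, {
    # (i) presence evolution, vectorized over OTUs edge by edge (preorder)
    tree <- ape::reorder.phylo(host, "cladewise")
    rate <- cfg$gain_rate + cfg$loss_rate
    pi1 <- if (rate > 0) cfg$gain_rate / rate else 0.5
    nn <- ns + tree$Nnode
    states <- matrix(NA_integer_, cfg$n_otus, nn)
    root <- ns + 1L
    states[, root] <- as.integer(stats::runif(cfg$n_otus) < pi1)
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      states[, child] <- .presence_step(states[, par], tree$edge.length[e],
                                        cfg$gain_rate, cfg$loss_rate)
    }
    presence <- states[, seq_len(ns), drop = FALSE]  # OTUs x species
    colnames(presence) <- species
    # (ii) signal dial: shuffle 1-s of the patterns across species
    shuffle <- stats::runif(cfg$n_otus) >= cfg$signal_strength
    for (o in which(shuffle)) presence[o, ] <- presence[o, sample.int(ns)]
    # (iii) expected species-level abundances: log-normal(0, sigma) per
    # species x OTU, masked by presence
    expected <- presence * matrix(stats::rlnorm(cfg$n_otus * ns,
                                                sdlog = cfg$abundance_sigma),
                                  cfg$n_otus, ns)
    # (iv) replicates: dropout then a multinomial draw at depth
    otus <- sprintf("OTU%05d", seq_len(cfg$n_otus))
    counts <- matrix(0L, ns * cfg$n_replicates, cfg$n_otus,
                     dimnames = list(NULL, otus))
    sample_names <- character(ns * cfg$n_replicates)
    row <- 0L
    for (s in seq_len(ns)) for (r in seq_len(cfg$n_replicates)) {
      row <- row + 1L
      sample_names[row] <- sprintf("%s_r%d", species[s], r)
      w <- expected[, s]
      if (cfg$replicate_dropout > 0) {
        w <- w * (stats::runif(cfg$n_otus) >= cfg$replicate_dropout)
      }
      if (sum(w) == 0) w <- rep(1, cfg$n_otus)  # degenerate: uniform reads
      counts[row, ] <- stats::rmultinom(1L, cfg$depth, w)[, 1L]
    }
    rownames(counts) <- sample_names
    taxonomy <- stats::setNames(.synthetic_taxonomy(cfg$n_otus), otus)
    metadata <- data.frame(
      sample_id = sample_names,
      host_species = rep(species, each = cfg$n_replicates),
      genus = rep(.species_genera(host), each = cfg$n_replicates),
      tribe = rep(.species_tribes(host), each = cfg$n_replicates),
      replicate = rep(seq_len(cfg$n_replicates), ns),
      stringsAsFactors = FALSE)
    otu_table(counts, taxonomy, metadata)
  })
}

# tribe = side of the root bipartition of the host tree
.species_tribes <- function(host) {
  ns <- length(host$tip.label)
  ch <- host$edge[host$edge[, 1L] == ns + 1L, 2L]
  first <- if (ch[1L] <= ns) host$tip.label[ch[1L]]
           else ape::extract.clade(host, ch[1L])$tip.label
  ifelse(host$tip.label %in% first, "tribeA", "tribeB")
}

# genus = sister-species cherry (shared label), singleton genus otherwise
.species_genera <- function(host) {
  ns <- length(host$tip.label)
  parent_of_tip <- host$edge[match(seq_len(ns), host$edge[, 2L]), 1L]
  cherries <- split(seq_len(ns), parent_of_tip)
  genus <- paste0("gen_", host$tip.label)
  gi <- 0L
  for (tips in cherries) if (length(tips) > 1L) {
    gi <- gi + 1L
    genus[tips] <- sprintf("genus%02d", gi)
  }
  genus
}

#' Permute host-species labels across replicate blocks
#'
#' Reassigns which species identity (and its genus/tribe attributes) each
#' block of replicate samples carries, leaving the count matrix untouched.
#' This breaks any host association exactly, giving a clean null for
#' type-I-error checks.
#'
#' @param t an [otu_table].
#' @param seed integer seed.
#' @return an [otu_table] with permuted species metadata.
#' @export
null_relabel <- function(t, seed = 1L) {
  md <- t$metadata
  species <- unique(md$host_species)
  perm <- local_seed_eval(seed, sample(species))
  idx <- match(md$host_species, species)
  attrs <- intersect(c("host_species", "genus", "tribe"), names(md))
  block <- unique(md[attrs])
  block <- block[!duplicated(block$host_species), , drop = FALSE]
  for (col in attrs)
    md[[col]] <- block[[col]][match(perm[idx], block$host_species)]
  otu_table(t$counts, t$taxonomy, md)
}
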