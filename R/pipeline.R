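#' Collapse replicate samples to one profile per host species
#'
#' `method = "mean"` averages the replicates' relative-abundance profiles
#' and rescales to integer counts (the scale is chosen so that no OTU with
#' non-zero mean abundance rounds to zero, preserving presence/absence
#' exactly); `method = "pooled"` sums the raw counts. Either way the result
#' is an [otu_table] with one row per species, ready for Jaccard + UPGMA.
#'
#' @param t an [otu_table] with replicated species.
#' @param method `"mean"` (default) or `"pooled"`.
#' @return an [otu_table] with one sample per host species.
#' @export
species_profile <- function(t, method = c("mean", "pooled")) {
  method <- match.arg(method)
  species <- unique(t$metadata$host_species)
  g <- factor(t$metadata$host_species, levels = species)
  if (method == "pooled") {
    m <- rowsum(t$counts, g)
  } else {
    rel <- t$counts / rowSums(t$counts)
    p <- rowsum(rel, g) / as.vector(table(g))
    nz <- p[p > 0]
    scale <- max(1e6, ceiling(2 / min(nz)))
    m <- round(p * scale)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- species
  md <- t$metadata[match(species, t$metadata$host_species), , drop = FALSE]
  md$sample_id <- species
  md$replicate <- NULL
  otu_table(m, t$taxonomy, md)
}

.default_config <- function() {
  list(depth = 9683L, seed = 1L, filter_singletons = TRUE,
       mantel_permutations = 9999L, anosim_permutations = 999L,
       congruence_draws = 80000L, congruence_mode = "auto",
       profile_method = "mean", unifrac_on_rarefied = TRUE)
}

#' Run the full phylosymbiosis analysis
#'
#' Orchestrates the end-to-end pipeline: read OTU table and metadata,
#' filter singletons, rarefy, alpha diversity with per-index one-way ANOVA
#' across species, phylum/family composition tables, per-species core OTUs
#' and their intersection counts, sample- and species-level Jaccard
#' matrices, UPGMA dendrogram, RF and MC congruence tests against the host
#' tree, Mantel test of host distances vs species-level Jaccard, and (when
#' an OTU tree is supplied) unweighted/weighted UniFrac with PCoA and
#' ANOSIM at species/genus/tribe level. Every stochastic stage gets its own
#' seed derived from the single config seed, so reruns are byte-identical.
#'
#' @param config named list or path to a YAML file. Required keys:
#'   `otu_table`, `metadata`, `host_tree` (paths). Optional: `otu_tree`,
#'   `host_distances` (paths), `out_dir`, `depth` (default 9683; 0 skips
#'   rarefaction), `seed` (1), `filter_singletons` (TRUE),
#'   `mantel_permutations` (9999), `anosim_permutations` (999),
#'   `congruence_draws` (80000), `congruence_mode` ("auto"),
#'   `profile_method` ("mean").
#' @return object of class `analysis_report` (a nested list of every stage
#'   result), invisibly if `out_dir` was written.
#' @export
run_analysis <- function(config) {
  config_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.default_config(), config)
  for (key in c("otu_table", "metadata", "host_tree")) {
    if (is.null(cfg[[key]])) .stopf("config is missing required key '%s'", key)
    if (!file.exists(cfg[[key]])) .stopf("input not found: %s", cfg[[key]])
  }
  for (key in c("otu_tree", "host_distances"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      .stopf("input not found: %s", cfg[[key]])

  note <- function(fmt, ...) message(sprintf(paste0("[cervsym] ", fmt), ...))
  report <- list(config = cfg)

  note("reading inputs")
  t <- read_otu_table(cfg$otu_table, cfg$metadata)
  host <- ape::read.tree(cfg$host_tree)
  if (isTRUE(cfg$filter_singletons)) t <- filter_singletons(t)
  if (cfg$depth > 0L) {
    note("rarefying to depth %d", cfg$depth)
    t <- rarefy(t, cfg$depth, seed = derive_seed(cfg$seed, "rarefy"))
  }
  report$table_dim <- dim(t)

  note("alpha diversity")
  alpha <- alpha_diversity(t)
  alpha$host_species <- t$metadata$host_species
  report$alpha <- alpha
  idx_cols <- c("observed_otus", "chao1", "shannon", "simpson", "equitability")
  report$alpha_anova <- do.call(rbind, lapply(idx_cols, function(col) {
    res <- one_way_anova(split(alpha[[col]], alpha$host_species))
    data.frame(index = col, F = res$statistic, df1 = res$df[1L],
               df2 = res$df[2L], p_value = res$p_value)
  }))

  note("taxonomic composition")
  report$composition <- list(phylum = aggregate_by_rank(t, "phylum"),
                             family = aggregate_by_rank(t, "family"))

  note("core OTUs")
  core <- core_otus(t, "host_species")
  report$core <- core
  sets <- stats::setNames(core$core_otu_ids, core$group)
  report$intersections <- intersection_counts(sets)

  note("beta diversity (Jaccard)")
  report$jaccard_samples <- jaccard_matrix(t)
  prof <- species_profile(t, cfg$profile_method)
  report$jaccard_species <- jaccard_matrix(prof)

  note("UPGMA dendrogram + congruence")
  dendro <- upgma(report$jaccard_species)
  report$dendrogram <- dendro
  report$host_tree <- host
  report$congruence <- lapply(c(rf = "rf", mc = "mc"), function(m)
    congruence_test(host, dendro, metric = m, n_random = cfg$congruence_draws,
                    mode = cfg$congruence_mode,
                    seed = derive_seed(cfg$seed, paste0("congruence_", m))))

  note("Mantel test")
  host_dm <- if (!is.null(cfg$host_distances))
    read_distance_matrix(cfg$host_distances) else ape::cophenetic.phylo(host)
  report$mantel <- mantel_test(host_dm, report$jaccard_species,
                               n_perm = cfg$mantel_permutations,
                               seed = derive_seed(cfg$seed, "mantel"))

  if (!is.null(cfg$otu_tree)) {
    note("UniFrac + PCoA + ANOSIM")
    otu_tree <- ape::read.tree(cfg$otu_tree)
    report$unifrac_unweighted <- unweighted_unifrac(t, otu_tree)
    report$unifrac_weighted <- weighted_unifrac(t, otu_tree)
    report$pcoa <- list(unweighted = pcoa(report$unifrac_unweighted),
                        weighted = pcoa(report$unifrac_weighted))
    report$anosim <- list()
    for (level in intersect(c("host_species", "genus", "tribe"),
                            names(t$metadata))) {
      g <- stats::setNames(t$metadata[[level]], t$metadata$sample_id)
      if (length(unique(g)) < 2L || any(table(g) < 2L)) next
      report$anosim[[level]] <- anosim_test(
        report$unifrac_unweighted, g, n_perm = cfg$anosim_permutations,
        seed = derive_seed(cfg$seed, paste0("anosim_", level)))
    }
  } else {
    note("no OTU tree given; skipping UniFrac, PCoA and ANOSIM")
  }

  report$provenance <- list(
    package = "cervsym",
    version = as.character(utils::packageVersion("cervsym")),
    seed = cfg$seed,
    stage_seeds = list(
      rarefy = derive_seed(cfg$seed, "rarefy"),
      congruence_rf = derive_seed(cfg$seed, "congruence_rf"),
      congruence_mc = derive_seed(cfg$seed, "congruence_mc"),
      mantel = derive_seed(cfg$seed, "mantel")),
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA_character_)
  class(report) <- "analysis_report"

  if (!is.null(cfg$out_dir)) {
    note("writing report to %s", cfg$out_dir)
    write_report(report, cfg$out_dir)
    return(invisible(report))
  }
  report
}

#' Write an analysis report to a directory of TSV/newick/JSON files
#'
#' The machine-readable outputs contain no timestamps, so two runs with the
#' same config and seed produce byte-identical directories.
#'
#' @param report an `analysis_report` from [run_analysis].
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  tsv <- function(df, f, rn = FALSE) utils::write.table(
    df, p(f), sep = "\t", quote = FALSE, row.names = rn,
    col.names = if (rn) NA else TRUE)
  tsv(report$alpha, "alpha_diversity.tsv")
  tsv(report$alpha_anova, "alpha_anova.tsv")
  tsv(round(report$composition$phylum, 10), "composition_phylum.tsv", rn = TRUE)
  tsv(round(report$composition$family, 10), "composition_family.tsv", rn = TRUE)
  core_flat <- report$core
  core_flat$core_otu_ids <- vapply(core_flat$core_otu_ids, paste, "",
                                   collapse = ",")
  tsv(core_flat, "core_otus.tsv")
  tsv(report$intersections, "intersection_counts.tsv")
  write_distance_matrix(round(report$jaccard_samples, 12),
                        p("jaccard_samples.tsv"))
  write_distance_matrix(round(report$jaccard_species, 12),
                        p("jaccard_species.tsv"))
  ape::write.tree(report$dendrogram, p("dendrogram.nwk"))
  ape::write.tree(report$host_tree, p("host_tree.nwk"))
  for (m in names(report$congruence))
    format_congruence_result(report$congruence[[m]],
                             p(sprintf("congruence_%s.txt", m)))
  stats_block <- list(
    mantel = report$mantel[c("statistic", "p_value", "n_permutations",
                             "tail", "convention")],
    anosim = lapply(report$anosim, function(a)
      a[c("statistic", "p_value", "n_permutations", "tail", "convention")]),
    congruence = lapply(report$congruence, function(cg)
      cg[c("metric", "observed", "normalized", "null_size", "null_mean",
           "null_sd", "p_value", "mode")]))
  jsonlite::write_json(stats_block, p("stats.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(report$unifrac_unweighted)) {
    write_distance_matrix(round(report$unifrac_unweighted, 12),
                          p("unifrac_unweighted.tsv"))
    write_distance_matrix(round(report$unifrac_weighted, 12),
                          p("unifrac_weighted.tsv"))
    for (w in names(report$pcoa)) {
      res <- report$pcoa[[w]]
      out <- data.frame(sample_id = rownames(res$coordinates),
                        round(res$coordinates, 12), check.names = FALSE)
      tsv(out, sprintf("pcoa_%s.tsv", w))
      writeLines(c(paste("eigenvalues:",
                         paste(format(res$eigenvalues, digits = 10),
                               collapse = "\t")),
                   paste("proportion_explained:",
                         paste(format(res$proportion_explained, digits = 10),
                               collapse = "\t"))),
                 p(sprintf("pcoa_%s_eigen.txt", w)))
    }
  }
  jsonlite::write_json(report$provenance, p("provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(.report_summary(report), p("summary.txt"))
  invisible(out_dir)
}

.report_summary <- function(report) {
  lines <- c("cervsym analysis summary",
             sprintf("samples: %d  OTUs: %d", report$table_dim[1L],
                     report$table_dim[2L]),
             sprintf("Mantel r = %.4f (p = %.4g)",
                     report$mantel$statistic, report$mantel$p_value))
  for (m in names(report$congruence)) {
    cg <- report$congruence[[m]]
    lines <- c(lines, sprintf("n%s = %.3f (raw %d, p = %.4g, %s null)",
                              cg$metric, cg$normalized, cg$observed,
                              cg$p_value, cg$mode))
  }
  for (level in names(report$anosim)) {
    a <- report$anosim[[level]]
    lines <- c(lines, sprintf("ANOSIM (%s): R = %.3f (p = %.4g)", level,
                              a$statistic, a$p_value))
  }
  lines
}

#' @export
print.analysis_report <- function(x, ...) {
  writeLines(.report_summary(x))
  invisible(x)
}
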