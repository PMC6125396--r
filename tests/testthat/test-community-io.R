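test_that("OTU tables round-trip through both TSV dialects", {
  t <- tiny_table()
  for (dialect in c("qiime", "samples")) {
    tp <- tempfile(fileext = ".tsv")
    mp <- tempfile(fileext = ".tsv")
    write_otu_table(t, tp, mp, dialect = dialect)
    back <- read_otu_table(tp, mp)
    expect_identical(back$counts, t$counts)
    expect_identical(back$metadata$host_species, t$metadata$host_species)
    if (dialect == "qiime") expect_identical(back$taxonomy, t$taxonomy)
  }
})

test_that("reader rejects unknown samples and non-integer counts", {
  t <- tiny_table()
  tp <- tempfile(fileext = ".tsv")
  mp <- tempfile(fileext = ".tsv")
  write_otu_table(t, tp, mp)
  md <- utils::read.delim(mp)
  md <- md[md$sample_id != "s2", ]
  utils::write.table(md, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_otu_table(tp, mp), "s2")

  write_otu_table(t, tp, mp)
  lines <- readLines(tp)
  lines[2] <- sub("\t5\t", "\t5.5\t", lines[2])
  writeLines(lines, tp)
  expect_error(read_otu_table(tp, mp), "non-integer")
})

test_that("constructor enforces table invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(otu_table(m), "duplicated sample")
  m <- matrix(c(1L, -1L, 0L, 2L), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(otu_table(m), "non-negative")
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(
    otu_table(m, metadata = data.frame(sample_id = "a", host_species = "h")),
    "missing from metadata")
})

test_that("singleton filtering removes exactly the total-count-1 OTUs", {
  m <- matrix(c(1L, 0L, 0L,
                1L, 1L, 0L,
                1L, 1L, 0L,
                2L, 1L, 0L,
                0L, 0L, 1L), 3, 5,
              dimnames = list(paste0("s", 1:3), paste0("o", 1:5)))
  # totals: 1, 2, 2, 3, 1 -> o1 and o5 removed
  f <- filter_singletons(make_table(m))
  expect_identical(otu_ids(f), c("o2", "o3", "o4"))
  expect_identical(f$counts, m[, 2:4])
})

test_that("rarefaction hits the target depth exactly and is seed-stable", {
  t <- rand_table(4, 50, seed = 7)
  r1 <- rarefy(t, 40, seed = 11)
  r2 <- rarefy(t, 40, seed = 11)
  expect_true(all(rowSums(r1$counts) == 40))
  expect_identical(r1$counts, r2$counts)
  # a sample already at depth is returned unchanged
  m <- matrix(c(3L, 2L), 1, 2, dimnames = list("s1", c("o1", "o2")))
  expect_identical(rarefy(make_table(m), 5, seed = 1)$counts, m)
  # single-category draw
  m <- matrix(c(1000000L, 0L), 1, 2, dimnames = list("s1", c("o1", "o2")))
  out <- rarefy(make_table(m), 100, seed = 1, prune_empty = FALSE)
  expect_identical(as.vector(out$counts), c(100L, 0L))
  expect_error(rarefy(t, 0, seed = 1), "depth")
})

test_that("rarefaction draws are hypergeometric and preserve support", {
  m <- matrix(c(50L, 50L), 1, 2, dimnames = list("s1", c("o1", "o2")))
  t <- make_table(m)
  draws <- vapply(1:2000, function(s)
    rarefy(t, 50, seed = s, prune_empty = FALSE)$counts[1, 1], integer(1))
  # multivariate hypergeometric moments: mean 25, var n*p*q*(N-n)/(N-1)
  sd_h <- sqrt(50 * 0.5 * 0.5 * 50 / 99)
  expect_lt(abs(mean(draws) - 25), 3 * sd_h / sqrt(2000))
  # support preservation: absent OTUs stay absent
  t2 <- rand_table(5, 80, seed = 3)
  r <- rarefy(t2, 100, seed = 5, prune_empty = FALSE)
  expect_true(all(r$counts[t2$counts == 0L] == 0L))
  expect_true(all(r$counts <= t2$counts))
})

test_that("samples below depth are dropped with a warning, not padded", {
  m <- matrix(c(30L, 30L, 2L, 3L), 2, 2, byrow = TRUE,
              dimnames = list(c("deep", "shallow"), c("o1", "o2")))
  expect_warning(r <- rarefy(make_table(m), 20, seed = 1), "shallow")
  expect_identical(sample_ids(r), "deep")
})

test_that("rank aggregation normalizes, pools unassigned, and orders taxa", {
  t <- tiny_table()
  ph <- aggregate_by_rank(t, "phylum")
  expect_equal(unname(rowSums(ph)), rep(1, 3), tolerance = 1e-9)
  expect_identical(sort(colnames(ph)), c("Bacteroidetes", "Firmicutes"))
  # s1: o1+o2 = 6 Firmicutes of 8 -> 0.75
  expect_equal(ph["s1", "Firmicutes"], 0.75)
  fam <- aggregate_by_rank(t, "family")
  expect_equal(unname(rowSums(fam)), rep(1, 3), tolerance = 1e-9)
  expect_true("unclassified_Clostridiales" %in% colnames(fam))
  # columns ordered by grand mean, descending
  expect_true(all(diff(colMeans(fam)) <= 1e-12))
  expect_error(aggregate_by_rank(t, "species_group"), "unknown taxonomic rank")
  # single-phylum table -> single column of ones
  one <- make_table(matrix(c(3L, 7L), 1, 2,
                           dimnames = list("s1", c("a", "b"))),
                    stats::setNames(rep("k__B;p__P;c__;o__;f__;g__;s__", 2),
                                    c("a", "b")))
  expect_equal(unname(aggregate_by_rank(one, "phylum")[, 1]), 1)
})

test_that("distance matrices round-trip and are validated", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  p <- tempfile(fileext = ".tsv")
  write_distance_matrix(m, p)
  expect_equal(read_distance_matrix(p), m)
  bad <- m; bad[1, 2] <- 9
  expect_error(validate_distance_matrix(bad), "symmetric")
  bad <- m; diag(bad) <- 1
  expect_error(validate_distance_matrix(bad), "diagonal")
})
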