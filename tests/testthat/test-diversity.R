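test_that("alpha-diversity indices match closed forms", {
  m <- matrix(c(4L, 4L, 0L, 0L, 0L,
                5L, 3L, 1L, 1L, 2L), 2, 5, byrow = TRUE,
              dimnames = list(c("even", "mixed"), paste0("o", 1:5)))
  a <- alpha_diversity(make_table(m))
  # two equal categories: H = 1 bit, Simpson = 0.5, equitability = 1
  expect_equal(a$shannon[1], 1)
  expect_equal(a$simpson[1], 0.5)
  expect_equal(a$equitability[1], 1)
  # counts (5,3,1,1,2): S=5, F1=2, F2=1 -> Chao1 = 5 + 2*1/(2*2)
  expect_identical(a$observed_otus[2], 5L)
  expect_equal(a$chao1[2], 5.5)
  # Good's coverage: 1 - F1/N
  expect_equal(a$goods_coverage[2], 1 - 2 / 12)
  # N = 100 with F1 = 5 singletons
  big <- matrix(c(95L, rep(1L, 5L)), 1, 6,
                dimnames = list("s", paste0("o", 1:6)))
  expect_equal(alpha_diversity(make_table(big))$goods_coverage, 0.95)
})

test_that("empty samples give missing indices, not zeros", {
  m <- matrix(c(0L, 0L, 3L, 1L), 2, 2, byrow = TRUE,
              dimnames = list(c("empty", "full"), c("o1", "o2")))
  a <- alpha_diversity(make_table(m))
  expect_true(all(is.na(a[1, -1])))
  expect_false(anyNA(a[2, -1]))
})

test_that("alpha-diversity invariants hold across random tables", {
  for (seed in 1:10) {
    t <- rand_table(5, 40, seed = seed)
    a <- alpha_diversity(t)
    f1 <- apply(t$counts, 1, function(x) sum(x == 1L))
    expect_true(all(a$chao1 >= a$observed_otus))
    expect_identical(unname(a$chao1 == a$observed_otus), unname(f1 <= 1L))
    expect_true(all(a$shannon <= log2(a$observed_otus) + 1e-12))
    expect_true(all(a$simpson >= 0 & a$simpson <= 1 - 1 / a$observed_otus))
  }
  # Shannon attains its maximum exactly at equal abundances
  eq <- make_table(matrix(rep(7L, 8), 1, 8,
                          dimnames = list("s", paste0("o", 1:8))))
  expect_equal(alpha_diversity(eq)$shannon, 3)
})

test_that("Good's coverage rarefaction curves behave at the boundaries", {
  t <- rand_table(2, 30, seed = 2)
  full <- alpha_diversity(t)
  at_total <- rarefaction_curve(t, depths = min(rowSums(t$counts)),
                                reps = 3, seed = 1)
  # depth == total for the shallower sample reproduces its full coverage
  shallow <- rownames(t$counts)[which.min(rowSums(t$counts))]
  expect_equal(at_total$goods_coverage[at_total$sample_id == shallow],
               full$goods_coverage[full$sample_id == shallow])
  # single-OTU sample: no singletons possible at depth > 1
  one <- make_table(matrix(500L, 1, 1, dimnames = list("s", "o1")))
  rc <- rarefaction_curve(one, depths = c(10, 100), reps = 2, seed = 1)
  expect_true(all(rc$goods_coverage == 1))
  expect_error(rarefaction_curve(t, depths = c(10, 10), reps = 1, seed = 1),
               "increasing")
})

test_that("mean coverage increases with depth on a uniform community", {
  m <- matrix(rep(20L, 100), 1, 100,
              dimnames = list("s", paste0("o", 1:100)))
  rc <- rarefaction_curve(make_table(m), depths = c(10, 1000), reps = 200,
                          seed = 4)
  expect_lt(rc$goods_coverage[rc$depth == 10],
            rc$goods_coverage[rc$depth == 1000])
})

test_that("core OTU accounting follows the set definitions", {
  # identical replicates: everything shared
  m <- matrix(rep(c(5L, 3L, 0L), 3), 3, 3, byrow = TRUE,
              dimnames = list(paste0("r", 1:3), paste0("o", 1:3)))
  cs <- core_otus(make_table(m, species = rep("sp", 3)))
  expect_equal(cs$shared_otu_pct, 100)
  expect_equal(cs$shared_seq_pct_mean, 100)
  # pairwise-disjoint replicates: nothing shared
  m <- diag(3L) * 5L
  dimnames(m) <- list(paste0("r", 1:3), paste0("o", 1:3))
  cs <- core_otus(make_table(m, species = rep("sp", 3)))
  expect_equal(cs$shared_otu_pct, 0)
  # A:{o1,o2}, B:{o1,o3}, C:{o1,o4}, o1 = 90 of 100 reads each
  m <- matrix(0L, 3, 4, dimnames = list(c("A", "B", "C"), paste0("o", 1:4)))
  m[, 1] <- 90L
  m[1, 2] <- 10L; m[2, 3] <- 10L; m[3, 4] <- 10L
  cs <- core_otus(make_table(m, species = rep("sp", 3)))
  expect_equal(cs$shared_otu_pct, 25)
  expect_equal(cs$shared_seq_pct_mean, 90)
  expect_equal(cs$shared_seq_pct_sd, 0)
  expect_identical(cs$core_otu_ids[[1]], "o1")
})

test_that("intersection counts partition the union", {
  ic <- intersection_counts(list(A = as.character(1:3), B = as.character(4:5)))
  expect_equal(ic$count[ic$signature == "A"], 3L)
  expect_equal(ic$count[ic$signature == "B"], 2L)
  expect_equal(ic$count[ic$signature == "A+B"], 0L)
  ic <- intersection_counts(list(A = c("1", "2", "3"), B = c("2", "3"),
                                 C = "3"))
  got <- stats::setNames(ic$count, ic$signature)
  expect_equal(unname(got[c("A", "A+B", "A+B+C")]), c(1L, 1L, 1L))
  expect_equal(sum(got), 3L)
  # identical sets: only the full signature is non-zero
  ic <- intersection_counts(list(A = letters[1:4], B = letters[1:4]))
  expect_equal(ic$count[ic$signature == "A+B"], 4L)
  expect_equal(sum(ic$count), 4L)
  # conservation on random sets
  set.seed(9)
  gs <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(gs) <- paste0("g", 1:4)
  ic <- intersection_counts(gs)
  expect_equal(sum(ic$count), length(unique(unlist(gs))))
})

test_that("Spearman co-occurrence uses average ranks and flags constants", {
  # 4 samples, equal totals so genus ranks mirror the built-in vectors
  g1 <- c(1L, 2L, 3L, 4L)
  g2 <- c(1L, 3L, 2L, 4L)
  g3 <- c(6L, 5L, 4L, 3L)  # perfectly anti-ordered vs g1
  g4 <- rep(2L, 4)         # constant
  filler <- 20L - (g1 + g2 + g3 + g4)
  m <- cbind(g1, g2, g3, g4, filler)
  dimnames(m) <- list(paste0("s", 1:4), paste0("o", 1:5))
  tax <- stats::setNames(sprintf(
    "k__B;p__P;c__C;o__O;f__F;g__Gen%d;s__", 1:5), paste0("o", 1:5))
  t <- make_table(m, tax, species = rep("sp", 4))
  res <- cooccurrence_spearman(t, paste0("Gen", 1:4))$sp
  expect_equal(diag(res$rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(res$rho["Gen1", "Gen2"], 0.8)
  expect_equal(res$rho["Gen1", "Gen3"], -1)
  expect_true(is.na(res$rho["Gen1", "Gen4"]))
  expect_true(isSymmetric(res$rho))
})
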