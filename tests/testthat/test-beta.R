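test_that("Jaccard distances follow the presence/absence definition", {
  m <- matrix(c(1L, 1L, 1L, 0L,
                0L, 1L, 1L, 1L,
                1L, 1L, 1L, 0L,
                0L, 0L, 0L, 0L), 4, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("o", 1:4)))
  expect_warning(d <- jaccard_matrix(make_table(m)), "empty")
  expect_equal(d["s1", "s3"], 0)            # identical presence sets
  expect_equal(d["s1", "s2"], 0.5)          # 2 shared of 4
  expect_equal(d["s4", "s4"], 0)
  disj <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                 dimnames = list(c("a", "b"), c("o1", "o2")))
  expect_equal(jaccard_matrix(make_table(disj))["a", "b"], 1)
})

test_that("Jaccard agrees with vegan and the direct definition", {
  t <- rand_table(6, 30, seed = 5)
  d <- jaccard_matrix(t)
  v <- as.matrix(vegan::vegdist(t$counts, method = "jaccard", binary = TRUE))
  expect_equal(d, v[rownames(d), colnames(d)], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(d["s1", "s2"], slow_jaccard(t$counts[1, ], t$counts[2, ]))
})

test_that("unweighted UniFrac matches branch-set enumeration", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- matrix(c(1L, 1L, 0L, 0L,
                0L, 0L, 1L, 1L,
                1L, 0L, 1L, 0L), 3, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("A", "B", "C", "D")))
  d <- unweighted_unifrac(make_table(m), tree)
  expect_equal(d["s1", "s2"], 1, tolerance = 1e-12)    # no shared branch
  expect_equal(d["s1", "s3"], 0.6, tolerance = 1e-12)  # unique 3 / union 5
  expect_equal(d["s1", "s1"], 0)
  # identical presence sets at distance zero (counts differ)
  m2 <- m[c(1, 1), , drop = FALSE] * matrix(c(1L, 3L), 2, 4)
  rownames(m2) <- c("x", "y")
  expect_equal(unweighted_unifrac(make_table(m2), tree)["x", "y"], 0)
  # missing OTUs are reported
  bad <- make_table(matrix(1L, 1, 5, dimnames = list("s", c(LETTERS[1:4], "E"))))
  expect_error(unweighted_unifrac(bad, tree), "E")
})

test_that("unweighted UniFrac equals Jaccard on unit-branch star trees", {
  for (seed in 1:6) {
    t <- rand_table(4, 25, seed = seed)
    star <- ape::read.tree(text = paste0(
      "(", paste0(otu_ids(t), ":1", collapse = ","), ");"))
    expect_equal(unweighted_unifrac(t, star), jaccard_matrix(t),
                 tolerance = 1e-12)
  }
})

test_that("unweighted UniFrac agrees with picante", {
  skip_if_not_installed("picante")
  t <- rand_table(5, 20, seed = 8)
  tree <- ape::rtree(20, tip.label = otu_ids(t))
  d <- unweighted_unifrac(t, tree)
  p <- as.matrix(picante::unifrac(t$counts, tree))
  expect_equal(d, p[rownames(d), colnames(d)], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("weighted UniFrac is linear in branch lengths and count-scale free", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  m <- matrix(c(10L, 0L, 0L, 7L), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  t <- make_table(m)
  d <- weighted_unifrac(t, tree)
  expect_equal(d["s1", "s2"], 2, tolerance = 1e-12)
  half <- tree; half$edge.length <- half$edge.length / 2
  expect_equal(weighted_unifrac(t, half)["s1", "s2"], 1, tolerance = 1e-12)
  # identical profiles -> 0; uniform within-sample count scaling is a no-op
  t2 <- rand_table(3, 12, seed = 3)
  tr2 <- ape::rtree(12, tip.label = otu_ids(t2))
  scaled <- make_table(t2$counts * 5L)
  expect_equal(weighted_unifrac(t2, tr2), weighted_unifrac(scaled, tr2),
               tolerance = 1e-12)
  expect_equal(max(abs(diag(weighted_unifrac(t2, tr2)))), 0)
  # normalized variant is bounded by 1
  expect_true(all(weighted_unifrac(t2, tr2, normalized = TRUE) <= 1 + 1e-12))
})

test_that("PCoA recovers Euclidean configurations", {
  # collinear points 0, 1, 2 apart: one axis carries all positive inertia
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  res <- pcoa(m)
  pos <- res$eigenvalues[res$eigenvalues > 1e-10]
  expect_equal(length(pos), 1L)
  expect_equal(res$proportion_explained[1], 1)
  # Euclidean input: recovered coordinates reproduce the distances
  set.seed(13)
  pts <- matrix(rnorm(5 * 3), 5, dimnames = list(paste0("p", 1:5), NULL))
  dm <- as.matrix(dist(pts))
  res <- pcoa(dm)
  rec <- as.matrix(dist(res$coordinates))
  expect_equal(rec, dm, tolerance = 1e-8, ignore_attr = TRUE)
  # sign canonicalization: first non-zero loading positive
  expect_true(all(apply(res$coordinates, 2, function(v) v[v != 0][1]) > 0))
  # degenerate all-zero input
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(abs(pcoa(z)$eigenvalues) < 1e-10))
  bad <- m; bad[1, 2] <- 5
  expect_error(pcoa(bad), "symmetric")
})
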