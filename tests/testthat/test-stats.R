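rand_dm <- function(n, seed, labels = paste0("x", seq_len(n))) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(labels, labels)
  m
}

test_that("Mantel r is exact on self- and affine-related matrices", {
  dm <- rand_dm(7, 1)
  res <- mantel_test(dm, dm, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  res2 <- mantel_test(dm, 0.3 + 2 * dm - diag(0.3, 7), n_perm = 99, seed = 1)
  expect_equal(res2$statistic, 1)
  # statistic agrees with vegan
  dm2 <- rand_dm(7, 2, labels = rownames(dm))
  mine <- mantel_test(dm, dm2, n_perm = 49, seed = 1)
  ref <- vegan::mantel(as.dist(dm), as.dist(dm2), permutations = 49)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_error(mantel_test(dm, rand_dm(7, 3, labels = paste0("z", 1:7))),
               "labels differ")
  flat <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(flat) <- 0
  expect_error(mantel_test(flat, rand_dm(4, 1, letters[1:4])), "variance")
})

test_that("Mantel permutation p matches exhaustive enumeration", {
  dm1 <- rand_dm(5, 4)
  dm2 <- rand_dm(5, 5, labels = rownames(dm1))
  ut <- upper.tri(dm1)
  obs <- cor(dm1[ut], dm2[ut])
  exact <- mean(vapply(all_perms(5), function(p)
    cor(dm1[ut], dm2[p, p][ut]) >= obs, logical(1)))
  mc <- mantel_test(dm1, dm2, n_perm = 4999, seed = 8)
  se <- sqrt(exact * (1 - exact) / 4999)
  expect_lt(abs(mc$p_value - exact), 3 * se + 1e-12)
})

test_that("ANOSIM attains R = 1 under complete separation", {
  # two tight clusters far apart: all within < all between
  set.seed(6)
  pts <- rbind(matrix(rnorm(9, 0, 0.01), 3), matrix(rnorm(9, 10, 0.01), 3))
  dm <- as.matrix(dist(pts))
  labs <- paste0("s", 1:6)
  dimnames(dm) <- list(labs, labs)
  g <- stats::setNames(rep(c("a", "b"), each = 3), labs)
  res <- anosim_test(dm, g, n_perm = 199, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.2)
  expect_error(anosim_test(dm, stats::setNames(c("a", rep("b", 5)), labs)),
               "size 1")
})

test_that("ANOSIM agrees with vegan and with exhaustive label enumeration", {
  dm <- rand_dm(8, 9, labels = paste0("s", 1:8))
  g <- stats::setNames(rep(c("a", "b"), each = 4), rownames(dm))
  mine <- anosim_test(dm, g, n_perm = 99, seed = 2)
  ref <- vegan::anosim(as.dist(dm), factor(g), permutations = 99)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  # exhaustive: 6 samples, 2 groups of 3 -> stat depends on the chosen triple
  dm6 <- rand_dm(6, 10, labels = paste0("s", 1:6))
  g6 <- stats::setNames(rep(c("a", "b"), each = 3), rownames(dm6))
  obs <- anosim_test(dm6, g6, n_perm = 1, seed = 1)$statistic
  ut <- upper.tri(dm6)
  r <- rank(dm6[ut])
  stat_of <- function(members) {
    gg <- ifelse(seq_len(6) %in% members, "a", "b")
    within <- outer(gg, gg, `==`)[ut]
    (mean(r[!within]) - mean(r[within])) / (15 / 2)
  }
  exact <- mean(apply(utils::combn(6, 3), 2, function(m)
    stat_of(m) >= obs - 1e-12))
  mc <- anosim_test(dm6, g6, n_perm = 4999, seed = 3)
  se <- sqrt(exact * (1 - exact) / 4999)
  expect_lt(abs(mc$p_value - exact), 3 * se + 0.002)
})

test_that("permutation tests are bit-reproducible given a seed", {
  dm1 <- rand_dm(7, 11)
  dm2 <- rand_dm(7, 12, labels = rownames(dm1))
  a <- mantel_test(dm1, dm2, n_perm = 499, seed = 42)
  b <- mantel_test(dm1, dm2, n_perm = 499, seed = 42)
  expect_identical(a$p_value, b$p_value)
  g <- stats::setNames(rep(c("u", "v"), c(4, 3)), rownames(dm1))
  x <- anosim_test(dm1, g, n_perm = 499, seed = 42)
  y <- anosim_test(dm1, g, n_perm = 499, seed = 42)
  expect_identical(x$p_value, y$p_value)
  expect_true(x$statistic >= -1 && x$statistic <= 1)
})

test_that("one-way ANOVA reproduces the classical F statistic", {
  res <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4)))
  expect_equal(res$statistic, 1.5)
  expect_equal(res$df, c(1, 4))
  expect_equal(res$p_value, stats::pf(1.5, 1, 4, lower.tail = FALSE))
  # identical means with spread: F ~ 0
  res0 <- one_way_anova(list(a = c(1, 3), b = c(0, 4)))
  expect_equal(res0$statistic, 0)
  # separation strictly increases F
  base <- list(a = c(1, 2, 3), b = c(2, 3, 4))
  shifted <- list(a = c(1, 2, 3), b = c(2, 3, 4) + 1000)
  expect_gt(one_way_anova(shifted)$statistic, one_way_anova(base)$statistic)
  expect_error(one_way_anova(list(a = c(1, 1), b = c(2, 2))), "undefined")
})
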