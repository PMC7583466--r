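test_that("Bray-Curtis dissimilarity has its metric properties and hand value", {
  m <- rbind(a = c(1, 3), b = c(3, 1), c = c(1, 3), d = c(0, 0), e = c(0, 0))
  d <- bray_curtis(m, transform = "none")
  expect_equal(d["a", "b"], 0.5) # (|1-3| + |3-1|) / 8
  expect_equal(d["a", "c"], 0) # identical rows
  expect_equal(d["a", "d"], 1) # disjoint supports
  expect_equal(d["d", "e"], 0) # two all-zero rows defined as 0
  expect_true(all(diag(unclass(d)) == 0))
  expect_equal(unclass(d), t(unclass(d)))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(rbind(c(-1, 0), c(0, 1))), "non-negative")
  expect_error(bray_curtis(m[1, , drop = FALSE]), "at least 2")
})

test_that("square-root transform matches vegan's Bray-Curtis on counts", {
  set.seed(8)
  counts <- matrix(rpois(60, 4), nrow = 6)
  rownames(counts) <- paste0("s", 1:6)
  ours <- bray_curtis(counts, transform = "sqrt")
  ref <- as.matrix(vegan::vegdist(sqrt(counts), method = "bray"))
  expect_equal(unclass(ours), ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("ANOSIM attains R = 1 under perfect separation and matches vegan", {
  # construct D where every between-group dissimilarity exceeds every within
  set.seed(14)
  g <- rep(c("x", "y"), each = 4)
  d <- matrix(0, 8, 8)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      d[i, j] <- d[j, i] <- if (g[i] == g[j]) runif(1, 0, 0.2) else runif(1, 0.5, 1)
    }
  }
  res <- avipref::anosim(d, g, n_perm = 99, seed = 2)
  expect_equal(res$statistic, 1)
  # only relabellings reproducing the partition tie R = 1: p stays small
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 0.15)
  # agreement with vegan on unstructured data
  dm <- bray_curtis(matrix(rpois(80, 5), nrow = 8))
  ref <- vegan::anosim(stats::as.dist(unclass(dm)), g, permutations = 99)
  ours <- avipref::anosim(dm, g, n_perm = 99, seed = 3)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("ANOSIM R is centred near zero for structureless dissimilarities", {
  set.seed(15)
  g <- rep(c("a", "b", "c"), each = 4)
  rs <- replicate(200, {
    d <- as.matrix(stats::dist(matrix(rnorm(24), nrow = 12)))
    avipref::anosim(d, sample(g), n_perm = 0)$statistic
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_true(all(rs >= -1 & rs <= 1))
})

test_that("ANOSIM R is invariant to monotone transforms of the dissimilarities", {
  set.seed(16)
  d <- as.matrix(stats::dist(matrix(rnorm(16), nrow = 8)))
  g <- rep(c("a", "b"), each = 4)
  r1 <- avipref::anosim(d, g, n_perm = 0)$statistic
  r2 <- avipref::anosim(d^2, g, n_perm = 0)$statistic
  r3 <- avipref::anosim(log1p(d), g, n_perm = 0)$statistic
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})

test_that("ANOSIM rejects degenerate inputs and reports pairwise contrasts", {
  d <- as.matrix(stats::dist(matrix(rnorm(12), nrow = 6)))
  expect_error(avipref::anosim(d, c("a", "a", "a", "a", "a", "b")), ">= 2 groups")
  expect_error(avipref::anosim(matrix(1, 6, 6) - diag(6) * 0, rep(c("a", "b"), 3)),
    "constant")
  set.seed(17)
  d9 <- as.matrix(stats::dist(matrix(rnorm(27), nrow = 9)))
  res <- avipref::anosim(d9, rep(c("a", "b", "c"), each = 3), n_perm = 49, seed = 1)
  expect_equal(nrow(res$pairwise), 3L)
  expect_equal(res$pairwise$alpha, rep(0.05 / 3, 3))
  expect_true(all(res$pairwise$p_value >= 1 / 50))
})

test_that("one-way ANOVA matches the hand-computed table and the two-group t-test", {
  # 3 x 3 example: SSB = 14 (df 2), SSW = 6 (df 6), F = 7
  vals <- c(1, 2, 3, 2, 3, 4, 4, 5, 6)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  res <- one_way_anova(vals, grp)
  expect_equal(res$F, 7)
  expect_equal(c(res$df1, res$df2), c(2, 6))
  expect_equal(res$p_value, stats::pf(7, 2, 6, lower.tail = FALSE))
  # two groups: F = t^2
  set.seed(18)
  v2 <- rnorm(20)
  g2 <- rep(c("a", "b"), each = 10)
  tt <- stats::t.test(v2 ~ g2, var.equal = TRUE)
  res2 <- one_way_anova(v2, g2)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-12)
  expect_error(one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")), "undefined")
})

test_that("Kruskal-Wallis separates ordered groups and rejects all-tied data", {
  # fully separated rank layout maximizes H across random relabellings
  vals <- c(1, 2, 3, 4, 11, 12, 13, 14, 21, 22, 23, 24)
  grp <- rep(c("a", "b", "c"), each = 4)
  h_obs <- kruskal_wallis(vals, grp)$H
  set.seed(19)
  h_perm <- replicate(100, kruskal_wallis(sample(vals), grp)$H)
  expect_true(all(h_obs >= h_perm))
  expect_error(kruskal_wallis(rep(3, 8), rep(c("a", "b"), 4)), "tied")
  # null p-values are approximately uniform
  set.seed(20)
  ps <- replicate(300, kruskal_wallis(rnorm(45), rep(c("a", "b", "c"), each = 15))$p_value)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.001)
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum decision", {
  set.seed(22)
  v <- c(rnorm(12), rnorm(12) + 2)
  g <- rep(c("a", "b"), each = 12)
  kw <- kruskal_wallis(v, g)
  mw <- suppressWarnings(stats::wilcox.test(v ~ g, exact = FALSE, correct = FALSE))
  expect_equal(kw$p_value < 0.05, mw$p.value < 0.05)
  expect_equal(kw$p_value, mw$p.value, tolerance = 1e-6)
})

test_that("pairwise contrasts flag the shifted group and assign letters", {
  set.seed(24)
  base <- rnorm(30)
  vals <- c(base[1:10], base[11:20], base[21:30] + 10)
  grp <- rep(c("low", "medium", "high"), each = 10)
  for (method in c("tukey", "rank")) {
    res <- pairwise_contrasts(vals, grp, method = method)
    involved <- res$pairs$group1 == "high" | res$pairs$group2 == "high"
    expect_equal(res$pairs$significant, involved)
    expect_equal(res$letters[["low"]], res$letters[["medium"]])
    expect_false(res$letters[["high"]] == res$letters[["low"]])
  }
  # identical spread, same values in every group: nothing significant
  same <- rep(c(1, 2, 3, 4, 5), 3)
  res0 <- pairwise_contrasts(same, rep(c("a", "b", "c"), each = 5))
  expect_false(any(res0$pairs$significant))
  expect_equal(unique(unlist(res0$letters)), "A")
  expect_error(pairwise_contrasts(c(1, 2, 3), c("a", "a", "b")), ">= 2 observations")
})

test_that("Spearman rho matches the classical rank formula with a valid permutation p", {
  expect_equal(spearman_rho(1:8, (1:8)^3, n_perm = 99)$rho, 1)
  expect_equal(spearman_rho(1:8, -(1:8), n_perm = 99)$rho, -1)
  # tied example against R's own Spearman estimate
  x <- c(1, 2, 2, 3, 5, 5, 7)
  y <- c(2, 1, 4, 4, 6, 8, 8)
  res <- spearman_rho(x, y, n_perm = 999, seed = 4)
  expect_equal(res$rho, stats::cor(x, y, method = "spearman"))
  expect_gte(res$p_value, 1 / 1000)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), ">= 3")
  # seeding makes the permutation p reproducible
  expect_equal(
    spearman_rho(x, y, n_perm = 199, seed = 9)$p_value,
    spearman_rho(x, y, n_perm = 199, seed = 9)$p_value
  )
})
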