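test_that("route generation honours the balanced income design", {
  set.seed(40)
  routes <- generate_routes(sim_config())
  expect_equal(nrow(routes), 36L)
  expect_equal(unname(table(routes$income_class)[c("low", "medium", "high")]),
    rep(12L, 3), ignore_attr = TRUE)
  expect_true(all(routes$length_km > 0))
  # income values are consistent with their class
  expect_equal(classify_income(routes$median_income), routes$income_class)
  # empty design
  empty <- generate_routes(sim_config(n_routes_per_class = 0))
  expect_equal(nrow(empty), 0L)
})

test_that("a fixed seed reproduces the whole study exactly", {
  a <- simulate_study(sim_config(n_routes_per_class = 2), seed = 77)
  b <- simulate_study(sim_config(n_routes_per_class = 2), seed = 77)
  expect_identical(a, b)
})

test_that("per-class tree densities match the configured gradient", {
  cfg <- sim_config()
  mean_dens <- matrix(0, 3, 20, dimnames = list(c("low", "medium", "high"), NULL))
  for (s in 1:20) {
    set.seed(s)
    routes <- generate_routes(cfg)
    trees <- generate_inventory(routes, cfg)
    n <- table(factor(trees$route_id, levels = routes$route_id))
    d <- tapply(as.numeric(n) / routes$length_km, routes$income_class, mean)
    mean_dens[, s] <- d[rownames(mean_dens)]
  }
  got <- rowMeans(mean_dens)
  target <- c(low = 54, medium = 81, high = 113)
  expect_true(all(abs(got - target) / target < 0.10))
  # the luxury-effect ordering holds
  expect_true(got["low"] < got["medium"] && got["medium"] < got["high"])
})

test_that("degenerate generator settings give empty outputs", {
  cfg0 <- sim_config(density_by_class = c(low = 0, medium = 0, high = 0))
  set.seed(41)
  routes <- generate_routes(cfg0)
  expect_equal(nrow(generate_inventory(routes, cfg0)), 0L)
  cfg_noobs <- sim_config(obs_rate = 0)
  set.seed(42)
  st_routes <- generate_routes(cfg_noobs)
  inv <- generate_inventory(st_routes, cfg_noobs)
  det <- generate_foraging(inv, st_routes, cfg_noobs)
  expect_equal(nrow(det), 0L)
  expect_true(all(c("route_id", "bird_species", "trees", "position_m") %in% names(det)))
})

test_that("species shares in large inventories track their generative weights", {
  # with natives at fraction p and log-series weights w_k for nonnatives,
  # the expected count share of nonnative rank 1 is (1 - p) * w_1
  cfg <- sim_config()
  set.seed(43)
  routes <- generate_routes(cfg)
  trees <- generate_inventory(routes, cfg)
  k <- seq_len(cfg$n_species - cfg$n_native)
  w <- cfg$sad_x^k / k
  w1 <- w[1] / sum(w)
  # class mix: weight classes by their expected tree totals
  exp_trees <- cfg$density_by_class * tapply(routes$length_km, routes$income_class, sum)[
    names(cfg$density_by_class)
  ]
  p_nat <- sum(cfg$native_fraction_by_class[names(exp_trees)] * exp_trees) / sum(exp_trees)
  expected_share <- (1 - p_nat) * w1
  got_share <- mean(trees$species == "southern magnolia")
  expect_lt(abs(got_share - expected_share), 0.02)
  # native fraction close to its class-weighted expectation
  expect_lt(abs(mean(trees$origin == "native") - p_nat), 0.01)
})

test_that("feeding draws are availability-weighted: null multipliers recover no preference", {
  cfg <- sim_config(obs_rate = 0.21) # ~5000 foraging observations
  set.seed(44)
  st <- simulate_study(cfg, seed = 44)
  obs <- reduce_observations(st$detections)
  iv <- importance_values(st$trees, st$routes)
  pt <- preference_table(obs, iv, grouping = "total")
  expect_gt(sum(pt$n_obs), 3000)
  expect_true(all(abs(pt$preference_index) < 2))
})

test_that("a tripled preference multiplier is recovered as roughly tripled use", {
  cfg <- sim_config(preference_multipliers = c("carrotwood" = 3))
  pu <- vapply(1:8, function(s) {
    st <- simulate_study(cfg, seed = 100 + s)
    obs <- reduce_observations(st$detections)
    iv <- importance_values(st$trees, st$routes)
    pt <- preference_table(obs, iv, grouping = "total")
    pt$proportional_use[pt$species == "carrotwood"]
  }, numeric(1))
  # expected use/availability: 300% shrunk by the boosted species' own share
  expect_lt(abs(mean(pu) - 300) / 300, 0.15)
})

test_that("the luxury-effect gradient is recovered by the group tests", {
  set.seed(45)
  st <- simulate_study(seed = 45)
  obs <- reduce_observations(st$detections)
  rs <- route_summary(st$trees, obs, st$routes)
  kw <- kruskal_wallis(rs$tree_density, rs$income_class)
  expect_lt(kw$p_value, 0.05)
  pc <- pairwise_contrasts(rs$tree_density, rs$income_class, method = "rank")
  hl <- pc$pairs$significant[
    (pc$pairs$group1 == "high" & pc$pairs$group2 == "low") |
      (pc$pairs$group1 == "low" & pc$pairs$group2 == "high")
  ]
  expect_true(hl)
  # fully disjoint class-specific species pools force strong ANOSIM separation
  counts <- route_species_counts(st$trees, st$routes)
  disjoint <- matrix(0, nrow(counts), 3 * ncol(counts), dimnames = list(rownames(counts), NULL))
  cls <- match(st$routes$income_class, c("low", "medium", "high"))
  for (i in seq_len(nrow(counts))) {
    disjoint[i, (cls[i] - 1) * ncol(counts) + seq_len(ncol(counts))] <- counts[i, ]
  }
  res <- avipref::anosim(bray_curtis(disjoint), st$routes$income_class,
    n_perm = 199, seed = 5)
  expect_gt(res$statistic, 0)
  expect_lte(res$p_value, 0.05)
})

test_that("tree availability is the best-supported predictor of generated bird density", {
  preds <- c("richness_per_km", "shannon", "tree_density", "basal_area")
  top <- vapply(1:25, function(s) {
    st <- simulate_study(seed = 200 + s)
    obs <- reduce_observations(st$detections)
    rs <- route_summary(st$trees, obs, st$routes)
    ms <- fit_model_set(rs, "total_density", preds)
    ms$predictor[1] %in% c("tree_density", "basal_area") &&
      ms$delta_aic[ms$predictor == "intercept_only"] > 2
  }, logical(1))
  expect_gte(mean(top), 0.9)
})
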