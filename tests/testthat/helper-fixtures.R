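# small in-code fixtures shared across test files

two_route_meta <- function() {
  data.frame(
    route_id = c("r1", "r2"), length_km = c(2.0, 2.5),
    income_class = c("low", "high"), median_income = c(45000, 90000),
    stringsAsFactors = FALSE
  )
}

# two species, equal counts, basal-area totals 3 m^2 vs 1 m^2
# (dbh giving basal area 1.5 and 0.5 m^2 per tree)
two_species_trees <- function() {
  dbh_for_ba <- function(ba) 200 * sqrt(ba / pi)
  data.frame(
    route_id = rep(c("r1", "r2"), each = 2),
    species = c("A", "B", "A", "B"),
    origin = "nonnative",
    dbh_cm = dbh_for_ba(c(1.5, 0.5, 1.5, 0.5)),
    position_m = c(10, 500, 20, 700),
    stringsAsFactors = FALSE
  )
}

raw_detection <- function(route_id = "r1", visit_id = 1, bird_species = "Yellow-rumped Warbler",
                          group = "migratory", trees = "Chinese elm",
                          flock_size = 1L, flock_members = bird_species,
                          sex_distinct = FALSE, position_m = 0,
                          substrate = "leaf", duration_s = 45) {
  data.frame(
    route_id = route_id, visit_id = visit_id, bird_species = bird_species,
    group = group, trees = trees, flock_size = flock_size,
    flock_members = flock_members, sex_distinct = sex_distinct,
    position_m = position_m, substrate = substrate, duration_s = duration_s,
    stringsAsFactors = FALSE
  )
}

# observation rows (already reduced) on given tree species
obs_on <- function(tree_species, group = "migratory", bird_species = "Yellow-rumped Warbler") {
  data.frame(
    route_id = "r1", visit_id = 1, bird_species = bird_species, group = group,
    tree_species = tree_species, position_m = seq_along(tree_species) * 200,
    stringsAsFactors = FALSE
  )
}

# minimal importance table for preference arithmetic
iv_fixture <- function(species, iv) {
  data.frame(species = species, importance_value = iv, stringsAsFactors = FALSE)
}

# ANOSIM R computed straight from its definition (test-side oracle)
anosim_r_oracle <- function(d, groups) {
  lower <- lower.tri(d)
  ranks <- rank(d[lower])
  within <- (groups[row(d)[lower]] == groups[col(d)[lower]])
  m <- length(ranks)
  (mean(ranks[!within]) - mean(ranks[within])) / (m / 2)
}
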