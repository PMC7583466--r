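#' Configuration for the synthetic street-tree / foraging-bird generator
#'
#' Builds the parameter list driving [generate_routes()],
#' [generate_inventory()] and [generate_foraging()]. The defaults emulate
#' the study conditions of the Los Angeles winter surveys: 36 routes of
#' about 2.49 km, 12 per income class, class-mean tree densities of 54 / 81
#' / 113 trees per km and basal areas of 17 / 29 / 80 m^2 per km (the
#' luxury-effect gradient), an 85-species pool with a log-series abundance
#' distribution in which 5 species are native (two of them common) and
#' natives are enriched in high-income communities, and a detection rate
#' calibrated so four visits to all routes yield on the order of 900
#' reduced feeding observations.
#'
#' @param n_routes_per_class routes per income class (default 12).
#' @param route_length_km mean and sd of route length, km.
#' @param density_by_class named class means, trees per km.
#' @param basal_by_class named class means, m^2 basal area per km.
#' @param n_species size of the species pool (default 85).
#' @param n_native number of native species (default 5; the first two are
#'   common, the rest rare).
#' @param native_fraction_by_class expected fraction of trees that are
#'   native, per class (natives concentrate in high-income areas).
#' @param sad_x log-series parameter for nonnative abundance ranks
#'   (weight of rank k proportional to `sad_x^k / k`).
#' @param dbh_sigma within-species lognormal sd of DBH (log scale).
#' @param species_sigma between-species sd of mean log DBH.
#' @param preference_multipliers named non-negative weights `w` multiplying
#'   a tree species' availability in the feeding draw (`w > 1` makes the
#'   species preferred, `w < 1` avoided); species not named have `w = 1`.
#' @param obs_rate expected raw detections per tree per visit.
#' @param n_visits visits per route (default 4).
#' @param route_disp_cv coefficient of variation of a per-route gamma
#'   multiplier on detection intensity (extra-Poisson spread between
#'   routes; 0 disables it).
#' @param p_flock probability a detection of a flocking species is a flock.
#' @param p_mixed probability a flock is mixed-species.
#' @param flock_size_lambda Poisson mean of (flock size - 2).
#' @param p_second_tree probability a bout continues onto a second tree.
#' @param p_sex_distinct probability a detection of a sexually dimorphic
#'   species is marked male/female-distinct.
#' @param income_thresholds passed to [classify_income()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_routes_per_class = 12,
                       route_length_km = c(mean = 2.49, sd = 0.1),
                       density_by_class = c(low = 54, medium = 81, high = 113),
                       basal_by_class = c(low = 17, medium = 29, high = 80),
                       n_species = 85,
                       n_native = 5,
                       native_fraction_by_class = c(low = 0.010, medium = 0.013, high = 0.070),
                       sad_x = 0.97,
                       dbh_sigma = 0.45,
                       species_sigma = 0.15,
                       preference_multipliers = numeric(0),
                       obs_rate = 0.031,
                       n_visits = 4,
                       route_disp_cv = 0.3,
                       p_flock = 0.5,
                       p_mixed = 0.15,
                       flock_size_lambda = 4,
                       p_second_tree = 0.2,
                       p_sex_distinct = 0.5,
                       income_thresholds = c(low_max = 53219, high_min = 70720)) {
  stopifnot(
    all(density_by_class >= 0), all(basal_by_class >= 0), obs_rate >= 0,
    all(preference_multipliers >= 0), n_native >= 2, n_species > n_native
  )
  if (is.unsorted(density_by_class) || is.unsorted(basal_by_class)) {
    stop("class means must be ordered low < medium < high (luxury effect)", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

native_species_pool <- function(n_native) {
  pool <- c(
    "coast live oak", "California sycamore", "Engelmann oak",
    "California bay", "toyon"
  )
  pool[seq_len(min(n_native, length(pool)))]
}

nonnative_species_pool <- function(n) {
  named <- c(
    "southern magnolia", "common crape myrtle", "American sweetgum",
    "camphor tree", "Chinese elm", "Italian stone pine", "carrotwood",
    "Mexican fan palm", "London plane tree", "southern live oak",
    "Brisbane box", "deodar cedar", "Brachychiton spp.", "Indian laurel fig",
    "carob", "holly oak", "Canary Island date palm", "Fraxinus spp.",
    "jacaranda", "unknown nonnative"
  )
  if (n <= length(named)) {
    named[seq_len(n)]
  } else {
    c(named, sprintf("nonnative sp. %02d", seq_len(n - length(named))))
  }
}

#' Bird species pools and groups of the synthetic surveys
#'
#' Five wintering migratory species and five year-round residents, with
#' relative encounter weights matching their observed commonness.
#'
#' @return data.frame with `bird_species`, `group`, `weight`, `flocking`,
#'   `dimorphic`.
#' @export
bird_pool <- function() {
  data.frame(
    bird_species = c(
      "Yellow-rumped Warbler", "Ruby-crowned Kinglet", "Townsend's Warbler",
      "Orange-crowned Warbler", "Black-throated Gray Warbler",
      "Bushtit", "House Finch", "Lesser Goldfinch",
      "Anna's Hummingbird", "Allen's Hummingbird"
    ),
    group = rep(c("migratory", "year_round"), each = 5L),
    weight = c(348, 136, 69, 23, 10, 141, 96, 61, 30, 23),
    flocking = c(rep(FALSE, 5L), TRUE, TRUE, TRUE, FALSE, FALSE),
    dimorphic = c(rep(FALSE, 5L), FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate route metadata along the income gradient
#'
#' @param config a [sim_config()].
#' @return data.frame with `route_id`, `length_km`, `income_class`,
#'   `median_income`; `n_routes_per_class` routes per class, incomes drawn
#'   within the class band so the tercile classification is consistent.
#' @export
generate_routes <- function(config = sim_config()) {
  k <- config$n_routes_per_class
  if (k == 0L) {
    return(data.frame(
      route_id = character(0), length_km = numeric(0),
      income_class = character(0), median_income = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  classes <- rep(c("low", "medium", "high"), each = k)
  n <- length(classes)
  len <- stats::rnorm(n, config$route_length_km["mean"], config$route_length_km["sd"])
  len <- pmax(len, 0.5)
  thr <- config$income_thresholds
  income <- vapply(classes, function(cl) {
    switch(cl,
      low = stats::runif(1, 30000, thr[1]),
      medium = stats::runif(1, thr[1] + 1, thr[2] - 1),
      high = stats::runif(1, thr[2], 160000)
    )
  }, numeric(1))
  data.frame(
    route_id = sprintf("R%02d", seq_len(n)),
    length_km = len,
    income_class = classes,
    median_income = round(income),
    stringsAsFactors = FALSE
  )
}

species_probs <- function(config) {
  natives <- native_species_pool(config$n_native)
  nonnat <- nonnative_species_pool(config$n_species - config$n_native)
  k <- seq_along(nonnat)
  w_nn <- config$sad_x^k / k
  w_nn <- w_nn / sum(w_nn)
  # within natives: two common species carry most of the native share
  w_nat <- c(0.62, 0.26, rep(0.12 / max(1, length(natives) - 2), max(0, length(natives) - 2)))
  w_nat <- w_nat[seq_along(natives)] / sum(w_nat[seq_along(natives)])
  list(natives = natives, nonnatives = nonnat, w_nat = w_nat, w_nn = w_nn)
}

#' Generate a street-tree inventory for a set of routes
#'
#' Per-route tree counts are Poisson in the class density times route
#' length; species follow a log-series abundance distribution with the
#' native share enriched in high-income routes; DBH is lognormal per
#' species, scaled per class so the expected basal area matches the class
#' target; positions are uniform along the route.
#'
#' @param routes output of [generate_routes()].
#' @param config a [sim_config()].
#' @return data.frame of trees: `route_id`, `species`, `origin`, `dbh_cm`,
#'   `position_m`.
#' @export
generate_inventory <- function(routes, config = sim_config()) {
  empty <- data.frame(
    route_id = character(0), species = character(0), origin = character(0),
    dbh_cm = numeric(0), position_m = numeric(0), stringsAsFactors = FALSE
  )
  if (nrow(routes) == 0L) stop("`routes` is empty", call. = FALSE)
  sp <- species_probs(config)
  all_species <- c(sp$natives, sp$nonnatives)
  # per-species DBH size effect, mean-corrected so class basal-area targets hold
  e_s <- stats::rnorm(length(all_species), 0, config$species_sigma)
  e_s <- stats::setNames(e_s - config$species_sigma^2, all_species)
  sigma <- config$dbh_sigma
  out <- vector("list", nrow(routes))
  for (i in seq_len(nrow(routes))) {
    cl <- routes$income_class[i]
    dens <- config$density_by_class[[cl]]
    n <- stats::rpois(1, dens * routes$length_km[i])
    if (n == 0L) {
      out[[i]] <- empty
      next
    }
    p_nat <- config$native_fraction_by_class[[cl]]
    probs <- c(p_nat * sp$w_nat, (1 - p_nat) * sp$w_nn)
    species <- sample(all_species, n, replace = TRUE, prob = probs)
    # class target: mean squared DBH (cm^2) giving basal_by_class/density_by_class m^2/tree
    target_dbh2 <- (config$basal_by_class[[cl]] / dens) * 4e4 / pi
    mu_class <- 0.5 * log(target_dbh2) - sigma^2
    dbh <- stats::rlnorm(n, mu_class + e_s[species], sigma)
    out[[i]] <- data.frame(
      route_id = routes$route_id[i],
      species = species,
      origin = resolve_origin(species, sp$natives),
      dbh_cm = dbh,
      position_m = stats::runif(n, 0, routes$length_km[i] * 1000),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate raw bird-foraging detections over an inventory
#'
#' Detection events arrive Poisson at `obs_rate` per tree per visit, with a
#' persistent per-route gamma multiplier (extra-Poisson heterogeneity).
#' Each detection's tree is drawn with probability proportional to
#' availability times the species' preference multiplier, where a tree's
#' availability is half its count share plus half its basal-area share —
#' so a species' total draw weight is proportional to its importance value
#' times `w`. Flocks are generated for the flocking year-round species, a
#' fraction of bouts continue onto a second tree, and positions are the
#' positions of the trees fed on, so the 100-m pseudo-replication rule is
#' exercised on reduction.
#'
#' @param inventory output of [generate_inventory()].
#' @param routes output of [generate_routes()].
#' @param config a [sim_config()].
#' @return data.frame of raw detections with columns `route_id`, `visit_id`,
#'   `bird_species`, `group`, `trees`, `flock_size`, `flock_members`,
#'   `sex_distinct`, `position_m`, `substrate`, `duration_s`.
#' @export
generate_foraging <- function(inventory, routes, config = sim_config()) {
  if (nrow(inventory) == 0L) stop("`inventory` is empty", call. = FALSE)
  birds <- bird_pool()
  n_tot <- nrow(inventory)
  ba <- basal_area_from_dbh(inventory$dbh_cm)
  avail <- 0.5 / n_tot + 0.5 * ba / sum(ba)
  w <- rep(1, n_tot)
  if (length(config$preference_multipliers) > 0L) {
    m <- config$preference_multipliers[inventory$species]
    w <- ifelse(is.na(m), 1, unname(m))
  }
  g <- rep(1, nrow(routes))
  if (config$route_disp_cv > 0) {
    shape <- 1 / config$route_disp_cv^2
    g <- stats::rgamma(nrow(routes), shape = shape, rate = shape)
  }
  g_tree <- g[match(inventory$route_id, routes$route_id)]
  weight <- avail * w * g_tree
  p_mig <- sum(birds$weight[birds$group == "migratory"]) / sum(birds$weight)
  res <- vector("list", config$n_visits)
  for (v in seq_len(config$n_visits)) {
    n_det <- stats::rpois(1, config$obs_rate * n_tot)
    if (n_det == 0L) {
      res[v] <- list(NULL)
      next
    }
    tree_idx <- sample.int(n_tot, n_det, replace = TRUE, prob = weight)
    mig <- stats::runif(n_det) < p_mig
    pick_bird <- function(grp, n) {
      b <- birds[birds$group == grp, ]
      sample(b$bird_species, n, replace = TRUE, prob = b$weight)
    }
    bird <- character(n_det)
    bird[mig] <- pick_bird("migratory", sum(mig))
    bird[!mig] <- pick_bird("year_round", sum(!mig))
    info <- birds[match(bird, birds$bird_species), ]
    is_flock <- info$flocking & stats::runif(n_det) < config$p_flock
    flock_size <- ifelse(is_flock, 2L + stats::rpois(n_det, config$flock_size_lambda), 1L)
    is_mixed <- is_flock & stats::runif(n_det) < config$p_mixed
    members <- bird
    if (any(is_mixed)) {
      flockers <- birds$bird_species[birds$flocking]
      other <- vapply(bird[is_mixed], function(b) {
        sample(setdiff(flockers, b), 1L)
      }, character(1))
      members[is_mixed] <- paste(bird[is_mixed], other, sep = ";")
    }
    sexd <- info$dimorphic & stats::runif(n_det) < config$p_sex_distinct
    trees <- inventory$species[tree_idx]
    second <- stats::runif(n_det) < config$p_second_tree
    if (any(second)) {
      rid <- inventory$route_id[tree_idx[second]]
      extra <- vapply(rid, function(r) {
        cand <- which(inventory$route_id == r)
        inventory$species[sample(cand, 1L)]
      }, character(1))
      trees[second] <- paste(trees[second], extra, sep = ";")
    }
    res[[v]] <- data.frame(
      route_id = inventory$route_id[tree_idx],
      visit_id = v,
      bird_species = bird,
      group = info$group,
      trees = trees,
      flock_size = flock_size,
      flock_members = members,
      sex_distinct = sexd,
      position_m = inventory$position_m[tree_idx],
      substrate = sample(c("leaf", "bark", "flower", "seed", "aerial"),
        n_det,
        replace = TRUE, prob = c(0.45, 0.2, 0.15, 0.15, 0.05)
      ),
      duration_s = pmin(180, 1 + round(stats::rexp(n_det, 1 / 46))),
      stringsAsFactors = FALSE
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(
      route_id = character(0), visit_id = integer(0), bird_species = character(0),
      group = character(0), trees = character(0), flock_size = integer(0),
      flock_members = character(0), sex_distinct = logical(0),
      position_m = numeric(0), substrate = character(0), duration_s = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Routes, street-tree inventory and raw foraging detections in one call.
#'
#' @param config a [sim_config()].
#' @param seed optional RNG seed (one seed reproduces the whole study).
#' @return list with elements `routes`, `trees`, `detections`, and
#'   `native_species` (the configured native list).
#' @export
simulate_study <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  routes <- generate_routes(config)
  trees <- generate_inventory(routes, config)
  detections <- generate_foraging(trees, routes, config)
  list(
    routes = routes, trees = trees, detections = detections,
    native_species = native_species_pool(config$n_native)
  )
}
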