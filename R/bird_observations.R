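#' Collapse flocks into single feeding-observation units
#'
#' A flock of one bird species feeding on a tree counts as a single
#' observation unit, so that a large mobile flock does not inflate the
#' apparent importance of one tree. A mixed-species flock contributes one
#' unit per member species. Single birds pass through unchanged.
#'
#' @param detections data.frame of raw detections with at least
#'   `bird_species` and `flock_members` (a `";"`-separated list of the bird
#'   species in the flock; for a single bird, its own species or `""`).
#'   A `group` column, if present, is re-resolved per member through
#'   `group_map` when supplied.
#' @param group_map optional named character vector mapping bird species to
#'   `"migratory"`/`"year_round"`, used to relabel the `group` of members of
#'   mixed flocks.
#' @return data.frame with one row per collapsed unit; `flock_members` is
#'   reduced to the single member species of each row.
#' @export
collapse_flocks <- function(detections, group_map = NULL) {
  stopifnot(is.data.frame(detections))
  if (nrow(detections) == 0L) return(detections)
  members <- as.character(detections$flock_members)
  members[is.na(members) | members == ""] <- as.character(detections$bird_species)[
    is.na(members) | members == ""
  ]
  member_list <- strsplit(members, ";", fixed = TRUE)
  if (any(lengths(member_list) == 0L)) {
    stop("flock with empty member set", call. = FALSE)
  }
  reps <- lengths(member_list)
  out <- detections[rep(seq_len(nrow(detections)), reps), , drop = FALSE]
  out$bird_species <- unlist(member_list)
  out$flock_members <- out$bird_species
  if (!is.null(group_map) && "group" %in% names(out)) {
    mapped <- group_map[out$bird_species]
    out$group <- ifelse(is.na(mapped), out$group, unname(mapped))
  }
  rownames(out) <- NULL
  out
}

#' Drop pseudo-replicated detections with the 100-m rule
#'
#' Walking a route, a second detection of the same bird species within 100 m
#' of where the previous retained observation of that species ended is
#' treated as a possible re-sight of the same individual and dropped, unless
#' the two birds were visibly distinct (male vs female plumage,
#' `sex_distinct = TRUE`). The rule is applied independently within each
#' route x visit, against the previous *retained* detection of the species.
#'
#' @param detections data.frame with `route_id`, `visit_id`, `bird_species`,
#'   `position_m`, and optionally `sex_distinct` (logical, default `FALSE`).
#' @param min_distance_m minimum spacing, metres (default 100).
#' @return the retained detections, ordered by route, visit and position.
#' @export
dedupe_observations <- function(detections, min_distance_m = 100) {
  stopifnot(is.data.frame(detections))
  if (nrow(detections) == 0L) return(detections)
  sexd <- if ("sex_distinct" %in% names(detections)) {
    as.logical(detections$sex_distinct)
  } else {
    rep(FALSE, nrow(detections))
  }
  sexd[is.na(sexd)] <- FALSE
  ord <- order(detections$route_id, detections$visit_id, detections$position_m)
  detections <- detections[ord, , drop = FALSE]
  sexd <- sexd[ord]
  key <- paste(detections$route_id, detections$visit_id, detections$bird_species, sep = "\r")
  keep <- logical(nrow(detections))
  last_pos <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(detections))) {
    prev <- get0(key[i], envir = last_pos, ifnotfound = NULL)
    if (is.null(prev) || detections$position_m[i] - prev > min_distance_m || sexd[i]) {
      keep[i] <- TRUE
      assign(key[i], detections$position_m[i], envir = last_pos)
    }
  }
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only the first tree of a multi-tree foraging bout
#'
#' A bird followed across several trees contributes a single observation:
#' the behaviour on the first tree on which it was observed.
#'
#' @param detections data.frame with a `trees` column, a `";"`-separated
#'   ordered list of the tree species fed on during the bout.
#' @return the same data.frame with a `tree_species` column holding the first
#'   tree of each bout (the `trees` column is retained).
#' @export
first_tree_rule <- function(detections) {
  stopifnot(is.data.frame(detections), "trees" %in% names(detections))
  trees <- as.character(detections$trees)
  if (nrow(detections) > 0L && any(is.na(trees) | trees == "")) {
    stop("foraging bout with empty tree list", call. = FALSE)
  }
  detections$tree_species <- vapply(
    strsplit(trees, ";", fixed = TRUE),
    function(x) x[[1]], character(1)
  )
  detections
}

#' Reduce raw detections to foraging-observation units
#'
#' Applies, in order, flock collapsing, the 100-m pseudo-replication rule and
#' the first-tree rule, and returns the reduced observation table used by all
#' downstream preference and density analyses. The reduction is idempotent.
#'
#' @inheritParams collapse_flocks
#' @inheritParams dedupe_observations
#' @param verbose if `TRUE`, message the number of units dropped by each rule.
#' @return data.frame of foraging observations with columns `route_id`,
#'   `visit_id`, `bird_species`, `group`, `tree_species`, `position_m` (plus
#'   pass-through columns).
#' @export
reduce_observations <- function(detections, group_map = NULL, min_distance_m = 100,
                                verbose = FALSE) {
  collapsed <- collapse_flocks(detections, group_map = group_map)
  deduped <- dedupe_observations(collapsed, min_distance_m = min_distance_m)
  out <- first_tree_rule(deduped)
  if (verbose) {
    message(
      "flock collapsing: ", nrow(detections), " detections -> ",
      nrow(collapsed), " units; 100-m rule dropped ",
      nrow(collapsed) - nrow(deduped), "; ", nrow(out), " observations retained"
    )
  }
  rownames(out) <- NULL
  out
}

#' Per-route feeding-bird density
#'
#' Sums foraging observations per route across all visits and standardizes to
#' one km of walking route.
#'
#' @param observations reduced observation data.frame (`route_id`, `group`).
#' @param routes data.frame with `route_id`, `length_km`.
#' @param group one of `"migratory"`, `"year_round"`, `"total"`.
#' @return data.frame with `route_id`, `n_obs`, `density_per_km`, one row per
#'   route in `routes` (routes with no observations get 0).
#' @export
feeding_density <- function(observations, routes, group = c("total", "migratory", "year_round")) {
  group <- match.arg(group)
  stopifnot(is.data.frame(observations), is.data.frame(routes))
  unknown <- setdiff(unique(observations$route_id), routes$route_id)
  if (length(unknown) > 0L) {
    stop("observations reference unknown route_id(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (group != "total") {
    observations <- observations[observations$group == group, , drop = FALSE]
  }
  n <- table(factor(observations$route_id, levels = routes$route_id))
  data.frame(
    route_id = routes$route_id,
    n_obs = as.integer(n),
    density_per_km = standardize_per_km(as.numeric(n), routes$length_km),
    stringsAsFactors = FALSE
  )
}

#' Sensitivity of flock reduction: reduced units vs full tallies
#'
#' Rank correlation between the per-route count of reduced observation units
#' and the per-route tally of all individuals in flocks, to check that
#' counting each flock as one unit does not distort route-level effect sizes.
#'
#' @param reduced numeric vector of per-route reduced counts.
#' @param tallies numeric vector of per-route full individual tallies.
#' @param n_perm permutations for the p-value.
#' @param seed optional RNG seed.
#' @return a `spearman_result`, see [spearman_rho()].
#' @export
flock_sensitivity <- function(reduced, tallies, n_perm = 10000, seed = NULL) {
  if (length(reduced) != length(tallies) || length(reduced) < 3L) {
    stop("need >= 3 paired per-route values", call. = FALSE)
  }
  spearman_rho(reduced, tallies, n_perm = n_perm, seed = seed)
}
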