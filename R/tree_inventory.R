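#' Basal area of a tree from its diameter at breast height
#'
#' Converts a diameter at breast height (DBH, cm) into the cross-sectional
#' area of the trunk at breast height in square metres, using the standard
#' forestry circle-area formula \eqn{\pi (d/200)^2}. Summed per species this
#' area is the species' "dominance".
#'
#' @param dbh_cm numeric vector of diameters at breast height, cm; all > 0.
#' @return numeric vector of basal areas, m^2.
#' @examples
#' basal_area_from_dbh(200 / sqrt(pi)) # exactly 1 m^2
#' @export
basal_area_from_dbh <- function(dbh_cm) {
  if (!is.numeric(dbh_cm) || anyNA(dbh_cm) || any(dbh_cm <= 0)) {
    stop("`dbh_cm` must be positive and non-missing", call. = FALSE)
  }
  pi * (dbh_cm / 200)^2
}

#' Standardize a route total to one kilometre of walking route
#'
#' @param total numeric vector of per-route totals (tree counts, basal areas,
#'   observation counts, ...).
#' @param length_km route length(s) in km; all > 0. Recycled against `total`.
#' @return `total / length_km`, a per-km quantity.
#' @export
standardize_per_km <- function(total, length_km) {
  if (!is.numeric(length_km) || anyNA(length_km) || any(length_km <= 0)) {
    stop("`length_km` must be positive and non-missing", call. = FALSE)
  }
  total / length_km
}

#' Classify a median household income into low / medium / high
#'
#' Tercile classification of census-tract median household income. The
#' default thresholds are the 2010-census terciles used for the Los Angeles
#' gradient: low below $53,220, medium $53,220 to $70,719, high at $70,720
#' and above.
#'
#' @param median_income numeric vector of incomes (currency units, >= 0).
#' @param thresholds numeric of length 2, `c(low_max, high_min)` with
#'   `low_max < high_min`: incomes `<= low_max` are low, `>= high_min` high.
#' @return character vector in `c("low", "medium", "high")`.
#' @export
classify_income <- function(median_income, thresholds = c(low_max = 53219, high_min = 70720)) {
  if (any(median_income < 0, na.rm = TRUE)) {
    stop("negative income is not a valid median household income", call. = FALSE)
  }
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2]) {
    stop("`thresholds` must be c(low_max, high_min) with low_max < high_min", call. = FALSE)
  }
  thresholds <- unname(thresholds)
  ifelse(median_income <= thresholds[1], "low",
    ifelse(median_income >= thresholds[2], "high", "medium")
  )
}

#' Resolve native/nonnative origin from a configured native-species list
#'
#' Labels on the native list are `"native"`; everything else (including
#' family-level groups and "unknown nonnative") defaults to `"nonnative"`.
#'
#' @param species character vector of tree species labels.
#' @param native_species character vector of labels treated as native.
#' @return character vector `"native"`/`"nonnative"`.
#' @export
resolve_origin <- function(species, native_species) {
  ifelse(species %in% native_species, "native", "nonnative")
}

#' Species importance values for a street-tree inventory
#'
#' For each tree species (or group of species) computes the count, per-km
#' density, per-km basal area (dominance), relative density, relative
#' dominance, and the importance value
#' \deqn{IV = (relative\ density + relative\ dominance) / 2,}
#' each relative value expressed as a percent of the community total. The
#' frequency term of classical importance values is deliberately not part of
#' the calculation: street-tree routes are censuses, not plot samples, so a
#' frequency metric is undefined here.
#'
#' By default relative values are computed over the pooled inventory across
#' all routes; `per_route = TRUE` instead returns one table per route.
#'
#' @param trees data.frame with columns `route_id`, `species`, `dbh_cm`
#'   (origin/position columns pass through unused).
#' @param routes data.frame with columns `route_id`, `length_km`.
#' @param grouping optional named character vector mapping species label to a
#'   group label (e.g. all native species to `"native"`); unmapped species
#'   keep their own label.
#' @param per_route if `TRUE`, return a named list of per-route tables.
#' @return a `species_importance` data.frame with columns `species`, `count`,
#'   `density_per_km`, `basal_area_m2_per_km`, `rel_density`, `rel_dominance`,
#'   `importance_value`, sorted by decreasing importance value.
#' @export
importance_values <- function(trees, routes, grouping = NULL, per_route = FALSE) {
  stopifnot(is.data.frame(trees), is.data.frame(routes))
  if (nrow(trees) == 0L) stop("empty inventory: no trees to summarize", call. = FALSE)
  need <- c("route_id", "species", "dbh_cm")
  if (!all(need %in% names(trees))) {
    stop("`trees` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(trees$route_id), routes$route_id)
  if (length(unknown) > 0L) {
    stop("trees reference unknown route_id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (per_route) {
    ids <- sort(unique(as.character(trees$route_id)))
    out <- lapply(ids, function(r) {
      importance_values(trees[trees$route_id == r, , drop = FALSE],
        routes[routes$route_id == r, , drop = FALSE],
        grouping = grouping
      )
    })
    names(out) <- ids
    return(out)
  }

  species <- as.character(trees$species)
  if (!is.null(grouping)) {
    mapped <- grouping[species]
    species <- ifelse(is.na(mapped), species, unname(mapped))
  }
  ba <- basal_area_from_dbh(trees$dbh_cm)
  # pooled convention: standardize by the summed length of all supplied routes
  total_km <- sum(routes$length_km)
  if (total_km <= 0) stop("route lengths must be positive", call. = FALSE)

  count <- tapply(ba, species, length)
  ba_sum <- tapply(ba, species, sum)
  tab <- data.frame(
    species = names(count),
    count = as.integer(count),
    density_per_km = standardize_per_km(as.numeric(count), total_km),
    basal_area_m2_per_km = standardize_per_km(as.numeric(ba_sum), total_km),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$rel_density <- 100 * tab$count / sum(tab$count)
  tab$rel_dominance <- 100 * as.numeric(ba_sum) / sum(ba_sum)
  tab$importance_value <- (tab$rel_density + tab$rel_dominance) / 2
  tab <- tab[order(-tab$importance_value, tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("species_importance", "data.frame")
  tab
}

#' @export
print.species_importance <- function(x, digits = 2, ...) {
  cat("Street-tree species importance (", nrow(x), " taxa, ",
    sum(x$count), " trees)\n",
    sep = ""
  )
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) & names(y) != "count"
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, ...)
  invisible(x)
}

#' Look up the importance value of one species
#'
#' @param iv_table a `species_importance` table.
#' @param species species label(s).
#' @return numeric importance value(s), in percent; `NA` for absent labels.
#' @export
iv_of <- function(iv_table, species) {
  iv_table$importance_value[match(species, iv_table$species)]
}
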