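#' Feeding proportions of a bird grouping across tree species
#'
#' The percentage of a bird grouping's foraging observations that fell on
#' each tree species of a species universe; species never fed on get 0.
#'
#' @param observations reduced observation data.frame with `tree_species`
#'   (and `group` / `bird_species` if `grouping` filters are used).
#' @param species_universe character vector of tree species labels defining
#'   the complete availability set (typically `iv_table$species`).
#' @param grouping `"total"`, `"migratory"`, `"year_round"`, or a bird
#'   species label: which observations to pool.
#' @return data.frame with `species`, `n_obs`, `use_pct`; `use_pct` sums to
#'   100 over the universe (observations on species outside the universe are
#'   rejected).
#' @export
feeding_proportions <- function(observations, species_universe, grouping = "total") {
  stopifnot(is.data.frame(observations), "tree_species" %in% names(observations))
  obs <- switch(grouping,
    total = observations,
    migratory = ,
    year_round = observations[observations$group == grouping, , drop = FALSE],
    observations[observations$bird_species == grouping, , drop = FALSE]
  )
  if (nrow(obs) == 0L) {
    stop("no observations in grouping '", grouping, "'", call. = FALSE)
  }
  outside <- setdiff(unique(obs$tree_species), species_universe)
  if (length(outside) > 0L) {
    stop(
      "observations on species outside the universe: ",
      paste(outside, collapse = ", "),
      call. = FALSE
    )
  }
  n <- table(factor(obs$tree_species, levels = species_universe))
  data.frame(
    species = species_universe,
    n_obs = as.integer(n),
    use_pct = 100 * as.numeric(n) / sum(n),
    stringsAsFactors = FALSE
  )
}

#' Preference/aversion index
#'
#' The difference between a bird grouping's feeding-use percentage on a tree
#' species and that species' importance value (its availability). Positive
#' values indicate preference, negative values aversion. A species with zero
#' use has `PI = -IV` exactly. The index does not measure resource selection
#' (availabilities are unequal); it is a descriptive preference measure.
#'
#' @param use_pct feeding-use percentage(s), in \[0, 100\].
#' @param iv_pct importance value(s), in (0, 100\].
#' @return preference index, percentage points.
#' @export
preference_index <- function(use_pct, iv_pct) {
  if (any(iv_pct <= 0)) stop("importance value must be positive", call. = FALSE)
  if (any(use_pct < 0 | use_pct > 100)) stop("use_pct must lie in [0, 100]", call. = FALSE)
  use_pct - iv_pct
}

#' Proportional use: feeding use as a percentage of availability
#'
#' `100 * use_pct / iv_pct`, equivalently `100 * (iv_pct + PI) / iv_pct`.
#' A value of 100% means a tree species is used exactly in proportion to its
#' availability; 300% means three times its availability.
#'
#' @inheritParams preference_index
#' @return proportional use, percent.
#' @export
proportional_use <- function(use_pct, iv_pct) {
  if (any(iv_pct <= 0)) stop("importance value must be positive", call. = FALSE)
  100 * use_pct / iv_pct
}

#' Preference table for a bird grouping
#'
#' Joins feeding proportions with importance values and derives the
#' preference index and proportional use for every species of the importance
#' table.
#'
#' @inheritParams feeding_proportions
#' @param iv_table a `species_importance` table; its species define the
#'   universe.
#' @return a `preference_table` data.frame with columns `species`, `n_obs`,
#'   `use_pct`, `iv_pct`, `preference_index`, `proportional_use`.
#' @export
preference_table <- function(observations, iv_table, grouping = "total") {
  fp <- feeding_proportions(observations, iv_table$species, grouping = grouping)
  out <- data.frame(
    species = fp$species,
    n_obs = fp$n_obs,
    use_pct = fp$use_pct,
    iv_pct = iv_table$importance_value[match(fp$species, iv_table$species)],
    stringsAsFactors = FALSE
  )
  out$preference_index <- preference_index(out$use_pct, out$iv_pct)
  out$proportional_use <- proportional_use(out$use_pct, out$iv_pct)
  out <- out[order(-out$preference_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("preference_table", "data.frame")
  out
}

#' @export
print.preference_table <- function(x, digits = 2, ...) {
  cat("Foraging preference/aversion (", sum(x$n_obs), " observations, ",
    nrow(x), " tree taxa)\n",
    sep = ""
  )
  y <- as.data.frame(x)
  y$use_pct <- round(y$use_pct, digits)
  y$iv_pct <- round(y$iv_pct, digits)
  y$preference_index <- round(y$preference_index, digits)
  y$proportional_use <- round(y$proportional_use)
  print(y, ...)
  invisible(x)
}

#' Chi-square goodness-of-fit test of feeding use vs availability
#'
#' Tests whether a bird grouping feeds on common street-tree species in
#' proportion to their availability. Species are included when their
#' importance value exceeds `min_iv` (strictly), and the test is only run for
#' groupings with at least `min_n` feeding observations on the included
#' species. Expected counts are proportional to importance values; with
#' `renormalize = TRUE` (default) the IVs of the included species are
#' renormalized so expected counts sum to the observed total.
#'
#' @inheritParams preference_table
#' @param min_iv inclusion threshold on importance value, percent
#'   (default 1.5, strict `>`).
#' @param min_n minimum number of feeding observations (default 30).
#' @param renormalize renormalize IVs over the included species (default
#'   `TRUE`); otherwise expected counts are `N * IV / 100`.
#' @return a `use_avail_chisq` list: `statistic`, `df`, `p_value`,
#'   `included_species`, `observed`, `expected`, `n_obs`, `sufficient_n`.
#'   When the grouping has fewer than `min_n` observations the test is not
#'   performed: `sufficient_n` is `FALSE` and the statistic fields are `NA`.
#' @export
use_availability_chisq <- function(observations, iv_table, grouping = "total",
                                   min_iv = 1.5, min_n = 30, renormalize = TRUE) {
  keep <- iv_table$importance_value > min_iv
  if (sum(keep) < 2L) {
    stop("fewer than 2 species exceed min_iv = ", min_iv, "%", call. = FALSE)
  }
  fp <- feeding_proportions(observations, iv_table$species, grouping = grouping)
  included <- iv_table$species[keep]
  observed <- fp$n_obs[match(included, fp$species)]
  iv <- iv_table$importance_value[keep]
  n <- sum(observed)
  res <- list(
    grouping = grouping, included_species = included,
    observed = stats::setNames(observed, included), n_obs = n,
    min_iv = min_iv, min_n = min_n, renormalize = renormalize,
    sufficient_n = n >= min_n,
    statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
    expected = NULL
  )
  class(res) <- "use_avail_chisq"
  if (!res$sufficient_n) {
    return(res)
  }
  expected <- if (renormalize) n * iv / sum(iv) else n * iv / 100
  if (any(expected == 0)) stop("expected cell count of zero", call. = FALSE)
  res$expected <- stats::setNames(expected, included)
  res$statistic <- sum((observed - expected)^2 / expected)
  res$df <- length(included) - 1L
  res$p_value <- stats::pchisq(res$statistic, df = res$df, lower.tail = FALSE)
  res
}

#' @export
print.use_avail_chisq <- function(x, ...) {
  cat("Use vs availability chi-square goodness of fit (", x$grouping, ")\n", sep = "")
  cat(
    " ", length(x$included_species), "tree taxa with IV >", x$min_iv,
    "%;", x$n_obs, "feeding observations\n"
  )
  if (!x$sufficient_n) {
    cat("  grouping excluded: fewer than", x$min_n, "observations\n")
  } else {
    cat(sprintf(
      "  X-squared = %.2f, df = %d, p = %.4g\n",
      x$statistic, x$df, x$p_value
    ))
  }
  invisible(x)
}
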