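#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarity \eqn{d(x, y) = \sum|x_i - y_i| /
#' \sum(x_i + y_i)} between the rows of a site-by-species count matrix,
#' optionally after a square-root transform of the counts. Two all-zero rows
#' are defined to have dissimilarity 0.
#'
#' @param counts numeric matrix or data.frame, sites in rows, species in
#'   columns; non-negative.
#' @param transform `"sqrt"` (default, the convention used for count data) or
#'   `"none"`.
#' @return a `dissimilarity_matrix`: symmetric numeric matrix with zero
#'   diagonal and entries in \[0, 1\], row/col names from `counts`.
#' @export
bray_curtis <- function(counts, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  x <- as.matrix(counts)
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop("`counts` must be a non-negative numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 2L) stop("need at least 2 sites", call. = FALSE)
  if (transform == "sqrt") x <- sqrt(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- sum(x[i, ] + x[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else sum(abs(x[i, ] - x[j, ])) / denom
    }
  }
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

anosim_r <- function(ranks, within) {
  m <- length(ranks)
  (mean(ranks[!within]) - mean(ranks[within])) / (m / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether dissimilarities between groups
#' exceed dissimilarities within groups. The statistic
#' \deqn{R = \frac{\bar r_{between} - \bar r_{within}}{M / 2}, \quad
#'   M = n(n-1)/2,}
#' computed on midranks of the off-diagonal dissimilarities, ranges from -1
#' to 1; values near zero indicate no group structure. The p-value is the
#' permutation estimate \eqn{(1 + \#\{R^* \ge R\}) / (n_{perm} + 1)} under
#' random relabelling of sites. Pairwise group contrasts re-run the test on
#' the subset of each pair, judged at a Bonferroni-adjusted alpha of
#' `0.05 / n_pairs`.
#'
#' @param d a `dissimilarity_matrix` (or any symmetric dissimilarity matrix).
#' @param groups group labels, one per row of `d`; at least 2 groups with at
#'   least 2 members each.
#' @param n_perm number of Monte Carlo permutations (default 999).
#' @param seed optional RNG seed for reproducibility.
#' @param pairwise compute pairwise contrasts (default `TRUE` when more than
#'   2 groups).
#' @return an `anosim_result` list: `statistic` (R), `p_value`, `n_perm`,
#'   `seed`, and optionally `pairwise` (data.frame with per-pair R, p and the
#'   Bonferroni-adjusted alpha).
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL, pairwise = NULL) {
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per site is required", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  lower <- lower.tri(d)
  dv <- d[lower]
  if (diff(range(dv)) == 0) {
    stop("constant dissimilarities: R is undefined", call. = FALSE)
  }
  ranks <- rank(dv) # midranks for ties
  pair_i <- row(d)[lower]
  pair_j <- col(d)[lower]
  if (!is.null(seed)) set.seed(seed)
  within <- groups[pair_i] == groups[pair_j]
  r_obs <- anosim_r(ranks, within)
  count <- 0L
  for (k in seq_len(n_perm)) {
    g <- sample(groups)
    if (anosim_r(ranks, g[pair_i] == g[pair_j]) >= r_obs) count <- count + 1L
  }
  res <- list(
    statistic = r_obs, p_value = (1 + count) / (n_perm + 1),
    n_perm = n_perm, seed = seed, groups = sizes
  )
  if (is.null(pairwise)) pairwise <- length(sizes) > 2L
  if (pairwise && length(sizes) >= 2L) {
    gl <- names(sizes)
    pairs <- utils::combn(gl, 2L)
    alpha <- 0.05 / ncol(pairs)
    pw <- apply(pairs, 2L, function(p) {
      idx <- groups %in% p
      sub <- anosim(d[idx, idx, drop = FALSE], groups[idx],
        n_perm = n_perm, pairwise = FALSE
      )
      c(R = sub$statistic, p = sub$p_value)
    })
    res$pairwise <- data.frame(
      group1 = pairs[1, ], group2 = pairs[2, ],
      R = pw["R", ], p_value = pw["p", ],
      alpha = alpha, significant = pw["p", ] < alpha,
      stringsAsFactors = FALSE
    )
  }
  class(res) <- "anosim_result"
  res
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM:", sum(x$groups), "sites in", length(x$groups), "groups\n")
  cat(sprintf(
    "  R = %.3f, p = %.4g (%d permutations)\n",
    x$statistic, x$p_value, x$n_perm
  ))
  if (!is.null(x$pairwise)) {
    cat(sprintf("  pairwise contrasts (Bonferroni alpha = %.4f):\n", x$pairwise$alpha[1]))
    print(data.frame(
      pair = paste(x$pairwise$group1, "vs", x$pairwise$group2),
      R = round(x$pairwise$R, 3), p = signif(x$pairwise$p_value, 3),
      significant = x$pairwise$significant
    ), row.names = FALSE)
  }
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects ANOVA of a response across groups.
#'
#' @param values numeric response.
#' @param groups group labels, same length as `values`.
#' @return list with `F`, `df1`, `df2`, `p_value`, and per-group means.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (length(values) - nlevels(groups) < 2L) {
    stop("need >= 2 residual degrees of freedom", call. = FALSE)
  }
  wss <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (wss == 0) stop("zero within-group variance: F is undefined", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  list(
    F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
    p_value = s[["Pr(>F)"]][1],
    group_means = tapply(values, groups, mean)
  )
}

#' Kruskal-Wallis rank-sum test
#'
#' Nonparametric one-way comparison of a response across groups, with
#' midrank tie correction and a chi-square reference distribution.
#'
#' @inheritParams one_way_anova
#' @return list with `H` (the chi-squared statistic), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (diff(range(values)) == 0) stop("all values tied: H is undefined", call. = FALSE)
  k <- stats::kruskal.test(values, groups)
  list(
    H = unname(k$statistic), df = unname(k$parameter),
    p_value = k$p.value
  )
}

compact_letters <- function(levels_sorted, sig_pairs) {
  # insert-absorb compact letter display: groups sharing a letter do not differ
  letters_list <- list(levels_sorted)
  for (p in sig_pairs) {
    repeat {
      hit <- which(vapply(letters_list, function(s) all(p %in% s), logical(1)))
      if (length(hit) == 0L) break
      s <- letters_list[[hit[1]]]
      letters_list[[hit[1]]] <- setdiff(s, p[1])
      letters_list <- c(letters_list, list(setdiff(s, p[2])))
    }
  }
  # drop empty sets, duplicates, and sets contained in another set
  letters_list <- Filter(length, letters_list)
  letters_list <- unique(lapply(letters_list, sort))
  keep <- rep(TRUE, length(letters_list))
  for (i in seq_along(letters_list)) {
    for (j in seq_along(letters_list)) {
      if (i != j && keep[i] && all(letters_list[[i]] %in% letters_list[[j]]) &&
        !identical(letters_list[[i]], letters_list[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  letters_list <- letters_list[keep]
  # letter order follows the group order (sorted by mean)
  first_idx <- vapply(letters_list, function(s) min(match(s, levels_sorted)), numeric(1))
  letters_list <- letters_list[order(first_idx)]
  out <- stats::setNames(rep("", length(levels_sorted)), levels_sorted)
  for (i in seq_along(letters_list)) {
    out[letters_list[[i]]] <- paste0(out[letters_list[[i]]], LETTERS[i])
  }
  out
}

#' Pairwise multiple comparisons with a letters display
#'
#' Follow-up contrasts after a significant omnibus test: either a parametric
#' Tukey HSD (studentized-range quantiles) or nonparametric pairwise Wilcoxon
#' rank-sum tests with a Bonferroni-adjusted alpha of `0.05 / n_pairs`.
#' Groups that do not differ significantly share a letter in the compact
#' letter display.
#'
#' @inheritParams one_way_anova
#' @param method `"tukey"` (parametric) or `"rank"` (pairwise Wilcoxon with
#'   Bonferroni alpha).
#' @return list with `pairs` (data.frame: group1, group2, p_value, alpha,
#'   significant) and `letters` (named character, groups ordered by
#'   decreasing mean).
#' @export
pairwise_contrasts <- function(values, groups, method = c("tukey", "rank")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (any(table(groups) < 2L)) stop("need >= 2 observations per group", call. = FALSE)
  gl <- levels(groups)
  cmb <- utils::combn(gl, 2L)
  if (method == "tukey") {
    tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
    pairnames <- rownames(tk)
    p <- tk[, "p adj"]
    # align TukeyHSD's "b-a" labels with our pairs
    key <- apply(cmb, 2L, function(x) paste(sort(x), collapse = "|"))
    tkey <- vapply(
      strsplit(pairnames, "-", fixed = TRUE),
      function(x) paste(sort(x), collapse = "|"), character(1)
    )
    p <- p[match(key, tkey)]
    alpha <- 0.05
  } else {
    p <- apply(cmb, 2L, function(pr) {
      suppressWarnings(stats::wilcox.test(
        values[groups == pr[1]], values[groups == pr[2]], exact = FALSE
      )$p.value)
    })
    alpha <- 0.05 / ncol(cmb)
  }
  sig <- p < alpha
  pairs <- data.frame(
    group1 = cmb[1, ], group2 = cmb[2, ], p_value = p,
    alpha = alpha, significant = sig, stringsAsFactors = FALSE
  )
  means <- sort(tapply(values, groups, mean), decreasing = FALSE)
  sig_pairs <- lapply(which(sig), function(i) c(cmb[1, i], cmb[2, i]))
  list(pairs = pairs, letters = compact_letters(names(means), sig_pairs))
}

#' Spearman rank correlation with a permutation p-value
#'
#' Pearson correlation of midranks, with a two-sided permutation p-value
#' estimated as `(1 + #{|rho*| >= |rho|}) / (n_perm + 1)`.
#'
#' @param x,y paired numeric vectors, length >= 3, neither constant.
#' @param n_perm permutations (default 10000).
#' @param seed optional RNG seed.
#' @return a `spearman_result` list: `rho`, `p_value`, `n_perm`.
#' @export
spearman_rho <- function(x, y, n_perm = 10000, seed = NULL) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need >= 3 paired values", call. = FALSE)
  }
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("constant vector: rank correlation undefined", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (k in seq_len(n_perm)) {
    if (abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12) count <- count + 1L
  }
  res <- list(rho = rho, p_value = (1 + count) / (n_perm + 1), n_perm = n_perm)
  class(res) <- "spearman_result"
  res
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf(
    "Spearman rank correlation: rho = %.3f, permutation p = %.4g (%d perms)\n",
    x$rho, x$p_value, x$n_perm
  ))
  invisible(x)
}
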