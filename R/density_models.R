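#' Fit a single-variable negative-binomial GLM
#'
#' Maximum-likelihood fit of a negative-binomial generalized linear model
#' with a log link, mean \eqn{\mu = \exp(\beta_0 + \beta_1 x [+ \beta_2
#' x^2])} and variance \eqn{\mu + \mu^2/\theta}, with the dispersion
#' parameter \eqn{\theta} estimated by maximum likelihood. Coefficients are
#' reported exponentiated (the original response scale): the exponentiated
#' intercept of the intercept-only model is the mean of the response, and
#' exponentiated slopes below 1 indicate negative relationships.
#'
#' The response may be a non-integer per-km density: the negative-binomial
#' log-likelihood is evaluated through its gamma-function form, which extends
#' continuously to non-integer values. `integer_mode = TRUE` rounds the
#' response to integers first.
#'
#' @param y non-negative response (per-km feeding-bird density).
#' @param x numeric predictor, or `NULL` for the intercept-only model.
#' @param quadratic add an `x^2` term (the predictor is not centred first).
#' @param integer_mode round `y` to integers before fitting.
#' @param response,predictor optional labels carried into the result.
#' @return an `nb_fit` list: `response`, `predictor`, `quadratic`, `beta`
#'   (link scale), `beta_exp`, `se`, `z`, `p_value` (Wald), `theta`, `aic`,
#'   `deviance`, `df_residual`, `dispersion_ratio`, `pearson_chi2`,
#'   `converged`, and the underlying `fit` object.
#' @export
fit_nb_glm <- function(y, x = NULL, quadratic = FALSE, integer_mode = FALSE,
                       response = "y", predictor = if (is.null(x)) "intercept_only" else "x") {
  if (any(y < 0) || anyNA(y)) stop("response must be non-negative and non-missing", call. = FALSE)
  if (length(y) < 10L) stop("need >= 10 observations", call. = FALSE)
  if (!is.null(x) && (anyNA(x) || any(!is.finite(x)))) {
    stop("predictor must be finite", call. = FALSE)
  }
  if (integer_mode) y <- round(y)
  dat <- data.frame(y = y)
  fml <- if (is.null(x)) {
    y ~ 1
  } else {
    dat$x <- x
    if (quadratic) y ~ x + I(x^2) else y ~ x
  }
  fit <- NULL
  converged <- FALSE
  suppressWarnings(
    tryCatch(
      {
        fit <- MASS::glm.nb(fml, data = dat)
        converged <- fit$converged && !isTRUE(fit$th.warn == "iteration limit reached")
      },
      error = function(e) NULL
    )
  )
  if (is.null(fit)) {
    res <- list(
      response = response, predictor = predictor, quadratic = quadratic,
      converged = FALSE
    )
    class(res) <- "nb_fit"
    return(res)
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- cf / se
  res <- list(
    response = response, predictor = predictor, quadratic = quadratic,
    beta = cf, beta_exp = exp(cf), se = se, z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    theta = fit$theta, aic = stats::AIC(fit),
    deviance = stats::deviance(fit), df_residual = stats::df.residual(fit),
    dispersion_ratio = stats::deviance(fit) / stats::df.residual(fit),
    pearson_chi2 = sum(stats::residuals(fit, type = "pearson")^2),
    converged = converged, fit = fit
  )
  class(res) <- "nb_fit"
  res
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative-binomial GLM:", x$response, "~", x$predictor,
    if (isTRUE(x$quadratic)) "+ quadratic term" else "", "\n"
  )
  if (!isTRUE(x$converged) && is.null(x$beta)) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "  exp(beta): %s\n", paste(sprintf("%.3f", x$beta_exp), collapse = ", ")
  ))
  cat(sprintf(
    "  theta = %.3f, AIC = %.2f, deviance/df = %.3f\n",
    x$theta, x$aic, x$dispersion_ratio
  ))
  invisible(x)
}

#' Overdispersion diagnostics for a fitted GLM
#'
#' Pearson chi-square statistic and the ratio of residual deviance to
#' residual degrees of freedom; a ratio above `threshold` is flagged as
#' overdispersed (a Poisson fit to overdispersed counts typically is, a
#' negative-binomial fit is not).
#'
#' @param fit an `nb_fit`, or any `glm` object.
#' @param threshold dispersion-ratio verdict threshold (default 1.5).
#' @return list with `pearson_chi2`, `ratio`, `verdict` ("overdispersed" or
#'   "adequate").
#' @export
overdispersion_check <- function(fit, threshold = 1.5) {
  if (inherits(fit, "nb_fit")) fit <- fit$fit
  df <- stats::df.residual(fit)
  if (is.null(df) || df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  ratio <- stats::deviance(fit) / df
  list(
    pearson_chi2 = sum(stats::residuals(fit, type = "pearson")^2),
    ratio = ratio,
    verdict = if (ratio > threshold) "overdispersed" else "adequate"
  )
}

#' Rank a set of fitted models by AIC
#'
#' Computes each model's AIC difference from the best model of the set
#' (`delta_aic = 0` marks the best-supported model) and sorts ascending.
#' All fits must share the same response.
#'
#' @param fits list of `nb_fit` objects on the same response.
#' @return an `nb_model_set`: data.frame with `predictor`, `quadratic`,
#'   `aic`, `delta_aic`, `beta_exp_linear`, `beta_exp_quadratic`,
#'   `p_linear`, `converged`; the fits are attached as attribute `"fits"`.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "nb_fit")))
  responses <- unique(vapply(fits, `[[`, character(1), "response"))
  if (length(responses) != 1L) {
    stop("all models in a set must share the same response", call. = FALSE)
  }
  aic <- vapply(fits, function(f) if (is.null(f$aic)) NA_real_ else f$aic, numeric(1))
  get_beta <- function(f, idx) {
    if (is.null(f$beta_exp) || length(f$beta_exp) < idx) NA_real_ else unname(f$beta_exp[idx])
  }
  get_p <- function(f, idx) {
    if (is.null(f$p_value) || length(f$p_value) < idx) NA_real_ else unname(f$p_value[idx])
  }
  tab <- data.frame(
    predictor = vapply(fits, `[[`, character(1), "predictor"),
    quadratic = vapply(fits, `[[`, logical(1), "quadratic"),
    aic = aic,
    delta_aic = aic - min(aic, na.rm = TRUE),
    beta_exp_intercept = vapply(fits, get_beta, numeric(1), idx = 1L),
    beta_exp_linear = vapply(fits, get_beta, numeric(1), idx = 2L),
    beta_exp_quadratic = vapply(fits, get_beta, numeric(1), idx = 3L),
    p_linear = vapply(fits, get_p, numeric(1), idx = 2L),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$delta_aic)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  attr(tab, "response") <- responses
  class(tab) <- c("nb_model_set", "data.frame")
  tab
}

#' Fit and rank the single-variable model set for one response
#'
#' Fits one negative-binomial GLM per predictor column (plus the
#' intercept-only model) and ranks the set by AIC — the nine-model,
#' single-variable model-selection design: eight street-tree diversity,
#' density and size predictors against one feeding-bird density response.
#'
#' @param data data.frame of route-level summaries.
#' @param response name of the response column (per-km density).
#' @param predictors character vector of predictor column names.
#' @param quadratic add a quadratic term to every non-intercept model.
#' @return an `nb_model_set`, see [rank_models()].
#' @export
fit_model_set <- function(data, response, predictors, quadratic = TRUE) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  y <- data[[response]]
  fits <- c(
    list(fit_nb_glm(y, NULL, response = response)),
    lapply(predictors, function(p) {
      fit_nb_glm(y, data[[p]],
        quadratic = quadratic,
        response = response, predictor = p
      )
    })
  )
  rank_models(fits)
}

#' @export
print.nb_model_set <- function(x, digits = 2, ...) {
  cat("Negative-binomial model set, response:", attr(x, "response"), "\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, ...)
  invisible(x)
}
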