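#' Genotype x environment yield table
#'
#' Builds the complete genotype x environment matrix of mean yield per plant
#' (kg/plant) that the stability regression operates on. Replicate-level
#' input is collapsed to environment means; an environment is one
#' location-year combination.
#'
#' @param x either a replicate-level data.frame with columns genotype,
#'   location, year and a yield column, or a numeric matrix (genotypes in
#'   rows, environments in columns, dimnames required).
#' @param value name of the yield column when \code{x} is a data.frame.
#' @return object of class \code{yield_table}: list with \code{Y} (v x l
#'   matrix), \code{genotypes}, \code{environments}.
#' @export
yield_table <- function(x, value = "yield") {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop_cfg("matrix input must have genotype rownames and environment colnames")
    Y <- x
  } else {
    stopifnot(is.data.frame(x))
    need <- c("genotype", "location", "year", value)
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop_cfg("missing column(s): %s", paste(miss, collapse = ", "))
    env <- paste(x$location, x$year, sep = "_")
    Y <- tapply(x[[value]], list(x$genotype, env), mean)
  }
  if (anyNA(Y)) {
    bad <- which(is.na(Y), arr.ind = TRUE)
    stop_cfg("incomplete yield table; missing cell(s): %s",
             paste(sprintf("(%s, %s)", rownames(Y)[bad[, 1]],
                           colnames(Y)[bad[, 2]]), collapse = ", "))
  }
  if (nrow(Y) < 2L) stop_cfg("need at least 2 genotypes, got %d", nrow(Y))
  if (ncol(Y) < 3L) stop_cfg("need at least 3 environments, got %d", ncol(Y))
  structure(list(Y = Y, genotypes = rownames(Y), environments = colnames(Y)),
            class = "yield_table")
}

#' Environment index
#'
#' The environment index EI_j is the deviation of environment j's mean yield
#' (over all v genotypes) from the grand mean:
#' \deqn{EI_j = \sum_i Y_{ij}/v - \sum_i\sum_j Y_{ij}/(vl)}
#' so that the indices sum to zero. EI is the regressor of the stability
#' model; it is computed from all genotypes present in the table, controls
#' included.
#'
#' @param yields a \code{yield_table}.
#' @return named numeric vector of EI_j, kg/plant; sums to 0 within 1e-9.
#' @export
environment_index <- function(yields) {
  stopifnot(inherits(yields, "yield_table"))
  ei <- colMeans(yields$Y) - mean(yields$Y)
  stopifnot(abs(sum(ei)) < 1e-9)
  ei
}

#' Per-genotype stability regression
#'
#' Ordinary least squares of each genotype's environment means on the
#' environment index: slope b_i (the coefficient of regression; b = 1 is
#' average environmental sensitivity), intercept, and r^2. When EI is
#' computed from the same complete table, mean EI = 0, hence the intercept
#' equals the genotype's pooled mean, and the slopes average exactly 1.
#'
#' @param yields a \code{yield_table}.
#' @param ei environment index; defaults to \code{environment_index(yields)}.
#'   Supplying an external EI is flagged in the result's
#'   \code{"external_ei"} attribute.
#' @return data.frame: genotype, b, intercept, r2, pooled_mean. A genotype
#'   with zero yield variance gets \code{r2 = NA} with a warning (SS_tot = 0
#'   makes r^2 meaningless); such genotypes fail the r^2 selection criterion.
#' @export
fit_linear <- function(yields, ei = NULL) {
  stopifnot(inherits(yields, "yield_table"))
  external <- !is.null(ei)
  if (is.null(ei)) ei <- environment_index(yields)
  if (length(ei) != ncol(yields$Y))
    stop_cfg("ei length %d != number of environments %d",
             length(ei), ncol(yields$Y))
  x <- ei - mean(ei)
  sxx <- sum(x^2)
  if (sxx < 1e-12) stop_cfg("environment index has zero variance")
  out <- do.call(rbind, lapply(seq_len(nrow(yields$Y)), function(i) {
    y <- yields$Y[i, ]
    mu <- mean(y)
    b <- sum((y - mu) * x) / sxx
    intercept <- mu - b * mean(ei)
    ss_tot <- sum((y - mu)^2)
    ss_res <- sum((y - intercept - b * ei)^2)
    r2 <- if (ss_tot < 1e-12) {
      warning(sprintf("genotype %s has zero yield variance; r2 undefined",
                      yields$genotypes[i]), call. = FALSE)
      NA_real_
    } else 1 - ss_res / ss_tot
    data.frame(genotype = yields$genotypes[i], b = b, intercept = intercept,
               r2 = r2, pooled_mean = mu, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "external_ei") <- external
  out
}

#' Average deviation from linearity (ADL)
#'
#' For each genotype, the environment means are fit by the linear model (in
#' EI) and by a quadratic model; ADL is the summed squared gap between the
#' quadratic and linear predictions, scaled by the genotype pooled mean:
#' \deqn{ADL_i = \sum_j (\hat\mu_{Q,ij} - \hat\mu_{L,ij})^2 / \bar\mu_i}
#' ADL = 0 iff the quadratic coefficient is 0; a significantly nonzero ADL
#' flags a non-linear environmental response, making b_i unreliable for
#' selection. Significance uses the extra-sum-of-squares F-test of the
#' quadratic term (quadratic vs linear model on the l environment means,
#' df = 1 and l - 3); with l = 3 the quadratic fit is saturated and the
#' p-value is undefined (NA).
#'
#' @param yields a \code{yield_table}.
#' @param ei environment index (defaults to the table's own).
#' @param fit result of \code{\link{fit_linear}}; recomputed when NULL.
#' @param denominator \code{"pooled_mean"} (default) divides by the genotype
#'   mean; \code{"n_env"} divides by the number of environments instead.
#' @return data.frame: genotype, adl, adl_p, quad_coef; attribute
#'   \code{"detail"} holds per-environment linear and quadratic predictions.
#' @export
compute_adl <- function(yields, ei = NULL, fit = NULL,
                        denominator = c("pooled_mean", "n_env")) {
  stopifnot(inherits(yields, "yield_table"))
  denominator <- match.arg(denominator)
  if (is.null(ei)) ei <- environment_index(yields)
  if (is.null(fit)) fit <- fit_linear(yields, ei)
  l <- ncol(yields$Y)
  detail <- vector("list", nrow(yields$Y))
  out <- do.call(rbind, lapply(seq_len(nrow(yields$Y)), function(i) {
    y <- yields$Y[i, ]
    mu <- mean(y)
    lin <- lm(y ~ ei)
    quad <- lm(y ~ ei + I(ei^2))
    mu_l <- fitted(lin)
    mu_q <- fitted(quad)
    den <- if (denominator == "pooled_mean") {
      if (abs(mu) < 1e-12)
        stop_cfg("genotype %s has zero pooled mean; ADL undefined",
                 yields$genotypes[i])
      mu
    } else l
    adl <- sum((mu_q - mu_l)^2) / den
    p <- if (l < 4L) {
      NA_real_                        # saturated quadratic: no residual df
    } else if (adl < 1e-12) {
      1                               # no deviation from linearity at all
    } else {
      anova(lin, quad)[["Pr(>F)"]][2]
    }
    detail[[i]] <<- data.frame(environment = yields$environments,
                               ei = ei, y = y, mu_L = mu_l, mu_Q = mu_q,
                               row.names = NULL)
    data.frame(genotype = yields$genotypes[i], adl = adl, adl_p = p,
               quad_coef = unname(coef(quad)[3]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  names(detail) <- yields$genotypes
  attr(out, "detail") <- detail
  out
}

#' Selection criteria for stable-yielding genotypes
#'
#' The four-part rule: pooled yield above the grand mean; slope b_i at most 1
#' and/or inside the population band mean(b) +/- k * SD(b); r^2 above 0.50;
#' ADL not significantly different from 0.
#'
#' @param slope_rule \code{"both"} (default: b <= 1 AND inside the band),
#'   \code{"le_one"}, or \code{"within_band"}. Both readings are reported in
#'   the output either way, so the choice is auditable.
#' @param band_k band half-width in slope standard deviations (default 1).
#' @param r2_min minimum r^2, strict (default 0.50).
#' @param adl_alpha significance level for the ADL test (default 0.05).
#' @param require_mean_above_grand require pooled mean > grand mean.
#' @return object of class \code{selection_criteria}.
#' @export
selection_criteria <- function(slope_rule = c("both", "le_one", "within_band"),
                               band_k = 1, r2_min = 0.50, adl_alpha = 0.05,
                               require_mean_above_grand = TRUE) {
  slope_rule <- match.arg(slope_rule)
  if (r2_min <= 0 || r2_min >= 1) stop_cfg("'r2_min' must be in (0, 1)")
  if (adl_alpha <= 0 || adl_alpha >= 1) stop_cfg("'adl_alpha' must be in (0, 1)")
  structure(list(slope_rule = slope_rule, band_k = band_k, r2_min = r2_min,
                 adl_alpha = adl_alpha,
                 require_mean_above_grand = require_mean_above_grand),
            class = "selection_criteria")
}

#' Select high- and stable-yielding genotypes
#'
#' Applies \code{\link{selection_criteria}} to per-genotype stability fits.
#' Slope criterion is boundary-inclusive (b = 1 passes). A genotype with
#' undefined r^2 or an unevaluable ADL p-value fails the corresponding
#' criterion (ADL exactly 0 with no p-value available passes: there is no
#' deviation from linearity at all).
#'
#' @param fits data.frame with columns genotype, b, r2, pooled_mean, adl,
#'   adl_p (e.g. merged output of \code{\link{fit_linear}} and
#'   \code{\link{compute_adl}}, or \code{\link{stability_analysis}$fits}).
#' @param grand_mean grand mean yield over all genotypes and environments.
#' @param criteria a \code{selection_criteria}.
#' @return data.frame with per-criterion logical flags, the band bounds as
#'   attributes \code{"band"} and \code{"slope_mean"}, and a final
#'   \code{selected} verdict.
#' @export
select_stable <- function(fits, grand_mean, criteria = selection_criteria()) {
  if (!is.data.frame(fits) || nrow(fits) == 0L)
    stop_cfg("'fits' must be a non-empty data.frame")
  need <- c("genotype", "b", "r2", "pooled_mean", "adl", "adl_p")
  miss <- setdiff(need, names(fits))
  if (length(miss))
    stop_cfg("'fits' missing column(s): %s", paste(miss, collapse = ", "))
  b_mean <- mean(fits$b)
  b_sd <- sd(fits$b)
  band <- c(lower = b_mean - criteria$band_k * b_sd,
            upper = b_mean + criteria$band_k * b_sd)

  mean_ok <- if (criteria$require_mean_above_grand)
    fits$pooled_mean > grand_mean else rep(TRUE, nrow(fits))
  slope_le_one <- fits$b <= 1
  slope_in_band <- fits$b >= band["lower"] & fits$b <= band["upper"]
  slope_ok <- switch(criteria$slope_rule,
                     le_one = slope_le_one,
                     within_band = slope_in_band,
                     both = slope_le_one & slope_in_band)
  r2_ok <- !is.na(fits$r2) & fits$r2 > criteria$r2_min
  adl_ok <- ifelse(is.na(fits$adl_p),
                   fits$adl < 1e-12,
                   fits$adl_p > criteria$adl_alpha)

  out <- data.frame(
    genotype = fits$genotype,
    pooled_mean = fits$pooled_mean,
    b = fits$b, r2 = fits$r2, adl = fits$adl, adl_p = fits$adl_p,
    mean_above_grand = mean_ok,
    slope_le_one = slope_le_one,
    slope_in_band = slope_in_band,
    slope_ok = slope_ok,
    r2_ok = r2_ok,
    adl_ok = adl_ok,
    selected = mean_ok & slope_ok & r2_ok & adl_ok,
    stringsAsFactors = FALSE
  )
  attr(out, "grand_mean") <- grand_mean
  attr(out, "slope_mean") <- b_mean
  attr(out, "band") <- band
  out
}

#' Full stability analysis of a replicate-level trial
#'
#' Convenience wrapper: collapse to environment means, compute EI, fit the
#' per-genotype regressions and ADL, and apply the selection rule.
#'
#' @param x replicate-level data.frame or a \code{yield_table}.
#' @param criteria a \code{selection_criteria}.
#' @inheritParams compute_adl
#' @return list with \code{table} (yield_table), \code{ei}, \code{fits}
#'   (fit + ADL columns merged), \code{grand_mean}, \code{selection}.
#' @export
stability_analysis <- function(x, criteria = selection_criteria(),
                               denominator = "pooled_mean") {
  yt <- if (inherits(x, "yield_table")) x else yield_table(x)
  ei <- environment_index(yt)
  fit <- fit_linear(yt, ei)
  adl <- compute_adl(yt, ei, fit, denominator = denominator)
  fits <- merge(fit, adl, by = "genotype", sort = FALSE)
  grand_mean <- mean(yt$Y)
  sel <- select_stable(fits, grand_mean, criteria)
  list(table = yt, ei = ei, fits = fits, grand_mean = grand_mean,
       selection = sel)
}
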