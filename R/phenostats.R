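#' Aggregate raw phenotype records into the five trait values
#'
#' Computes the replicate-level trait table from raw plant/truss records:
#' \itemize{
#'   \item NFL: mean number of flowers per inflorescence over trusses 2-5.
#'   \item FS: mean fraction of flowers setting fruit per inflorescence,
#'     trusses 2-5.
#'   \item TNF: all fruits collected divided by the number of plants.
#'   \item FW: weight of the sampled fruits (at least 50 recommended)
#'     divided by the number of fruits sampled, g.
#'   \item YP: total fruit weight divided by the number of plants, kg/plant.
#' }
#'
#' @param flowers data.frame with columns genotype, location, year,
#'   replicate, plant, truss, flowers, fruits (fruits = flowers that set).
#' @param harvest data.frame with columns genotype, location, year,
#'   replicate, n_plants, total_fruits, total_weight_kg, sample_fruits,
#'   sample_weight_g (one row per replicate).
#' @param trusses trusses retained for NFL/FS (default 2:5).
#' @return long data.frame: genotype, location, year, replicate, trait, value.
#' @export
aggregate_traits <- function(flowers, harvest, trusses = 2:5) {
  stopifnot(is.data.frame(flowers), is.data.frame(harvest))
  fneed <- c("genotype", "location", "year", "replicate", "plant", "truss",
             "flowers", "fruits")
  hneed <- c("genotype", "location", "year", "replicate", "n_plants",
             "total_fruits", "total_weight_kg", "sample_fruits",
             "sample_weight_g")
  if (length(miss <- setdiff(fneed, names(flowers))))
    stop_cfg("'flowers' missing column(s): %s", paste(miss, collapse = ", "))
  if (length(miss <- setdiff(hneed, names(harvest))))
    stop_cfg("'harvest' missing column(s): %s", paste(miss, collapse = ", "))

  fl <- flowers[flowers$truss %in% trusses, , drop = FALSE]
  if (any(fl$flowers <= 0))
    stop_cfg("non-positive flower count in 'flowers' (genotype %s)",
             fl$genotype[which(fl$flowers <= 0)[1]])
  key <- c("genotype", "location", "year", "replicate")
  nfl <- aggregate(fl["flowers"], fl[key], mean)
  fs <- aggregate(list(value = fl$fruits / fl$flowers), fl[key], mean)

  bad <- harvest$n_plants <= 0 | harvest$sample_fruits <= 0
  if (any(bad))
    stop_cfg("zero plants or zero sampled fruits for genotype %s in %s %s",
             harvest$genotype[which(bad)[1]],
             harvest$location[which(bad)[1]], harvest$year[which(bad)[1]])

  long <- function(df, trait, value) {
    data.frame(df[key], trait = trait, value = value,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- rbind(
    long(nfl, "NFL", nfl$flowers),
    long(fs, "FS", fs$value),
    long(harvest, "TNF", harvest$total_fruits / harvest$n_plants),
    long(harvest, "FW", harvest$sample_weight_g / harvest$sample_fruits),
    long(harvest, "YP", harvest$total_weight_kg / harvest$n_plants)
  )
  rownames(out) <- NULL
  out
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Compare genotypes to control genotypes by Student's t-test
#'
#' Two-sample t-tests of each non-control genotype against each control, per
#' trait and per field (location-year), on replicate values. The classic
#' pooled-variance Student test is the default; \code{var_equal = FALSE}
#' switches to Welch. Stars mark p < 0.05 / 0.01 / 0.001; direction records
#' whether the genotype mean is above (increase) or below (decrease) the
#' control mean. No multiple-testing correction is applied by default,
#' matching per-comparison reporting; \code{p_adjust = "BH"} turns on
#' Benjamini-Hochberg across all comparisons.
#'
#' @param traits long trait table (see \code{\link{aggregate_traits}}).
#' @param controls character vector of control genotype labels.
#' @param var_equal pooled-variance t-test (default TRUE).
#' @param p_adjust "none" (default) or "BH".
#' @return data.frame: genotype, control, trait, location, year, n, t, df, p,
#'   stars, direction. Cells with fewer than 2 replicates on either side are
#'   skipped with a warning.
#' @export
compare_to_controls <- function(traits, controls, var_equal = TRUE,
                                p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.data.frame(traits), length(controls) >= 1L)
  if (!all(controls %in% traits$genotype))
    stop_cfg("control genotype(s) not in table: %s",
             paste(setdiff(controls, traits$genotype), collapse = ", "))
  cells <- unique(traits[c("trait", "location", "year")])
  rows <- list()
  skipped <- 0L
  for (k in seq_len(nrow(cells))) {
    sub <- traits[traits$trait == cells$trait[k] &
                  traits$location == cells$location[k] &
                  traits$year == cells$year[k], ]
    for (g in setdiff(unique(sub$genotype), controls)) {
      xg <- sub$value[sub$genotype == g]
      for (ctrl in controls) {
        xc <- sub$value[sub$genotype == ctrl]
        if (length(xg) < 2L || length(xc) < 2L) {
          skipped <- skipped + 1L
          next
        }
        tt <- tryCatch(t.test(xg, xc, var.equal = var_equal),
                       error = function(e) NULL)
        if (is.null(tt)) { # e.g. both samples constant
          tval <- 0; p <- 1; dfree <- length(xg) + length(xc) - 2
        } else {
          tval <- unname(tt$statistic); p <- tt$p.value
          dfree <- unname(tt$parameter)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, control = ctrl, trait = cells$trait[k],
          location = cells$location[k], year = cells$year[k],
          n = length(xg), t = tval, df = dfree, p = p,
          direction = if (mean(xg) > mean(xc)) "increase" else "decrease",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0L)
    warning(sprintf("%d comparison(s) skipped: fewer than 2 replicates",
                    skipped), call. = FALSE)
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$stars <- significance_stars(out$p)
  out
}

#' Balanced three-way fixed-effects ANOVA with TSS%
#'
#' Decomposes a trait's replicate-level values over genotype (G), location
#' (L) and year (Y) as fixed factors, with all interactions, on a balanced
#' complete design. Each source's contribution is also expressed as a
#' percentage of the total sum of squares (TSS%); the TSS% column sums
#' to 100. F-tests are against the residual mean square.
#'
#' @param traits long trait table.
#' @param trait which trait to analyse (e.g. "YP").
#' @return data.frame: source (G, L, Y, G:L, G:Y, L:Y, G:L:Y, Residuals),
#'   df, ss, ms, f, p, tss_pct.
#' @export
three_way_anova <- function(traits, trait) {
  sub <- traits[traits$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop_cfg("trait '%s' not found", trait)
  counts <- table(sub$genotype, sub$location, sub$year)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0))
    stop_cfg(paste("unbalanced design for trait '%s': balance or subsample",
                   "so every genotype x location x year cell has the same",
                   "number of replicates"), trait)
  d <- data.frame(value = sub$value,
                  G = factor(sub$genotype),
                  L = factor(sub$location),
                  Y = factor(sub$year))
  a <- anova(lm(value ~ G * L * Y, data = d))
  ss_total <- sum(a[["Sum Sq"]])
  out <- data.frame(source = rownames(a),
                    df = a[["Df"]], ss = a[["Sum Sq"]],
                    ms = a[["Mean Sq"]], f = a[["F value"]],
                    p = a[["Pr(>F)"]],
                    tss_pct = 100 * a[["Sum Sq"]] / ss_total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations among traits
#'
#' Correlates the five traits on matched (genotype, location, year,
#' replicate) observations, either within each field (location-year, across
#' genotypes) or within each genotype (across fields), as the study reports
#' both. p-values come from the t transform with n - 2 df. A trait with zero
#' variance in a group yields NA correlations, flagged with a warning.
#'
#' @param traits long trait table.
#' @param by "field" (per location-year) or "genotype".
#' @return data.frame: group, trait1, trait2, n, r, p.
#' @export
pearson_correlations <- function(traits, by = c("field", "genotype")) {
  by <- match.arg(by)
  key <- c("genotype", "location", "year", "replicate")
  wide <- stats::reshape(traits, direction = "wide", idvar = key,
                         timevar = "trait")
  names(wide) <- sub("^value\\.", "", names(wide))
  trait_names <- setdiff(names(wide), key)
  group <- if (by == "field") paste(wide$location, wide$year, sep = "_")
           else wide$genotype
  rows <- list()
  flagged <- character(0)
  for (grp in unique(group)) {
    sub <- wide[group == grp, trait_names, drop = FALSE]
    for (i in seq_along(trait_names)) for (j in seq_along(trait_names)) {
      if (j <= i) next
      x <- sub[[i]]; y <- sub[[j]]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      if (n < 3L) next
      if (sd(x) < 1e-12 || sd(y) < 1e-12) {
        flagged <- c(flagged, sprintf("%s:%s~%s", grp, trait_names[i],
                                      trait_names[j]))
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- cor.test(x, y, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, trait1 = trait_names[i], trait2 = trait_names[j],
        n = n, r = r, p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(flagged))
    warning(sprintf("zero-variance trait in: %s",
                    paste(flagged, collapse = ", ")), call. = FALSE)
  do.call(rbind, rows)
}
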