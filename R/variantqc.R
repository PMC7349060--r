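#' Variant filtering configuration
#'
#' Mirrors the reduced-representation panel filter: keep a site when at
#' least \code{max_missing_kept_fraction} of samples are called (the
#' VcfTools \code{--max-missing} convention: the value is the minimum CALLED
#' fraction, boundary inclusive), its mean depth over called samples is at
#' least \code{min_mean_dp}, and (optionally) it is polymorphic among the
#' samples — sites where every called genotype is the same class, e.g. the
#' same alternative allele in every sample (a reference-cultivar difference,
#' not a within-panel polymorphism), are dropped.
#'
#' @param max_missing_kept_fraction minimum called fraction (default 0.50).
#' @param min_mean_dp minimum mean depth over called samples (default 5).
#'   Sites lacking DP fail this rule unless \code{min_mean_dp = 0}.
#' @param drop_monomorphic drop sites with < 2 distinct called genotype
#'   classes (default TRUE).
#' @return object of class \code{filter_config}.
#' @export
filter_config <- function(max_missing_kept_fraction = 0.50,
                          min_mean_dp = 5,
                          drop_monomorphic = TRUE) {
  check_fraction(max_missing_kept_fraction, "max_missing_kept_fraction")
  if (min_mean_dp < 0) stop_cfg("'min_mean_dp' must be >= 0")
  structure(list(max_missing_kept_fraction = max_missing_kept_fraction,
                 min_mean_dp = min_mean_dp,
                 drop_monomorphic = drop_monomorphic),
            class = "filter_config")
}

#' Filter a variant panel
#'
#' Applies the three rules of \code{\link{filter_config}} in order
#' (missingness, depth, monomorphism) and reports how many sites each rule
#' removed.
#'
#' @param ds a \code{variant_dataset}.
#' @param cfg a \code{filter_config}.
#' @return list: \code{dataset} (filtered \code{variant_dataset}),
#'   \code{removed} (named counts per rule), \code{kept}.
#' @export
filter_variants <- function(ds, cfg = filter_config()) {
  stopifnot(inherits(ds, "variant_dataset"))
  if (n_sites(ds) == 0L) stop_cfg("empty variant dataset")
  called <- !is.na(ds$calls)
  called_frac <- rowMeans(called)
  pass_miss <- called_frac >= cfg$max_missing_kept_fraction

  mean_dp <- vapply(seq_len(n_sites(ds)), function(i) {
    d <- ds$depths[i, called[i, ]]
    if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
  }, numeric(1))
  pass_dp <- if (cfg$min_mean_dp == 0) rep(TRUE, n_sites(ds))
             else !is.na(mean_dp) & mean_dp >= cfg$min_mean_dp

  n_classes <- apply(ds$calls, 1L, function(g) length(unique(g[!is.na(g)])))
  pass_poly <- if (cfg$drop_monomorphic) n_classes >= 2L
               else rep(TRUE, n_sites(ds))

  removed <- c(missingness = sum(!pass_miss),
               depth = sum(pass_miss & !pass_dp),
               monomorphic = sum(pass_miss & pass_dp & !pass_poly))
  keep <- pass_miss & pass_dp & pass_poly
  if (!any(keep))
    warning("all sites removed by filtering; returning empty dataset",
            call. = FALSE)
  out <- ds
  out$sites <- ds$sites[keep, , drop = FALSE]
  out$calls <- ds$calls[keep, , drop = FALSE]
  out$depths <- ds$depths[keep, , drop = FALSE]
  list(dataset = out, removed = removed, kept = sum(keep))
}

#' Genotype-class composition of a panel
#'
#' @param ds a \code{variant_dataset}.
#' @return list: \code{percent} (named percentages of hom_ref, het, hom_alt,
#'   missing over all calls; sums to 100) and \code{per_sample} (data.frame
#'   with per-sample heterozygosity = het / called and missing rate).
#' @export
genotype_composition <- function(ds) {
  stopifnot(inherits(ds, "variant_dataset"))
  if (n_sites(ds) == 0L) stop_cfg("empty variant dataset")
  g <- ds$calls
  n <- length(g)
  pct <- c(hom_ref = sum(g == 0L, na.rm = TRUE),
           het = sum(g == 1L, na.rm = TRUE),
           hom_alt = sum(g == 2L, na.rm = TRUE),
           missing = sum(is.na(g))) / n * 100
  per_sample <- data.frame(
    sample = ds$samples,
    n_called = colSums(!is.na(g)),
    het_rate = colSums(g == 1L, na.rm = TRUE) /
      pmax(1L, colSums(!is.na(g))),
    missing_rate = colMeans(is.na(g)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(percent = pct, per_sample = per_sample)
}

#' Private markers per sample
#'
#' A site is private to sample s iff s carries at least one alternative
#' allele (het or hom_alt) and every other called sample is hom_ref, with at
#' least half of the other samples called. Sites whose single carrier is
#' accompanied by too much missingness are counted as unassignable rather
#' than private (missing genotypes could hide a second carrier).
#'
#' @param ds a (filtered) \code{variant_dataset}.
#' @param min_other_called_fraction minimum called fraction among the
#'   non-carrier samples (default 0.5).
#' @return list: \code{counts} (data.frame sample x SNP/InDel private
#'   counts), \code{by_chrom} (adds a chromosome breakdown), \code{sites}
#'   (site-level owner list), \code{unassignable} (count).
#' @export
private_markers <- function(ds, min_other_called_fraction = 0.5) {
  stopifnot(inherits(ds, "variant_dataset"))
  owner <- rep(NA_character_, n_sites(ds))
  unassignable <- 0L
  for (i in seq_len(n_sites(ds))) {
    g <- ds$calls[i, ]
    carriers <- which(!is.na(g) & g >= 1L)
    if (length(carriers) != 1L) next
    others <- g[-carriers]
    if (length(others) == 0L) next
    if (mean(!is.na(others)) >= min_other_called_fraction) {
      owner[i] <- ds$samples[carriers]
    } else {
      unassignable <- unassignable + 1L
    }
  }
  counts <- as.data.frame.matrix(
    table(factor(owner[!is.na(owner)], levels = ds$samples),
          factor(ds$sites$class[!is.na(owner)], levels = c("SNP", "InDel"))))
  counts <- data.frame(sample = rownames(counts), counts,
                       stringsAsFactors = FALSE, row.names = NULL)
  sel <- !is.na(owner)
  by_chrom <- if (any(sel)) {
    bc <- as.data.frame(table(sample = owner[sel],
                              chrom = ds$sites$chrom[sel],
                              class = ds$sites$class[sel]),
                        stringsAsFactors = FALSE)
    bc[bc$Freq > 0L, , drop = FALSE]
  } else data.frame(sample = character(0), chrom = character(0),
                    class = character(0), Freq = integer(0))
  sites <- cbind(ds$sites[sel, c("chrom", "pos", "ref", "alt", "class"),
                          drop = FALSE],
                 owner = owner[sel])
  rownames(sites) <- NULL
  list(counts = counts, by_chrom = by_chrom, sites = sites,
       unassignable = unassignable)
}

#' Identity-by-state allele-sharing matrix
#'
#' For each sample pair, over the loci where both are called:
#' similarity = (N_ibs2 + 0.5 N_ibs1) / N, where ibs2 loci carry identical
#' genotypes and ibs1 loci share exactly one allele (the PLINK DST
#' similarity; values near 0 mean high genetic distance).
#'
#' @param ds a (filtered) \code{variant_dataset}.
#' @param snps_only use only SNP sites (default TRUE, matching the common
#'   practice of computing IBS on the SNP panel; set FALSE to include
#'   InDels).
#' @return list: \code{ibs} (symmetric sample x sample matrix, diagonal 1;
#'   NA where a pair shares no co-called locus, flagged with a warning) and
#'   \code{n_loci} (per-pair co-called locus counts).
#' @export
ibs_matrix <- function(ds, snps_only = TRUE) {
  stopifnot(inherits(ds, "variant_dataset"))
  g <- ds$calls
  if (snps_only) g <- g[ds$sites$class == "SNP", , drop = FALSE]
  ns <- length(ds$samples)
  ibs <- matrix(NA_real_, ns, ns, dimnames = list(ds$samples, ds$samples))
  nl <- matrix(0L, ns, ns, dimnames = list(ds$samples, ds$samples))
  diag(ibs) <- 1
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    ok <- !is.na(g[, a]) & !is.na(g[, b])
    n <- sum(ok)
    nl[a, b] <- nl[b, a] <- n
    if (n == 0L) next
    d <- abs(g[ok, a] - g[ok, b])
    sim <- (sum(d == 0L) + 0.5 * sum(d == 1L)) / n
    ibs[a, b] <- ibs[b, a] <- sim
  }
  if (ns >= 2L && any(is.na(ibs[upper.tri(ibs)])))
    warning("some sample pairs share no co-called locus; IBS undefined (NA)",
            call. = FALSE)
  diag(nl) <- colSums(!is.na(g))
  list(ibs = ibs, n_loci = nl)
}

#' Windowed marker density per sample
#'
#' Counts, per sample, the variant-carrying sites (het or hom_alt) in
#' fixed-size windows along each chromosome. Output uses BED conventions
#' (0-based, half-open intervals).
#'
#' @param ds a \code{variant_dataset}.
#' @param window window size in bp (> 0).
#' @param chrom_lengths optional named vector; defaults to the last variant
#'   position per chromosome.
#' @return data.frame: chrom, start (0-based), end, sample, count.
#' @export
marker_density <- function(ds, window, chrom_lengths = NULL) {
  stopifnot(inherits(ds, "variant_dataset"))
  if (window <= 0) stop_cfg("'window' must be > 0")
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths)
            else unique(ds$sites$chrom)
  rows <- list()
  for (chrom in chroms) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]]
           else max(ds$sites$pos[ds$sites$chrom == chrom], 1L)
    n_win <- ceiling(len / window)
    sel <- ds$sites$chrom == chrom
    win_of <- ((ds$sites$pos[sel] - 1L) %/% window) + 1L  # 1-based window id
    for (s in seq_along(ds$samples)) {
      carried <- !is.na(ds$calls[sel, s]) & ds$calls[sel, s] >= 1L
      cnt <- tabulate(win_of[carried], nbins = n_win)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom,
        start = (seq_len(n_win) - 1L) * window,
        end = pmin(seq_len(n_win) * window, len),
        sample = ds$samples[s],
        count = cnt, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
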