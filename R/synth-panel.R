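#' Specification of a synthetic multi-sample variant panel
#'
#' Controls a toy GBS-like panel with known ground truth: per-sample planted
#' private variants (carried by exactly one sample), shared variants
#' segregating in two or more samples, and configurable heterozygosity,
#' missingness, depth, and InDel/SSR make-up.
#'
#' Defaults emulate the structure of a 12-sample landrace panel (10 inbred
#' landraces plus 2 heterozygous control hybrids) at toy scale (~500 sites
#' over 2 x 50 kb): one landrace (E42) owns the large majority of private
#' markers, per-genotype private counts are scaled down proportionally from
#' the reference panel, shared sites segregate in a few samples, and the
#' hybrids are far more heterozygous than the inbred landraces.
#'
#' @param sample_names unique sample labels.
#' @param private_counts per-sample planted private-variant counts
#'   (length = number of samples).
#' @param shared_count number of variants segregating in >= 2 samples.
#' @param het_fraction probability an alt-carrying call is heterozygous;
#'   scalar or one value per sample. Default (NULL): 0.05 for every sample
#'   except the control hybrids DOCET/JAG8810 at 0.6 (inbred landraces are
#'   nearly homozygous, F1 hybrids are not).
#' @param missing_fraction per-call missingness probability (applied after
#'   planting).
#' @param mean_depth Poisson mean of per-call read depth.
#' @param indel_fraction proportion of sites that are InDels.
#' @param ssr_fraction proportion of InDels built as SSR-type (a tandem
#'   motif inserted in whole repeat units).
#' @param seed integer RNG seed.
#' @return object of class \code{variant_panel_spec}.
#' @export
variant_panel_spec <- function(sample_names = c("E7", "E8", "E17", "E36",
                                                "E37", "E42", "E45", "E53",
                                                "E76", "E107", "DOCET",
                                                "JAG8810"),
                               private_counts = c(2L, 1L, 7L, 1L, 1L, 243L,
                                                  3L, 2L, 2L, 19L, 2L, 5L),
                               shared_count = 212L,
                               het_fraction = NULL,
                               missing_fraction = 0.005,
                               mean_depth = 12,
                               indel_fraction = 0.135,
                               ssr_fraction = 0.3,
                               seed = 1L) {
  if (anyDuplicated(sample_names)) stop_cfg("sample_names must be unique")
  if (length(private_counts) != length(sample_names))
    stop_cfg("'private_counts' must have one entry per sample (%d)",
             length(sample_names))
  if (any(private_counts < 0)) stop_cfg("'private_counts' must be >= 0")
  check_count(shared_count, "shared_count")
  if (is.null(het_fraction)) {
    # inbred landraces nearly homozygous, F1 hybrids highly heterozygous
    het_fraction <- rep(0.05, length(sample_names))
    het_fraction[sample_names %in% c("DOCET", "JAG8810")] <- 0.6
  }
  if (length(het_fraction) == 1L)
    het_fraction <- rep(het_fraction, length(sample_names))
  if (length(het_fraction) != length(sample_names))
    stop_cfg("'het_fraction' must be scalar or one value per sample")
  for (h in het_fraction) check_fraction(h, "het_fraction")
  for (f in c("missing_fraction", "indel_fraction", "ssr_fraction"))
    check_fraction(get(f), f)
  if (mean_depth < 0) stop_cfg("'mean_depth' must be >= 0")
  structure(list(sample_names = sample_names,
                 private_counts = as.integer(private_counts),
                 shared_count = as.integer(shared_count),
                 het_fraction = het_fraction,
                 missing_fraction = missing_fraction,
                 mean_depth = mean_depth,
                 indel_fraction = indel_fraction,
                 ssr_fraction = ssr_fraction,
                 seed = as.integer(seed)),
            class = "variant_panel_spec")
}

random_nonrepetitive <- function(len) {
  repeat {
    s <- random_dna(len)
    tandem <- any(vapply(1:min(6L, len - 1L), function(u) {
      len %% u == 0L &&
        s == strrep(substr(s, 1L, u), len %/% u)
    }, logical(1)))
    if (!tandem) return(s)
  }
}

#' Generate a synthetic variant panel over a toy genome
#'
#' Positions are sampled without replacement on a 40-bp grid (so allele
#' intervals never overlap), at least 150 bp from chromosome ends (so the
#' 100-bp flank queries always fit). Private variants are carried (het or
#' hom-alt per \code{het_fraction}) by exactly their target sample; shared
#' variants by 2 or more samples. Depths are Poisson around
#' \code{mean_depth}; missingness is applied after planting.
#'
#' @param genome a \code{toy_genome}.
#' @param spec a \code{variant_panel_spec}.
#' @return list: \code{dataset} (a \code{variant_dataset}) and \code{truth}
#'   (data.frame listing every planted site: chrom, pos, ref, alt, class,
#'   ssr flag, owner (NA for shared), carriers comma-joined).
#' @export
generate_variant_panel <- function(genome, spec) {
  stopifnot(inherits(genome, "toy_genome"),
            inherits(spec, "variant_panel_spec"))
  set.seed(spec$seed)
  n_total <- sum(spec$private_counts) + spec$shared_count
  ns <- length(spec$sample_names)

  # non-overlapping positions: one candidate per 40-bp bin, 150-bp margins
  bin <- 40L
  slots <- do.call(rbind, lapply(names(genome$seq), function(chrom) {
    len <- nchar(genome$seq[[chrom]])
    starts <- seq(151L, len - 151L - bin, by = bin)
    data.frame(chrom = chrom, pos = starts + sample(0:(bin - 21L),
                                                    length(starts),
                                                    replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (n_total > nrow(slots))
    stop_cfg("requested %d variants but only %d non-overlapping positions available",
             n_total, nrow(slots))
  picked <- slots[sample(nrow(slots), n_total), , drop = FALSE]
  picked <- picked[order(picked$chrom, picked$pos), , drop = FALSE]

  is_indel <- runif(n_total) < spec$indel_fraction
  is_ssr <- is_indel & runif(n_total) < spec$ssr_fraction
  ref <- alt <- character(n_total)
  for (i in seq_len(n_total)) {
    s <- genome$seq[[picked$chrom[i]]]
    p <- picked$pos[i]
    base <- substring(s, p, p)
    if (!is_indel[i]) {
      ref[i] <- base
      alt[i] <- sample(setdiff(DNA_BASES_CHR, base), 1L)
    } else if (is_ssr[i]) {
      u <- sample(1:4, 1L)
      motif <- random_dna(u)
      ref[i] <- base
      alt[i] <- paste0(base, strrep(motif, sample(3:5, 1L)))
    } else if (runif(1) < 0.5) {             # plain insertion
      ref[i] <- base
      alt[i] <- paste0(base, random_nonrepetitive(sample(5:12, 1L)))
    } else {                                 # plain deletion
      dlen <- sample(5:12, 1L)
      ref[i] <- substring(s, p, p + dlen)
      alt[i] <- base
    }
  }

  calls <- matrix(0L, n_total, ns)
  owner <- rep(NA_character_, n_total)
  carrier_code <- function(sample_idx)
    ifelse(runif(length(sample_idx)) < spec$het_fraction[sample_idx], 1L, 2L)
  idx <- sample(n_total)                     # random site-to-role assignment
  at <- 1L
  for (s_i in seq_len(ns)) {
    k <- spec$private_counts[s_i]
    if (k == 0L) next
    sites <- idx[at:(at + k - 1L)]
    at <- at + k
    owner[sites] <- spec$sample_names[s_i]
    calls[cbind(sites, s_i)] <- carrier_code(rep(s_i, k))
  }
  shared_sites <- if (spec$shared_count > 0L) idx[at:(at + spec$shared_count - 1L)]
                  else integer(0)
  for (i in shared_sites) {
    # few-carrier sites dominate, as in a mostly-homozygous-reference panel
    ks <- 2:ns
    k <- if (length(ks) == 1L) ks else sample(ks, 1L, prob = 0.55^ks)
    carriers <- sample(ns, k)
    calls[i, carriers] <- carrier_code(carriers)
  }

  carriers_str <- apply(calls, 1L, function(g)
    paste(spec$sample_names[g >= 1L], collapse = ","))

  depths <- matrix(rpois(n_total * ns, spec$mean_depth), n_total, ns)
  if (spec$missing_fraction > 0) {
    miss <- matrix(runif(n_total * ns) < spec$missing_fraction, n_total, ns)
    calls[miss] <- NA_integer_
  }

  sites <- data.frame(chrom = picked$chrom, pos = picked$pos,
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  ds <- variant_dataset(sites, spec$sample_names, calls, depths)
  truth <- data.frame(sites,
                      class = ifelse(is_indel, "InDel", "SNP"),
                      ssr = is_ssr, owner = owner,
                      carriers = carriers_str, stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(dataset = ds, truth = truth)
}
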