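#' Specification of synthetic wild-relative genomes
#'
#' Each wild genome is the reference mutated by random substitutions at a
#' per-species background divergence rate, except inside planted
#' introgression intervals, which are copied from the reference exactly and
#' additionally carry the target sample's alternative alleles — emulating a
#' cultivated genotype whose segment descends from that wild species.
#'
#' @param species_names wild species labels.
#' @param background_divergence substitution rate(s) in [0, 1), scalar or
#'   one per species. The default 0.15 places background identity near 85%,
#'   safely below the 90% acceptance threshold of the origin-assignment
#'   rule.
#' @param introgressions data.frame with columns species, sample, chrom,
#'   start, end (1-based inclusive intervals).
#' @param seed integer RNG seed.
#' @return object of class \code{wild_panel_spec}.
#' @export
wild_panel_spec <- function(species_names,
                            background_divergence = 0.15,
                            introgressions,
                            seed = 1L) {
  stopifnot(is.data.frame(introgressions),
            all(c("species", "sample", "chrom", "start", "end") %in%
                  names(introgressions)))
  if (length(background_divergence) == 1L)
    background_divergence <- rep(background_divergence,
                                 length(species_names))
  if (length(background_divergence) != length(species_names))
    stop_cfg("'background_divergence' must be scalar or one per species")
  if (any(background_divergence < 0 | background_divergence >= 1))
    stop_cfg("'background_divergence' must be in [0, 1)")
  if (!all(introgressions$species %in% species_names))
    stop_cfg("introgression species not in 'species_names'")
  if (any(introgressions$start > introgressions$end))
    stop_cfg("introgression intervals must have start <= end")
  for (sp in unique(introgressions$species)) {
    sub <- introgressions[introgressions$species == sp, ]
    for (ch in unique(sub$chrom)) {
      iv <- sub[sub$chrom == ch, ]
      iv <- iv[order(iv$start), ]
      if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)]))
        stop_cfg("overlapping introgression intervals for %s on %s", sp, ch)
    }
  }
  structure(list(species_names = species_names,
                 background_divergence = setNames(background_divergence,
                                                  species_names),
                 introgressions = introgressions,
                 seed = as.integer(seed)),
            class = "wild_panel_spec")
}

#' Generate synthetic wild-relative genomes
#'
#' @param genome the reference \code{toy_genome}.
#' @param ds the cultivated-panel \code{variant_dataset}; alt alleles
#'   carried by an interval's target sample are applied inside that
#'   interval.
#' @param spec a \code{wild_panel_spec}.
#' @return list: \code{genomes} (named list: species -> named character
#'   vector of chromosome sequences) and \code{truth} (the planted interval
#'   table). Deterministic given the seed.
#' @export
generate_wild_panel <- function(genome, ds, spec) {
  stopifnot(inherits(genome, "toy_genome"),
            inherits(ds, "variant_dataset"),
            inherits(spec, "wild_panel_spec"))
  for (i in seq_len(nrow(spec$introgressions))) {
    iv <- spec$introgressions[i, ]
    if (!iv$chrom %in% names(genome$seq))
      stop_cfg("introgression chromosome '%s' not in genome", iv$chrom)
    if (iv$start < 1L || iv$end > nchar(genome$seq[[iv$chrom]]))
      stop_cfg("introgression interval [%d, %d] outside %s bounds",
               iv$start, iv$end, iv$chrom)
    if (!iv$sample %in% ds$samples)
      stop_cfg("introgression target sample '%s' not in panel", iv$sample)
  }
  set.seed(spec$seed)
  genomes <- list()
  for (sp in spec$species_names) {
    div <- spec$background_divergence[[sp]]
    ivs <- spec$introgressions[spec$introgressions$species == sp, ,
                               drop = FALSE]
    seqs <- genome$seq
    for (chrom in names(seqs)) {
      chars <- strsplit(seqs[[chrom]], "", fixed = TRUE)[[1]]
      len <- length(chars)
      protected <- rep(FALSE, len)
      civ <- ivs[ivs$chrom == chrom, , drop = FALSE]
      for (r in seq_len(nrow(civ)))
        protected[civ$start[r]:civ$end[r]] <- TRUE
      if (div > 0) {
        hit <- which(runif(len) < div & !protected)
        if (length(hit)) {
          repl <- vapply(chars[hit], function(b)
            sample(setdiff(DNA_BASES_CHR, b), 1L), character(1),
            USE.NAMES = FALSE)
          chars[hit] <- repl
        }
      }
      s <- paste(chars, collapse = "")
      # apply the target sample's alt alleles inside each interval,
      # right-to-left so earlier coordinates stay valid
      if (nrow(civ)) {
        edits <- list()
        for (r in seq_len(nrow(civ))) {
          samp_i <- match(civ$sample[r], ds$samples)
          sel <- which(ds$sites$chrom == chrom &
                         ds$sites$pos >= civ$start[r] &
                         ds$sites$pos + nchar(ds$sites$ref) - 1L <=
                           civ$end[r] &
                         !is.na(ds$calls[, samp_i]) &
                         ds$calls[, samp_i] >= 1L)
          if (length(sel))
            edits[[length(edits) + 1L]] <-
              ds$sites[sel, c("pos", "ref", "alt")]
        }
        if (length(edits)) {
          ed <- do.call(rbind, edits)
          ed <- ed[order(-ed$pos), , drop = FALSE]
          for (r in seq_len(nrow(ed))) {
            s <- paste0(substring(s, 1L, ed$pos[r] - 1L),
                        ed$alt[r],
                        substring(s, ed$pos[r] + nchar(ed$ref[r])))
          }
        }
      }
      seqs[[chrom]] <- s
    }
    genomes[[sp]] <- seqs
  }
  list(genomes = genomes, truth = spec$introgressions)
}

#' Plan disjoint introgression intervals over a sample's candidate InDels
#'
#' Utility for building a wild-panel design: orders the sample's candidate
#' InDel loci along the genome and carves them into disjoint blocks (one per
#' species), closing a block only at a spatial gap larger than
#' \code{min_gap} once it holds \code{per} loci, so that no candidate locus
#' falls inside another species' interval or within \code{margin} of an
#' interval edge.
#'
#' @param ds a \code{variant_dataset}.
#' @param genome the reference genome.
#' @param sample carrier sample the intervals are planted for.
#' @param species species labels, one block each.
#' @param per minimum loci per block.
#' @param margin interval margin beyond the outermost locus, bp.
#' @param min_gap minimum spatial gap at which a block may close, bp.
#' @param min_len candidate-selection length threshold.
#' @return data.frame of intervals (species, sample, chrom, start, end)
#'   suitable for \code{\link{wild_panel_spec}}; errors if fewer blocks than
#'   species can be carved.
#' @export
plan_introgressions <- function(ds, genome, sample, species, per = 10L,
                                margin = 150L, min_gap = 2L * margin,
                                min_len = 5L) {
  cand <- select_candidate_indels(ds, genome, min_len = min_len)
  samp_i <- match(sample, ds$samples)
  if (is.na(samp_i)) stop_cfg("sample '%s' not in panel", sample)
  carried <- !is.na(ds$calls[cand$site, samp_i]) &
    ds$calls[cand$site, samp_i] >= 1L
  cand <- cand[carried, , drop = FALSE]
  cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
  blocks <- list()
  for (ch in unique(cand$chrom)) {
    rows <- cand[cand$chrom == ch, , drop = FALSE]
    members <- integer(0)
    for (i in seq_len(nrow(rows))) {
      members <- c(members, i)
      gap_next <- if (i < nrow(rows)) rows$pos[i + 1L] - rows$pos[i] else Inf
      if (length(members) >= per && gap_next > min_gap) {
        blocks[[length(blocks) + 1L]] <- rows[members, , drop = FALSE]
        members <- integer(0)
      }
    }
  }
  if (length(blocks) < length(species))
    stop_cfg("only %d candidate blocks available for %d species; lower 'per' or enlarge the panel",
             length(blocks), length(species))
  do.call(rbind, lapply(seq_along(species), function(i) {
    rows <- blocks[[i]]
    data.frame(species = species[i], sample = sample,
               chrom = rows$chrom[1L],
               start = max(1L, min(rows$pos) - margin),
               end = min(nchar(genome$seq[[rows$chrom[1L]]]),
                         max(rows$pos) + margin),
               n_loci = nrow(rows), stringsAsFactors = FALSE)
  }))
}
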