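#' Consequence-term severity order and impact tiers
#'
#' Severity-ordered consequence vocabulary with SnpEff-style impact tiers:
#' high = disruptive to the protein (stop gain/loss, start loss, frameshift,
#' splice acceptor/donor), moderate = non-disruptive protein change,
#' low = synonymous or splice-region, modifier = non-coding.
#' @export
EFFECT_SEVERITY <- c(
  stop_gained = "high", stop_lost = "high", start_lost = "high",
  frameshift_variant = "high", splice_acceptor_variant = "high",
  splice_donor_variant = "high",
  inframe_insertion = "moderate", inframe_deletion = "moderate",
  missense_variant = "moderate",
  synonymous_variant = "low", splice_region_variant = "low",
  five_prime_UTR_variant = "modifier", three_prime_UTR_variant = "modifier",
  intron_variant = "modifier", upstream_gene_variant = "modifier",
  downstream_gene_variant = "modifier", intergenic_variant = "modifier")

IMPACT_ORDER <- c("high", "moderate", "low", "modifier")

order_terms <- function(terms) {
  terms <- unique(terms)
  terms[order(match(terms, names(EFFECT_SEVERITY)))]
}

impact_of <- function(terms) {
  IMPACT_ORDER[min(match(EFFECT_SEVERITY[terms], IMPACT_ORDER))]
}

# trim the shared leading anchor base(s) of a VCF-style record; returns the
# left-normalized representation: for an insertion ref becomes "", for a
# deletion alt becomes "", pos points at the first differing base.
trim_anchor <- function(pos, ref, alt) {
  while (nchar(ref) >= 1L && nchar(alt) >= 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         !(nchar(ref) == 1L && nchar(alt) == 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# region terms for one genomic position inside a gene (splice windows:
# acceptor/donor = intronic 1-2; splice_region = exonic 1-3 / intronic 3-8)
position_terms <- function(p, gene) {
  n_ex <- nrow(gene$exons)
  ex_hit <- which(p >= gene$exons[, 1L] & p <= gene$exons[, 2L])
  terms <- character(0)
  if (length(ex_hit)) {
    k <- ex_hit[1L]
    in_cds <- any(p >= gene$cds[, 1L] & p <= gene$cds[, 2L])
    if (!in_cds) {
      cds_min <- min(gene$cds[, 1L]); cds_max <- max(gene$cds[, 2L])
      five <- if (gene$strand == "+") p < cds_min else p > cds_max
      terms <- c(terms, if (five) "five_prime_UTR_variant"
                        else "three_prime_UTR_variant")
    }
    # exonic splice region: 1-3 bases from an internal junction
    d_left <- p - gene$exons[k, 1L] + 1L
    d_right <- gene$exons[k, 2L] - p + 1L
    near <- (k > 1L && d_left <= 3L) || (k < n_ex && d_right <= 3L)
    if (near) terms <- c(terms, "splice_region_variant")
    attr(terms, "cds") <- in_cds
    return(terms)
  }
  # intronic: locate intron
  for (k in seq_len(n_ex - 1L)) {
    s <- gene$exons[k, 2L] + 1L
    e <- gene$exons[k + 1L, 1L] - 1L
    if (p < s || p > e) next
    d_left <- p - s + 1L
    d_right <- e - p + 1L
    if (gene$strand == "+") { d_donor <- d_left; d_acc <- d_right }
    else { d_donor <- d_right; d_acc <- d_left }
    if (d_donor <= 2L) terms <- c("splice_donor_variant", "intron_variant")
    else if (d_acc <= 2L) terms <- c("splice_acceptor_variant",
                                     "intron_variant")
    else if (min(d_donor, d_acc) <= 8L)
      terms <- c("splice_region_variant", "intron_variant")
    else terms <- "intron_variant"
    attr(terms, "cds") <- FALSE
    return(terms)
  }
  attr(terms, "cds") <- FALSE
  terms
}

# 1-based coordinate of genomic position p within the spliced CDS
# (transcript orientation); NA when p is not coding.
cds_coordinate <- function(p, gene) {
  lens <- gene$cds[, 2L] - gene$cds[, 1L] + 1L
  total <- sum(lens)
  before <- 0L
  for (k in seq_len(nrow(gene$cds))) {
    if (p >= gene$cds[k, 1L] && p <= gene$cds[k, 2L]) {
      plus_coord <- before + (p - gene$cds[k, 1L] + 1L)
      return(if (gene$strand == "+") plus_coord else total - plus_coord + 1L)
    }
    before <- before + lens[k]
  }
  NA_integer_
}

classify_one <- function(chrom, pos, ref, alt, genome, upstream_bp = 5000L) {
  s <- genome$seq[[chrom]]
  if (is.null(s)) stop_cfg("chromosome '%s' not in genome", chrom)
  if (substring(s, pos, pos + nchar(ref) - 1L) != ref)
    stop_cfg("ref allele mismatch at %s:%d (VCF says %s, genome has %s)",
             chrom, pos, ref, substring(s, pos, pos + nchar(ref) - 1L))
  tr <- trim_anchor(pos, ref, alt)
  is_ins <- nchar(tr$ref) == 0L
  is_del <- nchar(tr$alt) == 0L
  is_indel <- is_ins || is_del
  net <- nchar(tr$alt) - nchar(tr$ref)
  affected <- if (is_ins) c(max(1L, tr$pos - 1L), tr$pos)
              else tr$pos:(tr$pos + max(0L, nchar(tr$ref) - 1L))

  genes <- Filter(function(g) g$chrom == chrom, genome$genes)
  overl <- Filter(function(g) min(affected) <= g$end &&
                    max(affected) >= g$start, genes)

  if (length(overl) == 0L) {
    # nearest gene within the up/downstream window
    if (length(genes)) {
      dist <- vapply(genes, function(g)
        max(0L, max(g$start - max(affected), min(affected) - g$end)),
        numeric(1))
      near <- which.min(dist)
      if (dist[near] <= upstream_bp) {
        g <- genes[[near]]
        before <- max(affected) < g$start
        upstream <- if (g$strand == "+") before else !before
        term <- if (upstream) "upstream_gene_variant"
                else "downstream_gene_variant"
        return(list(gene_id = g$gene_id, terms = term,
                    impact = impact_of(term)))
      }
    }
    return(list(gene_id = NA_character_, terms = "intergenic_variant",
                impact = "modifier"))
  }

  best <- NULL
  for (g in overl) {
    terms <- character(0)
    any_cds <- FALSE
    for (p in affected[affected >= g$start & affected <= g$end]) {
      pt <- position_terms(p, g)
      any_cds <- any_cds || isTRUE(attr(pt, "cds"))
      terms <- c(terms, pt)
    }
    if (any_cds) {
      if (is_indel) {
        terms <- c(terms,
                   if (net %% 3L != 0L) "frameshift_variant"
                   else if (net > 0L) "inframe_insertion"
                   else "inframe_deletion")
      } else if (nchar(tr$ref) == 1L) {
        cpos <- cds_coordinate(tr$pos, g)
        if (!is.na(cpos)) {
          cds_seq <- cds_sequence(genome, g)
          codon_i <- (cpos - 1L) %/% 3L + 1L
          within <- (cpos - 1L) %% 3L + 1L
          ref_codon <- substring(cds_seq, 3L * codon_i - 2L, 3L * codon_i)
          alt_base <- if (g$strand == "+") tr$alt else revcomp_chr(tr$alt)
          alt_codon <- ref_codon
          substr(alt_codon, within, within) <- alt_base
          ref_aa <- translate_codon(ref_codon)
          alt_aa <- translate_codon(alt_codon)
          terms <- c(terms,
                     if (codon_i == 1L && alt_codon != "ATG") "start_lost"
                     else if (ref_aa == "*" && alt_aa != "*") "stop_lost"
                     else if (ref_aa != "*" && alt_aa == "*") "stop_gained"
                     else if (ref_aa == alt_aa) "synonymous_variant"
                     else "missense_variant")
        }
      }
    }
    if (length(terms) == 0L) terms <- "intergenic_variant"
    terms <- order_terms(terms)
    cand <- list(gene_id = g$gene_id, terms = terms,
                 impact = impact_of(terms))
    if (is.null(best) ||
        match(cand$impact, IMPACT_ORDER) < match(best$impact, IMPACT_ORDER))
      best <- cand
  }
  best
}

#' Classify panel variants against gene models
#'
#' SnpEff-style consequence assignment: coding SNVs are resolved through the
#' standard genetic code (minus-strand genes via reverse complement) into
#' stop_gained / stop_lost / start_lost / missense / synonymous; coding
#' InDels into frameshift (net length not a multiple of 3) or inframe
#' insertion/deletion; variants in the first/last 2 intronic bases are
#' splice acceptor/donor (high) and the 1-3 exonic / 3-8 intronic junction
#' windows are splice_region (low); intron, UTR, upstream/downstream (5 kb)
#' and intergenic variants are modifiers. InDels are left-normalized by
#' trimming the shared anchor base before classification. Multi-term calls
#' are joined with " & " in severity order; the impact tier is the maximum
#' severity over terms.
#'
#' @param ds a \code{variant_dataset} (or data.frame with chrom, pos, ref,
#'   alt columns).
#' @param genome a \code{toy_genome} (sequences plus gene structures, e.g.
#'   from \code{\link{generate_genome}} or rebuilt via
#'   \code{\link{read_genome_fasta}} + \code{\link{read_gff3_genes}}).
#' @param upstream_bp up/downstream window, bp (default 5000).
#' @return data.frame: chrom, pos, ref, alt, class, gene, effect
#'   (severity-ordered terms joined by " & "), impact.
#' @export
classify_variants <- function(ds, genome, upstream_bp = 5000L) {
  sites <- if (inherits(ds, "variant_dataset")) ds$sites else ds
  if (!"class" %in% names(sites))
    sites$class <- ifelse(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L,
                          "SNP", "InDel")
  res <- lapply(seq_len(nrow(sites)), function(i)
    classify_one(sites$chrom[i], sites$pos[i], sites$ref[i], sites$alt[i],
                 genome, upstream_bp))
  data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    class = sites$class,
    gene = vapply(res, `[[`, character(1), "gene_id"),
    effect = vapply(res, function(r) paste(r$terms, collapse = " & "),
                    character(1)),
    impact = vapply(res, `[[`, character(1), "impact"),
    stringsAsFactors = FALSE)
}

#' Impact-tier summary by variant class
#'
#' Tier x class counts plus the number of distinct affected genes (a gene
#' hit by several mutations counts once), reported per class and as the
#' union (the per-class gene sets can overlap, so the union is not their
#' sum).
#'
#' @param calls output of \code{\link{classify_variants}}.
#' @return list: \code{counts} (data.frame class x tier counts with totals)
#'   and \code{affected_genes} (named counts: SNP, InDel, union).
#' @export
summarize_impacts <- function(calls) {
  classes <- c("SNP", "InDel")
  counts <- do.call(rbind, lapply(classes, function(cl) {
    sub <- calls[calls$class == cl, , drop = FALSE]
    data.frame(class = cl, total = nrow(sub),
               high = sum(sub$impact == "high"),
               moderate = sum(sub$impact == "moderate"),
               low = sum(sub$impact == "low"),
               modifier = sum(sub$impact == "modifier"),
               stringsAsFactors = FALSE)
  }))
  genes_of <- function(sub) unique(sub$gene[!is.na(sub$gene)])
  affected <- c(
    SNP = length(genes_of(calls[calls$class == "SNP", ])),
    InDel = length(genes_of(calls[calls$class == "InDel", ])),
    union = length(genes_of(calls)))
  list(counts = counts, affected_genes = affected)
}

#' High-impact mutation report
#'
#' One row per high-impact mutation (a gene with several such mutations
#' appears once per mutation), with the carrier samples and a private-owner
#' flag set when exactly one sample carries the mutation.
#'
#' @param calls output of \code{\link{classify_variants}}.
#' @param ds the \code{variant_dataset} the calls were made on (for carrier
#'   genotypes).
#' @return data.frame: gene, class, chrom, pos, ref, alt, effect, carriers
#'   (comma-joined), n_carriers, private_to (NA unless a single carrier).
#' @export
high_impact_report <- function(calls, ds) {
  stopifnot(inherits(ds, "variant_dataset"))
  hi <- which(calls$impact == "high")
  rows <- lapply(hi, function(i) {
    j <- which(ds$sites$chrom == calls$chrom[i] &
                 ds$sites$pos == calls$pos[i] &
                 ds$sites$alt == calls$alt[i])[1L]
    g <- ds$calls[j, ]
    carriers <- ds$samples[!is.na(g) & g >= 1L]
    data.frame(gene = calls$gene[i], class = calls$class[i],
               chrom = calls$chrom[i], pos = calls$pos[i],
               ref = calls$ref[i], alt = calls$alt[i],
               effect = calls$effect[i],
               carriers = paste(carriers, collapse = ","),
               n_carriers = length(carriers),
               private_to = if (length(carriers) == 1L) carriers
                            else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(gene = character(0), class = character(0),
               chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), effect = character(0),
               carriers = character(0), n_carriers = integer(0),
               private_to = character(0))
  rownames(out) <- NULL
  out
}
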