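# Compact variant_dataset builder: `calls` is a sites x samples integer
# matrix (0/1/2/NA); sites default to SNPs on one chromosome.
make_ds <- function(calls, chrom = "chr1", pos = NULL, ref = NULL,
                    alt = NULL, depths = NULL, samples = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(calls)))
  variant_dataset(
    data.frame(chrom = rep(chrom, length.out = n), pos = pos,
               ref = ref, alt = alt, stringsAsFactors = FALSE),
    samples, calls, depths)
}

# Brute-force IBS oracle: enumerate the four alleles of each pair at each
# co-called locus and count shared alleles (0/1/2), independent of the
# matrix-coded implementation.
ibs_brute <- function(ds) {
  geno_alleles <- function(code) switch(as.character(code),
                                        "0" = c(0L, 0L),
                                        "1" = c(0L, 1L),
                                        "2" = c(1L, 1L))
  ns <- length(ds$samples)
  out <- matrix(NA_real_, ns, ns, dimnames = list(ds$samples, ds$samples))
  diag(out) <- 1
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    num <- 0; den <- 0L
    for (i in seq_len(nrow(ds$sites))) {
      ga <- ds$calls[i, a]; gb <- ds$calls[i, b]
      if (is.na(ga) || is.na(gb)) next
      aa <- sort(geno_alleles(ga)); bb <- sort(geno_alleles(gb))
      shared <- if (identical(aa, bb)) 2L
                else if (length(intersect(aa, bb)) > 0L) 1L else 0L
      num <- num + shared / 2
      den <- den + 1L
    }
    if (den > 0L) out[a, b] <- out[b, a] <- num / den
  }
  out
}

# Brute-force balanced three-way ANOVA oracle: sums of squares from the
# textbook mean decomposition, n x (effect deviation)^2 per source.
anova_brute <- function(df) {
  gm <- mean(df$value)
  mg <- tapply(df$value, df$G, mean)
  ml <- tapply(df$value, df$L, mean)
  my <- tapply(df$value, df$Y, mean)
  mgl <- tapply(df$value, list(df$G, df$L), mean)
  mgy <- tapply(df$value, list(df$G, df$Y), mean)
  mly <- tapply(df$value, list(df$L, df$Y), mean)
  mgly <- tapply(df$value, list(df$G, df$L, df$Y), mean)
  r <- nrow(df) / length(mgly)
  ng <- length(mg); nl <- length(ml); ny <- length(my)
  ss <- c(
    G = r * nl * ny * sum((mg - gm)^2),
    L = r * ng * ny * sum((ml - gm)^2),
    Y = r * ng * nl * sum((my - gm)^2))
  ss["G:L"] <- r * ny * sum((sweep(sweep(mgl, 1, mg), 2, ml) + gm)^2)
  ss["G:Y"] <- r * nl * sum((sweep(sweep(mgy, 1, mg), 2, my) + gm)^2)
  ss["L:Y"] <- r * ng * sum((sweep(sweep(mly, 1, ml), 2, my) + gm)^2)
  dev3 <- mgly
  for (g in seq_len(ng)) for (l in seq_len(nl)) for (y in seq_len(ny))
    dev3[g, l, y] <- mgly[g, l, y] - mgl[g, l] - mgy[g, y] - mly[l, y] +
      mg[g] + ml[l] + my[y] - gm
  ss["G:L:Y"] <- r * sum(dev3^2)
  cellmean <- mgly[cbind(match(df$G, dimnames(mgly)[[1]]),
                         match(df$L, dimnames(mgly)[[2]]),
                         match(df$Y, dimnames(mgly)[[3]]))]
  ss["Residuals"] <- sum((df$value - cellmean)^2)
  ss
}

# --- enumerated effect-classifier truth table ---------------------------

helper_severity <- c(
  stop_gained = "high", stop_lost = "high", start_lost = "high",
  frameshift_variant = "high", splice_acceptor_variant = "high",
  splice_donor_variant = "high",
  inframe_insertion = "moderate", inframe_deletion = "moderate",
  missense_variant = "moderate",
  synonymous_variant = "low", splice_region_variant = "low",
  five_prime_UTR_variant = "modifier", three_prime_UTR_variant = "modifier",
  intron_variant = "modifier", upstream_gene_variant = "modifier",
  downstream_gene_variant = "modifier", intergenic_variant = "modifier")

helper_impact <- function(terms) {
  lev <- c("high", "moderate", "low", "modifier")
  lev[min(match(helper_severity[terms], lev))]
}

helper_revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

helper_translate <- function(codon) {
  if (grepl("N", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

# spliced CDS extracted with Biostrings (independent of the package path)
helper_cds_seq <- function(gene, chromseq) {
  parts <- vapply(seq_len(nrow(gene$cds)), function(k)
    substring(chromseq, gene$cds[k, 1], gene$cds[k, 2]), character(1))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") helper_revcomp(s) else s
}

# genomic position of 1-based CDS (transcript) coordinate c
helper_cds_genomic <- function(gene, c) {
  lens <- gene$cds[, 2] - gene$cds[, 1] + 1
  if (gene$strand == "+") {
    k <- 1L
    while (c > lens[k]) { c <- c - lens[k]; k <- k + 1L }
    gene$cds[k, 1] + c - 1L
  } else {
    k <- nrow(gene$cds)
    while (c > lens[k]) { c <- c - lens[k]; k <- k - 1L }
    gene$cds[k, 2] - c + 1L
  }
}

# Construct a truth table of variants with expected consequence terms for
# one gene (codon arithmetic and splice-window bookkeeping done here, by
# hand, independently of the classifier).
effect_truth_for_gene <- function(genome, gene) {
  s <- genome$seq[[gene$chrom]]
  cds <- helper_cds_seq(gene, s)
  n_codon <- nchar(cds) / 3
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  bases <- c("A", "C", "G", "T")
  variants <- list()
  add <- function(pos, ref, alt, terms) {
    variants[[length(variants) + 1L]] <<- data.frame(
      chrom = gene$chrom, pos = pos, ref = ref, alt = alt,
      expected = paste(sort(terms), collapse = "|"),
      expected_impact = helper_impact(terms), stringsAsFactors = FALSE)
  }
  # place a designed SNV at CDS coordinate c: ref/alt given in CDS strand
  snv_at <- function(c, alt_cds_base, terms) {
    p <- helper_cds_genomic(gene, c)
    ref_g <- substring(s, p, p)
    cds_base <- substring(cds, c, c)
    stopifnot(ref_g == if (gene$strand == "+") cds_base
                       else helper_revcomp(cds_base))
    alt_g <- if (gene$strand == "+") alt_cds_base
             else helper_revcomp(alt_cds_base)
    # exonic splice_region co-term when within 3 bases of an internal junction
    extra <- character(0)
    for (k in seq_len(nrow(gene$exons))) {
      if (p < gene$exons[k, 1] || p > gene$exons[k, 2]) next
      if (k > 1 && p - gene$exons[k, 1] + 1 <= 3)
        extra <- "splice_region_variant"
      if (k < nrow(gene$exons) && gene$exons[k, 2] - p + 1 <= 3)
        extra <- "splice_region_variant"
    }
    add(p, ref_g, alt_g, c(terms, extra))
  }
  # search a codon/position/base giving the wanted amino-acid transition
  find_snv <- function(pred, from = 2, to = n_codon - 1) {
    for (ci in from:to) for (w in 1:3) for (b in bases) {
      cod <- codons[ci]
      if (substring(cod, w, w) == b) next
      alt_cod <- cod
      substr(alt_cod, w, w) <- b
      if (pred(helper_translate(cod), helper_translate(alt_cod)))
        return(list(c = 3 * (ci - 1) + w, b = b))
    }
    NULL
  }
  sg <- find_snv(function(a1, a2) a1 != "*" && a2 == "*")
  if (!is.null(sg)) snv_at(sg$c, sg$b, "stop_gained")
  mis <- find_snv(function(a1, a2) a1 != "*" && a2 != "*" && a1 != a2)
  snv_at(mis$c, mis$b, "missense_variant")
  syn <- find_snv(function(a1, a2) a1 != "*" && a1 == a2)
  snv_at(syn$c, syn$b, "synonymous_variant")
  # start codon: ATG -> ACG
  snv_at(2, "C", "start_lost")
  # stop codon: last codon, change so it no longer stops
  sl <- find_snv(function(a1, a2) a1 == "*" && a2 != "*",
                 from = n_codon, to = n_codon)
  snv_at(sl$c, sl$b, "stop_lost")

  # mid-CDS indels: find a CDS coordinate with >= 6 contiguous CDS bases
  p0 <- NULL
  for (cc in 10:(nchar(cds) - 10)) {
    p_try <- helper_cds_genomic(gene, cc)
    ok <- all(vapply(0:5, function(d) {
      pp <- p_try + d
      any(pp >= gene$cds[, 1] & pp <= gene$cds[, 2])
    }, logical(1)))
    if (ok) { p0 <- p_try; break }
  }
  if (!is.null(p0)) {
    b0 <- substring(s, p0, p0)
    add(p0, b0, paste0(b0, "A"), "frameshift_variant")
    add(p0, b0, paste0(b0, "ACT"), "inframe_insertion")
    add(p0, substring(s, p0, p0 + 3), b0, "inframe_deletion")
    add(p0, substring(s, p0, p0 + 1), b0, "frameshift_variant")
  }

  if (nrow(gene$exons) > 1) {
    i_start <- gene$exons[1, 2] + 1
    i_end <- gene$exons[2, 1] - 1
    donor_p <- if (gene$strand == "+") i_start else i_end
    acc_p <- if (gene$strand == "+") i_end else i_start
    step <- if (gene$strand == "+") 1L else -1L
    flip <- function(p) {
      b <- substring(s, p, p)
      setdiff(bases, b)[1]
    }
    add(donor_p, substring(s, donor_p, donor_p), flip(donor_p),
        c("splice_donor_variant", "intron_variant"))
    add(acc_p, substring(s, acc_p, acc_p), flip(acc_p),
        c("splice_acceptor_variant", "intron_variant"))
    sr_p <- donor_p + 4L * step            # intronic base 5 from the donor
    if (i_end - i_start + 1 >= 13)
      add(sr_p, substring(s, sr_p, sr_p), flip(sr_p),
          c("splice_region_variant", "intron_variant"))
    mid_p <- (i_start + i_end) %/% 2
    if (mid_p - i_start + 1 > 8 && i_end - mid_p + 1 > 8)
      add(mid_p, substring(s, mid_p, mid_p), flip(mid_p), "intron_variant")
  }

  # UTRs: 4 bases inside the transcript ends (UTRs are >= 20 bp by design)
  flip <- function(p) setdiff(bases, substring(s, p, p))[1]
  utr5_p <- if (gene$strand == "+") gene$start + 3 else gene$end - 3
  utr3_p <- if (gene$strand == "+") gene$end - 3 else gene$start + 3
  add(utr5_p, substring(s, utr5_p, utr5_p), flip(utr5_p),
      "five_prime_UTR_variant")
  add(utr3_p, substring(s, utr3_p, utr3_p), flip(utr3_p),
      "three_prime_UTR_variant")

  do.call(rbind, variants)
}

# Up/downstream and intergenic cases need genome-level placement.
effect_truth_flanking <- function(genome) {
  flip <- function(s, p) setdiff(c("A", "C", "G", "T"),
                                 substring(s, p, p))[1]
  rows <- list()
  for (gid in names(genome$genes)[1:2]) {
    g <- genome$genes[[gid]]
    s <- genome$seq[[g$chrom]]
    others <- Filter(function(x) x$chrom == g$chrom &&
                       x$gene_id != g$gene_id, genome$genes)
    up_p <- g$start - 100L
    dn_p <- g$end + 100L
    near <- function(p) min(vapply(others, function(o)
      max(0, max(o$start - p, p - o$end)), numeric(1)), Inf)
    if (up_p >= 1 && near(up_p) > 100) {
      term <- if (g$strand == "+") "upstream_gene_variant"
              else "downstream_gene_variant"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, pos = up_p, ref = substring(s, up_p, up_p),
        alt = flip(s, up_p), expected = term,
        expected_impact = "modifier", stringsAsFactors = FALSE)
    }
    if (dn_p <= nchar(s) && near(dn_p) > 100) {
      term <- if (g$strand == "+") "downstream_gene_variant"
              else "upstream_gene_variant"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, pos = dn_p, ref = substring(s, dn_p, dn_p),
        alt = flip(s, dn_p), expected = term,
        expected_impact = "modifier", stringsAsFactors = FALSE)
    }
  }
  # intergenic: far beyond the last gene on its chromosome
  for (chrom in names(genome$seq)) {
    s <- genome$seq[[chrom]]
    genes_c <- Filter(function(x) x$chrom == chrom, genome$genes)
    last_end <- if (length(genes_c)) max(vapply(genes_c, `[[`, 0, "end"))
                else 0
    p <- last_end + 6000L
    if (p <= nchar(s)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = p, ref = substring(s, p, p),
        alt = flip(s, p), expected = "intergenic_variant",
        expected_impact = "modifier", stringsAsFactors = FALSE)
      break
    }
  }
  do.call(rbind, rows)
}

# Full truth table on a genome that has a multi-exon gene on each strand.
effect_truth_table <- function(genome) {
  multi <- Filter(function(g) nrow(g$exons) > 1, genome$genes)
  strands <- vapply(multi, `[[`, "", "strand")
  stopifnot(any(strands == "+"), any(strands == "-"))
  plus <- multi[[which(strands == "+")[1]]]
  minus <- multi[[which(strands == "-")[1]]]
  rbind(effect_truth_for_gene(genome, plus),
        effect_truth_for_gene(genome, minus),
        effect_truth_flanking(genome))
}
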