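STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(DNA_BASES_CHR, DNA_BASES_CHR, DNA_BASES_CHR)
  paste0(g[, 3], g[, 2], g[, 1])
}

#' Specification of a synthetic toy genome
#'
#' A stand-in reference genome for exercising the variant pipeline: random
#' background sequence at a target GC content, carrying simple protein-coding
#' gene models (single transcript per gene; 5'UTR, spliced CDS starting with
#' ATG and ending with a stop codon, 3'UTR; canonical GT..AG introns) on
#' random strands.
#'
#' @param chromosome_lengths base counts per chromosome (default 2 x 50 kb,
#'   the package's seconds-scale toy default).
#' @param n_genes number of genes to place (0 allowed).
#' @param mean_exons_per_gene mean exon count per gene.
#' @param gc_fraction background GC proportion, in (0, 1).
#' @param seed integer RNG seed.
#' @return object of class \code{genome_spec}.
#' @export
genome_spec <- function(chromosome_lengths = c(chr01 = 50000L, chr02 = 50000L),
                        n_genes = 16L, mean_exons_per_gene = 3,
                        gc_fraction = 0.38, seed = 1L) {
  if (any(chromosome_lengths <= 0)) stop_cfg("chromosome lengths must be > 0")
  check_count(n_genes, "n_genes", min = 0L)
  check_fraction(gc_fraction, "gc_fraction")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop_cfg("'gc_fraction' must be strictly inside (0, 1)")
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- sprintf("chr%02d",
                                         seq_along(chromosome_lengths))
  structure(list(chromosome_lengths = chromosome_lengths,
                 n_genes = as.integer(n_genes),
                 mean_exons_per_gene = mean_exons_per_gene,
                 gc_fraction = gc_fraction, seed = as.integer(seed)),
            class = "genome_spec")
}

# Build one gene's transcript-coordinate layout, then anchor it at a genomic
# start and mirror it for minus-strand genes.
build_gene <- function(gene_id, chrom, g_start, strand, mean_exons) {
  n_ex <- max(1L, 1L + rpois(1L, max(0, mean_exons - 1)))
  n_codons <- sample(40:120, 1L)
  cds_len <- 3L * n_codons
  extra <- cds_len - 3L * n_ex
  if (extra < 0) { n_ex <- 1L; extra <- cds_len - 3L }
  pieces <- 3L + as.vector(stats::rmultinom(1L, extra, rep(1, n_ex)))
  utr5 <- sample(20:80, 1L)
  utr3 <- sample(20:80, 1L)
  introns <- if (n_ex > 1L) sample(40:150, n_ex - 1L, replace = TRUE)
             else integer(0)

  # transcript-order exon lengths
  ex_len <- pieces
  ex_len[1L] <- ex_len[1L] + utr5
  ex_len[n_ex] <- ex_len[n_ex] + utr3
  span <- sum(ex_len) + sum(introns)

  # transcript-forward coordinates, 0-based offsets within the gene
  off <- 0L
  ex_t <- matrix(0L, n_ex, 2L)
  for (k in seq_len(n_ex)) {
    ex_t[k, ] <- c(off, off + ex_len[k] - 1L)
    off <- off + ex_len[k] + if (k < n_ex) introns[k] else 0L
  }
  cds_t <- ex_t
  cds_t[1L, 1L] <- cds_t[1L, 1L] + utr5
  cds_t[n_ex, 2L] <- cds_t[n_ex, 2L] - utr3

  g_end <- g_start + span - 1L
  to_genomic <- function(m) {
    if (strand == "+") m + g_start
    else cbind(g_start + g_end - (m[, 2L] + g_start),
               g_start + g_end - (m[, 1L] + g_start)) + 0L
  }
  exons <- to_genomic(ex_t)
  cds <- to_genomic(cds_t)
  ord <- order(exons[, 1L])
  exons <- exons[ord, , drop = FALSE]
  cds <- cds[order(cds[, 1L]), , drop = FALSE]

  # GFF phase per CDS piece in transcript order
  phase_t <- (3L - cumsum(c(0L, pieces[-n_ex])) %% 3L) %% 3L
  phases <- if (strand == "+") phase_t else rev(phase_t)

  # design the coding sequence: ATG + non-stop codons + stop
  sense <- setdiff(all_codons(), STOP_CODONS)
  cds_seq <- paste0("ATG",
                    paste(sample(sense, n_codons - 2L, replace = TRUE),
                          collapse = ""),
                    sample(STOP_CODONS, 1L))

  list(gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
       chrom = chrom, strand = strand, start = g_start, end = g_end,
       exons = exons, cds = cds, phases = phases,
       pieces = pieces, cds_seq = cds_seq)
}

# paint the designed CDS and canonical splice sites onto the chromosome string
paint_gene <- function(seq, gene) {
  n_cds <- nrow(gene$cds)
  # transcript-order CDS rows: ascending for +, descending for -
  rows <- if (gene$strand == "+") seq_len(n_cds) else rev(seq_len(n_cds))
  offset <- 0L
  for (k in seq_along(rows)) {
    iv <- gene$cds[rows[k], ]
    piece <- substr(gene$cds_seq, offset + 1L, offset + (iv[2L] - iv[1L] + 1L))
    if (gene$strand == "-") piece <- revcomp_chr(piece)
    substr(seq, iv[1L], iv[2L]) <- piece
    offset <- offset + (iv[2L] - iv[1L] + 1L)
  }
  if (nrow(gene$exons) > 1L) {
    for (k in seq_len(nrow(gene$exons) - 1L)) {
      s <- gene$exons[k, 2L] + 1L       # genomic intron interval
      e <- gene$exons[k + 1L, 1L] - 1L
      if (gene$strand == "+") {
        substr(seq, s, s + 1L) <- "GT"
        substr(seq, e - 1L, e) <- "AG"
      } else {
        substr(seq, s, s + 1L) <- "CT"  # revcomp acceptor AG
        substr(seq, e - 1L, e) <- "AC"  # revcomp donor GT
      }
    }
  }
  seq
}

#' Generate a toy genome with gene models
#'
#' @param spec a \code{\link{genome_spec}}.
#' @return object of class \code{toy_genome}: list with \code{seq} (named
#'   character vector of chromosome sequences), \code{genes} (list of gene
#'   structures: exon/CDS genomic intervals, strand, phases, designed CDS)
#'   and \code{spec}. Deterministic given the seed.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  lens <- spec$chromosome_lengths
  seqs <- vapply(lens, function(n) random_dna(n, spec$gc_fraction),
                 character(1))
  names(seqs) <- names(lens)

  genes <- list()
  if (spec$n_genes > 0L) {
    cursors <- pmin(lens, 200L + sample(0:200, length(lens), replace = TRUE))
    chrom_order <- rep(seq_along(lens), length.out = spec$n_genes)
    for (g in seq_len(spec$n_genes)) {
      placed <- FALSE
      for (ci in unique(c(chrom_order[g], seq_along(lens)))) {
        gene <- build_gene(sprintf("gene%03d", g), names(lens)[ci],
                           as.integer(cursors[ci]),
                           sample(c("+", "-"), 1L),
                           spec$mean_exons_per_gene)
        if (gene$end <= lens[ci] - 200L) {
          genes[[gene$gene_id]] <- gene
          seqs[ci] <- paint_gene(seqs[ci], gene)
          cursors[ci] <- gene$end + sample(300:800, 1L)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_cfg("gene %d does not fit on any chromosome (lengths too small)", g)
    }
  }
  structure(list(seq = seqs, genes = genes, spec = spec),
            class = "toy_genome")
}

#' Spliced coding sequence of a gene, read from the genome
#' @param genome a \code{toy_genome} (or list with \code{$seq}).
#' @param gene one element of \code{genome$genes}.
#' @return character scalar, transcript orientation (starts with ATG).
#' @export
cds_sequence <- function(genome, gene) {
  s <- genome$seq[[gene$chrom]]
  parts <- vapply(seq_len(nrow(gene$cds)), function(k)
    substring(s, gene$cds[k, 1L], gene$cds[k, 2L]), character(1))
  out <- paste(parts, collapse = "")
  if (gene$strand == "-") out <- revcomp_chr(out)
  out
}

#' Write genome sequences as FASTA (60-column wrap)
#' @param genome a \code{toy_genome}.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a FASTA genome into the plain-string representation
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Gene models as a GFF3-style feature table
#' @param genome a \code{toy_genome}.
#' @return data.frame with GFF3 columns (1-based inclusive coordinates,
#'   \code{gene}/\code{mRNA}/\code{exon}/\code{CDS} features, CDS phase).
#' @export
gene_features <- function(genome) {
  rows <- list()
  add <- function(chrom, type, start, end, strand, phase, attrs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = chrom, source = "yieldvar", type = type,
      start = start, end = end, score = ".", strand = strand,
      phase = phase, attributes = attrs, stringsAsFactors = FALSE)
  }
  for (g in genome$genes) {
    add(g$chrom, "gene", g$start, g$end, g$strand, ".",
        sprintf("ID=%s", g$gene_id))
    add(g$chrom, "mRNA", g$start, g$end, g$strand, ".",
        sprintf("ID=%s;Parent=%s", g$transcript_id, g$gene_id))
    for (k in seq_len(nrow(g$exons)))
      add(g$chrom, "exon", g$exons[k, 1L], g$exons[k, 2L], g$strand, ".",
          sprintf("Parent=%s", g$transcript_id))
    for (k in seq_len(nrow(g$cds)))
      add(g$chrom, "CDS", g$cds[k, 1L], g$cds[k, 2L], g$strand,
          as.character(g$phases[k]), sprintf("Parent=%s", g$transcript_id))
  }
  do.call(rbind, rows) %||% data.frame()
}

#' Write gene models as GFF3
#' @inheritParams gene_features
#' @param path output file.
#' @export
write_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (chrom in names(genome$seq))
    writeLines(sprintf("##sequence-region %s 1 %d", chrom,
                       nchar(genome$seq[[chrom]])), con)
  feats <- gene_features(genome)
  if (nrow(feats))
    write.table(feats, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file written by \code{\link{write_gff3}}
#'
#' Reconstructs the per-gene structure list (exon/CDS intervals, strand,
#' phases) from a single-transcript-per-gene GFF3.
#'
#' @param path GFF3 file.
#' @return named list of gene structures (no designed-CDS field).
#' @export
read_gff3_genes <- function(path) {
  gff <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("seqid", "source", "type", "start", "end",
                                  "score", "strand", "phase", "attributes"))
  attr_val <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, "=[^;]+"), a))
    sub(paste0(key, "="), "", m)
  }
  genes <- list()
  for (i in which(gff$type == "gene")) {
    gid <- attr_val(gff$attributes[i], "ID")
    mrna <- gff[gff$type == "mRNA" &
                  grepl(paste0("Parent=", gid, "($|;)"), gff$attributes), ]
    tid <- attr_val(mrna$attributes[1], "ID")
    ex <- gff[gff$type == "exon" &
                grepl(paste0("Parent=", tid, "($|;)"), gff$attributes), ]
    cd <- gff[gff$type == "CDS" &
                grepl(paste0("Parent=", tid, "($|;)"), gff$attributes), ]
    ex <- ex[order(ex$start), ]
    cd <- cd[order(cd$start), ]
    genes[[gid]] <- list(
      gene_id = gid, transcript_id = tid, chrom = gff$seqid[i],
      strand = gff$strand[i], start = gff$start[i], end = gff$end[i],
      exons = cbind(ex$start, ex$end),
      cds = cbind(cd$start, cd$end),
      phases = as.integer(cd$phase))
  }
  genes
}
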