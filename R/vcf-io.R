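#' Multi-sample variant dataset
#'
#' The in-memory container for a biallelic multi-sample variant panel.
#' Genotypes are coded as alternative-allele dosage: 0 = hom_ref, 1 = het,
#' 2 = hom_alt, NA = missing. A site is a SNP iff both alleles are single
#' bases, otherwise an InDel. Multi-allelic records are split into biallelic
#' records on read.
#'
#' @param sites data.frame with columns chrom, pos (1-based), ref, alt.
#' @param samples character vector of sample names (unique).
#' @param calls integer matrix, sites x samples, values 0/1/2/NA.
#' @param depths integer matrix of per-call read depths (NA when absent).
#' @return object of class \code{variant_dataset}.
#' @export
variant_dataset <- function(sites, samples, calls, depths = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (anyDuplicated(samples)) stop_cfg("sample names must be unique")
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(sites) || ncol(calls) != length(samples))
    stop_cfg("calls must be a %d x %d matrix", nrow(sites), length(samples))
  if (is.null(depths))
    depths <- matrix(NA_integer_, nrow(sites), length(samples))
  depths <- as.matrix(depths)
  storage.mode(calls) <- "integer"
  storage.mode(depths) <- "integer"
  dimnames(calls) <- NULL
  dimnames(depths) <- NULL
  sites$class <- ifelse(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L,
                        "SNP", "InDel")
  ord <- order(sites$chrom, sites$pos)
  structure(list(sites = sites[ord, , drop = FALSE],
                 samples = samples,
                 calls = calls[ord, , drop = FALSE],
                 depths = depths[ord, , drop = FALSE]),
            class = "variant_dataset")
}

#' @export
print.variant_dataset <- function(x, ...) {
  cat(sprintf("variant_dataset: %d sites (%d SNP, %d InDel) x %d samples\n",
              nrow(x$sites), sum(x$sites$class == "SNP"),
              sum(x$sites$class == "InDel"), length(x$samples)))
  invisible(x)
}

n_sites <- function(ds) nrow(ds$sites)

subset_sites <- function(ds, keep) {
  variant_dataset(ds$sites[keep, c("chrom", "pos", "ref", "alt"),
                           drop = FALSE],
                  ds$samples,
                  ds$calls[keep, , drop = FALSE],
                  ds$depths[keep, , drop = FALSE])
}

gt_to_code <- function(gt, allele = "1") {
  vapply(strsplit(gt, "[/|]"), function(a) {
    if (any(a == "." ) || length(a) == 0L) return(NA_integer_)
    sum(a == allele)
  }, integer(1))
}

#' Read a multi-sample VCF into a \code{variant_dataset}
#'
#' Parsing is delegated to \code{VariantAnnotation::readVcf}; GT is required,
#' DP optional. Records with several ALT alleles are split into biallelic
#' records (one per alternative allele, remaining alternatives folded into
#' the reference class) with a warning.
#'
#' @param path VCF v4.2 file.
#' @return a \code{variant_dataset}.
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  if (!"GT" %in% rownames(VariantAnnotation::geno(
        VariantAnnotation::header(vcf))))
    stop_cfg("VCF '%s' has no GT format field", path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dp <- if ("DP" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$DP else NULL
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alts <- lapply(rr$ALT, as.character)
  samples <- colnames(gt)

  n_alt <- lengths(alts)
  if (any(n_alt > 1L))
    warning(sprintf("%d multi-allelic record(s) split into biallelic records",
                    sum(n_alt > 1L)), call. = FALSE)
  rows <- list(); call_rows <- list(); dp_rows <- list()
  for (i in seq_along(pos)) {
    for (k in seq_len(max(1L, n_alt[i]))) {
      a <- if (n_alt[i] >= 1L) alts[[i]][k] else NA_character_
      if (is.na(a) || a == "") next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = a,
        stringsAsFactors = FALSE)
      call_rows[[length(call_rows) + 1L]] <-
        gt_to_code(gt[i, ], allele = as.character(k))
      dp_rows[[length(dp_rows) + 1L]] <-
        if (is.null(dp)) rep(NA_integer_, length(samples))
        else as.integer(dp[i, ])
    }
  }
  variant_dataset(do.call(rbind, rows), samples,
                  do.call(rbind, call_rows), do.call(rbind, dp_rows))
}

#' Write a \code{variant_dataset} as VCF v4.2
#'
#' @param ds a \code{variant_dataset}.
#' @param path output file.
#' @param contig_lengths optional named vector for \code{##contig} header
#'   lines.
#' @export
write_vcf <- function(ds, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=yieldvar"), con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contig_lengths), contig_lengths), con)
  writeLines(c(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples), collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[ds$calls + 1L],
                   nrow = n_sites(ds))
  gt_str[is.na(gt_str)] <- "./."
  dp_str <- matrix(as.character(ds$depths), nrow = n_sites(ds))
  dp_str[is.na(dp_str)] <- "."
  for (i in seq_len(n_sites(ds))) {
    fields <- c(ds$sites$chrom[i], ds$sites$pos[i], ".", ds$sites$ref[i],
                ds$sites$alt[i], ".", "PASS", ".", "GT:DP",
                paste(gt_str[i, ], dp_str[i, ], sep = ":"))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}
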