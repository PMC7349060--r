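test_that("zero-noise trials follow the linear model exactly and are deterministic", {
  cfg <- trial_config(n_genotypes = 3,
                      environments = data.frame(location = c("A", "B", "C"),
                                                year = 2016),
                      noise_sd = 0,
                      genotype_means = c(2, 2, 2),
                      slopes = c(0.5, 1.0, 1.5),
                      env_effects = c(-1, 0, 1), seed = 7)
  tr <- generate_yield_trial(cfg)
  yt <- yield_table(tr)
  expect_equal(unname(yt$Y["G01", ]), c(1.5, 2.0, 2.5))
  expect_equal(unname(yt$Y["G03", ]), c(0.5, 2.0, 3.5))

  cfg2 <- trial_config(noise_sd = 0.4, seed = 11)
  expect_identical(generate_yield_trial(cfg2), generate_yield_trial(cfg2))

  truth <- attr(tr, "truth")
  expect_equal(unname(truth$beta), c(0.5, 1.0, 1.5))
})

test_that("trial configuration errors name the offending field", {
  expect_error(trial_config(n_genotypes = 3, slopes = c(1, 1)), "slopes")
  expect_error(trial_config(n_genotypes = 3, genotype_means = 1:2),
               "genotype_means")
  expect_error(trial_config(env_effects = c(1, 1, 1, 1)), "env_effects")
  expect_error(trial_config(noise_sd = -1), "noise_sd")
  expect_error(
    trial_config(environments = data.frame(location = "A", year = 1:2)),
    "at least 3")
})

test_that("toy genomes have valid gene models and hit the target GC", {
  g <- generate_genome(genome_spec(n_genes = 8, seed = 42))
  expect_length(g$genes, 8)
  for (gn in g$genes) {
    len <- nchar(g$seq[[gn$chrom]])
    expect_true(all(gn$exons[, 1] >= 1 & gn$exons[, 2] <= len))
    expect_true(all(gn$exons[, 1] <= gn$exons[, 2]))
    # CDS inside exons, sorted, non-overlapping
    expect_true(all(diff(gn$exons[, 1]) > 0))
    for (k in seq_len(nrow(gn$cds)))
      expect_true(any(gn$cds[k, 1] >= gn$exons[, 1] &
                        gn$cds[k, 2] <= gn$exons[, 2]))
    cs <- cds_sequence(g, gn)
    expect_equal(nchar(cs) %% 3, 0)
    expect_equal(substr(cs, 1, 3), "ATG")
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cs))), "")[[1]]
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }

  # GC calibration, gene-free background
  g2 <- generate_genome(genome_spec(chromosome_lengths = c(chrA = 100000L),
                                    n_genes = 0, gc_fraction = 0.5,
                                    seed = 1))
  gc <- sum(strsplit(g2$seq[[1]], "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 0.02)

  # determinism down to FASTA bytes
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(generate_genome(genome_spec(seed = 5)), f1)
  write_genome_fasta(generate_genome(genome_spec(seed = 5)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("genome generation fails when genes cannot fit", {
  expect_error(
    generate_genome(genome_spec(chromosome_lengths = c(chr1 = 600L),
                                n_genes = 2, seed = 1)),
    "does not fit")
})

test_that("FASTA/GFF3 round-trip preserves sequences and gene structures", {
  g <- generate_genome(genome_spec(n_genes = 6, seed = 9))
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome_fasta(g, fa)
  write_gff3(g, gff)
  seqs <- read_genome_fasta(fa)
  expect_identical(unname(seqs), unname(g$seq))
  genes <- read_gff3_genes(gff)
  expect_setequal(names(genes), names(g$genes))
  for (gid in names(genes)) {
    expect_identical(unname(genes[[gid]]$exons[, 1]),
                     unname(g$genes[[gid]]$exons[, 1]))
    expect_identical(unname(genes[[gid]]$cds[, 2]),
                     unname(g$genes[[gid]]$cds[, 2]))
    expect_identical(genes[[gid]]$strand, g$genes[[gid]]$strand)
    expect_identical(genes[[gid]]$phases, as.integer(g$genes[[gid]]$phases))
  }
})

test_that("variant panels round-trip their planted truth", {
  g <- generate_genome(genome_spec(n_genes = 4, seed = 3))
  spec <- variant_panel_spec(sample_names = c("A", "B", "C"),
                             private_counts = c(3L, 0L, 5L),
                             shared_count = 40L,
                             missing_fraction = 0, seed = 21)
  p <- generate_variant_panel(g, spec)
  pm <- private_markers(p$dataset)
  got <- pm$counts$SNP + pm$counts$InDel
  expect_equal(got[match(c("A", "B", "C"), pm$counts$sample)], c(3, 0, 5))
  # truth agrees site-by-site with the detector
  truth_private <- p$truth[!is.na(p$truth$owner), ]
  expect_setequal(paste(truth_private$chrom, truth_private$pos,
                        truth_private$owner),
                  paste(pm$sites$chrom, pm$sites$pos, pm$sites$owner))

  # fully heterozygous carriers
  p_het <- generate_variant_panel(
    g, variant_panel_spec(sample_names = c("A", "B", "C"),
                          private_counts = c(3L, 0L, 5L), shared_count = 40L,
                          het_fraction = 1, missing_fraction = 0, seed = 4))
  expect_equal(sum(p_het$dataset$calls == 2L, na.rm = TRUE), 0)

  # ref alleles match the genome at every site
  for (i in seq_len(nrow(p$dataset$sites))) {
    st <- p$dataset$sites[i, ]
    expect_identical(substring(g$seq[[st$chrom]], st$pos,
                               st$pos + nchar(st$ref) - 1L), st$ref)
  }
})

test_that("panel missingness is calibrated and capacity errors are raised", {
  g <- generate_genome(genome_spec(n_genes = 0, seed = 3))
  spec <- variant_panel_spec(sample_names = sprintf("S%d", 1:10),
                             private_counts = rep(0L, 10),
                             shared_count = 200L,
                             missing_fraction = 0.2, seed = 8)
  p <- generate_variant_panel(g, spec)
  realized <- mean(is.na(p$dataset$calls))   # 2000 calls
  expect_lt(abs(realized - 0.2), 0.04)

  expect_error(
    generate_variant_panel(
      g, variant_panel_spec(sample_names = "A", private_counts = 0L,
                            shared_count = 100000L, seed = 1)),
    "non-overlapping positions")
})

test_that("wild genomes honor divergence, protection, and determinism", {
  g <- generate_genome(genome_spec(
    chromosome_lengths = c(chr1 = 20000L, chr2 = 20000L), n_genes = 0,
    seed = 3))
  p <- generate_variant_panel(
    g, variant_panel_spec(sample_names = c("A", "B"),
                          private_counts = c(5L, 0L), shared_count = 20L,
                          missing_fraction = 0, seed = 2))
  iv <- data.frame(species = "sp1", sample = "A", chrom = "chr1",
                   start = 1000L, end = 5000L)
  spec0 <- wild_panel_spec("sp1", 0, iv, seed = 5)
  w0 <- generate_wild_panel(g, p$dataset, spec0)
  # zero divergence: identical outside edits; any difference must come from
  # sample A's alleles inside the interval
  a_sites <- p$dataset$sites[p$dataset$calls[, 1] >= 1L &
                               p$dataset$sites$chrom == "chr1" &
                               p$dataset$sites$pos >= 1000 &
                               p$dataset$sites$pos <= 5000, ]
  if (nrow(a_sites) == 0) {
    expect_identical(w0$genomes$sp1[["chr1"]], g$seq[["chr1"]])
  }
  expect_identical(w0$genomes$sp1[["chr2"]], g$seq[["chr2"]])

  spec1 <- wild_panel_spec("sp1", 0.15, iv, seed = 5)
  w1 <- generate_wild_panel(g, p$dataset, spec1)
  w1b <- generate_wild_panel(g, p$dataset, spec1)
  expect_identical(w1$genomes, w1b$genomes)
  # divergence realized outside the interval, protection inside
  ref_chars <- strsplit(g$seq[["chr2"]], "")[[1]]
  mut_chars <- strsplit(w1$genomes$sp1[["chr2"]], "")[[1]]
  expect_lt(abs(mean(ref_chars != mut_chars) - 0.15), 0.02)
  expect_error(
    wild_panel_spec("sp1", 0.15,
                    data.frame(species = "sp1", sample = "A",
                               chrom = "chr1",
                               start = c(100L, 400L), end = c(500L, 900L)),
                    seed = 1),
    "overlapping")
  expect_error(
    generate_wild_panel(g, p$dataset,
                        wild_panel_spec("sp1", 0.1,
                                        data.frame(species = "sp1",
                                                   sample = "A",
                                                   chrom = "chr1",
                                                   start = 10L,
                                                   end = 999999L),
                                        seed = 1)),
    "outside")
})
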