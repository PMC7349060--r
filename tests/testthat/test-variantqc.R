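test_that("VCF writing and reading round-trip, including multi-allelic splitting", {
  calls <- rbind(c(0L, 1L, 2L, NA), c(2L, 2L, 0L, 1L))
  depths <- rbind(c(10L, 8L, 7L, 0L), c(5L, 6L, 9L, 4L))
  ds <- make_ds(calls, ref = c("A", "AT"), alt = c("T", "A"),
                depths = depths)
  path <- tempfile(fileext = ".vcf")
  write_vcf(ds, path, contig_lengths = c(chr1 = 1000L))
  ds2 <- read_vcf(path)
  expect_identical(ds2$sites[c("chrom", "pos", "ref", "alt", "class")],
                   ds$sites[c("chrom", "pos", "ref", "alt", "class")])
  expect_identical(ds2$calls, ds$calls)
  expect_identical(ds2$depths, ds$depths)
  expect_identical(ds2$samples, ds$samples)
  expect_equal(ds2$sites$class, c("SNP", "InDel"))

  # GT string conventions
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", "s2", "s3", "s4"),
                   collapse = "\t"),
             paste(c("chr1", "100", ".", "A", "T", ".", "PASS", ".", "GT",
                     "0/0", "0/1", "1/1", "./."), collapse = "\t"),
             paste(c("chr1", "200", ".", "A", "AT,ATT", ".", "PASS", ".",
                     "GT", "0/1", "1/2", "2/2", "0/0"), collapse = "\t"))
  p2 <- tempfile(fileext = ".vcf")
  writeLines(lines, p2)
  expect_warning(ds3 <- read_vcf(p2), "multi-allelic")
  expect_equal(nrow(ds3$sites), 3)           # 1 + split pair
  expect_equal(unname(ds3$calls[1, ]), c(0L, 1L, 2L, NA))
  # alt AT: dosages of allele 1; alt ATT: dosages of allele 2
  expect_equal(unname(ds3$calls[2, ]), c(1L, 1L, 0L, 0L))
  expect_equal(unname(ds3$calls[3, ]), c(0L, 1L, 2L, 0L))
})

test_that("filtering applies the missingness, depth, and polymorphism rules", {
  ns <- 12
  # boundary: exactly half called is retained
  half <- c(rep(0L, 5L), 1L, rep(NA, 6L))
  # depth boundary: mean DP 4.9 < 5 removed
  dp_low <- rep(4.9, ns)
  dsb <- make_ds(rbind(half, rep(c(0L, 1L), 6)),
                 depths = rbind(rep(10L, ns), dp_low))
  res <- filter_variants(dsb)
  expect_equal(res$kept, 1)
  expect_equal(unname(res$removed["depth"]), 1)

  # same alternative allele in every genotype (reference-cultivar
  # difference): removed as monomorphic
  mono <- make_ds(rbind(rep(2L, 4), c(0L, 0L, 1L, 2L)),
                  depths = matrix(10L, 2, 4))
  resm <- filter_variants(mono)
  expect_equal(unname(resm$removed["monomorphic"]), 1)
  expect_equal(resm$dataset$sites$pos, mono$sites$pos[2])

  # sites without DP fail unless the depth rule is off
  nodp <- make_ds(rbind(c(0L, 1L, 0L, 1L)))
  expect_warning(r0 <- filter_variants(nodp), "all sites removed")
  expect_equal(r0$kept, 0)
  r1 <- filter_variants(nodp, filter_config(min_mean_dp = 0))
  expect_equal(r1$kept, 1)

  # idempotence
  g <- generate_genome(genome_spec(n_genes = 0, seed = 2))
  p <- generate_variant_panel(g, variant_panel_spec(seed = 3,
                                                    missing_fraction = 0.3,
                                                    mean_depth = 6))
  f1 <- filter_variants(p$dataset)
  f2 <- filter_variants(f1$dataset)
  expect_identical(f1$dataset$sites, f2$dataset$sites)
  expect_equal(sum(f2$removed), 0)
})

test_that("genotype composition percentages are complete and correct", {
  all_ref <- make_ds(matrix(0L, 3, 4))
  expect_equal(unname(genotype_composition(all_ref)$percent),
               c(100, 0, 0, 0))
  mix <- make_ds(rbind(c(0L, 0L, 0L, 0L, 0L),
                       c(0L, 0L, 0L, 2L, 1L)))
  pc <- genotype_composition(mix)$percent
  expect_equal(unname(pc), c(80, 10, 10, 0))
  expect_equal(sum(pc), 100)
  # per-sample heterozygosity
  ps <- genotype_composition(mix)$per_sample
  expect_equal(ps$het_rate[5], 0.5)
})

test_that("private markers honor ownership and the missingness guard", {
  one <- make_ds(rbind(c(1L, 0L, 0L, 0L),
                       c(2L, 1L, 0L, 0L),
                       c(NA, 2L, NA, NA)))
  pm <- private_markers(one)
  # site 1 private to S01; site 2 has two carriers; site 3's carrier S02 has
  # 0/3 other samples called -> unassignable
  expect_equal(sum(pm$counts$SNP), 1)
  expect_equal(pm$sites$owner, "S01")
  expect_equal(pm$unassignable, 1)
  # chromosome breakdown sums to the per-sample totals
  g <- generate_genome(genome_spec(n_genes = 0, seed = 2))
  p <- generate_variant_panel(g, variant_panel_spec(seed = 7,
                                                    missing_fraction = 0))
  pm2 <- private_markers(p$dataset)
  bc <- aggregate(Freq ~ sample, data = pm2$by_chrom, sum)
  tot <- pm2$counts$SNP + pm2$counts$InDel
  expect_equal(bc$Freq[match(pm2$counts$sample, bc$sample)], tot)
})

test_that("IBS similarity matches the hand count and the allele-sharing oracle", {
  ident <- make_ds(cbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(ibs_matrix(ident)$ibs[1, 2], 1)
  opp <- make_ds(cbind(rep(0L, 4), rep(2L, 4)))
  expect_equal(ibs_matrix(opp)$ibs[1, 2], 0)
  # states (ibs2, ibs1, ibs0, ibs2) -> (2 + 0.5)/4
  hand <- make_ds(cbind(c(0L, 0L, 0L, 2L), c(0L, 1L, 2L, 2L)))
  expect_equal(ibs_matrix(hand)$ibs[1, 2], 0.625)
  # pair with no co-called loci flagged
  nil <- make_ds(cbind(c(0L, NA), c(NA, 1L)))
  expect_warning(rn <- ibs_matrix(nil), "no co-called")
  expect_true(is.na(rn$ibs[1, 2]))

  # random panels against the brute-force enumeration
  set.seed(11)
  for (rep in 1:3) {
    calls <- matrix(sample(c(0L, 1L, 2L, NA), 60 * 6, replace = TRUE,
                           prob = c(0.6, 0.15, 0.2, 0.05)), 60, 6)
    ds <- make_ds(calls)
    expect_equal(ibs_matrix(ds)$ibs, ibs_brute(ds), tolerance = 1e-12)
  }
})

test_that("windowed marker density counts carried sites and sums correctly", {
  calls <- cbind(c(1L, 2L, 0L, 1L, NA), c(0L, 0L, 2L, 0L, 1L))
  ds <- make_ds(calls, pos = c(50L, 150L, 250L, 901L, 950L))
  d <- marker_density(ds, window = 100L, chrom_lengths = c(chr1 = 1000L))
  s1 <- d[d$sample == "S01", ]
  expect_equal(sum(s1$count), 3)             # sites 1, 2, 4 carried
  expect_equal(s1$count[s1$start == 0], 1)
  expect_equal(s1$count[s1$start == 900], 1)
  expect_equal(unique(s1$end - s1$start), 100)
  # empty chromosome: all-zero track
  d2 <- marker_density(ds, window = 100L,
                       chrom_lengths = c(chr1 = 1000L, chrX = 300L))
  expect_equal(sum(d2$count[d2$chrom == "chrX"]), 0)
  expect_equal(nrow(d2[d2$chrom == "chrX" & d2$sample == "S01", ]), 3)
  # ten variants in one window
  ds10 <- make_ds(matrix(1L, 10, 1), pos = 301:310)
  d3 <- marker_density(ds10, window = 100L, chrom_lengths = c(chr1 = 1000L))
  expect_equal(d3$count[d3$start == 300], 10)
  expect_equal(sum(d3$count), 10)
})
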