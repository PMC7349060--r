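test_that("SSR detection finds tandem arrays and canonicalizes the motif", {
  # insertion of (AT)x3 adjacent to an existing (AT)x4 array (the VCF
  # anchor is the last base of the flanking array)
  res <- detect_ssr("T", "TATATAT",
                    left_flank = paste0(strrep("C", 20), "ATATATA"),
                    right_flank = strrep("G", 28))
  expect_true(res$is_ssr)
  expect_equal(res$motif, "AT")
  expect_equal(res$delta_repeats, 3)
  expect_equal(res$copies_long, 7)    # 4 flanking + 3 inserted
  expect_equal(res$copies_short, 4)

  # same array phased as TA reports the same canonical motif
  res2 <- detect_ssr("A", "ATATATA",
                     left_flank = paste0(strrep("C", 20), "TATATAT"),
                     right_flank = strrep("G", 28))
  expect_true(res2$is_ssr)
  expect_equal(res2$motif, "AT")

  # a random non-repetitive 6-bp insertion is not an SSR
  res3 <- detect_ssr("G", "GTCAGGC", left_flank = strrep("C", 30),
                     right_flank = strrep("G", 30))
  expect_false(res3$is_ssr)

  # self-contained triple: inserted AGGAGGAGG with no flanking copies
  res4 <- detect_ssr("T", "TAGGAGGAGG", left_flank = strrep("C", 30),
                     right_flank = strrep("T", 30))
  expect_true(res4$is_ssr)
  expect_equal(res4$unit_len, 3)
  expect_equal(res4$delta_repeats, 3)
})

test_that("candidate selection keeps >=5 bp InDels and unit-shift SSRs", {
  set.seed(8)
  chrom <- random_dna(300)
  substr(chrom, 101, 112) <- "ATATATATATAT"      # (AT)x6 array
  # site A: 5-bp non-repetitive deletion at 50; site B: 4-bp insertion at
  # 200; site C: one extra AT unit anchored just before the array
  del_ref <- substring(chrom, 50, 55)
  sites <- data.frame(
    chrom = "c1",
    pos = c(50L, 200L, 100L),
    ref = c(del_ref, substring(chrom, 200, 200), substring(chrom, 100, 100)),
    alt = c(substring(chrom, 50, 50),
            paste0(substring(chrom, 200, 200), "TCAG"),
            paste0(substring(chrom, 100, 100), "AT")),
    stringsAsFactors = FALSE)
  ds <- variant_dataset(sites, c("A", "B"), matrix(1L, 3, 2))
  cand <- select_candidate_indels(ds, c(c1 = chrom))
  expect_equal(nrow(cand), 2)
  expect_equal(cand$class[cand$pos == 50], "N")
  expect_equal(cand$class[cand$pos == 100], "S")
  expect_equal(cand$motif[cand$pos == 100], "AT")
  expect_equal(cand$delta_repeats[cand$pos == 100], 1)
  expect_false(200 %in% cand$pos)
})

test_that("flank queries are centered, edge-shifted, and allele-faithful", {
  g <- generate_genome(genome_spec(n_genes = 0, seed = 6))
  s <- g$seq[[1]]
  # interior SNP-like slice round-trips against the genome
  loc <- list(chrom = names(g$seq)[1], pos = 5000L,
              ref = substring(s, 5000, 5000), alt = substring(s, 5000, 5000))
  q <- extract_flank(g, loc, allele = "ref")
  expect_equal(nchar(q$seq), 100)
  expect_identical(q$seq, substring(s, 5000 - q$indel_start + 1,
                                    5000 - q$indel_start + 100))
  # near the chromosome start the window shifts right but stays 100 bp
  loc2 <- list(chrom = names(g$seq)[1], pos = 10L,
               ref = substring(s, 10, 10), alt = substring(s, 10, 10))
  q2 <- extract_flank(g, loc2, allele = "ref")
  expect_equal(nchar(q2$seq), 100)
  expect_identical(q2$seq, substring(s, 1, 100))
  # alt-haplotype query contains the full inserted sequence
  ins <- "TTGACTGACC"
  loc3 <- list(chrom = names(g$seq)[1], pos = 8000L,
               ref = substring(s, 8000, 8000),
               alt = paste0(substring(s, 8000, 8000), ins))
  q3 <- extract_flank(g, loc3)
  expect_identical(substring(q3$seq, q3$indel_start,
                             q3$indel_start + nchar(loc3$alt) - 1),
                   loc3$alt)
  expect_true(grepl(ins, q3$seq, fixed = TRUE))
  # a chromosome shorter than the window warns and returns everything
  tiny <- c(c9 = random_dna(60))
  expect_warning(
    q4 <- extract_flank(tiny, list(chrom = "c9", pos = 30L,
                                   ref = substring(tiny, 30, 30),
                                   alt = "A")),
    "shorter")
  expect_equal(nchar(q4$seq), 60)
})

test_that("seed-and-extend alignment recovers planted queries with exact identities", {
  set.seed(21)
  wild <- random_dna(20000)
  q_seq <- random_dna(100)
  planted_at <- 7001L
  substr(wild, planted_at, planted_at + 99L) <- q_seq
  query <- list(seq = q_seq, indel_start = 48L, indel_end = 55L)
  hits <- align_query(query, c(w1 = wild), species = "sp")
  expect_gte(nrow(hits), 1)
  expect_equal(hits$overall_identity[1], 100)
  expect_equal(hits$indel_identity[1], 100)
  expect_equal(hits$start[1], planted_at)
  expect_equal(hits$strand[1], "+")

  # five substitutions outside the InDel interval -> 95% / 100%
  q5 <- q_seq
  for (p in c(3L, 20L, 40L, 70L, 95L)) {
    b <- substring(q5, p, p)
    substr(q5, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  hits5 <- align_query(list(seq = q5, indel_start = 48L, indel_end = 55L),
                       c(w1 = wild), species = "sp")
  expect_equal(hits5$overall_identity[1], 95)
  expect_equal(hits5$indel_identity[1], 100)

  # reverse-complement planting is found on the minus strand
  wild_rc <- random_dna(20000)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(q_seq)))
  substr(wild_rc, 3001, 3100) <- rc
  hits_rc <- align_query(query, c(w1 = wild_rc), species = "sp")
  expect_equal(hits_rc$strand[1], "-")
  expect_equal(hits_rc$overall_identity[1], 100)
  expect_equal(hits_rc$indel_identity[1], 100)
})

test_that("banded DP equals the unbanded program and the reference aligner", {
  set.seed(33)
  for (r in 1:20) {
    n <- sample(30:60, 1)
    a <- random_dna(n)
    b <- a
    # a few substitutions and a small indel, staying inside the band
    for (p in sample(seq_len(n - 6), 3)) {
      bb <- substring(b, p, p)
      substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), bb)[1]
    }
    if (r %% 2 == 0) b <- paste0(substring(b, 1, 10), "AC", substring(b, 11))
    else b <- paste0(substring(b, 1, 8), substring(b, 12))
    full <- banded_align(a, b, band = Inf)
    bnd <- banded_align(a, b, band = 12, diag0 = 0)
    expect_equal(bnd$score, full$score)
    # independent oracle: query-global / subject-local affine alignment
    pa <- Biostrings::pairwiseAlignment(
      a, b, type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
      gapOpening = 2, gapExtension = 1)
    expect_equal(full$score, Biostrings::score(pa))
  }
})

test_that("origin assignment applies the strict dual identity rule", {
  hit <- function(sp, ov, ind) data.frame(
    species = sp, chrom = "c", start = 1L, strand = "+",
    overall_identity = ov, indel_identity = ind, aligned_cols = 100L,
    score = 90, stringsAsFactors = FALSE)
  sps <- c("sp1", "sp2", "sp3")
  a1 <- assign_origin(rbind(hit("sp1", 95, 100), hit("sp2", 85, 100),
                            hit("sp3", 96, 95)), sps)
  expect_equal(a1$status, "assigned")
  expect_equal(a1$species, "sp1")
  # exactly 90% overall fails (strictly more than 90 required)
  a2 <- assign_origin(rbind(hit("sp1", 90, 100)), sps)
  expect_equal(a2$status, "unassigned")
  # two passing species: ambiguous, both listed
  a3 <- assign_origin(rbind(hit("sp1", 95, 100), hit("sp2", 99, 100)), sps)
  expect_equal(a3$status, "ambiguous")
  expect_setequal(a3$species, c("sp1", "sp2"))
  # a species with no hits simply fails
  a4 <- assign_origin(hit("sp1", 95, 100), c("sp1", "sp9"))
  expect_equal(a4$status, "assigned")
  expect_true(is.na(a4$best$overall_identity[a4$best$species == "sp9"]))
})
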