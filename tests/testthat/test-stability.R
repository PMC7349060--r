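test_that("environment index: two-point symmetry, printed field means, constants", {
  # the 2x2 symmetry case [[1,3],[3,5]] -> EI (-1, +1), padded with a third
  # environment at the grand mean to honour the l >= 3 contract
  Y <- matrix(c(1, 3, 3, 5, 2, 4), 2, 3,
              dimnames = list(c("g1", "g2"), c("e1", "e2", "e3")))
  ei <- environment_index(yield_table(Y))
  expect_equal(unname(ei), c(-1, 1, 0))
  expect_lt(abs(sum(ei)), 1e-9)

  # the four published field means (1.06, 2.04, 2.62, 3.86 kg/plant) as a
  # proxy table with identical genotypes
  Y2 <- rbind(c(1.06, 2.04, 2.62, 3.86), c(1.06, 2.04, 2.62, 3.86))
  dimnames(Y2) <- list(c("a", "b"), c("C2016", "C2017", "P2016", "P2017"))
  ei2 <- environment_index(yield_table(Y2))
  expect_equal(unname(ei2), c(-1.335, -0.355, 0.225, 1.465))
  expect_lt(abs(sum(ei2)), 1e-9)

  Yc <- matrix(2.5, 3, 4, dimnames = list(paste0("g", 1:3), paste0("e", 1:4)))
  expect_equal(unname(environment_index(yield_table(Yc))), rep(0, 4))
})

test_that("stability regression: exact fits, algebraic mean-slope identity, lm oracle", {
  # two informative environments plus one on the line: exact fit
  Y <- matrix(c(1, 2, 3, 2, 3, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("e1", "e2", "e3")))
  yt <- yield_table(Y)
  f <- fit_linear(yt)
  expect_equal(f$b, c(1, 1))
  expect_equal(f$intercept, f$pooled_mean)
  expect_equal(f$r2, c(1, 1))

  # zero-noise synthetic recovery with mean-1 slopes
  cfg <- trial_config(n_genotypes = 4,
                      environments = default_environments(),
                      noise_sd = 0, slopes = c(0.7, 0.9, 1.1, 1.3),
                      genotype_means = c(2, 2.2, 2.4, 2.6),
                      seed = 1)
  tr <- generate_yield_trial(cfg)
  f2 <- fit_linear(yield_table(tr))
  expect_equal(f2$b, c(0.7, 0.9, 1.1, 1.3), tolerance = 1e-12)

  # random tables: mean slope exactly 1, slopes match a brute-force lm fit
  for (seed in 1:5) {
    set.seed(seed)
    Yr <- matrix(rnorm(12 * 4, 2.4, 0.8), 12, 4,
                 dimnames = list(sprintf("g%02d", 1:12), paste0("e", 1:4)))
    ytr <- yield_table(Yr)
    eir <- environment_index(ytr)
    fr <- fit_linear(ytr, eir)
    expect_lt(abs(mean(fr$b) - 1), 1e-9)
    for (i in 1:12) {
      m <- lm(Yr[i, ] ~ eir)
      expect_equal(fr$b[i], unname(coef(m)[2]), tolerance = 1e-10)
      expect_equal(fr$intercept[i], unname(coef(m)[1]), tolerance = 1e-10)
      expect_equal(fr$r2[i], summary(m)$r.squared, tolerance = 1e-10)
    }
  }
})

test_that("ADL matches the hand-worked quadratic-gap computation", {
  Y <- matrix(c(1, 1, 3, 3, 3, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("e1", "e2", "e3")))
  yt <- yield_table(Y)
  ei <- c(-1, 0, 1)
  adl <- compute_adl(yt, ei)
  # g1: linear predictions (2/3, 5/3, 8/3), quadratic interpolates ->
  # sum sq gap 2/3, mean 5/3 -> ADL = 0.4
  expect_equal(adl$adl[1], 0.4, tolerance = 1e-12)
  detail <- attr(adl, "detail")$g1
  expect_equal(detail$mu_L, c(2 / 3, 5 / 3, 8 / 3), tolerance = 1e-12)
  expect_equal(detail$mu_Q, c(1, 1, 3), tolerance = 1e-12)
  # saturated quadratic with l = 3: p undefined
  expect_true(is.na(adl$adl_p[1]))

  # perfectly linear response
  Ylin <- matrix(c(1, 2, 3, 4, 2, 3, 4, 5), 2, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("e", 1:4)))
  adl_lin <- compute_adl(yield_table(Ylin), c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(adl_lin$adl, c(0, 0), tolerance = 1e-12)
  expect_equal(adl_lin$quad_coef, c(0, 0), tolerance = 1e-10)
  expect_equal(adl_lin$adl_p, c(1, 1))
})

test_that("ADL scaling and translation behave through the mean denominator", {
  set.seed(3)
  Y <- matrix(rnorm(8, 3, 0.5), 2, 4,
              dimnames = list(c("g1", "g2"), paste0("e", 1:4)))
  yt <- yield_table(Y)
  ei <- environment_index(yt)
  a1 <- compute_adl(yt, ei)
  # scaling all yields by c scales ADL by c (numerator c^2, denominator c);
  # EI must be rescaled with the table it derives from
  Y3 <- yield_table(3 * Y)
  a3 <- compute_adl(Y3, environment_index(Y3))
  expect_equal(a3$adl, 3 * a1$adl, tolerance = 1e-9)
  # adding a constant to one genotype changes only its denominator
  Yshift <- Y; Yshift[1, ] <- Yshift[1, ] + 2
  as <- compute_adl(yield_table(Yshift), ei)
  num1 <- a1$adl[1] * mean(Y[1, ])
  expect_equal(as$adl[1], num1 / mean(Yshift[1, ]), tolerance = 1e-9)

  # n_env denominator switch
  an <- compute_adl(yt, ei, denominator = "n_env")
  expect_equal(an$adl, unname(a1$adl * rowMeans(Y) / 4), tolerance = 1e-9)
})

test_that("selection applies the four criteria with inclusive slope boundary", {
  fits <- data.frame(
    genotype = c("g1", "g2", "g3", "g4"),
    b = c(1.0, 0.9, 1.4, 0.95),
    r2 = c(0.8, 0.3, 0.9, 0.85),
    pooled_mean = c(3.0, 3.1, 3.2, 2.0),
    adl = c(0, 0.1, 0, 0.05),
    adl_p = c(0.8, 0.6, 0.9, 0.02))
  sel <- select_stable(fits, grand_mean = 2.5,
                       criteria = selection_criteria(slope_rule = "le_one"))
  # g1: b exactly 1 -> passes (inclusive); g2 fails r2; g3 fails slope;
  # g4 fails mean (and ADL)
  expect_equal(sel$genotype[sel$selected], "g1")
  expect_true(sel$slope_le_one[1])
  expect_false(sel$r2_ok[2])
  expect_false(sel$slope_ok[3])
  expect_false(sel$mean_above_grand[4])

  # all means below the grand mean -> empty selection
  sel2 <- select_stable(fits, grand_mean = 5)
  expect_equal(sum(sel2$selected), 0)

  expect_error(select_stable(fits[0, ], 2.5), "non-empty")
})

test_that("degenerate stability inputs fail loudly", {
  Y <- matrix(c(1, 2, NA, 4, 5, 6), 2, 3,
              dimnames = list(c("g1", "g2"), c("e1", "e2", "e3")))
  df <- data.frame(genotype = rep(c("g1", "g2"), 3),
                   location = rep(c("A", "B", "C"), each = 2),
                   year = 2016,
                   yield = c(1, 4, 2, 5, NA, 6))
  expect_error(yield_table(df), "missing cell")
  yt <- yield_table(matrix(2, 2, 3,
                           dimnames = list(c("g1", "g2"), paste0("e", 1:3))))
  expect_error(fit_linear(yt), "zero variance")
  expect_warning(
    fit_linear(yield_table(matrix(c(1, 2, 3, 2, 2, 2), 2, 3, byrow = TRUE,
                                  dimnames = list(c("g1", "gflat"),
                                                  paste0("e", 1:3)))),
               c(-1, 0, 1)),
    "zero yield variance")
})
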