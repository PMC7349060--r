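#' Configuration for a synthetic multi-environment yield trial
#'
#' Describes a balanced genotype x environment x replicate trial generated
#' under the linear stability model: the replicate-level yield of genotype i
#' in environment j is \code{mu_i + beta_i * e_j + eps}, with
#' \code{eps ~ Normal(0, noise_sd^2)}. The true slopes \code{beta_i} play the
#' role of the stability coefficient of regression recovered downstream.
#'
#' Defaults emulate the trial design the package targets: 12 genotypes (10
#' landraces plus 2 control hybrids) grown in 4 location-year environments
#' with 3 replicates. Default environment effects are the deviations of the
#' four printed field means (1.06, 2.04, 2.62, 3.86 kg/plant) from their
#' grand mean; default true slopes span the reported 0.51-1.78 range.
#'
#' @param n_genotypes number of genotypes (v).
#' @param environments data.frame with columns \code{location} and
#'   \code{year}, one row per environment (l rows).
#' @param n_replicates replicates per genotype x environment cell.
#' @param grand_mean overall mean yield, kg/plant.
#' @param genotype_means vector of v true genotype means mu_i, kg/plant.
#' @param slopes vector of v true environmental-sensitivity slopes beta_i
#'   (unitless; 1 = average sensitivity).
#' @param env_effects vector of l true environment deviations e_j, kg/plant,
#'   summing to 0.
#' @param noise_sd replicate noise standard deviation, kg/plant.
#' @param genotype_names optional genotype labels (default G01..Gnn).
#' @param seed integer RNG seed; the generator is a pure function of it.
#' @return an object of class \code{trial_config}.
#' @export
trial_config <- function(n_genotypes = 12L,
                         environments = default_environments(),
                         n_replicates = 3L,
                         grand_mean = 2.39,
                         genotype_means = NULL,
                         slopes = NULL,
                         env_effects = NULL,
                         noise_sd = 0.3,
                         genotype_names = NULL,
                         seed = 1L) {
  n_genotypes <- check_count(n_genotypes, "n_genotypes", min = 2L)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  if (!is.data.frame(environments) ||
      !all(c("location", "year") %in% names(environments)))
    stop_cfg("'environments' must be a data.frame with columns location, year")
  l <- nrow(environments)
  if (l < 3L) stop_cfg("'environments' must have at least 3 rows, got %d", l)

  if (is.null(genotype_means))
    genotype_means <- grand_mean + seq(-0.9, 0.9, length.out = n_genotypes)
  if (is.null(slopes))
    slopes <- seq(0.51, 1.78, length.out = n_genotypes)
  if (is.null(env_effects)) {
    field_means <- seq(1.06, 3.86, length.out = l)
    if (l == 4L) field_means <- c(1.06, 2.04, 2.62, 3.86)
    env_effects <- field_means - mean(field_means)
  }
  if (length(genotype_means) != n_genotypes)
    stop_cfg("'genotype_means' must have length n_genotypes = %d (got %d)",
             n_genotypes, length(genotype_means))
  if (length(slopes) != n_genotypes)
    stop_cfg("'slopes' must have length n_genotypes = %d (got %d)",
             n_genotypes, length(slopes))
  if (length(env_effects) != l)
    stop_cfg("'env_effects' must have length %d (one per environment, got %d)",
             l, length(env_effects))
  if (abs(sum(env_effects)) > 1e-9)
    stop_cfg("'env_effects' must sum to 0 (sum = %g)", sum(env_effects))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_cfg("'noise_sd' must be >= 0")
  if (is.null(genotype_names))
    genotype_names <- sprintf("G%02d", seq_len(n_genotypes))
  if (length(genotype_names) != n_genotypes || anyDuplicated(genotype_names))
    stop_cfg("'genotype_names' must be %d unique labels", n_genotypes)

  structure(list(
    n_genotypes = n_genotypes,
    environments = environments,
    n_replicates = n_replicates,
    grand_mean = grand_mean,
    genotype_means = genotype_means,
    slopes = slopes,
    env_effects = env_effects,
    noise_sd = noise_sd,
    genotype_names = genotype_names,
    seed = as.integer(seed)
  ), class = "trial_config")
}

#' @rdname trial_config
#' @export
default_environments <- function() {
  data.frame(location = rep(c("Campania", "Puglia"), each = 2L),
             year = rep(c(2016L, 2017L), times = 2L))
}

#' Generate a replicate-level yield trial
#'
#' Simulates a balanced trial under the linear stability model of
#' \code{\link{trial_config}}. Replicate noise is i.i.d. Gaussian; no block
#' effect is simulated because the downstream regression operates on
#' environment means.
#'
#' @param cfg a \code{trial_config}.
#' @return data.frame with columns genotype, location, year, replicate, yield
#'   (kg/plant), with the true parameters attached as attribute
#'   \code{"truth"} (list with mu, beta, env_effects, genotypes,
#'   environments).
#' @export
generate_yield_trial <- function(cfg) {
  stopifnot(inherits(cfg, "trial_config"))
  v <- cfg$n_genotypes
  l <- nrow(cfg$environments)
  r <- cfg$n_replicates
  genotypes <- cfg$genotype_names
  env_lab <- paste0(substr(cfg$environments$location, 1, 1),
                    cfg$environments$year)

  grid <- expand.grid(replicate = seq_len(r),
                      env = seq_len(l),
                      genotype = seq_len(v),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- cfg$genotype_means[grid$genotype]
  beta <- cfg$slopes[grid$genotype]
  e <- cfg$env_effects[grid$env]

  set.seed(cfg$seed)
  eps <- if (cfg$noise_sd > 0) rnorm(nrow(grid), 0, cfg$noise_sd) else 0

  out <- data.frame(
    genotype = genotypes[grid$genotype],
    location = cfg$environments$location[grid$env],
    year = cfg$environments$year[grid$env],
    replicate = grid$replicate,
    yield = mu + beta * e + eps,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(
    genotypes = genotypes,
    environments = env_lab,
    mu = setNames(cfg$genotype_means, genotypes),
    beta = setNames(cfg$slopes, genotypes),
    env_effects = setNames(cfg$env_effects, env_lab)
  )
  out
}

#' Generate a replicate-level five-trait table
#'
#' Simulates the five yield-related traits (NFL flowers/inflorescence, FS
#' fruit-set proportion, TNF fruits/plant, FW g/fruit, YP kg/plant) at the
#' replicate level with the field's stylized relations: FW and TNF are
#' negatively related across genotypes, and YP ~ TNF x FW / 1000. Used by the
#' three-way ANOVA / correlation stages; yield stability analyses use
#' \code{\link{generate_yield_trial}}.
#'
#' @param cfg a \code{trial_config}; its yield model drives YP.
#' @param fw_range range of true fruit weights across genotypes, g.
#' @param nfl_mean,fs_mean trait grand means (flowers per inflorescence,
#'   fruit-set proportion).
#' @return long data.frame: genotype, location, year, replicate, trait, value.
#' @export
generate_trait_trial <- function(cfg, fw_range = c(20, 180),
                                 nfl_mean = 7, fs_mean = 0.6) {
  yp <- generate_yield_trial(cfg)
  truth <- attr(yp, "truth")
  set.seed(cfg$seed + 1L)
  v <- cfg$n_genotypes
  # big-fruited genotypes bear fewer fruits: FW decreasing in genotype rank,
  # TNF = YP / FW by construction
  fw_true <- setNames(seq(fw_range[2], fw_range[1], length.out = v),
                      truth$genotypes)
  n <- nrow(yp)
  fw <- pmax(5, fw_true[yp$genotype] * exp(rnorm(n, 0, 0.05)))
  tnf <- pmax(0.5, yp$yield * 1000 / fw)
  nfl <- pmax(1, nfl_mean + 0.02 * (tnf - mean(tnf)) + rnorm(n, 0, 0.6))
  fs <- pmin(1, pmax(0.05, fs_mean + 0.15 * (yp$yield - mean(yp$yield)) /
                       max(sd(yp$yield), 1e-9) + rnorm(n, 0, 0.05)))
  base <- yp[c("genotype", "location", "year", "replicate")]
  out <- rbind(
    cbind(base, trait = "NFL", value = nfl),
    cbind(base, trait = "FS", value = fs),
    cbind(base, trait = "TNF", value = tnf),
    cbind(base, trait = "FW", value = fw),
    cbind(base, trait = "YP", value = yp$yield)
  )
  rownames(out) <- NULL
  out
}
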