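#' Configuration for the synthetic feeder-population generator
#'
#' Bundles every tunable of the simulator: population size and structure,
#' marker panel, the variance decomposition of the latent resilience score,
#' and the illness process that perturbs daily intake.
#'
#' The latent resilience score of animal *i* is
#' \eqn{s_i = a_i + l_i + \epsilon_i} with additive-genetic, litter and
#' environmental components whose variance fractions are `h2_resilience`,
#' `litter_var_frac` and the remainder. The day-to-day residual standard
#' deviation of feed intake and feeding duration scales as
#' \eqn{\mathrm{SD}_i = \mathrm{SD}_0 \exp(s_i)}, so a larger score means a
#' more variable (less resilient) animal, matching the convention that larger
#' resilience-indicator values mean lower resilience.
#'
#' @param n_animals number of phenotyped offspring to simulate.
#' @param n_snps number of biallelic SNPs on the marker panel.
#' @param n_breeds number of breeds (founder populations with divergent
#'   allele frequencies); default 3.
#' @param age_range integer vector `c(lo, hi)` of on-test ages in days;
#'   default `c(90, 150)`.
#' @param maf_range range of ancestral minor-allele frequencies, within
#'   (0, 0.5].
#' @param h2_resilience narrow-sense heritability of the latent resilience
#'   score, in \[0, 1\].
#' @param litter_var_frac fraction of latent-score variance due to litter.
#' @param illness_rate per animal-day probability that an illness episode
#'   starts; episodes last `1 + Geometric(0.5)` days.
#' @param illness_depth fractional loss of intake and feeding duration during
#'   illness, in \[0, 1\].
#' @param seed integer seed controlling all randomness; stage-specific
#'   substreams are derived from it deterministically.
#' @param n_causal number of causal SNPs behind the additive component.
#' @param causal_frac fraction of additive variance explained by the causal
#'   SNPs (remainder is pedigree-polygenic).
#' @param score_sd total standard deviation of the latent score (log scale).
#' @param litter_size average number of offspring per litter.
#' @param fst Wright's fixation index controlling breed divergence of
#'   founder allele frequencies.
#' @param sd_fi0,sd_fd0 baseline day-to-day residual SD of feed intake (kg)
#'   and feeding duration (min) for an animal with latent score 0.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_animals = 50, n_snps = 200, seed = 1)
sim_config <- function(n_animals = 500,
                       n_snps = 5000,
                       n_breeds = 3,
                       age_range = c(90L, 150L),
                       maf_range = c(0.05, 0.5),
                       h2_resilience = 0.25,
                       litter_var_frac = 0.10,
                       illness_rate = 0.01,
                       illness_depth = 0.6,
                       seed = 1L,
                       n_causal = 50,
                       causal_frac = 0.5,
                       score_sd = 0.30,
                       litter_size = 10,
                       fst = 0.15,
                       sd_fi0 = 0.5,
                       sd_fd0 = 11) {
  stopifnot(n_animals >= 1, n_snps >= 1, n_breeds >= 1,
            length(age_range) == 2, age_range[1] < age_range[2],
            length(maf_range) == 2)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  fracs <- c(h2_resilience = h2_resilience, litter_var_frac = litter_var_frac,
             illness_depth = illness_depth)
  if (any(fracs < 0) || any(fracs > 1))
    stop("variance fractions and illness_depth must be in [0, 1]", call. = FALSE)
  if (h2_resilience + litter_var_frac > 1)
    stop("h2_resilience + litter_var_frac must not exceed 1", call. = FALSE)
  if (causal_frac < 0 || causal_frac > 1)
    stop("causal_frac must be in [0, 1]", call. = FALSE)
  if (illness_rate < 0 || illness_rate > 1)
    stop("illness_rate must be a probability", call. = FALSE)
  cfg <- list(n_animals = as.integer(n_animals), n_snps = as.integer(n_snps),
              n_breeds = as.integer(n_breeds),
              age_range = as.integer(age_range), maf_range = maf_range,
              h2_resilience = h2_resilience, litter_var_frac = litter_var_frac,
              illness_rate = illness_rate, illness_depth = illness_depth,
              seed = as.integer(seed), n_causal = as.integer(n_causal),
              causal_frac = causal_frac, score_sd = score_sd,
              litter_size = litter_size, fst = fst,
              sd_fi0 = sd_fi0, sd_fd0 = sd_fd0)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_animals, " animals, ", x$n_snps, " SNPs, ",
      x$n_breeds, " breeds; h2 = ", x$h2_resilience,
      ", litter = ", x$litter_var_frac,
      ", illness rate = ", x$illness_rate, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
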