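#' Descriptive statistics for a phenotype table
#'
#' @param pheno data.frame with `animal_id` and numeric trait columns.
#' @param traits trait columns to summarise (default: all numeric).
#' @return data.frame `trait`, `N`, `mean`, `sd`, `min`, `max` (SD is NA
#'   for a single observation).
#' @export
descriptive_stats <- function(pheno, traits = NULL) {
  if (is.null(traits))
    traits <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                      "animal_id")
  rows <- lapply(traits, function(tr) {
    x <- pheno[[tr]][is.finite(pheno[[tr]])]
    data.frame(trait = tr, N = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
               min = if (length(x)) min(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phenotypic and genetic correlation report
#'
#' Returns a square matrix layout with Pearson phenotypic correlations
#' below the diagonal (with significance stars from the t-test of r at
#' 0.05/0.01/0.001) and bivariate-REML genetic correlations (SE) above the
#' diagonal. Failed bivariate fits leave the cell NA.
#'
#' @param pheno phenotype + covariate data.frame.
#' @param traits trait columns to cross.
#' @param K relationship matrix (required unless `genetic = FALSE`).
#' @param fixed,litter model terms passed to [genetic_correlation()].
#' @param genetic compute the genetic (upper) triangle (default TRUE).
#' @return list `phenotypic` (matrix of r), `phenotypic_p`, `genetic`
#'   (matrix of rg), `genetic_se`, `display` (character matrix, lower = r
#'   with stars, upper = rg (SE)).
#' @export
correlation_report <- function(pheno, traits, K = NULL,
                               fixed = c("pen_batch", "breed", "sex"),
                               litter = "litter", genetic = TRUE) {
  k <- length(traits)
  rp <- pp <- rg <- rgse <- matrix(NA_real_, k, k,
                                   dimnames = list(traits, traits))
  diag(rp) <- 1; diag(rg) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i <= j) next
    ct <- stats::cor.test(pheno[[traits[i]]], pheno[[traits[j]]])
    rp[i, j] <- unname(ct$estimate); pp[i, j] <- ct$p.value
    rp[j, i] <- rp[i, j]; pp[j, i] <- pp[i, j]
  }
  if (genetic) {
    if (is.null(K)) stop("K required for genetic correlations", call. = FALSE)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i >= j) next
      fit <- tryCatch(
        genetic_correlation(pheno, traits[i], traits[j], K,
                            fixed = fixed, litter = litter),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rg[i, j] <- fit$rg; rg[j, i] <- fit$rg
        rgse[i, j] <- fit$se; rgse[j, i] <- fit$se
      }
    }
  }
  stars <- function(p) if (is.na(p)) "" else if (p < 0.001) "***" else
    if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  disp <- matrix("", k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) disp[i, j] <- "-"
    else if (i > j)
      disp[i, j] <- sprintf("%.3f %s", rp[i, j], stars(pp[i, j]))
    else if (!is.na(rg[i, j]))
      disp[i, j] <- sprintf("%.3f (%s)", rg[i, j],
                            if (is.na(rgse[i, j])) "NA"
                            else sprintf("%.3f", rgse[i, j]))
  }
  list(phenotypic = rp, phenotypic_p = pp, genetic = rg, genetic_se = rgse,
       display = disp)
}

#' Birth year-season covariate factor
#'
#' Codes birth dates as a year x quarter factor, the default "birth year
#' and season" fixed effect of the association model.
#'
#' @param birth_date Date vector (or parseable character).
#' @return factor like `"2024-Q1"`.
#' @export
year_season <- function(birth_date) {
  bd <- as.Date(birth_date)
  q <- (as.integer(format(bd, "%m")) - 1L) %/% 3L + 1L
  factor(paste0(format(bd, "%Y"), "-Q", q))
}

#' Build the association-model covariate matrix
#'
#' Intercept, birth year-season, breed, and the top principal components of
#' the relationship matrix, reduced to full column rank.
#'
#' @param covariates data.frame with `animal_id`, `breed`, `birth_date`.
#' @param pca a [pca_grm()] result whose rows cover the animals, or NULL to
#'   omit PCs.
#' @param n_pcs number of PCs to include (default 5).
#' @return numeric matrix with rownames = animal ids.
#' @export
gwas_covariates <- function(covariates, pca = NULL, n_pcs = 5) {
  ids <- as.character(covariates$animal_id)
  df <- data.frame(ys = year_season(covariates$birth_date),
                   breed = factor(covariates$breed))
  W <- stats::model.matrix(~ ys + breed, df)
  if (!is.null(pca)) {
    V <- pca$vectors[ids, seq_len(min(n_pcs, ncol(pca$vectors))), drop = FALSE]
    W <- cbind(W, V)
  }
  qw <- qr(W)
  W <- W[, qw$pivot[seq_len(qw$rank)], drop = FALSE]
  rownames(W) <- ids
  W
}

#' Run the full resilience pipeline on synthetic data
#'
#' Simulation, feeder QC, resilience and production traits, genetic
#' parameters and (optionally) a GWAS per resilience trait, with a manifest
#' capturing every threshold and seed. Stages can be switched off to keep
#' runs small.
#'
#' @param cfg a [sim_config()].
#' @param tau fasting-threshold quantile level (default 0.05).
#' @param min_records,sd_k,window,rolling QC parameters (defaults 60, 4,
#'   c(90, 150), 5).
#' @param genotype_thresholds named list `ind_cr`, `snp_cr`, `maf`, `hwe_p`.
#' @param fdr GWAS FDR level (default 0.001).
#' @param do_reml estimate h2 per trait by pedigree REML.
#' @param do_gwas run the LMM GWAS (genomic K) for `gwas_traits`.
#' @param gwas_traits resilience traits to scan (default `"RMSE_FI"`).
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return list `phenotypes`, `qc_report`, `summary` (descriptive stats),
#'   `h2` (per-trait animal-model fits), `gwas` (named list of
#'   `gwas_result`), `manifest`, plus the simulated `population`.
#' @export
run_pipeline <- function(cfg = sim_config(),
                         tau = 0.05, min_records = 60, sd_k = 4,
                         window = c(90, 150), rolling = 5,
                         genotype_thresholds = list(ind_cr = 0.95,
                                                    snp_cr = 0.90,
                                                    maf = 0.05,
                                                    hwe_p = 1e-6),
                         fdr = 0.001, do_reml = FALSE, do_gwas = FALSE,
                         gwas_traits = "RMSE_FI", out_dir = NULL) {
  pop <- simulate_population(cfg)
  feeder <- simulate_feeder_series(cfg, pop)
  qc <- qc_feeder(feeder$visits, feeder$birthdates,
                  min_records = min_records, sd_k = sd_k,
                  window = window, rolling = rolling)
  res <- resilience_traits(qc$daily, tau = tau)
  prod <- production_traits(qc$daily,
                            backfat = data.frame(
                              animal_id = pop$covariates$animal_id,
                              bf_mm = pop$covariates$bf_mm))
  pheno <- merge(res, prod, by = "animal_id")
  pheno <- merge(pheno, pop$covariates, by = "animal_id")
  trait_cols <- c("RMSE_FI", "RMSE_FD", "RMSE_CFI", "RMSE_CFD",
                  "QR_FI", "QR_FD",
                  "ADG", "AGE", "BF", "ADFI", "ADFD", "FCR", "RFI")
  summary_tab <- descriptive_stats(pheno, trait_cols)

  h2 <- NULL
  if (do_reml) {
    A <- pedigree_A(pop$pedigree)
    h2 <- lapply(stats::setNames(nm = trait_cols), function(tr)
      tryCatch(fit_animal_model(pheno, tr, A), error = function(e) e))
  }

  gw <- NULL
  if (do_gwas) {
    ids <- as.character(pheno$animal_id)
    qcd <- genotype_qc(pop$genotypes[ids, , drop = FALSE], pop$map,
                       ind_cr = genotype_thresholds$ind_cr,
                       snp_cr = genotype_thresholds$snp_cr,
                       maf_min = genotype_thresholds$maf,
                       hwe_p = genotype_thresholds$hwe_p)
    Kg <- grm(qcd$genotypes)
    pc <- pca_grm(Kg, k = 5)
    keep <- as.character(pheno$animal_id) %in% rownames(qcd$genotypes)
    ph <- pheno[keep, , drop = FALSE]
    W <- gwas_covariates(ph, pc)
    gw <- lapply(stats::setNames(nm = gwas_traits), function(tr)
      lmm_assoc(ph[[tr]], W, Kg[rownames(W), rownames(W)],
                qcd$genotypes[rownames(W), , drop = FALSE],
                map = qcd$map, fdr = fdr))
  }

  manifest <- list(
    seed = cfg$seed, n_animals = cfg$n_animals, n_snps = cfg$n_snps,
    min_records = min_records, sd_k = sd_k, age_window = window,
    rolling_window = rolling, tau = tau,
    genotype_qc = genotype_thresholds, fdr = fdr,
    h2_resilience = cfg$h2_resilience,
    litter_var_frac = cfg$litter_var_frac,
    illness_rate = cfg$illness_rate, illness_depth = cfg$illness_depth)

  out <- list(phenotypes = pheno, qc_report = qc$report,
              summary = summary_tab, h2 = h2, gwas = gw,
              manifest = manifest, population = pop)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(pheno, file.path(out_dir, "phenotypes.csv"))
    data.table::fwrite(summary_tab, file.path(out_dir, "summary.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(gw))
      for (tr in names(gw))
        qq_manhattan_export(gw[[tr]], file.path(out_dir, "gwas", tr))
  }
  out
}
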