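#' Hardy-Weinberg equilibrium chi-square test for one SNP
#'
#' One-degree-of-freedom goodness-of-fit chi-square of observed genotype
#' counts against expectations from the estimated allele frequency.
#'
#' @param dosages vector of 0/1/2 dosages (NA allowed).
#' @return p-value (1 for monomorphic or empty SNPs).
#' @export
hwe_test <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  n <- length(d)
  if (n == 0) return(1)
  obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  exp <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - exp)^2 / exp)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Per-SNP minor allele frequency
#'
#' @param G dosage matrix (animals x SNPs, NA = missing).
#' @return vector of MAF per SNP.
#' @export
maf <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Genotype quality control
#'
#' Applies, in order: removal of individuals with genotype call rate below
#' `ind_cr`; removal of SNPs on sex chromosomes or unplaced scaffolds (when
#' a map is supplied); removal of SNPs with call rate below `snp_cr`, minor
#' allele frequency not exceeding `maf_min`, or Hardy-Weinberg equilibrium
#' chi-square p-value below `hwe_p`.
#'
#' @param G dosage matrix (animals x SNPs, NA = missing).
#' @param map optional SNP metadata with columns `snp` and `chrom`;
#'   autosomes are chromosome labels that parse as positive integers.
#' @param ind_cr individual call-rate threshold (default 0.95).
#' @param snp_cr SNP call-rate threshold (default 0.90).
#' @param maf_min MAF threshold; SNPs with MAF <= `maf_min` are removed
#'   (default 0.05).
#' @param hwe_p HWE p-value threshold (default 1e-6).
#' @return list `genotypes` (filtered matrix), `map` (filtered metadata or
#'   NULL), `report` (counts removed per rule).
#' @export
genotype_qc <- function(G, map = NULL, ind_cr = 0.95, snp_cr = 0.90,
                        maf_min = 0.05, hwe_p = 1e-6) {
  stopifnot(is.matrix(G))
  ind_call <- rowMeans(!is.na(G))
  keep_ind <- ind_call >= ind_cr
  G <- G[keep_ind, , drop = FALSE]

  removed_sex <- 0L
  if (!is.null(map)) {
    stopifnot(nrow(map) == ncol(G))
    auto <- suppressWarnings(as.integer(as.character(map$chrom)))
    keep_auto <- !is.na(auto) & auto >= 1
    removed_sex <- sum(!keep_auto)
    G <- G[, keep_auto, drop = FALSE]
    map <- map[keep_auto, , drop = FALSE]
  }

  snp_call <- colMeans(!is.na(G))
  mafs <- maf(G)
  hwe <- apply(G, 2, hwe_test)
  keep_snp <- snp_call >= snp_cr & mafs > maf_min & hwe >= hwe_p
  keep_snp[is.na(keep_snp)] <- FALSE
  report <- c(individuals_removed = sum(!keep_ind),
              snps_sex_or_unplaced = removed_sex,
              snps_low_call = sum(snp_call < snp_cr),
              snps_low_maf = sum(snp_call >= snp_cr & mafs <= maf_min),
              snps_hwe = sum(snp_call >= snp_cr & mafs > maf_min &
                               hwe < hwe_p),
              snps_kept = sum(keep_snp))
  if (!any(keep_snp)) stop("all SNPs removed by QC", call. = FALSE)
  list(genotypes = G[, keep_snp, drop = FALSE],
       map = if (!is.null(map)) map[keep_snp, , drop = FALSE],
       report = report)
}

#' Genomic relationship matrix from dosages
#'
#' Mean-imputes missing dosages per SNP, centres columns by twice the
#' observed allele frequency and forms the scaled cross-product. The
#' default VanRaden scaling divides by \eqn{2\sum p_j(1-p_j)} so the mean
#' diagonal is about 1 in an unstructured cohort; `"centered"` divides by
#' the SNP count (the GEMMA centred relatedness convention) and
#' `"standardized"` also divides each column by its expected SD.
#'
#' @param G dosage matrix (animals x SNPs, NA = missing).
#' @param method `"vanraden"` (default), `"centered"` or `"standardized"`.
#' @return symmetric relationship matrix with animal dimnames.
#' @export
grm <- function(G, method = c("vanraden", "centered", "standardized")) {
  method <- match.arg(method)
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance SNPs dropped from GRM")
    G <- G[, keep, drop = FALSE]; p <- p[keep]
  }
  Z <- sweep(G, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation after centring
  if (method == "standardized")
    Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z)
  K / switch(method,
             vanraden = 2 * sum(p * (1 - p)),
             centered = ncol(Z),
             standardized = ncol(Z))
}
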