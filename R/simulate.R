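#' Simulate a structured pig population with genotypes and ground truth
#'
#' Generates a two-generation pedigree (breed-specific founders and their
#' phenotyped offspring), SNP genotypes with breed-divergent founder allele
#' frequencies and Mendelian transmission, litter/pen/batch covariates, and
#' the ground-truth genetic architecture of the latent resilience score.
#'
#' Founder allele frequencies per breed are drawn around an ancestral
#' frequency using a Balding-Nichols model with fixation index `cfg$fst`,
#' which makes breeds separable on the leading principal components of the
#' genomic relationship matrix. The additive component of the latent score is
#' the sum of a causal-SNP part (`cfg$n_causal` markers, fraction
#' `cfg$causal_frac` of the additive variance) and a pedigree polygenic part,
#' jointly rescaled so that the realised additive variance equals
#' `cfg$h2_resilience * cfg$score_sd^2`.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{pedigree}{data.frame `id`, `sire`, `dam` (founders have `0`).}
#'     \item{genotypes}{integer matrix animals x SNPs with dosages 0/1/2,
#'       rownames = animal ids.}
#'     \item{map}{data.frame `snp`, `chrom`, `pos`, `a1`, `a2`.}
#'     \item{covariates}{data.frame `animal_id`, `breed`, `sex`, `pen`,
#'       `batch`, `pen_batch`, `litter`, `birth_date`, `bf_mm` for the
#'       phenotyped offspring.}
#'     \item{truth}{list: `true_breeding_values` (named, log-SD scale; larger
#'       = more variable = less resilient), `latent_score` (named; additive +
#'       litter + environment), `true_h2`, `causal_snps` (data.frame `snp`,
#'       `effect`), `litter_assignments`, `litter_effects`.}
#'   }
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  n_off  <- cfg$n_animals
  breeds <- paste0("B", seq_len(cfg$n_breeds))
  off_breed <- sort(rep_len(seq_len(cfg$n_breeds), n_off))

  ## founders: one litter per dam, dams nested in sires (~5 dams/sire)
  n_dam_b  <- pmax(1L, ceiling(tabulate(off_breed, cfg$n_breeds) / cfg$litter_size))
  n_sire_b <- pmax(1L, ceiling(n_dam_b / 5))
  n_founders <- sum(n_dam_b) + sum(n_sire_b)

  founder_breed <- integer(0)
  founder_role  <- character(0)
  for (b in seq_len(cfg$n_breeds)) {
    founder_breed <- c(founder_breed, rep(b, n_sire_b[b] + n_dam_b[b]))
    founder_role  <- c(founder_role, rep("sire", n_sire_b[b]), rep("dam", n_dam_b[b]))
  }
  founder_id <- sprintf("F%04d", seq_len(n_founders))
  off_id     <- sprintf("A%04d", seq_len(n_off))

  ## mate assignment: offspring -> dam (litter), dam -> sire
  dam_of  <- integer(n_off)
  sire_of <- integer(n_off)
  litter  <- character(n_off)
  for (b in seq_len(cfg$n_breeds)) {
    ob    <- which(off_breed == b)
    dams  <- which(founder_breed == b & founder_role == "dam")
    sires <- which(founder_breed == b & founder_role == "sire")
    dam_of[ob]  <- dams[sort(rep_len(seq_along(dams), length(ob)))]
    sire_of[ob] <- sires[rep_len(seq_along(sires), length(dams))][
      match(dam_of[ob], dams)]
  }
  ## two parities per dam: full sibs across parities share dam genetics but
  ## not litter environment, which separates the litter and additive terms
  parity <- integer(n_off)
  for (dm in unique(dam_of)) {
    k <- which(dam_of == dm)
    parity[k] <- rep(1:2, each = ceiling(length(k) / 2))[seq_along(k)]
  }
  litter <- paste0(founder_id[dam_of], ".", parity)

  pedigree <- data.frame(
    id   = c(founder_id, off_id),
    sire = c(rep("0", n_founders), founder_id[sire_of]),
    dam  = c(rep("0", n_founders), founder_id[dam_of]),
    stringsAsFactors = FALSE)

  ## genotypes: Balding-Nichols breed frequencies, Mendelian transmission
  m <- cfg$n_snps
  p_anc <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  theta <- (1 - cfg$fst) / cfg$fst
  p_breed <- matrix(0, cfg$n_breeds, m)
  for (b in seq_len(cfg$n_breeds)) {
    p_breed[b, ] <- rbeta(m, p_anc * theta, (1 - p_anc) * theta)
    p_breed[b, ] <- pmin(pmax(p_breed[b, ], 0.005), 0.995)
  }
  G_f <- matrix(0L, n_founders, m)
  for (b in seq_len(cfg$n_breeds)) {
    fb <- which(founder_breed == b)
    G_f[fb, ] <- matrix(rbinom(length(fb) * m, 2L, rep(p_breed[b, ], each = length(fb))),
                        length(fb), m)
  }
  gamete <- function(gp) {
    ## one transmitted allele per locus from parent dosage row-matrix gp
    matrix(rbinom(length(gp), 1L, gp / 2), nrow(gp), ncol(gp))
  }
  G_o <- gamete(G_f[sire_of, , drop = FALSE]) + gamete(G_f[dam_of, , drop = FALSE])
  G <- rbind(G_f, G_o)
  storage.mode(G) <- "integer"
  rownames(G) <- c(founder_id, off_id)

  map <- data.frame(
    snp   = sprintf("snp%05d", seq_len(m)),
    chrom = sort(rep_len(1:18, m)),
    pos   = NA_integer_, a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  map$pos <- as.integer(unlist(lapply(split(seq_len(m), map$chrom),
                                      function(i) seq_along(i) * 10000L)))
  colnames(G) <- map$snp

  ## latent resilience score: additive (causal + polygenic) + litter + env
  sigma_s2 <- cfg$score_sd^2
  sigma_a2 <- cfg$h2_resilience * sigma_s2
  sigma_l2 <- cfg$litter_var_frac * sigma_s2
  sigma_e2 <- sigma_s2 - sigma_a2 - sigma_l2

  n_all <- n_founders + n_off
  if (sigma_a2 > 0) {
    n_causal <- min(cfg$n_causal, m)
    causal_idx <- sort(sample.int(m, n_causal))
    raw_eff <- rnorm(n_causal)
    g_raw <- as.numeric(G[, causal_idx, drop = FALSE] %*% raw_eff)
    ## scale on the pooled within-breed variance: breed-frequency divergence
    ## puts part of the raw variance between breeds, which the animal
    ## model's fixed breed effect absorbs
    breed_all <- c(founder_breed, off_breed)
    v_raw <- mean(tapply(g_raw, breed_all, stats::var), na.rm = TRUE)
    sc <- if (v_raw > 0) sqrt(cfg$causal_frac * sigma_a2 / v_raw) else 0
    eff <- raw_eff * sc
    g_causal <- g_raw * sc

    ## pedigree polygenic flow
    v_poly <- (1 - cfg$causal_frac) * sigma_a2
    poly <- numeric(n_all)
    poly[seq_len(n_founders)] <- rnorm(n_founders, 0, sqrt(v_poly))
    ms <- rnorm(n_off, 0, sqrt(v_poly / 2))
    poly[n_founders + seq_len(n_off)] <-
      0.5 * (poly[sire_of] + poly[dam_of]) + ms
    a <- g_causal - mean(g_causal) + poly
    causal <- data.frame(snp = causal_idx, effect = eff)
  } else {
    a <- numeric(n_all)
    causal <- data.frame(snp = integer(0), effect = numeric(0))
  }
  names(a) <- rownames(G)

  litter_all <- c(founder_id, litter)  # founders: own "litter" (unused)
  litter_eff_by <- stats::setNames(rnorm(length(unique(litter)), 0, sqrt(sigma_l2)),
                                   unique(litter))
  env <- rnorm(n_off, 0, sqrt(sigma_e2))
  s_off <- a[off_id] + litter_eff_by[litter] + env
  names(s_off) <- off_id

  ## covariates for phenotyped offspring: a batch is an entry cohort (parity
  ## x dam group) spanning many litters, and pens interleave litters within a
  ## batch, so pen x batch cells never coincide with single litters
  sex <- sample(c("M", "F"), n_off, replace = TRUE)
  dam_rank <- match(dam_of, unique(dam_of))
  batch <- paste0("b", parity + 2L * ((dam_rank - 1L) %% 2L))
  within_litter <- stats::ave(seq_len(n_off), litter, FUN = seq_along)
  pen <- character(n_off)
  for (b in unique(batch)) {
    i <- which(batch == b)
    ord <- i[order(within_litter[i], litter[i])]
    pen[ord] <- paste0("p", b, "_", ceiling(seq_along(ord) / 15))
  }
  batch_start <- as.Date("2024-01-15") +
    (match(batch, sort(unique(batch))) - 1L) * 35L
  birth_date <- batch_start + sample(0:6, n_off, replace = TRUE)
  bf_mm <- round(rnorm(n_off, 10.7, 1.8) + 0.5 * (off_breed - 2), 2)

  covariates <- data.frame(
    animal_id = off_id,
    breed = breeds[off_breed], sex = sex, pen = pen, batch = batch,
    pen_batch = paste(pen, batch, sep = ":"),
    litter = litter, birth_date = birth_date, bf_mm = bf_mm,
    stringsAsFactors = FALSE)

  truth <- list(
    true_breeding_values = a[off_id],
    latent_score = s_off,
    true_h2 = cfg$h2_resilience,
    causal_snps = causal,
    litter_assignments = stats::setNames(litter, off_id),
    litter_effects = litter_eff_by)

  list(pedigree = pedigree, genotypes = G, map = map,
       covariates = covariates, truth = truth)
}

#' Simulate feeder visit records for a simulated population
#'
#' Builds daily target trajectories for feed intake (FI, kg), feeding
#' duration (FD, min) and body weight (kg) over the on-test age window,
#' perturbs them with animal-specific residual noise (SD scaled by the
#' latent resilience score), superimposes multi-day illness episodes that
#' multiply FI and FD by `1 - illness_depth`, and decomposes each daily
#' total into 1-12 visits whose consumed grams sum exactly to the daily
#' total (1-g feeder resolution).
#'
#' @param cfg a [sim_config()].
#' @param pop result of [simulate_population()] run with the same `cfg`.
#' @param noise_sd_scale multiplier on the residual SDs (0 gives noiseless
#'   trajectories; useful for analytic checks).
#' @return a list with `visits` (data.frame `animal_id`, `start_ts`,
#'   `end_ts`, `trough_in_g`, `trough_out_g`, `weight_kg`), `daily_truth`
#'   (the generated daily totals before visit decomposition) and
#'   `birthdates` (data.frame `animal_id`, `birth_date`).
#' @export
simulate_feeder_series <- function(cfg, pop, noise_sd_scale = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 97L)

  cov <- pop$covariates
  n <- nrow(cov)
  ages <- seq(cfg$age_range[1], cfg$age_range[2])
  nd <- length(ages)
  s <- pop$truth$latent_score[cov$animal_id]

  ## per-animal trajectory parameters (population means give ADFI ~ 2.5 kg,
  ## ADFD ~ 56 min, ADG ~ 1.05 kg/d over 90-150 d)
  breed_i <- match(cov$breed, sort(unique(cov$breed)))
  fi_int  <- 2.5 + 0.08 * (breed_i - 2) + rnorm(n, 0, 0.18)
  fi_slp  <- 0.023 + rnorm(n, 0, 0.002)
  fd_int  <- 56 + 1.5 * (breed_i - 2) + rnorm(n, 0, 5)
  fd_slp  <- -0.05 + rnorm(n, 0, 0.03)
  w90     <- rnorm(n, 41, 3)
  adg     <- 1.05 + 0.03 * (breed_i - 2) + rnorm(n, 0, 0.10)
  sd_fi   <- cfg$sd_fi0 * exp(s) * noise_sd_scale
  sd_fd   <- cfg$sd_fd0 * exp(s) * noise_sd_scale

  ## illness mask: episode starts are Bernoulli(illness_rate) per animal-day,
  ## durations 1 + Geometric(0.5)
  ill <- matrix(FALSE, n, nd)
  if (cfg$illness_rate > 0) {
    starts <- matrix(runif(n * nd) < cfg$illness_rate, n, nd)
    idx <- which(starts, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      durs <- 1L + rgeom(nrow(idx), 0.5)
      for (k in seq_len(nrow(idx))) {
        j <- idx[k, 2]:min(nd, idx[k, 2] + durs[k] - 1L)
        ill[idx[k, 1], j] <- TRUE
      }
    }
  }
  mult <- ifelse(ill, 1 - cfg$illness_depth, 1)

  age_m  <- matrix(ages, n, nd, byrow = TRUE)
  fi_day <- (fi_int + fi_slp * (age_m - 120)) * mult +
    matrix(rnorm(n * nd), n, nd) * sd_fi
  fd_day <- (fd_int + fd_slp * (age_m - 120)) * mult +
    matrix(rnorm(n * nd), n, nd) * sd_fd
  fi_day <- pmax(fi_day, 0.05)
  fd_day <- pmax(fd_day, 2)
  w_day  <- w90 + adg * (age_m - 90) + matrix(rnorm(n * nd, 0, 0.4), n, nd)

  daily <- data.table::data.table(
    animal_id = rep(cov$animal_id, nd),
    age = rep(ages, each = n),
    date = rep(cov$birth_date, nd) + rep(ages, each = n),
    fi_g = as.integer(round(as.vector(fi_day) * 1000)),
    fd_s = as.integer(round(as.vector(fd_day) * 60)),
    weight_kg = round(as.vector(w_day), 1),
    ill = as.vector(ill))
  data.table::setorder(daily, animal_id, age)

  ## visit decomposition: symmetric Dirichlet split, largest-remainder
  ## rounding so grams (and seconds) sum exactly to the daily totals
  nv <- pmin(1L + stats::rbinom(nrow(daily), 11L, 0.3), pmax(daily$fi_g, 1L))
  vis <- daily[rep(seq_len(nrow(daily)), nv)]
  vis[, visit := seq_len(.N), by = .(animal_id, age)]
  vis[, w := stats::rgamma(.N, 1)]
  split_int <- function(total, w) {
    p <- w / sum(w)
    x <- floor(p * total)
    r <- total - sum(x)
    if (r > 0) {
      frac <- p * total - x
      x[order(frac, decreasing = TRUE)[seq_len(r)]] <- x[order(frac, decreasing = TRUE)[seq_len(r)]] + 1L
    }
    as.integer(x)
  }
  vis[, grams := split_int(fi_g[1], w), by = .(animal_id, age)]
  vis[, dur_s := split_int(fd_s[1], w), by = .(animal_id, age)]
  vis[, dur_s := pmax(dur_s, 1L)]

  ## ordered, non-overlapping start times across the day (05:00-21:00)
  vis[, gap := stats::runif(.N)]
  vis[, start_off := {
    tot <- sum(dur_s)
    free <- max(16 * 3600 - tot, .N)
    starts <- cumsum(c(0, dur_s[-.N])) + round(cumsum(gap) / sum(gap) * free * 0.9)
    as.integer(5 * 3600 + starts)
  }, by = .(animal_id, age)]
  day0 <- as.POSIXct(paste(vis$date, "00:00:00"), tz = "UTC")
  vis[, start_ts := day0 + start_off]
  vis[, end_ts := start_ts + dur_s]
  vis[, weight_v := round(weight_kg + stats::rnorm(.N, 0, 0.2), 1)]

  visits <- data.frame(
    animal_id = vis$animal_id,
    start_ts = format(vis$start_ts, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    end_ts = format(vis$end_ts, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    trough_in_g = 4000L + vis$grams,
    trough_out_g = 4000L,
    weight_kg = vis$weight_v,
    stringsAsFactors = FALSE)

  daily_truth <- data.frame(
    animal_id = daily$animal_id, age = daily$age, date = daily$date,
    fi_kg = daily$fi_g / 1000, fd_min = daily$fd_s / 60,
    weight_kg = daily$weight_kg, ill = daily$ill,
    stringsAsFactors = FALSE)

  list(visits = visits,
       daily_truth = daily_truth,
       birthdates = data.frame(animal_id = cov$animal_id,
                               birth_date = cov$birth_date,
                               stringsAsFactors = FALSE))
}

utils::globalVariables(c(
  "visit", "w", "grams", "dur_s", "fi_g", "fd_s", "gap", "start_off",
  "start_ts", "end_ts", "weight_v", "weight_kg", ".N", "."))
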