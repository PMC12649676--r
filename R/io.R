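#' Write a simulated dataset to disk in standard interchange formats
#'
#' Visits, pedigree and covariates go to CSV; genotypes are written both as
#' PLINK-style PED/MAP text and as a minimal VCF 4.2; the ground-truth
#' architecture is serialised to JSON.
#'
#' @param pop result of [simulate_population()].
#' @param feeder result of [simulate_feeder_series()].
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of the files written.
#' @export
write_simulation <- function(pop, feeder, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    visits = file.path(dir, "visits.csv"),
    birthdates = file.path(dir, "birthdates.csv"),
    pedigree = file.path(dir, "pedigree.csv"),
    covariates = file.path(dir, "covariates.csv"),
    ped = file.path(dir, "genotypes.ped"),
    map = file.path(dir, "genotypes.map"),
    vcf = file.path(dir, "genotypes.vcf"),
    truth = file.path(dir, "ground_truth.json"))
  data.table::fwrite(feeder$visits, files["visits"])
  data.table::fwrite(feeder$birthdates, files["birthdates"])
  data.table::fwrite(pop$pedigree, files["pedigree"])
  data.table::fwrite(pop$covariates, files["covariates"])
  write_ped_map(pop$genotypes, pop$map, files["ped"], files["map"])
  write_vcf(pop$genotypes, pop$map, files["vcf"])
  truth <- pop$truth
  jsonlite::write_json(
    list(true_h2 = truth$true_h2,
         true_breeding_values = as.list(truth$true_breeding_values),
         latent_score = as.list(truth$latent_score),
         causal_snps = truth$causal_snps,
         litter_assignments = as.list(truth$litter_assignments)),
    files["truth"], auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Read feeder visit records from CSV
#'
#' @param path CSV with columns `animal_id`, `start_ts`, `end_ts`,
#'   `trough_in_g`, `trough_out_g`, `weight_kg` (names remappable via
#'   `col_map`).
#' @param col_map optional named character vector mapping the expected names
#'   to the names present in the file.
#' @return data.frame of visit records with parsed POSIXct timestamps (UTC).
#' @export
read_visits <- function(path, col_map = NULL) {
  v <- as.data.frame(data.table::fread(path))
  if (!is.null(col_map)) {
    for (std in names(col_map)) names(v)[names(v) == col_map[[std]]] <- std
  }
  need <- c("animal_id", "start_ts", "end_ts", "trough_in_g", "trough_out_g",
            "weight_kg")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("visits file lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  v$start_ts <- as.POSIXct(v$start_ts, tz = "UTC")
  v$end_ts <- as.POSIXct(v$end_ts, tz = "UTC")
  v
}

#' Write genotypes as PLINK-style PED/MAP text files
#'
#' @param G dosage matrix (animals x SNPs, values 0/1/2, rownames = ids).
#' @param map data.frame `snp`, `chrom`, `pos`, `a1`, `a2`.
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(G, map, ped_path, map_path) {
  stopifnot(ncol(G) == nrow(map))
  a1 <- map$a1; a2 <- map$a2
  alleles <- function(d, j) switch(as.character(d),
    "0" = c(a2[j], a2[j]), "1" = c(a1[j], a2[j]), "2" = c(a1[j], a1[j]),
    c("0", "0"))
  lines <- vapply(seq_len(nrow(G)), function(i) {
    al <- unlist(lapply(seq_len(ncol(G)), function(j) alleles(G[i, j], j)))
    paste(c("FAM", rownames(G)[i], "0", "0", "0", "-9", al), collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  write.table(data.frame(map$chrom, map$snp, 0, map$pos),
              map_path, quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
}

#' Read genotypes from PLINK-style PED/MAP text files
#'
#' Counts copies of the MAP file's first allele (`0 0` is missing).
#'
#' @param ped_path,map_path input paths.
#' @param a1 optional character vector of counted alleles per SNP; defaults
#'   to the first allele observed per locus.
#' @return list `genotypes` (dosage matrix, NA = missing) and `map`.
#' @export
read_ped_map <- function(ped_path, map_path, a1 = NULL) {
  mp <- read.table(map_path, header = FALSE,
                   col.names = c("chrom", "snp", "cm", "pos"),
                   colClasses = c("character", "character", "numeric", "integer"))
  rows <- strsplit(readLines(ped_path), "[ \t]+")
  m <- nrow(mp)
  G <- matrix(NA_real_, length(rows), m)
  ids <- character(length(rows))
  al1 <- matrix(NA_character_, length(rows), m)
  al2 <- matrix(NA_character_, length(rows), m)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != 6 + 2 * m)
      stop("PED row ", i, " has ", length(r), " fields; expected ", 6 + 2 * m,
           call. = FALSE)
    ids[i] <- r[2]
    al1[i, ] <- r[6 + 2 * seq_len(m) - 1]
    al2[i, ] <- r[6 + 2 * seq_len(m)]
  }
  if (is.null(a1)) {
    a1 <- vapply(seq_len(m), function(j) {
      obs <- c(al1[, j], al2[, j]); obs <- obs[obs != "0"]
      if (length(obs)) obs[1] else "A"
    }, character(1))
  }
  for (j in seq_len(m)) {
    miss <- al1[, j] == "0" | al2[, j] == "0"
    G[, j] <- (al1[, j] == a1[j]) + (al2[, j] == a1[j])
    G[miss, j] <- NA
  }
  rownames(G) <- ids
  colnames(G) <- mp$snp
  list(genotypes = G, map = mp)
}

#' Write genotypes as a minimal VCF 4.2 file
#'
#' Dosages are emitted as unphased GT fields with `a1` as the ALT allele
#' (dosage counts ALT copies); missing dosage becomes `./.`.
#'
#' @inheritParams write_ped_map
#' @param path output path.
#' @export
write_vcf <- function(G, map, path) {
  stopifnot(ncol(G) == nrow(map))
  gt_code <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=resilio",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(nrow(map)), function(j) {
    gt <- gt_code[as.character(G[, j])]
    gt[is.na(gt)] <- "./."
    paste(c(map$chrom[j], map$pos[j], map$snp[j], map$a2[j], map$a1[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read dosages from a VCF file
#'
#' Uses `vcfR` when available, otherwise a plain-text fallback parser for
#' the minimal GT-only layout written by [write_vcf()]. Dosage counts ALT
#' allele copies.
#'
#' @param path VCF path.
#' @return list `genotypes` (animals x SNPs dosage matrix, NA missing) and
#'   `map` (`snp`, `chrom`, `pos`, `a1` = ALT, `a2` = REF).
#' @export
read_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "##")]
    hdr <- strsplit(sub("^#", "", ln[1]), "\t")[[1]]
    body <- do.call(rbind, strsplit(ln[-1], "\t"))
    colnames(body) <- hdr
    fix <- as.data.frame(body[, c("CHROM", "POS", "ID", "REF", "ALT"),
                              drop = FALSE], stringsAsFactors = FALSE)
    gt <- body[, -(1:9), drop = FALSE]
    rownames(gt) <- body[, "ID"]
  }
  dose1 <- function(x) {
    x <- sub(":.*", "", x)
    out <- rep(NA_real_, length(x))
    ok <- grepl("^[0-9]([/|][0-9])?$", x)
    out[ok] <- vapply(strsplit(x[ok], "[/|]"),
                      function(a) sum(a == "1"), numeric(1))
    out
  }
  D <- apply(gt, 2, dose1)
  if (is.null(dim(D))) D <- matrix(D, nrow = 1, dimnames = list(NULL, names(D)))
  G <- t(D)
  colnames(G) <- fix$ID
  list(genotypes = G,
       map = data.frame(snp = fix$ID, chrom = fix$CHROM,
                        pos = as.integer(fix$POS), a1 = fix$ALT, a2 = fix$REF,
                        stringsAsFactors = FALSE))
}
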