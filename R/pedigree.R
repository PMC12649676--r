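#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive relationship matrix A by Henderson's tabular method
#' after topologically sorting the pedigree so parents precede offspring:
#' \eqn{A_{ii} = 1 + 0.5 A_{sd}} (diagonal carries the inbreeding
#' coefficient) and \eqn{A_{ij} = 0.5 (A_{j,s} + A_{j,d})} for `j` earlier
#' than `i`. Unknown parents are coded `0` or `NA`.
#'
#' @param pedigree data.frame `id`, `sire`, `dam` (character or numeric;
#'   `0`/`NA` = unknown). Parents appearing only as sire/dam are added as
#'   founders.
#' @return symmetric matrix with dimnames = animal ids (pedigree order after
#'   sorting).
#' @export
pedigree_A <- function(pedigree) {
  ped <- data.frame(id = as.character(pedigree$id),
                    sire = as.character(pedigree$sire),
                    dam = as.character(pedigree$dam),
                    stringsAsFactors = FALSE)
  ped$sire[is.na(ped$sire) | ped$sire == "0" | ped$sire == ""] <- NA
  ped$dam[is.na(ped$dam) | ped$dam == "0" | ped$dam == ""] <- NA
  if (anyDuplicated(ped$id)) stop("duplicated animal ids", call. = FALSE)
  extra <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(extra))
    ped <- rbind(data.frame(id = extra, sire = NA, dam = NA), ped)

  ## topological sort (Kahn); a leftover cycle is reported
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  placed <- logical(n); order_out <- integer(0)
  parent_placed <- function(k)
    ifelse(is.na(k), TRUE, placed[replace(k, is.na(k), 1L)])
  repeat {
    ready <- which(!placed & parent_placed(si) & parent_placed(di))
    if (!length(ready)) break
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
  }
  if (length(order_out) < n)
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[!placed], collapse = ", "), call. = FALSE)

  ped <- ped[order_out, ]
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      aij <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                      (if (!is.na(d)) A[j, d] else 0))
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}
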