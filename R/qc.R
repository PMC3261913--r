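# long call table -> dosage matrix (markers x samples)
.calls_matrix <- function(calls) {
  mk <- sort(unique(calls$marker_id))
  sm <- sort(unique(calls$sample_id))
  m <- matrix(NA_integer_, length(mk), length(sm), dimnames = list(mk, sm))
  m[cbind(match(calls$marker_id, mk), match(calls$sample_id, sm))] <-
    calls$dosage
  m
}

# possible gamete B-counts from a parent of total dosage d over n_loci loci
.gamete_range <- function(d, n_loci) {
  c(pmax(0L, d - n_loci), pmin(n_loci, d))
}

#' Quality-filter markers on call rate and Mendelian consistency
#'
#' A marker fails when its call rate over pedigree samples drops below
#' `call_rate_min` or when the rate of Mendelian-impossible transmissions
#' in parent-parent-offspring trios (opposing homozygotes and impossible
#' dosage sums, accounting for the marker's locus count) exceeds
#' `mendel_max`.
#'
#' @param calls long call table (`marker_id`, `sample_id`, `dosage`).
#' @param pedigree pedigree table as from [sample_pedigree()].
#' @param classifications classification table (`marker_id`, `klass`); used
#'   for the per-marker locus count (MSVs read two loci).
#' @param call_rate_min,mendel_max thresholds.
#' @return list with `pass` (character vector of passing marker ids) and
#'   `report` (per-marker metrics).
#' @export
qc_filter <- function(calls, pedigree, classifications,
                      call_rate_min = 0.9, mendel_max = 0.02) {
  unknown <- setdiff(unique(calls$sample_id), pedigree$id)
  if (length(unknown) > 0L)
    .tm_stop("call table contains sample id(s) not in pedigree: %s",
             paste(head(unknown, 5L), collapse = ", "))
  dm <- .calls_matrix(calls)
  ped_samples <- intersect(colnames(dm), pedigree$id)
  dm <- dm[, ped_samples, drop = FALSE]
  klass <- setNames(classifications$klass, classifications$marker_id)
  n_loci <- ifelse(klass[rownames(dm)] %in% c("MSV3", "MSV5"), 2L, 1L)

  trios <- pedigree[pedigree$sire != "0" &
                    pedigree$id %in% colnames(dm) &
                    pedigree$sire %in% colnames(dm) &
                    pedigree$dam %in% colnames(dm), , drop = FALSE]
  call_rate <- rowMeans(!is.na(dm))
  mendel_rate <- rep(0, nrow(dm))
  if (nrow(trios) > 0L) {
    oc <- dm[, trios$id, drop = FALSE]
    sc <- dm[, trios$sire, drop = FALSE]
    dc <- dm[, trios$dam, drop = FALSE]
    full <- !is.na(oc) & !is.na(sc) & !is.na(dc)
    lo <- pmax(0L, sc - n_loci) + pmax(0L, dc - n_loci)
    hi <- pmin(n_loci, sc) + pmin(n_loci, dc)
    bad <- full & (oc < lo | oc > hi)
    ntrio <- rowSums(full)
    mendel_rate <- ifelse(ntrio > 0, rowSums(bad) / ntrio, 0)
  }
  pass <- call_rate >= call_rate_min & mendel_rate <= mendel_max
  report <- data.frame(marker_id = rownames(dm), call_rate = call_rate,
                       mendel_rate = mendel_rate, pass = pass)
  rownames(report) <- NULL
  list(pass = report$marker_id[report$pass], report = report)
}

#' Flag probable pedigree errors
#'
#' For every recorded parent-offspring pair, computes the opposing-
#' homozygote rate over called SNP-class markers (parent dosage 0 with
#' offspring 2, or vice versa).  Pairs whose rate exceeds `multiple` times
#' the cohort median are flagged; flagged offspring should be excluded from
#' linkage analysis.
#'
#' @param calls long call table.
#' @param pedigree pedigree table.
#' @param classifications classification table (`marker_id`, `klass`).
#' @param multiple flag threshold as a multiple of the cohort median rate.
#' @param min_markers minimum number of SNP-class markers required.
#' @return data frame `offspring`, `parent`, `n_compared`, `rate`,
#'   `flagged`.
#' @export
check_pedigree <- function(calls, pedigree, classifications, multiple = 10,
                           min_markers = 50L) {
  snp_ids <- classifications$marker_id[classifications$klass == "SNP"]
  off <- pedigree[pedigree$sire != "0", , drop = FALSE]
  empty <- data.frame(offspring = character(), parent = character(),
                      n_compared = integer(), rate = numeric(),
                      flagged = logical())
  if (nrow(off) == 0L) return(empty)
  if (length(snp_ids) < min_markers)
    .tm_stop("pedigree check requires >= %d called SNP-class markers (have %d)",
             min_markers, length(snp_ids))
  dm <- .calls_matrix(calls[calls$marker_id %in% snp_ids, , drop = FALSE])
  rows <- list()
  for (i in seq_len(nrow(off))) {
    for (par in c(off$sire[i], off$dam[i])) {
      if (!off$id[i] %in% colnames(dm) || !par %in% colnames(dm)) next
      o <- dm[, off$id[i]]; p <- dm[, par]
      ok <- !is.na(o) & !is.na(p)
      opp <- sum((o == 0L & p == 2L) | (o == 2L & p == 0L), na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        offspring = off$id[i], parent = par, n_compared = sum(ok),
        rate = if (sum(ok) > 0) opp / sum(ok) else NA_real_)
    }
  }
  if (length(rows) == 0L) return(empty)
  res <- do.call(rbind, rows)
  med <- median(res$rate, na.rm = TRUE)
  res$flagged <- !is.na(res$rate) & res$rate > multiple * med
  res
}
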