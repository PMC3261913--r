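# P(offspring locus genotype = 0,1,2 | parent locus genotypes gs, gd):
# each parent transmits a B allele with probability g/2.
.locus_child_dist <- function(gs, gd) {
  ps <- gs / 2; pd <- gd / 2
  c((1 - ps) * (1 - pd), ps * (1 - pd) + (1 - ps) * pd, ps * pd)
}

# two-locus diploid splits of a 0..4 dosage
.dosage_splits <- function(d) {
  g1 <- max(0L, d - 2L):min(2L, d)
  cbind(g1 = g1, g2 = d - g1)
}

#' Resolve an MSV-5 dosage marker into two locus genotypes within a family
#'
#' An MSV-5 assay reads the summed B-allele count of two duplicated loci.
#' Within a full-sib family the two-locus parental genotypes can be
#' recovered from the offspring dosage segregation: all parental two-locus
#' configurations consistent with each parent's dosage are enumerated (up
#' to the joint locus-relabelling symmetry, which is unidentifiable) and
#' scored by the multinomial likelihood of the offspring dosage counts
#' under Mendelian segregation with the two loci unlinked (they lie on
#' different, homeologous chromosomes).  The maximum-likelihood
#' configuration determines each individual's two diploid locus genotypes;
#' where a dosage is compatible with several locus splits, or where
#' configurations within `delta` log10-likelihood of the best disagree, the
#' affected individuals are set missing rather than guessed.
#'
#' @param dosages named integer vector of called dosages (0..4, NA allowed)
#'   for one MSV-5 marker; must include both parents.
#' @param sire_id,dam_id parent ids.
#' @param offspring_ids offspring ids (>= 4 called offspring required).
#' @param delta log10-likelihood window within which configurations are
#'   treated as tied.
#' @return list with `locus1`, `locus2` (named 0/1/2 genotype vectors over
#'   parents + offspring, NA = missing/ambiguous), `configs` (scored
#'   configuration table) and `status` (`"ok"` or `"segregation_fail"`).
#' @export
resolve_msv5 <- function(dosages, sire_id, dam_id, offspring_ids,
                         delta = 2) {
  ds <- dosages[[sire_id]]; dd <- dosages[[dam_id]]
  if (is.na(ds) || is.na(dd))
    .tm_stop("both parents must have called dosages")
  kids <- offspring_ids[!is.na(dosages[offspring_ids])]
  if (length(kids) < 4L)
    .tm_stop("need >= 4 called offspring (have %d)", length(kids))
  kd <- dosages[kids]
  counts <- tabulate(kd + 1L, nbins = 5L)

  ss <- .dosage_splits(ds); dsp <- .dosage_splits(dd)
  configs <- list()
  for (i in seq_len(nrow(ss))) for (j in seq_len(nrow(dsp))) {
    s1 <- ss[i, 1]; s2 <- ss[i, 2]; d1 <- dsp[j, 1]; d2 <- dsp[j, 2]
    # canonical under joint locus swap: sire (s1 >= s2), dam breaks sire ties
    if (s1 < s2 || (s1 == s2 && d1 < d2)) next
    p1 <- .locus_child_dist(s1, d1)
    p2 <- .locus_child_dist(s2, d2)
    pd <- convolve(p1, rev(p2), type = "open")  # dosage 0..4 distribution
    pd[pd < 1e-12] <- 0  # clear FFT noise so impossible dosages stay impossible
    ll <- sum(counts * log10(pmax(pd, 1e-300)))
    if (any(counts > 0 & pd <= 0)) ll <- -Inf
    configs[[length(configs) + 1L]] <- list(
      s1 = s1, s2 = s2, d1 = d1, d2 = d2, ll = ll, p1 = p1, p2 = p2)
  }
  lls <- vapply(configs, `[[`, 0, "ll")
  tab <- data.frame(
    sire_locus1 = vapply(configs, `[[`, 0, "s1"),
    sire_locus2 = vapply(configs, `[[`, 0, "s2"),
    dam_locus1 = vapply(configs, `[[`, 0, "d1"),
    dam_locus2 = vapply(configs, `[[`, 0, "d2"),
    log10_lik = lls)
  ids <- c(sire_id, dam_id, kids)
  l1 <- setNames(rep(NA_integer_, length(ids)), ids)
  l2 <- l1
  if (all(!is.finite(lls)))
    return(list(locus1 = l1, locus2 = l2, configs = tab,
                status = "segregation_fail"))

  # per-individual assignments implied by one configuration: unique locus
  # split given the dosage, else NA
  assign_for <- function(cf) {
    a1 <- setNames(c(cf$s1, cf$d1, rep(NA_integer_, length(kids))), ids)
    a2 <- setNames(c(cf$s2, cf$d2, rep(NA_integer_, length(kids))), ids)
    for (o in kids) {
      d <- dosages[[o]]
      sp <- .dosage_splits(d)
      pr <- cf$p1[sp[, 1] + 1L] * cf$p2[sp[, 2] + 1L]
      pos <- which(pr > 0)
      if (length(pos) == 1L) {
        a1[[o]] <- sp[pos, 1]; a2[[o]] <- sp[pos, 2]
      }
    }
    list(a1, a2)
  }
  best <- which.max(lls)
  tied <- which(lls >= lls[best] - delta)
  asg <- lapply(configs[tied], assign_for)
  l1 <- asg[[1]][[1]]; l2 <- asg[[1]][[2]]
  if (length(asg) > 1L) {
    for (k in seq_along(asg)[-1]) {
      conflict <- !(is.na(l1) & is.na(asg[[k]][[1]])) &
        (is.na(l1) | is.na(asg[[k]][[1]]) |
           l1 != asg[[k]][[1]] | l2 != asg[[k]][[2]])
      l1[conflict] <- NA_integer_; l2[conflict] <- NA_integer_
    }
  }
  # `complete`: every called individual received a unique assignment.  In
  # incomplete families the retained offspring are selected by their dosage
  # (only unambiguous splits survive), which correlates the two locus
  # columns and would fake linkage between a locus and its homeolog's
  # neighbourhood; linkage analysis should use complete families only.
  list(locus1 = l1, locus2 = l2, configs = tab, status = "ok",
       complete = !anyNA(l1))
}

#' Per-chromosome MSV percentage summary
#'
#' @param classifications classification table (`marker_id`, `klass`).
#' @param chrom_assign named character vector mapping marker ids to
#'   chromosomes (e.g. linkage-group labels).
#' @return data frame `chromosome`, `n_markers`, `n_msv`, `pct_msv`, with a
#'   final `ALL` row giving the genome-wide share.
#' @export
msv_summary <- function(classifications, chrom_assign) {
  cl <- classifications[classifications$marker_id %in% names(chrom_assign), ,
                        drop = FALSE]
  chrom <- chrom_assign[cl$marker_id]
  is_msv <- cl$klass %in% c("MSV3", "MSV5")
  tot <- table(chrom)
  msv <- tapply(is_msv, chrom, sum)
  out <- data.frame(chromosome = names(tot), n_markers = as.integer(tot),
                    n_msv = as.integer(msv[names(tot)]))
  out <- rbind(out, data.frame(chromosome = "ALL",
                               n_markers = sum(out$n_markers),
                               n_msv = sum(out$n_msv)))
  out$pct_msv <- ifelse(out$n_markers > 0,
                        100 * out$n_msv / out$n_markers, NA_real_)
  rownames(out) <- NULL
  out
}
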