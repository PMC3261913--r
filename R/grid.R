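# Deduce the allele transmitted by the focal parent.
# gp: focal parent diploid genotype (0/1/2), gq: other parent, go: offspring.
# A cell is informative only where the focal parent is heterozygous and the
# transmitted allele is uniquely determined given the other parent's
# possible gametes (unknown other parent allows both gametes).
.deduce_cells <- function(gp, gq, go) {
  n <- length(gp)
  lo <- ifelse(is.na(gq), 0L, (gq == 2L) * 1L)
  hi <- ifelse(is.na(gq), 1L, (gq >= 1L) * 1L)
  t0 <- !is.na(go) & (go - 0L) >= lo & (go - 0L) <= hi
  t1 <- !is.na(go) & (go - 1L) >= lo & (go - 1L) <= hi
  val <- rep(NA_integer_, n)
  inf <- !is.na(gp) & gp == 1L & !is.na(go)
  val[inf & t0 & !t1] <- 0L
  val[inf & t1 & !t0] <- 1L
  impossible <- inf & !t0 & !t1
  # a deduction through a heterozygous (or unknown) other parent succeeds
  # only for specific other-parent transmissions: such cells are a selected
  # sample, and selecting at BOTH markers of a pair (the other parent's
  # transmissions being linked) biases recombination estimates, so the
  # flag is carried along and pair estimators drop doubly-conditional cells
  conditional <- !is.na(val) & (is.na(gq) | gq == 1L)
  list(value = val, impossible = impossible, conditional = conditional)
}

# genotype matrix for grid construction: SNP dosage as-is; MSV3 reduced to
# its segregating locus by subtracting the fixed paralog's dosage offset
.diploid_genotypes <- function(calls, classifications) {
  dm <- .calls_matrix(calls)
  cl <- classifications[match(rownames(dm), classifications$marker_id), ]
  keep <- cl$klass %in% c("SNP", "MSV3")
  dm <- dm[keep, , drop = FALSE]
  cl <- cl[keep, , drop = FALSE]
  off <- ifelse(cl$klass == "MSV3", cl$msv3_offset, 0L)
  g <- dm - off
  g[g < 0L | g > 2L] <- NA_integer_
  g
}

# phase-folded per-parent recombination signature of one grid column
# against a set of reference columns, used to harmonize MSV-5 locus labels
# across families (the within-family labelling is arbitrary).
.fold_signature <- function(a, ref_cells, pidx, min_n = 5L) {
  vapply(seq_len(ncol(ref_cells)), function(j) {
    b <- ref_cells[, j]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_n) return(NA_real_)
    k <- tapply(a[ok] != b[ok], pidx[ok], sum)
    n <- tapply(rep(1L, sum(ok)), pidx[ok], sum)
    sum(pmin(k, n - k)) / sum(n)
  }, 0)
}

#' Build the meiosis grid
#'
#' Constructs the per-meiosis transmitted-allele matrix that all linkage
#' estimation runs on.  Each offspring contributes two meioses (one per
#' parent); each QC-passing SNP or MSV-3 marker contributes one column
#' (MSV-3 dosages are reduced to the segregating locus), and each resolved
#' MSV-5 contributes two pseudo-marker columns (`<id>_L1`, `<id>_L2`), one
#' per duplicated locus.  Because the locus labelling of an MSV-5 is
#' arbitrary within each family, per-family label orientations are
#' harmonized by matching phase-folded recombination signatures against the
#' SNP columns before pooling.  Mendelian-impossible cells are set unknown
#' and counted.
#'
#' @param calls long call table of QC-passing markers.
#' @param classifications classification table (`marker_id`, `klass`,
#'   `msv3_offset`).
#' @param pedigree pedigree table.
#' @param msv5_resolutions optional nested list
#'   `res[[marker_id]][[family]]` of [resolve_msv5()] results.
#' @return an object of class `tm_grid`: list with `cells` (meioses x
#'   markers matrix of 0/1/NA), `meioses` (data frame `id`, `parent`,
#'   `offspring`, `family`, `parent_sex`) and `n_impossible`.
#' @export
build_meiosis_grid <- function(calls, classifications, pedigree,
                               msv5_resolutions = NULL) {
  off <- pedigree[pedigree$sire != "0", , drop = FALSE]
  meioses <- rbind(
    data.frame(id = paste(off$sire, off$id, sep = ":"), parent = off$sire,
               offspring = off$id, family = off$family, parent_sex = "M"),
    data.frame(id = paste(off$dam, off$id, sep = ":"), parent = off$dam,
               offspring = off$id, family = off$family, parent_sex = "F"))
  meioses <- meioses[order(meioses$id), ]
  rownames(meioses) <- NULL

  g <- .diploid_genotypes(calls, classifications)
  nm <- nrow(meioses)
  n_imp <- 0L
  samp <- colnames(g)
  gidx <- function(ids) {
    j <- match(ids, samp)
    function(m) ifelse(is.na(j), NA_integer_, g[m, j])
  }
  go_f <- gidx(meioses$offspring)
  gp_f <- gidx(meioses$parent)
  other <- ifelse(meioses$parent_sex == "M",
                  off$dam[match(meioses$offspring, off$id)],
                  off$sire[match(meioses$offspring, off$id)])
  gq_f <- gidx(other)

  base_cols <- rownames(g)
  cells <- matrix(NA_integer_, nm, length(base_cols),
                  dimnames = list(meioses$id, base_cols))
  conditional <- matrix(FALSE, nm, length(base_cols),
                        dimnames = list(meioses$id, base_cols))
  for (m in base_cols) {
    dd <- .deduce_cells(gp_f(m), gq_f(m), go_f(m))
    cells[, m] <- dd$value
    conditional[, m] <- dd$conditional
    n_imp <- n_imp + sum(dd$impossible)
  }

  if (!is.null(msv5_resolutions) && length(msv5_resolutions) > 0L) {
    snp_cols <- cells[, classifications$marker_id[
      classifications$klass == "SNP"] |> intersect(base_cols), drop = FALSE]
    pidx <- meioses$parent
    fam_of <- split(seq_len(nm), meioses$family)
    for (mid in names(msv5_resolutions)) {
      col1 <- rep(NA_integer_, nm); col2 <- rep(NA_integer_, nm)
      cnd1 <- rep(FALSE, nm); cnd2 <- rep(FALSE, nm)
      fams <- msv5_resolutions[[mid]]
      # per-family transmitted alleles for each locus
      fam_cols <- list()
      for (fam in names(fams)) {
        res <- fams[[fam]]
        if (is.null(res) || res$status != "ok" || !isTRUE(res$complete)) next
        rows <- fam_of[[fam]]
        if (is.null(rows)) next
        gmap <- function(gen, ids) unname(gen[ids])
        for (loc in 1:2) {
          gen <- res[[paste0("locus", loc)]]
          gp <- gmap(gen, meioses$parent[rows])
          gq <- gmap(gen, other[rows])
          go <- gmap(gen, meioses$offspring[rows])
          dd <- .deduce_cells(gp, gq, go)
          fam_cols[[fam]][[loc]] <- dd$value
          fam_cols[[fam]][[loc + 2L]] <- dd$conditional
          n_imp <- n_imp + sum(dd$impossible)
        }
      }
      if (length(fam_cols) == 0L) next
      # greedy harmonization: families join the pooled columns in order of
      # informativeness, each oriented to match the pool's phase-folded
      # recombination signature against the SNP columns
      inf_n <- vapply(fam_cols, function(z)
        sum(!is.na(z[[1]])) + sum(!is.na(z[[2]])), 0)
      fam_order <- names(fam_cols)[order(-inf_n, names(fam_cols))]
      first <- TRUE
      for (fam in fam_order) {
        rows <- fam_of[[fam]]
        a1 <- rep(NA_integer_, nm); a1[rows] <- fam_cols[[fam]][[1]]
        a2 <- rep(NA_integer_, nm); a2[rows] <- fam_cols[[fam]][[2]]
        swap <- FALSE
        if (!first) {
          s1 <- .fold_signature(col1, snp_cols, pidx)
          s2 <- .fold_signature(col2, snp_cols, pidx)
          t1 <- .fold_signature(a1, snp_cols, pidx)
          t2 <- .fold_signature(a2, snp_cols, pidx)
          keep_d <- mean(abs(t1 - s1), na.rm = TRUE) +
            mean(abs(t2 - s2), na.rm = TRUE)
          swap_d <- mean(abs(t1 - s2), na.rm = TRUE) +
            mean(abs(t2 - s1), na.rm = TRUE)
          swap <- !is.na(keep_d) && !is.na(swap_d) && swap_d < keep_d
        }
        first <- FALSE
        c1v <- rep(FALSE, nm); c1v[rows] <- fam_cols[[fam]][[3L]]
        c2v <- rep(FALSE, nm); c2v[rows] <- fam_cols[[fam]][[4L]]
        if (swap) {
          tmp <- a1; a1 <- a2; a2 <- tmp
          tmp <- c1v; c1v <- c2v; c2v <- tmp
        }
        col1[rows] <- a1[rows]; col2[rows] <- a2[rows]
        cnd1[rows] <- c1v[rows]; cnd2[rows] <- c2v[rows]
      }
      add <- cbind(col1, col2)
      colnames(add) <- paste0(mid, c("_L1", "_L2"))
      cells <- cbind(cells, add)
      addc <- cbind(cnd1, cnd2)
      colnames(addc) <- colnames(add)
      conditional <- cbind(conditional, addc)
    }
  }
  structure(list(cells = cells, conditional = conditional,
                 meioses = meioses, n_impossible = n_imp),
            class = "tm_grid")
}

#' Resolve every MSV-5 marker in every full-sib family
#'
#' @param calls long call table.
#' @param classifications classification table.
#' @param pedigree pedigree table.
#' @param min_offspring minimum called offspring per family.
#' @param delta tie window passed to [resolve_msv5()].
#' @return nested list `res[[marker_id]][[family]]`.
#' @export
resolve_msv5_all <- function(calls, classifications, pedigree,
                             min_offspring = 4L, delta = 2) {
  msv5 <- classifications$marker_id[classifications$klass == "MSV5"]
  dm <- .calls_matrix(calls)
  msv5 <- intersect(msv5, rownames(dm))
  off <- pedigree[pedigree$sire != "0", , drop = FALSE]
  fams <- unique(off[, c("family", "sire", "dam")])
  out <- list()
  for (m in msv5) {
    for (i in seq_len(nrow(fams))) {
      fam <- fams$family[i]
      kids <- off$id[off$family == fam]
      ids <- c(fams$sire[i], fams$dam[i], kids)
      if (!all(c(fams$sire[i], fams$dam[i]) %in% colnames(dm))) next
      d <- setNames(dm[m, ids[ids %in% colnames(dm)]],
                    ids[ids %in% colnames(dm)])
      if (is.na(d[[fams$sire[i]]]) || is.na(d[[fams$dam[i]]])) next
      if (sum(!is.na(d[kids[kids %in% names(d)]])) < min_offspring) next
      out[[m]][[fam]] <- resolve_msv5(d, fams$sire[i], fams$dam[i],
                                      kids[kids %in% names(d)], delta = delta)
    }
  }
  out
}
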