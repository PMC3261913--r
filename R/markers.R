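#' Simulate marker truth for a genome model
#'
#' Draws marker classes (SNP / MSV-3 / MSV-5 / monomorphic), positions and
#' allele frequencies.  MSVs are placed on homeologous arm pairs: the
#' assayed locus goes on one member of a randomly chosen pair and the
#' paralogous locus at the corresponding relative position (plus a small
#' jitter) on the partner arm, so MSVs concentrate on duplicated regions as
#' they do in a pseudo-tetraploid genome.  Single-locus markers are placed
#' uniformly, chromosomes weighted by female map length.
#'
#' @param genome a `tm_genome`.
#' @param n_markers total marker count.
#' @param msv_fraction probability that a marker is an MSV (requires
#'   homeolog pairs when > 0).
#' @param msv5_fraction probability that an MSV segregates in both paralogs
#'   (MSV-5 rather than MSV-3).
#' @param mono_fraction probability that a non-MSV marker is monomorphic.
#' @param maf_range allele-frequency range for segregating loci.
#' @param marker_grid if `TRUE`, single-locus markers on each chromosome
#'   are re-spaced onto an even grid (emulating a well-spaced framework
#'   panel); MSV positions are left as drawn.
#' @return data frame of marker truth, one row per marker, ordered by
#'   chromosome and position.
#' @export
sim_markers <- function(genome, n_markers, msv_fraction = 0.21,
                        msv5_fraction = 0.5, mono_fraction = 0.02,
                        maf_range = c(0.25, 0.75), marker_grid = FALSE) {
  if (n_markers == 0L) {
    return(data.frame(id = character(), chromosome = character(),
                      u = numeric(), arm = character(), klass = character(),
                      paralog_arm = character(), paralog_u = numeric(),
                      allele_freq_locus1 = numeric(),
                      allele_freq_locus2 = numeric(), pos_female = numeric(),
                      pos_male = numeric(), paralog_pos = numeric()))
  }
  pairs <- genome$homeolog_pairs
  if (msv_fraction > 0 && nrow(pairs) == 0L)
    .tm_stop("msv_fraction > 0 requires homeolog pairs in the genome model")
  specs <- genome$chromosomes
  wlen <- vapply(specs, `[[`, 0, "female_length")
  if (all(wlen == 0)) wlen <- rep(1, length(wlen))

  n <- n_markers
  is_msv <- runif(n) < msv_fraction
  is_msv5 <- is_msv & runif(n) < msv5_fraction
  klass <- ifelse(is_msv, ifelse(is_msv5, "MSV5", "MSV3"),
                  ifelse(runif(n) < mono_fraction, "MONO", "SNP"))

  chrom <- character(n); u <- numeric(n)
  arm <- character(n); paralog_arm <- rep(NA_character_, n)
  paralog_u <- rep(NA_real_, n)
  f1 <- runif(n, maf_range[1], maf_range[2])
  f2 <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    if (is_msv[i]) {
      p <- pairs[sample.int(nrow(pairs), 1L), ]
      arms <- c(p$arm_a, p$arm_b)
      if (runif(1) < 0.5) arms <- rev(arms)
      a1 <- .split_arm(genome, arms[1]); a2 <- .split_arm(genome, arms[2])
      iv1 <- .arm_interval(specs[[a1$chrom]], a1$label)
      iv2 <- .arm_interval(specs[[a2$chrom]], a2$label)
      rel <- runif(1)
      rel2 <- min(max(rel + runif(1, -0.05, 0.05), 0), 1 - 1e-9)
      chrom[i] <- a1$chrom
      u[i] <- iv1[1] + rel * (iv1[2] - iv1[1]) * (1 - 1e-9)
      arm[i] <- arms[1]
      paralog_arm[i] <- arms[2]
      paralog_u[i] <- iv2[1] + rel2 * (iv2[2] - iv2[1])
      f2[i] <- if (klass[i] == "MSV5") runif(1, maf_range[1], maf_range[2])
               else sample(c(0, 1), 1L)
    } else {
      ci <- sample.int(length(specs), 1L, prob = wlen)
      chrom[i] <- names(specs)[ci]
      u[i] <- runif(1)
      arm[i] <- .arm_of(specs[[ci]], u[i])
      if (klass[i] == "MONO") f1[i] <- sample(c(0, 1), 1L)
    }
  }

  if (marker_grid) {
    for (cc in unique(chrom)) {
      sel <- which(chrom == cc & !is_msv)
      if (length(sel) > 0L)
        u[sel[order(u[sel])]] <- (seq_along(sel) - 0.5) / length(sel)
    }
  }
  ord <- order(chrom, u)
  mk <- data.frame(
    id = sprintf("M%05d", seq_len(n)), chromosome = chrom[ord],
    u = u[ord], arm = arm[ord], klass = klass[ord],
    paralog_arm = paralog_arm[ord], paralog_u = paralog_u[ord],
    allele_freq_locus1 = f1[ord], allele_freq_locus2 = f2[ord])
  mk$pos_female <- vapply(seq_len(n), function(i)
    .map_pos(mk$u[i], specs[[mk$chromosome[i]]], "F"), 0)
  mk$pos_male <- vapply(seq_len(n), function(i)
    .map_pos(mk$u[i], specs[[mk$chromosome[i]]], "M"), 0)
  mk$paralog_pos <- NA_real_
  has_par <- !is.na(mk$paralog_arm)
  mk$paralog_pos[has_par] <- vapply(which(has_par), function(i) {
    a <- .split_arm(genome, mk$paralog_arm[i])
    .map_pos(mk$paralog_u[i], specs[[a$chrom]], "F")
  }, 0)
  rownames(mk) <- NULL
  mk
}

# locus table: every segregating position in the genome.  locus 1 is the
# assayed position; MSVs add locus 2 on the paralog arm.
.build_loci <- function(genome, markers) {
  l1 <- data.frame(locus_id = markers$id, marker_id = markers$id,
                   locus = rep(1L, nrow(markers)),
                   chrom = markers$chromosome, u = markers$u,
                   freq = markers$allele_freq_locus1)
  msv <- markers[markers$klass %in% c("MSV3", "MSV5"), ]
  if (nrow(msv) > 0) {
    pchrom <- vapply(msv$paralog_arm, function(a)
      .split_arm(genome, a)$chrom, "")
    l2 <- data.frame(locus_id = paste0(msv$id, "_L2"), marker_id = msv$id,
                     locus = 2L, chrom = pchrom, u = msv$paralog_u,
                     freq = msv$allele_freq_locus2)
    l1 <- rbind(l1, l2)
  }
  l1[order(l1$chrom, l1$u), , drop = FALSE]
}
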