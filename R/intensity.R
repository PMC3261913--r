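# canonical theta cluster centers for a marker class / dosage
.theta_center <- function(dosage, klass) {
  mx <- ifelse(klass == "SNP" | klass == "MONO", 2L, 4L)
  if (any(dosage < 0 | dosage > mx, na.rm = TRUE))
    .tm_stop("dosage out of range for class")
  dosage / mx
}

# vectorized theta + R simulation; dosage NA propagates to theta NA
.dosage_to_theta <- function(dosage, klass, sd_snp, sd_msv) {
  ctr <- .theta_center(dosage, klass)
  noise <- ifelse(klass %in% c("MSV3", "MSV5"), sd_msv, sd_snp)
  th <- ctr + rnorm(length(ctr), 0, noise)
  pmin(pmax(th, 0), 1)
}

#' Convert a dosage genotype into a simulated intensity record
#'
#' Emulates the bead-array signal summary: the allelic-ratio coordinate
#' theta is the class-specific cluster center (dosage/2 for diploid SNPs,
#' dosage/4 for MSVs) plus Gaussian noise, clamped to \[0, 1\]; the total
#' intensity R is log-normal and independent of theta.  MSV cluster noise is
#' smaller than SNP noise by default, reflecting the tighter cluster spacing
#' of mixed allelic ratios.
#'
#' @param dosage B-allele count: 0..2 for `SNP`/`MONO`, 0..4 for
#'   `MSV3`/`MSV5`.
#' @param klass marker class.
#' @param noise named or positional pair `c(snp, msv)` of cluster standard
#'   deviations.
#' @param r_meanlog,r_sdlog log-normal parameters of the total intensity.
#' @return list with `theta` and `R`.
#' @export
genotype_to_intensity <- function(dosage, klass, noise = c(0.04, 0.02),
                                  r_meanlog = log(1000), r_sdlog = 0.3) {
  if (!klass %in% c("SNP", "MONO", "MSV3", "MSV5"))
    .tm_stop("unknown marker class '%s'", klass)
  th <- .dosage_to_theta(dosage, klass, noise[1], noise[2])
  list(theta = th, R = rlnorm(length(th), r_meanlog, r_sdlog))
}
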