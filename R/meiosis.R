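# Crossover positions (axis coordinates) for n meioses on one chromosome.
# Counts are Poisson(map_length/100) on the sex-specific length (no
# interference, Haldane-consistent); positions follow the sex-specific
# density: uniform in females, uniform + triangular telomere kernels in
# males.  Returns a list of numeric vectors.
.sim_crossovers <- function(n, spec, sex) {
  len <- if (sex == "F") spec$female_length else spec$male_length
  counts <- rpois(n, len / 100)
  total <- sum(counts)
  if (total == 0L) return(rep(list(numeric()), n))
  if (sex == "F") {
    pos <- runif(total)
  } else {
    mix <- .male_mix(spec)
    comp <- sample.int(3L, total, replace = TRUE, prob = mix)
    pos <- numeric(total)
    wk <- spec$kernel_width
    nu <- sum(comp == 1L); nl <- sum(comp == 2L); nr <- sum(comp == 3L)
    if (nu > 0) pos[comp == 1L] <- runif(nu)
    if (nl > 0) pos[comp == 2L] <- wk * (1 - sqrt(runif(nl)))
    if (nr > 0) pos[comp == 3L] <- 1 - wk * (1 - sqrt(runif(nr)))
  }
  split(pos, rep(seq_len(n), counts))[as.character(seq_len(n))] |>
    lapply(function(x) if (is.null(x)) numeric() else sort(x))
}

# Grandparental-origin matrix (n meioses x length(marker_u)), values 1/2.
# Each meiosis starts from a random haplotype and switches at crossovers.
.meiosis_origins <- function(xovers, marker_u, starts = NULL) {
  n <- length(xovers)
  L <- length(marker_u)
  if (is.null(starts)) starts <- sample.int(2L, n, replace = TRUE)
  par <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    xo <- xovers[[i]]
    if (length(xo) > 0L)
      par[i, ] <- findInterval(marker_u, xo)
  }
  (starts - 1L + par) %% 2L + 1L
}

#' Simulate one meiosis of a phased parent
#'
#' Draws a crossover count from Poisson(map length / 100) on the parent
#' sex's map, places crossovers according to the sex-specific density
#' (uniform in females; uniform plus telomeric kernels in males, with a
#' suppressed end receiving none) and returns a legal recombinant gamete of
#' the two parental haplotypes.
#'
#' @param parent_haplotypes 2 x L integer matrix (alleles 0/1, no missing
#'   values) of the parent's phased haplotypes at the marker positions.
#' @param sex `"F"` or `"M"`.
#' @param spec a [chromosome_spec()].
#' @param marker_u axis positions (fractions in \[0, 1\]) of the L markers.
#' @return list with `gamete` (length-L 0/1 vector), `crossovers_cM`
#'   (positions on the sex-specific map, in cM) and `crossovers_u`
#'   (axis positions).
#' @export
simulate_meiosis <- function(parent_haplotypes, sex, spec, marker_u) {
  if (!is.matrix(parent_haplotypes) || nrow(parent_haplotypes) != 2L ||
      anyNA(parent_haplotypes))
    .tm_stop("parent must be phased: a 2 x L matrix of 0/1 alleles without NAs")
  if (ncol(parent_haplotypes) != length(marker_u))
    .tm_stop("marker_u length must match haplotype columns")
  xo <- .sim_crossovers(1L, spec, sex)
  org <- .meiosis_origins(xo, marker_u)
  gam <- parent_haplotypes[cbind(org[1L, ], seq_along(marker_u))]
  list(gamete = as.integer(gam),
       crossovers_cM = .map_pos(xo[[1L]], spec, sex),
       crossovers_u = xo[[1L]])
}
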