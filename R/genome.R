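#' Define one chromosome of the genome model
#'
#' A chromosome is parameterized on an abstract axis `u` in \[0, 1\] shared by
#' both sexes.  Female map positions are `u * female_length`; male positions
#' follow the male crossover-density CDF, so a marker's male position is
#' `male_length * F_m(u)`.  The male density is a mixture of a uniform
#' component and triangular kernels at the chromosome ends, emulating the
#' strong telomeric localization of male recombination seen in salmonids;
#' the female density is uniform.
#'
#' @param id chromosome label (e.g. `"ssa01"`).
#' @param female_length,male_length sex-specific map lengths in centiMorgans.
#' @param centromere_fraction position of the centromere as a fraction of the
#'   chromosome axis; also the default arm breakpoint.
#' @param arm_labels labels of the intervals delimited by `breakpoints`
#'   (default `c("p", "q")`).
#' @param breakpoints increasing fractions in (0, 1) splitting the axis into
#'   arms; default is `centromere_fraction`.
#' @param male_telomere_weights two non-negative weights controlling how much
#'   male crossover mass is placed in the left and right telomeric kernels.
#' @param kernel_width width of each triangular end kernel as a fraction of
#'   the axis.
#' @param uniform_weight fraction of male crossovers drawn from the uniform
#'   component (before end suppression).
#' @param suppressed_end `NA`, `"left"` or `"right"`: an end whose telomeric
#'   kernel is forced to zero weight (emulates heterochromatin-suppressed
#'   telomeric recombination).
#' @return an object of class `tm_chromspec`.
#' @export
chromosome_spec <- function(id, female_length, male_length,
                            centromere_fraction = 0.4,
                            arm_labels = c("p", "q"),
                            breakpoints = centromere_fraction,
                            male_telomere_weights = c(1, 1),
                            kernel_width = 0.1,
                            uniform_weight = 0.2,
                            suppressed_end = NA_character_) {
  if (female_length < 0 || male_length < 0)
    .tm_stop("chromosome %s: map lengths must be >= 0", id)
  if (centromere_fraction < 0 || centromere_fraction > 1)
    .tm_stop("chromosome %s: centromere_fraction must be in [0, 1]", id)
  if (any(male_telomere_weights < 0) || length(male_telomere_weights) != 2L)
    .tm_stop("chromosome %s: male_telomere_weights must be two weights >= 0", id)
  if (length(breakpoints) != length(arm_labels) - 1L)
    .tm_stop("chromosome %s: need one more arm label than breakpoints", id)
  if (is.unsorted(breakpoints, strictly = TRUE) ||
      any(breakpoints <= 0) || any(breakpoints >= 1))
    .tm_stop("chromosome %s: breakpoints must be strictly increasing in (0, 1)", id)
  w <- male_telomere_weights
  if (!is.na(suppressed_end)) {
    if (!suppressed_end %in% c("left", "right"))
      .tm_stop("chromosome %s: suppressed_end must be 'left' or 'right'", id)
    w[if (suppressed_end == "left") 1L else 2L] <- 0
  }
  if (male_length > 0 && uniform_weight <= 0 && sum(w) == 0)
    .tm_stop("chromosome %s: male density has no mass (all weights zero)", id)
  structure(list(
    id = as.character(id), female_length = female_length,
    male_length = male_length, centromere_fraction = centromere_fraction,
    arm_labels = arm_labels, breakpoints = breakpoints,
    male_telomere_weights = male_telomere_weights,
    kernel_width = kernel_width, uniform_weight = uniform_weight,
    suppressed_end = suppressed_end
  ), class = "tm_chromspec")
}

# mixture component probabilities of the male crossover density:
# c(uniform, left kernel, right kernel); suppression already applied.
.male_mix <- function(spec) {
  w <- spec$male_telomere_weights
  if (!is.na(spec$suppressed_end))
    w[if (spec$suppressed_end == "left") 1L else 2L] <- 0
  pu <- spec$uniform_weight
  if (sum(w) == 0) return(c(1, 0, 0))
  c(pu, (1 - pu) * w / sum(w))
}

# CDF of the male crossover density at axis positions u
.male_cdf <- function(u, spec) {
  mix <- .male_mix(spec)
  wk <- spec$kernel_width
  fl <- ifelse(u >= wk, 1, pmax(u, 0) * (2 * wk - pmax(u, 0)) / wk^2)
  v <- 1 - u
  fr <- ifelse(v >= wk, 0, 1 - pmax(v, 0) * (2 * wk - pmax(v, 0)) / wk^2)
  mix[1] * u + mix[2] * fl + mix[3] * fr
}

# sex-specific map position (cM) of axis positions u
.map_pos <- function(u, spec, sex) {
  if (sex == "F") u * spec$female_length
  else spec$male_length * .male_cdf(u, spec)
}

#' Build a genome model
#'
#' Assembles chromosomes and homeologous arm pairs into a genome model used
#' by the simulator.  Chromosomes may be given explicitly (a data frame with
#' columns `id`, `female_length`, `male_length` and optionally
#' `centromere_fraction`) or generated from `n_chromosomes` with lengths
#' drawn uniformly from `female_length_range` and male lengths set by
#' `female_male_ratio`.  Homeolog pairs may likewise be explicit (data frame
#' `arm_a`, `arm_b`, `divergence`) or generated as `n_homeolog_pairs` pairs
#' joining the q arm of one chromosome to the p arm of the next at the given
#' `divergence` (substitutions/site between paralogous flanking sequences).
#'
#' @param config a list of settings; unknown keys are rejected.  See
#'   Details of [sim_config()] for the full set.
#' @return an object of class `tm_genome`: a list with elements
#'   `chromosomes` (named list of [chromosome_spec()] objects),
#'   `homeolog_pairs` (data frame) and `global_female_male_ratio`.
#' @export
build_genome <- function(config) {
  cfg <- .tm_merge_config(.genome_defaults(), config, "genome config")
  chroms <- cfg$chromosomes
  if (is.null(chroms)) {
    n <- cfg$n_chromosomes
    lf <- runif(n, cfg$female_length_range[1], cfg$female_length_range[2])
    chroms <- data.frame(
      id = sprintf("chr%02d", seq_len(n)),
      female_length = lf, male_length = lf / cfg$female_male_ratio)
  }
  if (is.null(chroms$centromere_fraction))
    chroms$centromere_fraction <- cfg$centromere_fraction
  specs <- lapply(seq_len(nrow(chroms)), function(i) {
    row <- chroms[i, ]
    supp <- cfg$suppressed_ends[[row$id]] %||% NA_character_
    chromosome_spec(row$id, row$female_length, row$male_length,
                    centromere_fraction = row$centromere_fraction,
                    male_telomere_weights = cfg$male_telomere_weights,
                    kernel_width = cfg$kernel_width,
                    uniform_weight = cfg$uniform_weight,
                    suppressed_end = supp)
  })
  names(specs) <- vapply(specs, `[[`, "", "id")

  pairs <- cfg$homeolog_pairs
  if (is.null(pairs)) {
    np <- cfg$n_homeolog_pairs
    if (np > 0) {
      if (2L * np > length(specs))
        .tm_stop("need %d chromosomes for %d homeolog pairs", 2L * np, np)
      pairs <- data.frame(
        arm_a = paste0(names(specs)[seq(1L, 2L * np, by = 2L)], "q"),
        arm_b = paste0(names(specs)[seq(2L, 2L * np, by = 2L)], "p"),
        divergence = cfg$divergence)
    } else {
      pairs <- data.frame(arm_a = character(), arm_b = character(),
                          divergence = numeric())
    }
  }
  if (is.null(pairs$divergence)) pairs$divergence <- cfg$divergence
  all_arms <- unlist(lapply(specs, function(s) paste0(s$id, s$arm_labels)))
  used <- c(pairs$arm_a, pairs$arm_b)
  bad <- setdiff(used, all_arms)
  if (length(bad) > 0L)
    .tm_stop("homeolog pair references unknown arm(s): %s",
             paste(bad, collapse = ", "))
  if (anyDuplicated(used))
    .tm_stop("arm %s appears in more than one homeolog pair",
             used[duplicated(used)][1])
  if (any(pairs$divergence < 0 | pairs$divergence > 0.5))
    .tm_stop("homeolog divergence must be in [0, 0.5]")

  lf <- sum(vapply(specs, `[[`, 0, "female_length"))
  lm <- sum(vapply(specs, `[[`, 0, "male_length"))
  structure(list(chromosomes = specs, homeolog_pairs = pairs,
                 global_female_male_ratio = if (lm > 0) lf / lm else NA_real_),
            class = "tm_genome")
}

.genome_defaults <- function() list(
  chromosomes = NULL, n_chromosomes = 10L,
  female_length_range = c(50, 135), female_male_ratio = 1.38,
  centromere_fraction = 0.4, homeolog_pairs = NULL, n_homeolog_pairs = 0L,
  divergence = 0.05, male_telomere_weights = c(1, 1), kernel_width = 0.1,
  uniform_weight = 0.2, suppressed_ends = list()
)

# arm membership of axis positions u on a chromosome (half-open intervals,
# a breakpoint belongs to the distal interval)
.arm_of <- function(spec, u) {
  idx <- findInterval(u, c(0, spec$breakpoints, 1), rightmost.closed = TRUE)
  paste0(spec$id, spec$arm_labels[idx])
}

# [start, end) fractions of one arm
.arm_interval <- function(spec, label) {
  k <- match(label, spec$arm_labels)
  if (is.na(k)) .tm_stop("chromosome %s has no arm '%s'", spec$id, label)
  b <- c(0, spec$breakpoints, 1)
  c(b[k], b[k + 1L])
}

.split_arm <- function(genome, arm) {
  ids <- names(genome$chromosomes)
  hit <- ids[vapply(ids, function(i) startsWith(arm, i), TRUE)]
  hit <- hit[which.max(nchar(hit))]
  if (length(hit) == 0L) .tm_stop("arm '%s' matches no chromosome", arm)
  list(chrom = hit, label = substring(arm, nchar(hit) + 1L))
}

#' Sample a half-sib/full-sib pedigree
#'
#' Generates a two-generation pedigree in which each sire is mated to
#' `dams_per_sire` dams and each mating produces `offspring_per_dam`
#' offspring, giving full-sib families nested in paternal half-sib groups --
#' the family structure of typical aquaculture breeding designs.
#'
#' @param config list with `n_sires`, `dams_per_sire`, `offspring_per_dam`
#'   (all >= 1).
#' @return data frame with columns `family`, `id`, `sire`, `dam`, `sex`;
#'   founders carry `sire = dam = "0"`.
#' @export
sample_pedigree <- function(config) {
  cfg <- .tm_merge_config(list(n_sires = 2L, dams_per_sire = 2L,
                               offspring_per_dam = 10L),
                          config[intersect(names(config),
                                           c("n_sires", "dams_per_sire",
                                             "offspring_per_dam"))],
                          "pedigree config")
  ns <- cfg$n_sires; nd <- cfg$dams_per_sire; no <- cfg$offspring_per_dam
  if (ns < 1 || nd < 1 || no < 1)
    .tm_stop("pedigree design requires n_sires, dams_per_sire, offspring_per_dam >= 1")
  sires <- sprintf("SIRE%03d", seq_len(ns))
  dams <- sprintf("DAM%03d", seq_len(ns * nd))
  fam <- 0L; rows <- list()
  rows[[1]] <- data.frame(family = "0", id = sires, sire = "0", dam = "0",
                          sex = "M")
  rows[[2]] <- data.frame(family = "0", id = dams, sire = "0", dam = "0",
                          sex = "F")
  k <- 0L
  for (s in seq_len(ns)) for (d in seq_len(nd)) {
    fam <- fam + 1L
    ids <- sprintf("IND%05d", k + seq_len(no)); k <- k + no
    rows[[length(rows) + 1L]] <- data.frame(
      family = sprintf("FAM%03d", fam), id = ids,
      sire = sires[s], dam = dams[(s - 1L) * nd + d],
      sex = rep_len(c("M", "F"), no))
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped
}
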