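#' Default simulation configuration
#'
#' Returns the full configuration list for [simulate_dataset()], with any
#' supplied settings overriding the defaults.  Unknown keys are rejected.
#'
#' Defaults emulate the salmon study design at desk scale: the 29
#' chromosomes with the published sex-specific map lengths (see
#' [table1_fixture()]), four strong homeolog pairs
#' (2p-5q, 3q-6p, 4p-8q, 7q-17q) at sequence divergence 0.05, 21% MSV
#' markers, male crossovers concentrated in telomeric kernels, 0.5%
#' genotyping error and 2% missingness.  The pedigree defaults to 10
#' full-sib families (5 sires x 2 dams x 10 offspring); the full study used
#' 143 families and ~3300 fish, which the same generator reproduces by
#' raising the design counts.
#'
#' @param ... named settings overriding the defaults.
#' @return a named list of class `tm_config`.
#' @export
sim_config <- function(...) {
  t1 <- table1_fixture()
  defaults <- list(
    # genome
    chromosomes = data.frame(id = t1$chromosome,
                             female_length = t1$female_cM,
                             male_length = t1$male_cM),
    n_chromosomes = 29L, female_length_range = c(50, 135),
    female_male_ratio = 1.38, centromere_fraction = 0.4,
    homeolog_pairs = data.frame(
      arm_a = c("ssa02p", "ssa03q", "ssa04p", "ssa07q"),
      arm_b = c("ssa05q", "ssa06p", "ssa08q", "ssa17q"),
      divergence = 0.05),
    n_homeolog_pairs = 0L, divergence = 0.05,
    male_telomere_weights = c(1, 1), kernel_width = 0.1,
    uniform_weight = 0.2, suppressed_ends = list(),
    # markers
    n_markers = 300L, msv_fraction = 0.21, msv5_fraction = 0.5,
    mono_fraction = 0.02, maf_range = c(0.25, 0.75), marker_grid = FALSE,
    # "none": founder genotypes drawn from allele frequencies (outbred);
    # "female"/"male": testcross design -- that parent sex is heterozygous
    # (phased 1|0) at every locus and the other homozygous, maximizing
    # informative meioses for parameter-recovery studies
    testcross = "none",
    # pedigree
    n_sires = 5L, dams_per_sire = 2L, offspring_per_dam = 10L,
    # noise model
    error_rate = 0.005, missing_rate = 0.02, sd_snp = 0.04, sd_msv = 0.02,
    r_meanlog = log(1000), r_sdlog = 0.3,
    # sequences
    seq_len = 500L, outgroup_divergence = 0.1, spacer_len = 100L,
    # male-specific cross-pair association (emulated pseudo-linkage)
    pseudolinkage_coupling = 0
  )
  structure(.tm_merge_config(defaults, list(...)), class = "tm_config")
}

.dosage_max <- function(klass) ifelse(klass %in% c("MSV3", "MSV5"), 4L, 2L)

#' Simulate a complete genotyping study
#'
#' Generates a genome model, markers, pedigree, per-meiosis gametes with
#' sex-specific crossover landscapes, true and observed dosage genotypes
#' (with configurable genotyping error and missingness), bead-array style
#' intensity records and flanking/outgroup sequences.  Deterministic given
#' `rng_seed`; when `out_dir` is given, the file set (pedigree TSV, marker
#' truth TSV, intensity TSV, flank and outgroup FASTA) is also written and
#' identical seeds give byte-identical files.
#'
#' @param config a [sim_config()] (or list of overrides passed to it).
#' @param rng_seed integer seed governing all randomness.
#' @param out_dir optional output directory for the file set.
#' @return an object of class `tm_sim`: a list holding the genome, marker
#'   truth, loci, pedigree, haplotypes, per-meiosis gamete and crossover
#'   truth, true and observed dosage matrices, the intensity table and the
#'   sequence set.
#' @export
simulate_dataset <- function(config = sim_config(), rng_seed = 1L,
                             out_dir = NULL) {
  if (!inherits(config, "tm_config")) config <- do.call(sim_config, config)
  set.seed(rng_seed)
  gkeys <- intersect(names(config), names(.genome_defaults()))
  genome <- build_genome(config[gkeys])
  markers <- sim_markers(genome, config$n_markers,
                         msv_fraction = config$msv_fraction,
                         msv5_fraction = config$msv5_fraction,
                         mono_fraction = config$mono_fraction,
                         maf_range = config$maf_range,
                         marker_grid = config$marker_grid)
  loci <- .build_loci(genome, markers)
  ped <- sample_pedigree(config)

  specs <- genome$chromosomes
  loci_by_chrom <- split(seq_len(nrow(loci)), loci$chrom)
  chrom_ids <- names(specs)

  founders <- ped$id[ped$sire == "0"]
  offspring <- ped[ped$sire != "0", , drop = FALSE]
  inds <- c(founders, offspring$id)
  founder_sex <- setNames(ped$sex[match(founders, ped$id)], founders)

  # phased haplotypes: per individual, per chromosome, 2 x L matrix
  haplotypes <- setNames(vector("list", length(inds)), inds)
  for (f in founders) {
    haplotypes[[f]] <- lapply(setNames(chrom_ids, chrom_ids), function(cc) {
      idx <- loci_by_chrom[[cc]]
      L <- length(idx)
      if (is.null(idx) || L == 0L) return(matrix(integer(), 2, 0))
      if (config$testcross != "none") {
        het <- (config$testcross == "female") == (founder_sex[[f]] == "F")
        if (het) rbind(rep(1L, L), rep(0L, L))
        else matrix(0L, 2L, L)
      } else {
        matrix(rbinom(2L * L, 1L, rep(loci$freq[idx], each = 2L)), 2L, L)
      }
    })
  }

  coupling <- config$pseudolinkage_coupling
  pair_mid_locus <- NULL
  if (coupling > 0 && nrow(genome$homeolog_pairs) > 0) {
    # per pair, index (within chromosome locus vector) of the locus closest
    # to each arm's midpoint; pairs without loci on both arms are skipped
    pair_mid_locus <- lapply(seq_len(nrow(genome$homeolog_pairs)), function(i) {
      p <- genome$homeolog_pairs[i, ]
      find_mid <- function(armlab) {
        a <- .split_arm(genome, armlab)
        iv <- .arm_interval(specs[[a$chrom]], a$label)
        idx <- loci_by_chrom[[a$chrom]]
        on_arm <- idx[loci$u[idx] >= iv[1] & loci$u[idx] < iv[2]]
        if (length(on_arm) == 0L) return(NULL)
        best <- on_arm[which.min(abs(loci$u[on_arm] - mean(iv)))]
        list(chrom = a$chrom, col = match(best, idx))
      }
      list(a = find_mid(p$arm_a), b = find_mid(p$arm_b))
    })
  }

  gametes <- list()     # offspring -> parent role -> chrom -> allele vector
  crossovers <- list()  # offspring -> parent role -> chrom -> u positions
  matings <- unique(offspring[, c("sire", "dam")])
  for (mi in seq_len(nrow(matings))) {
    sire <- matings$sire[mi]; dam <- matings$dam[mi]
    kids <- offspring$id[offspring$sire == sire & offspring$dam == dam]
    k <- length(kids)
    for (role in c("sire", "dam")) {
      par_id <- if (role == "sire") sire else dam
      sex <- if (role == "sire") "M" else "F"
      org_by_chrom <- list(); xo_by_chrom <- list()
      for (cc in chrom_ids) {
        idx <- loci_by_chrom[[cc]]
        uu <- if (is.null(idx)) numeric() else loci$u[idx]
        xo <- .sim_crossovers(k, specs[[cc]], sex)
        org_by_chrom[[cc]] <- .meiosis_origins(xo, uu)
        xo_by_chrom[[cc]] <- xo
      }
      if (sex == "M" && !is.null(pair_mid_locus)) {
        for (pm in pair_mid_locus) {
          if (is.null(pm$a) || is.null(pm$b)) next
          oa <- org_by_chrom[[pm$a$chrom]][, pm$a$col]
          ob <- org_by_chrom[[pm$b$chrom]][, pm$b$col]
          force_i <- which(runif(k) < coupling & oa != ob)
          if (length(force_i) > 0L)
            org_by_chrom[[pm$b$chrom]][force_i, ] <-
              3L - org_by_chrom[[pm$b$chrom]][force_i, , drop = FALSE]
        }
      }
      hap <- haplotypes[[par_id]]
      for (j in seq_len(k)) {
        kid <- kids[j]
        gametes[[kid]][[role]] <- lapply(setNames(chrom_ids, chrom_ids),
          function(cc) {
            L <- ncol(hap[[cc]])
            if (L == 0L) return(integer())
            as.integer(hap[[cc]][cbind(org_by_chrom[[cc]][j, ], seq_len(L))])
          })
        crossovers[[kid]][[role]] <- lapply(xo_by_chrom, `[[`, j)
      }
    }
  }
  for (j in seq_len(nrow(offspring))) {
    kid <- offspring$id[j]
    haplotypes[[kid]] <- lapply(setNames(chrom_ids, chrom_ids), function(cc)
      rbind(gametes[[kid]][["sire"]][[cc]], gametes[[kid]][["dam"]][[cc]]))
  }

  # genotype (allele-count) matrix per chromosome, then marker dosages
  geno_by_chrom <- lapply(setNames(chrom_ids, chrom_ids), function(cc) {
    idx <- loci_by_chrom[[cc]]
    if (is.null(idx) || length(idx) == 0L)
      return(matrix(integer(), length(inds), 0,
                    dimnames = list(inds, NULL)))
    m <- matrix(vapply(inds, function(ind)
      as.integer(colSums(haplotypes[[ind]][[cc]])), integer(length(idx))),
      nrow = length(inds), ncol = length(idx), byrow = TRUE,
      dimnames = list(inds, NULL))
    m
  })
  locus_pos <- setNames(
    lapply(seq_len(nrow(loci)), function(i)
      list(chrom = loci$chrom[i],
           col = match(i, loci_by_chrom[[loci$chrom[i]]]))),
    loci$locus_id)

  n_mk <- nrow(markers)
  dosage_true <- matrix(0L, n_mk, length(inds),
                        dimnames = list(markers$id, inds))
  for (i in seq_len(n_mk)) {
    lp <- locus_pos[[markers$id[i]]]
    d <- geno_by_chrom[[lp$chrom]][, lp$col]
    if (markers$klass[i] %in% c("MSV3", "MSV5")) {
      lp2 <- locus_pos[[paste0(markers$id[i], "_L2")]]
      d <- d + geno_by_chrom[[lp2$chrom]][, lp2$col]
    }
    dosage_true[i, ] <- d
  }

  # observed dosages: symmetric +/-1 errors, then missingness
  dosage_obs <- dosage_true
  mx <- .dosage_max(markers$klass)
  ncell <- length(dosage_obs)
  err <- which(runif(ncell) < config$error_rate)
  if (length(err) > 0L) {
    shift <- sample(c(-1L, 1L), length(err), replace = TRUE)
    mxv <- mx[(err - 1L) %% n_mk + 1L]
    dosage_obs[err] <- pmin(pmax(dosage_obs[err] + shift, 0L), mxv)
  }
  miss <- which(runif(ncell) < config$missing_rate)
  dosage_obs[miss] <- NA_integer_

  # intensity table
  theta <- matrix(NA_real_, n_mk, length(inds))
  for (i in seq_len(n_mk)) {
    ok <- !is.na(dosage_obs[i, ])
    theta[i, ok] <- .dosage_to_theta(dosage_obs[i, ok], markers$klass[i],
                                     config$sd_snp, config$sd_msv)
  }
  intensities <- data.frame(
    marker_id = rep(markers$id, times = length(inds)),
    sample_id = rep(inds, each = n_mk),
    theta = as.vector(theta),
    R = rlnorm(n_mk * length(inds), config$r_meanlog, config$r_sdlog))

  sequences <- generate_sequences(genome, markers,
                                  seq_len = config$seq_len,
                                  outgroup_divergence = config$outgroup_divergence,
                                  spacer_len = config$spacer_len)
  markers$outgroup_chrom <- sequences$anchors$outgroup_chrom[
    match(markers$id, sequences$anchors$marker_id)]
  markers$outgroup_pos <- sequences$anchors$outgroup_pos[
    match(markers$id, sequences$anchors$marker_id)]
  markers$flank_seq <- unname(sequences$flanks[markers$id])
  markers$paralog_seq <- unname(sequences$paralogs[markers$id])

  sim <- structure(list(
    genome = genome, markers = markers, loci = loci, pedigree = ped,
    haplotypes = haplotypes, gametes = gametes, crossovers = crossovers,
    dosage_true = dosage_true, dosage_obs = dosage_obs,
    intensities = intensities, sequences = sequences, config = config,
    seed = rng_seed), class = "tm_sim")
  if (!is.null(out_dir)) write_sim_files(sim, out_dir)
  invisible(sim)
}

#' Write the simulated file set
#'
#' @param sim a `tm_sim` object.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_sim_files <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("pedigree.tsv", "marker_truth.tsv",
                                "intensities.tsv", "flanks.fa",
                                "outgroup.fa"))
  names(paths) <- c("pedigree", "truth", "intensities", "flanks", "outgroup")
  .write_tsv(sim$pedigree, paths["pedigree"])
  .write_tsv(sim$markers, paths["truth"])
  .write_tsv(sim$intensities, paths["intensities"])
  .write_fasta(sim$sequences$flanks, paths["flanks"])
  .write_fasta(sim$sequences$outgroup, paths["outgroup"])
  invisible(paths)
}
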