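#' Pipeline configuration
#'
#' Collects every stage threshold with its documented default.  Unknown
#' keys are rejected.  `sim` holds the [sim_config()] of the synthetic
#' dataset the pipeline runs on.
#'
#' @param ... named overrides.
#' @return list of class `tm_pipeconfig`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sim = sim_config(), seed = 1L, out_dir = NULL,
    # calling
    k_max = 5L, center_tol = 0.08, tight_sd = 0.03, call_threshold = 0.95,
    # qc
    call_rate_min = 0.9, mendel_max = 0.02, pedcheck_multiple = 10,
    # grouping
    lod_threshold = 5, max_r = 0.35, use_anchors = TRUE,
    anchors_per_chrom = 2L,
    # ordering / mapping
    lod_margin = 3, expansion_cap = 10, window = 4L, max_span_cM = 10,
    mapfn = "kosambi", min_group_size = 3L,
    # pseudo-linkage
    pseudo_lod_male = 3, pseudo_r_female = 0.4,
    # homeology
    min_evidence = 3L, seed_k = 16L, min_ident = 0.85, min_len = 100L,
    anchor_margin = 0.1, gap_tol = 10000L, place_lod = 3
  )
  cfg <- list(...)
  if (length(cfg) == 1L && is.null(names(cfg)) && is.list(cfg[[1]]))
    cfg <- cfg[[1]]
  structure(.tm_merge_config(defaults, cfg, "pipeline config"),
            class = "tm_pipeconfig")
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Executes simulate -> genotype calling -> QC -> MSV-5 resolution ->
#' meiosis grid -> linkage grouping -> ordering -> double-recombinant
#' correction -> sex-specific maps -> pseudo-linkage scan -> homeology
#' detection -> report.  When `config$out_dir` is set, every stage output
#' is written as a headered TSV carrying the package version, seed and
#' thresholds; identical seeds give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results (invisible when writing to disk): `sim`,
#'   `calls`, `classifications`, `qc`, `grid`, `groups`, `maps`,
#'   `map_summary`, `msv_summary`, `pseudolinkage`, `homeology`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "tm_pipeconfig")) config <- pipeline_config(config)
  out <- config$out_dir
  meta <- list(package = "tetramap",
               version = as.character(packageVersion("tetramap")),
               seed = config$seed, mapfn = config$mapfn,
               lod_threshold = config$lod_threshold,
               min_evidence = config$min_evidence)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      .tm_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    res
  }

  sim <- stage("simulate", simulate_dataset(config$sim, config$seed,
    out_dir = if (is.null(out)) NULL else file.path(out, "sim")))

  cm <- stage("callgt", call_markers(sim$intensities, k_max = config$k_max,
    center_tol = config$center_tol, tight_sd = config$tight_sd,
    call_threshold = config$call_threshold))

  qc <- stage("qc", qc_filter(cm$calls, sim$pedigree, cm$classifications,
    call_rate_min = config$call_rate_min, mendel_max = config$mendel_max))
  calls <- cm$calls[cm$calls$marker_id %in% qc$pass, , drop = FALSE]

  res5 <- stage("msv5", resolve_msv5_all(calls, cm$classifications,
                                         sim$pedigree))
  grid <- stage("grid", build_meiosis_grid(calls, cm$classifications,
                                           sim$pedigree, res5))

  anchors <- NULL
  if (config$use_anchors) {
    snps <- sim$markers[sim$markers$klass == "SNP" &
                          sim$markers$id %in% colnames(grid$cells), ]
    anchors <- unlist(lapply(split(snps, snps$chromosome), function(z)
      setNames(rep(z$chromosome[1], min(nrow(z), config$anchors_per_chrom)),
               head(z$id, config$anchors_per_chrom))))
    names(anchors) <- sub("^.*\\.", "", names(anchors))
  }
  grp <- stage("group", group_markers(grid, anchors,
    lod_threshold = config$lod_threshold, max_r = config$max_r))

  # order + map per linkage group
  maps <- list(); orders <- list(); changes <- list()
  gtab <- grp$groups
  for (g in unique(gtab$group)) {
    mk <- gtab$marker[gtab$group == g]
    mk <- mk[!grepl("_L[12]$", mk)]
    if (length(mk) < config$min_group_size) next
    bo <- stage("order", build_order(grid, mk,
      lod_margin = config$lod_margin, expansion_cap = config$expansion_cap,
      mapfn = config$mapfn))
    ord <- improve_order(bo$order, grid, window = config$window)
    map0 <- estimate_sex_maps(ord, grid, mapfn = config$mapfn)
    cd <- correct_double_recombinants(ord, grid, map0, calls,
                                      max_span_cM = config$max_span_cM)
    grid <- cd$grid; calls <- cd$calls
    changes[[g]] <- cd$changes
    lab <- gtab$anchor_label[gtab$group == g][1]
    key <- if (!is.na(lab)) lab else g
    maps[[key]] <- estimate_sex_maps(ord, grid, mapfn = config$mapfn)
    orders[[key]] <- ord
  }
  map_summary <- summarize_maps(maps)

  chrom_assign <- unlist(lapply(names(maps), function(k)
    setNames(rep(k, nrow(maps[[k]])), maps[[k]]$marker)))
  msum <- msv_summary(cm$classifications, chrom_assign)

  pl <- stage("pseudolinkage", detect_pseudolinkage(grid, grp,
    lod_male_min = config$pseudo_lod_male,
    r_female_min = config$pseudo_r_female))

  # homeology: arm labels from mapped positions + simulator annotations
  ann <- lapply(sim$genome$chromosomes, function(sp)
    list(breakpoints = sp$breakpoints, labels = sp$arm_labels))
  map_all <- do.call(rbind, lapply(names(maps), function(k)
    data.frame(marker = maps[[k]]$marker, chromosome = k,
               pos_female = maps[[k]]$pos_female)))
  homeo <- list(table = assert_homeologies(min_evidence = config$min_evidence))
  if (!is.null(map_all) && nrow(map_all) > 0L) {
    arms <- stage("arm_assign", arm_assign(map_all, ann))
    # flank + paralog records; paralog records carry the truth paralog arm
    # (stand-in for genomic sequence at the duplicated locus)
    seqs <- c(sim$sequences$flanks,
              setNames(sim$sequences$paralogs,
                       paste0(names(sim$sequences$paralogs), "_par")))
    par_arms <- setNames(sim$markers$paralog_arm,
                         paste0(sim$markers$id, "_par"))
    par_arms <- par_arms[!is.na(par_arms)]
    seq_arms <- c(arms, par_arms)
    phits <- stage("paralog_hits", find_paralog_hits(seqs, seq_arms,
      k = config$seed_k, min_ident = config$min_ident,
      min_len = config$min_len))
    ahits <- stage("anchor_hits", map_anchor_hits(
      sim$sequences$flanks[names(sim$sequences$flanks) %in% names(arms)],
      sim$sequences$outgroup, k = config$seed_k,
      min_ident = config$min_ident, min_len = config$min_len,
      margin = config$anchor_margin))
    plc <- stage("msv5_place", place_msv5_loci(grid, arms,
                                               lod_min = config$place_lod))
    homeo <- list(
      paralog_hits = phits, anchor_hits = ahits, placements = plc,
      table = assert_homeologies(msv5_homeologies(plc),
                                 paralog_homeologies(phits),
                                 anchor_homeologies(ahits, arms,
                                                    gap_tol = config$gap_tol),
                                 min_evidence = config$min_evidence))
  }

  rpt <- report(map_summary, homeo$table, msum,
                n_groups = length(unique(gtab$group)))

  result <- list(sim = sim, calls = calls, classifications = cm$classifications,
                 qc = qc, grid = grid, groups = grp, orders = orders,
                 maps = maps, map_summary = map_summary, msv_summary = msum,
                 pseudolinkage = pl, homeology = homeo,
                 corrections = do.call(rbind, changes), report = rpt)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(calls, file.path(out, "calls.tsv"), meta)
    .write_tsv(cm$classifications, file.path(out, "classifications.tsv"), meta)
    .write_tsv(qc$report, file.path(out, "qc_report.tsv"), meta)
    .write_tsv(grp$groups, file.path(out, "groups.tsv"), meta)
    map_out <- do.call(rbind, lapply(names(maps), function(k)
      cbind(chromosome = k, maps[[k]])))
    if (!is.null(map_out))
      .write_tsv(map_out, file.path(out, "map.tsv"), meta)
    .write_tsv(map_summary, file.path(out, "map_summary.tsv"), meta)
    .write_tsv(msum, file.path(out, "msv_summary.tsv"), meta)
    .write_tsv(homeo$table, file.path(out, "homeology.tsv"), meta)
    writeLines(rpt, file.path(out, "report.txt"))
  }
  invisible(result)
}

.fmt_table <- function(df) {
  if (nrow(df) == 0L) return(paste(names(df), collapse = "\t"))
  c(paste(names(df), collapse = "\t"),
    apply(df, 1L, function(z) paste(trimws(z), collapse = "\t")))
}

#' Render the summary report
#'
#' Emits the per-chromosome map summary, the homeology evidence table, the
#' genome-wide MSV share and the linkage-group count as plain-text tables.
#'
#' @param map_summary result of [summarize_maps()].
#' @param homeology_table result of [assert_homeologies()].
#' @param msv_summary result of [msv_summary()].
#' @param n_groups number of linkage groups found.
#' @return character vector of report lines.
#' @export
report <- function(map_summary, homeology_table, msv_summary,
                   n_groups = NA_integer_) {
  gw <- msv_summary$pct_msv[msv_summary$chromosome == "ALL"]
  c("== Linkage map summary ==", .fmt_table(map_summary), "",
    "== Homeologous chromosome regions ==", .fmt_table(homeology_table), "",
    "== MSV share by chromosome ==", .fmt_table(msv_summary), "",
    sprintf("Linkage groups: %s", n_groups),
    sprintf("Genome-wide MSV share: %s%%",
            if (length(gw)) round(gw, 1) else NA))
}
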