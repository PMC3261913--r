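# Per-parent sufficient statistics for a marker pair: number of doubly-
# informative meioses n and mismatch count k under an arbitrary reference
# phase, per parent.  Cells whose deduction was conditional on the other
# parent at BOTH markers are excluded: the other parent\'s transmissions at
# linked markers are correlated, making doubly-conditional cells a biased
# sample of the focal parent\'s recombination events.
.pair_counts <- function(a, b, parent, cond_a = NULL, cond_b = NULL) {
  ok <- !is.na(a) & !is.na(b)
  if (!is.null(cond_a)) ok <- ok & !(cond_a & cond_b)
  if (!any(ok)) return(list(n = integer(), k = integer()))
  p <- parent[ok]
  mism <- a[ok] != b[ok]
  k <- tapply(mism, p, sum)
  n <- tapply(rep(1L, length(p)), p, sum)
  list(n = as.integer(n), k = as.integer(k[names(n)]))
}

# ML recombination fraction with per-parent linkage phase as a hidden
# variable (EM over the two-component phase mixture; both phases have
# prior 1/2).  Treating phase as hidden matters: profiling (phase-folding)
# is badly biased when parents contribute few doubly-informative meioses
# (a single-meiosis parent can never look recombinant under the folded
# count), whereas under the mixture such parents are correctly neutral.
# With known phase the EM degenerates to the recombinant-count fraction.
# The reported LOD is the log10 likelihood ratio against r = 1/2 with the
# phases profiled at the EM optimum, so a fully linked pair of n meioses
# scores n*log10(2).
.rf_ml <- function(n, k, phase_known = FALSE, tol = 1e-10,
                   max_iter = 200L) {
  N <- sum(n)
  if (N == 0L) return(list(r = NA_real_, lod = 0, n = 0L))
  if (phase_known) {
    r <- sum(k) / N
  } else {
    keff <- pmin(k, n - k)
    r <- min(max(sum(keff) / N, 1e-6), 0.499)
    for (it in seq_len(max_iter)) {
      la <- k * log(r) + (n - k) * log(1 - r)
      lb <- (n - k) * log(r) + k * log(1 - r)
      w <- 1 / (1 + exp(lb - la))
      r_new <- sum(w * k + (1 - w) * (n - k)) / N
      r_new <- min(max(r_new, 1e-9), 0.5)
      if (abs(r_new - r) < tol) { r <- r_new; break }
      r <- r_new
    }
  }
  if (r >= 0.5 - 1e-9) return(list(r = 0.5, lod = 0, n = N))
  keff <- if (phase_known) k else pmin(k, n - k)
  rr <- max(r, 1e-12)
  lod <- sum(keff) * log10(rr) + (N - sum(keff)) * log10(1 - rr) -
    N * log10(0.5)
  list(r = r, lod = max(lod, 0), n = N)
}

#' Two-point recombination fraction and LOD for a marker pair
#'
#' Estimates sex-specific and pooled recombination fractions from the
#' meiosis grid.  Parental linkage phase is unknown in a two-generation
#' pedigree and is treated as a hidden variable per parent (EM over the
#' two-phase mixture with prior 1/2); with known phase the estimate is the
#' plain recombinant-count fraction.  LOD is
#' log10 L(r-hat) - log10 L(1/2) with phases profiled at the optimum,
#' hence 0 when r-hat = 1/2 and n * log10(2) for a fully linked pair with
#' n meioses.  Cells deduced through the other parent at both markers are
#' excluded (see [build_meiosis_grid()]).
#'
#' @param grid a `tm_grid`.
#' @param marker_a,marker_b column names in the grid.
#' @return one-row data frame: `marker_a`, `marker_b`, `r_female`,
#'   `r_male`, `r_pooled`, `lod_female`, `lod_male`, `lod_pooled`,
#'   `n_female`, `n_male`.  A sex with no doubly-informative meioses
#'   reports `r = NA`, `lod = 0`.
#' @export
estimate_twopoint <- function(grid, marker_a, marker_b) {
  a <- grid$cells[, marker_a]; b <- grid$cells[, marker_b]
  ca <- grid$conditional[, marker_a]; cb <- grid$conditional[, marker_b]
  sexes <- grid$meioses$parent_sex
  parent <- grid$meioses$parent
  fem <- sexes == "F"
  cf <- .pair_counts(a[fem], b[fem], parent[fem], ca[fem], cb[fem])
  cm <- .pair_counts(a[!fem], b[!fem], parent[!fem], ca[!fem], cb[!fem])
  ef <- .rf_ml(cf$n, cf$k)
  em <- .rf_ml(cm$n, cm$k)
  ep <- .rf_ml(c(cf$n, cm$n), c(cf$k, cm$k))
  data.frame(marker_a = marker_a, marker_b = marker_b,
             r_female = ef$r, r_male = em$r, r_pooled = ep$r,
             lod_female = ef$lod, lod_male = em$lod, lod_pooled = ep$lod,
             n_female = ef$n, n_male = em$n)
}

# memoizing pair-statistics cache over a grid
.tp_cache <- function(grid) {
  env <- new.env(parent = emptyenv())
  function(a, b) {
    key <- if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    got <- env[[key]]
    if (is.null(got)) {
      got <- estimate_twopoint(grid, a, b)
      env[[key]] <- got
    }
    got
  }
}

#' Group markers into linkage groups by two-point LOD
#'
#' Seeds one group per anchor label (markers with a known chromosome
#' assignment), then includes the remaining markers stepwise, most
#' informative first, attaching each to the group of its best-linked
#' placed partner when the pooled LOD reaches `lod_threshold` and the
#' pooled recombination fraction is at most `max_r`.  A marker linking two
#' groups carrying different anchor labels is left unplaced and flagged; a
#' marker linking nothing seeds a new group.  Ties break deterministically
#' on (informativeness descending, marker id ascending).
#'
#' @param grid a `tm_grid`.
#' @param anchors optional named character vector: marker id -> chromosome
#'   label.
#' @param lod_threshold minimum pooled LOD for attachment.
#' @param max_r maximum pooled recombination fraction for attachment.
#' @return list with `groups` (data frame `marker`, `group`, `anchor_label`),
#'   `unplaced` (data frame `marker`, `reason`) and `singletons`.
#' @export
group_markers <- function(grid, anchors = NULL, lod_threshold = 5,
                          max_r = 0.35) {
  markers <- colnames(grid$cells)
  tp <- .tp_cache(grid)
  inf_n <- colSums(!is.na(grid$cells))
  group_of <- setNames(rep(NA_character_, length(markers)), markers)
  label_of_group <- character()
  unplaced <- data.frame(marker = character(), reason = character())

  if (!is.null(anchors) && length(anchors) > 0L) {
    anchors <- anchors[names(anchors) %in% markers]
    for (lab in unique(anchors)) {
      gid <- paste0("LG_", lab)
      group_of[names(anchors)[anchors == lab]] <- gid
      label_of_group[gid] <- lab
    }
  }
  todo <- markers[is.na(group_of)]
  todo <- todo[order(-inf_n[todo], todo)]
  next_gid <- 1L
  for (m in todo) {
    placed <- names(group_of)[!is.na(group_of)]
    best <- data.frame()
    if (length(placed) > 0L) {
      res <- do.call(rbind, lapply(placed, function(p) tp(m, p)))
      qual <- !is.na(res$r_pooled) & res$r_pooled <= max_r &
        res$lod_pooled >= lod_threshold
      best <- res[qual, , drop = FALSE]
    }
    if (nrow(best) > 0L) {
      partner <- ifelse(best$marker_a == m, best$marker_b, best$marker_a)
      gids <- unique(group_of[partner])
      labs <- unique(stats::na.omit(label_of_group[gids]))
      if (length(labs) > 1L) {
        unplaced <- rbind(unplaced,
                          data.frame(marker = m, reason = "anchor_conflict"))
        next
      }
      target <- group_of[[partner[which.max(best$lod_pooled)]]]
      # a marker linking several groups (at most one anchored) merges them;
      # an anchored group keeps its identity
      if (length(labs) == 1L)
        target <- gids[!is.na(label_of_group[gids])][1L]
      group_of[m] <- target
      if (length(gids) > 1L)
        group_of[group_of %in% gids] <- target
    } else {
      gid <- sprintf("LG%03d", next_gid); next_gid <- next_gid + 1L
      group_of[m] <- gid
    }
  }
  groups <- data.frame(marker = names(group_of), group = unname(group_of))
  groups <- groups[!is.na(groups$group), , drop = FALSE]
  groups$anchor_label <- label_of_group[groups$group]
  sizes <- table(groups$group)
  singles <- groups$marker[groups$group %in% names(sizes)[sizes == 1L]]
  rownames(groups) <- NULL
  list(groups = groups, unplaced = unplaced, singletons = singles)
}

#' Detect male-specific pseudo-linkage between linkage groups
#'
#' In a genome with residual tetrasomic behaviour, homeologous chromosomes
#' can show apparent linkage in males only.  This reports cross-group
#' marker pairs with `lod_male >= lod_male_min` while the female data show
#' free recombination (`r_female >= r_female_min`), aggregated per group
#' pair.
#'
#' @param grid a `tm_grid`.
#' @param groups grouping result from [group_markers()] (or its `groups`
#'   data frame).
#' @param lod_male_min minimum male LOD.
#' @param r_female_min minimum female recombination fraction (male-only
#'   association).
#' @return list with `pairs` (data frame `group_a`, `group_b`, `n_pairs`)
#'   and `support` (the qualifying marker-pair table).
#' @export
detect_pseudolinkage <- function(grid, groups, lod_male_min = 3,
                                 r_female_min = 0.4) {
  if (is.list(groups) && !is.data.frame(groups)) groups <- groups$groups
  gmap <- setNames(groups$group, groups$marker)
  mk <- groups$marker
  sup <- list()
  if (length(mk) >= 2L) {
    tp <- .tp_cache(grid)
    cmb <- combn(mk, 2L)
    for (i in seq_len(ncol(cmb))) {
      a <- cmb[1L, i]; b <- cmb[2L, i]
      if (gmap[[a]] == gmap[[b]]) next
      res <- tp(a, b)
      if (res$lod_male >= lod_male_min && !is.na(res$r_female) &&
          res$r_female >= r_female_min)
        sup[[length(sup) + 1L]] <- res
    }
  }
  if (length(sup) == 0L)
    return(list(pairs = data.frame(group_a = character(),
                                   group_b = character(),
                                   n_pairs = integer()),
                support = data.frame()))
  sup <- do.call(rbind, sup)
  ga <- gmap[sup$marker_a]; gb <- gmap[sup$marker_b]
  key <- ifelse(ga < gb, paste(ga, gb), paste(gb, ga))
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  pairs <- data.frame(group_a = vapply(parts, `[`, "", 1L),
                      group_b = vapply(parts, `[`, "", 2L),
                      n_pairs = as.integer(tab))
  list(pairs = pairs[order(-pairs$n_pairs), , drop = FALSE], support = sup)
}
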