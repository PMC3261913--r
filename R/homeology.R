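#' Assign mapped markers to chromosome arms
#'
#' Labels each marker by the arm interval of the female map containing its
#' position.  Arm intervals are half-open `[start, end)` on the cM axis
#' (a marker exactly on a breakpoint belongs to the distal interval; the
#' final position belongs to the last interval).
#'
#' @param map data frame with `marker`, `chromosome`, `pos_female`.
#' @param annotations named list: chromosome -> list with `breakpoints`
#'   (fractions of the female span, strictly increasing in (0,1)) and
#'   `labels` (one more than breakpoints); chromosomes without annotation
#'   get the single label `""` (whole chromosome as one arm).
#' @return named character vector: marker id -> arm label
#'   (`<chromosome><label>`).
#' @export
arm_assign <- function(map, annotations = list()) {
  out <- setNames(rep(NA_character_, nrow(map)), map$marker)
  for (cc in unique(map$chromosome)) {
    sel <- map$chromosome == cc
    pos <- map$pos_female[sel]
    span <- max(pos)
    ann <- annotations[[cc]] %||% list(breakpoints = numeric(), labels = "")
    if (any(pos < 0 | pos > span))
      .tm_stop("marker position outside [0, %g] on %s", span, cc)
    cuts <- c(0, ann$breakpoints * span, span + 1e-9)
    idx <- findInterval(pos, cuts, rightmost.closed = FALSE, left.open = FALSE)
    out[map$marker[sel]] <- paste0(cc, ann$labels[idx])
  }
  out
}

.pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Place MSV-5 locus pairs on arms by within-family two-point linkage
#'
#' Each resolved MSV-5 contributes two pseudo-marker columns whose
#' locus labels are only defined up to a per-family swap; the unordered
#' pair of arms the two loci map to is, however, swap-invariant.  For each
#' full-sib family with resolved genotypes, both locus columns are linked
#' against the framework markers using that family's meioses alone; when
#' both loci reach `lod_min` against some framework partner, the family
#' votes for the unordered pair of partner arms.  The marker's placement
#' is the modal voted pair across families.
#'
#' @param grid a `tm_grid` containing `_L1`/`_L2` pseudo-marker columns.
#' @param framework_arms named character vector: framework marker -> arm.
#' @param lod_min minimum within-family LOD for placing one locus.
#' @return data frame `marker_id`, `arm_a`, `arm_b` (`NA` when not
#'   dual-placed), `n_votes`, `n_families`.
#' @export
place_msv5_loci <- function(grid, framework_arms, lod_min = 3) {
  pseudo <- grep("_L1$", colnames(grid$cells), value = TRUE)
  fw <- intersect(colnames(grid$cells), names(framework_arms))
  out <- lapply(pseudo, function(p1) {
    mid <- sub("_L1$", "", p1)
    p2 <- paste0(mid, "_L2")
    fams <- unique(grid$meioses$family[!is.na(grid$cells[, p1]) |
                                         !is.na(grid$cells[, p2])])
    # a dosage-determinate family segregates at only one of the two loci,
    # so each family contributes the arm of whichever locus it informs;
    # the dual placement is the union of arms voted by different families
    votes <- character()
    for (fam in fams) {
      keep <- grid$meioses$family == fam
      sub <- structure(list(cells = grid$cells[keep, , drop = FALSE],
                            conditional = grid$conditional[keep, ,
                                                           drop = FALSE],
                            meioses = grid$meioses[keep, , drop = FALSE]),
                       class = "tm_grid")
      for (pm in c(p1, p2)) {
        if (all(is.na(sub$cells[, pm]))) next
        best_lod <- 0; best_arm <- NA_character_
        for (m in fw) {
          res <- estimate_twopoint(sub, pm, m)
          if (res$lod_pooled > best_lod) {
            best_lod <- res$lod_pooled
            best_arm <- framework_arms[[m]]
          }
        }
        if (best_lod >= lod_min && !is.na(best_arm))
          votes <- c(votes, best_arm)
      }
    }
    if (length(votes) == 0L)
      return(data.frame(marker_id = mid, arm_a = NA_character_,
                        arm_b = NA_character_, n_votes = 0L,
                        n_families = length(fams)))
    tab <- sort(table(votes), decreasing = TRUE)
    if (length(tab) == 1L)  # only one locus ever placed
      return(data.frame(marker_id = mid, arm_a = names(tab)[1],
                        arm_b = NA_character_,
                        n_votes = as.integer(tab[1]),
                        n_families = length(fams)))
    data.frame(marker_id = mid, arm_a = names(tab)[1], arm_b = names(tab)[2],
               n_votes = as.integer(tab[2]), n_families = length(fams))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(marker_id = character(), arm_a = character(),
                      arm_b = character(), n_votes = integer(),
                      n_families = integer())
  out
}

#' Arm-pair counts from dual-placed MSV-5 markers
#'
#' Every MSV-5 whose two resolved loci are dual-placed on a pair of
#' (different) arms contributes one count to that unordered arm pair;
#' MSV-5s without a dual placement contribute nothing.
#'
#' @param placements result of [place_msv5_loci()].
#' @return data frame `arm_a`, `arm_b`, `count`.
#' @export
msv5_homeologies <- function(placements) {
  empty <- data.frame(arm_a = character(), arm_b = character(),
                      count = integer())
  ok <- !is.na(placements$arm_a) & !is.na(placements$arm_b)
  if (!any(ok)) return(empty)
  keys <- .pair_key(placements$arm_a[ok], placements$arm_b[ok])
  tab <- table(keys)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  data.frame(arm_a = vapply(parts, `[`, "", 1L),
             arm_b = vapply(parts, `[`, "", 2L),
             count = as.integer(tab))
}

#' Arm-pair counts from paralogous sequence hits
#'
#' @param hits result of [find_paralog_hits()].
#' @return data frame `arm_a`, `arm_b`, `count` (number of cross-arm hit
#'   pairs).
#' @export
paralog_homeologies <- function(hits) {
  empty <- data.frame(arm_a = character(), arm_b = character(),
                      count = integer())
  if (nrow(hits) == 0L) return(empty)
  keys <- .pair_key(hits$arm_a, hits$arm_b)
  tab <- table(keys)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  data.frame(arm_a = vapply(parts, `[`, "", 1L),
             arm_b = vapply(parts, `[`, "", 2L),
             count = as.integer(tab))
}

#' Arm-pair counts from shared outgroup synteny segments
#'
#' Anchored markers are clustered into maximal runs (segments) along each
#' outgroup chromosome, splitting where consecutive anchors are more than
#' `gap_tol` bp apart.  Two salmon arms anchored in the same segment form a
#' candidate homeolog pair; the pair's count is the smaller of the two
#' arms' anchor counts in the segment (so the minimum-evidence rule applies
#' to each arm), maximized over segments.
#'
#' @param anchor_hits result of [map_anchor_hits()].
#' @param arm_assignment named character vector: marker -> arm.
#' @param gap_tol segment gap tolerance in bp.
#' @return data frame `arm_a`, `arm_b`, `count`.
#' @export
anchor_homeologies <- function(anchor_hits, arm_assignment,
                               gap_tol = 10000L) {
  empty <- data.frame(arm_a = character(), arm_b = character(),
                      count = integer())
  hits <- anchor_hits[anchor_hits$marker_id %in% names(arm_assignment), ,
                      drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits$arm <- arm_assignment[hits$marker_id]
  best <- new.env(parent = emptyenv())
  for (og in unique(hits$outgroup_chrom)) {
    sub <- hits[hits$outgroup_chrom == og, , drop = FALSE]
    sub <- sub[order(sub$outgroup_pos), , drop = FALSE]
    seg <- cumsum(c(0L, diff(sub$outgroup_pos) > gap_tol))
    for (sg in unique(seg)) {
      arms <- table(sub$arm[seg == sg])
      if (length(arms) < 2L) next
      an <- names(arms)
      for (i in seq_len(length(an) - 1L)) for (j in (i + 1L):length(an)) {
        key <- .pair_key(an[i], an[j])
        cnt <- min(arms[[i]], arms[[j]])
        if (is.null(best[[key]]) || cnt > best[[key]]) best[[key]] <- cnt
      }
    }
  }
  keys <- ls(best)
  if (length(keys) == 0L) return(empty)
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(arm_a = vapply(parts, `[`, "", 1L),
             arm_b = vapply(parts, `[`, "", 2L),
             count = vapply(keys, function(k) as.integer(best[[k]]), 0L),
             row.names = NULL)
}

#' Combine homeology evidence under the minimum-evidence rule
#'
#' Merges arm-pair counts from the three evidence sources (dual-locus
#' MSV-5 placements, within-genome paralog hits, outgroup synteny anchors).
#' A pair is asserted homeologous when at least one single source reaches
#' `min_evidence` counts -- the safeguard against false positives; combined
#' sub-threshold evidence never asserts.
#'
#' @param msv5_counts,paralog_counts,anchor_counts data frames
#'   `arm_a`, `arm_b`, `count` (any may be empty or `NULL`).
#' @param min_evidence minimum single-source count.
#' @return data frame `arm_a`, `arm_b`, `msv5`, `paralog`, `anchor`,
#'   `asserted`, `sources`, sorted by arm pair.
#' @export
assert_homeologies <- function(msv5_counts = NULL, paralog_counts = NULL,
                               anchor_counts = NULL, min_evidence = 3L) {
  norm <- function(x) {
    if (is.null(x) || nrow(x) == 0L)
      return(setNames(integer(), character()))
    setNames(as.integer(x$count), .pair_key(x$arm_a, x$arm_b))
  }
  m <- norm(msv5_counts); p <- norm(paralog_counts); a <- norm(anchor_counts)
  keys <- sort(unique(c(names(m), names(p), names(a))))
  if (length(keys) == 0L)
    return(data.frame(arm_a = character(), arm_b = character(),
                      msv5 = integer(), paralog = integer(),
                      anchor = integer(), asserted = logical(),
                      sources = character()))
  get0i <- function(v, k) ifelse(k %in% names(v), v[k], 0L)
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    arm_a = vapply(parts, `[`, "", 1L),
    arm_b = vapply(parts, `[`, "", 2L),
    msv5 = as.integer(get0i(m, keys)),
    paralog = as.integer(get0i(p, keys)),
    anchor = as.integer(get0i(a, keys)))
  out$asserted <- pmax(out$msv5, out$paralog, out$anchor) >= min_evidence
  srcs <- cbind(msv5 = out$msv5, paralog = out$paralog, anchor = out$anchor)
  out$sources <- apply(srcs >= min_evidence, 1L, function(z)
    paste(colnames(srcs)[z], collapse = "+"))
  rownames(out) <- NULL
  out
}
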