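# log10 likelihood of one adjacency at its ML recombination fraction
# (profiled phases): LOD minus the free-recombination baseline n*log10(2).
# Tightly linked pairs cost ~0 regardless of informativeness; unlinked
# adjacencies cost ~ -0.3 per doubly-informative meiosis.
.adj_ll <- function(res, sex) {
  half <- log10(0.5)
  switch(sex,
         female = res$lod_female + res$n_female * half,
         male = res$lod_male + res$n_male * half,
         both = res$lod_female + res$n_female * half +
           res$lod_male + res$n_male * half)
}

# multipoint criterion of an order: sum of adjacent-interval log10
# likelihoods (first-order product of adjacent-interval likelihoods)
.order_score <- function(ord, tp, sex = "female") {
  if (length(ord) < 2L) return(0)
  s <- 0
  for (i in seq_len(length(ord) - 1L))
    s <- s + .adj_ll(tp(ord[i], ord[i + 1L]), sex)
  s
}

#' Order markers within a linkage group
#'
#' Builds an initial order from female meioses only (male recombination is
#' too localized to order by): starting from the most informative
#' strongly-linked pair, each remaining marker (most informative first) is
#' inserted at the position maximizing the multipoint criterion, the sum of
#' adjacent-interval log10 likelihoods at their ML recombination fractions
#' (female meioses).  A marker is left unplaced when its best and
#' second-best insertion positions differ by less than `lod_margin` log10
#' units (insufficient support) or when the best interior insertion expands
#' the map by more than `expansion_cap` cM beyond the direct two-point
#' distance of the broken interval (map expansion).
#'
#' @param grid a `tm_grid`.
#' @param markers markers of one group.
#' @param lod_margin placement-support margin in log10 units.
#' @param expansion_cap map-expansion cap in cM.
#' @param mapfn mapping function for the expansion check.
#' @param seed_lod minimum LOD for the seeding pair.
#' @return list with `order`, `unplaced` (data frame `marker`, `reason`)
#'   and `score`.
#' @export
build_order <- function(grid, markers, lod_margin = 3, expansion_cap = 10,
                        mapfn = "kosambi", seed_lod = 3) {
  unplaced <- data.frame(marker = character(), reason = character())
  if (length(markers) < 2L)
    return(list(order = markers, unplaced = unplaced, score = 0))
  fem <- grid$meioses$parent_sex == "F"
  fgrid <- list(cells = grid$cells[fem, markers, drop = FALSE],
                meioses = grid$meioses[fem, , drop = FALSE])
  class(fgrid) <- "tm_grid"
  tp <- .tp_cache(fgrid)
  inf_n <- colSums(!is.na(fgrid$cells))

  # seed with the most informative strongly-linked pair
  cmb <- combn(markers, 2L)
  pair_lod <- vapply(seq_len(ncol(cmb)), function(i)
    tp(cmb[1L, i], cmb[2L, i])$lod_female, 0)
  pair_ll <- vapply(seq_len(ncol(cmb)), function(i)
    .adj_ll(tp(cmb[1L, i], cmb[2L, i]), "female"), 0)
  strong <- which(pair_lod >= seed_lod)
  if (length(strong) == 0L) strong <- which.max(pair_lod)
  # a zero-length pair (coincident markers) carries no ordering
  # information and would grandfather duplicates into the framework
  pair_r <- vapply(seq_len(ncol(cmb)), function(i)
    tp(cmb[1L, i], cmb[2L, i])$r_female, 0)
  pos_r <- strong[!is.na(pair_r[strong]) & pair_r[strong] > 1e-6]
  if (length(pos_r) > 0L) strong <- pos_r
  pinf <- inf_n[cmb[1L, strong]] + inf_n[cmb[2L, strong]]
  pick <- strong[order(-pinf, -pair_lod[strong],
                       cmb[1L, strong], cmb[2L, strong])][1L]
  ord <- sort(cmb[, pick])

  rest <- setdiff(markers, ord)
  rest <- rest[order(-inf_n[rest], rest)]
  try_insert <- function(m) {
    L <- length(ord)
    delta <- numeric(L + 1L)
    for (pos in 0:L) {
      left <- if (pos >= 1L) .adj_ll(tp(ord[pos], m), "female") else NA_real_
      right <- if (pos < L) .adj_ll(tp(m, ord[pos + 1L]), "female")
               else NA_real_
      cut <- if (pos >= 1L && pos < L)
        .adj_ll(tp(ord[pos], ord[pos + 1L]), "female") else 0
      delta[pos + 1L] <- sum(left, right, na.rm = TRUE) - cut
    }
    best <- order(-delta)[1L]
    margin <- if (L + 1L >= 2L) delta[best] - sort(delta, decreasing = TRUE)[2L]
              else Inf
    if (margin < lod_margin) return("insufficient_support")
    pos <- best - 1L
    if (pos >= 1L && pos < L) {
      dfun <- function(a, b) {
        r <- tp(a, b)$r_female
        if (is.na(r)) 0 else rf_to_cM(r, mapfn)
      }
      expansion <- dfun(ord[pos], m) + dfun(m, ord[pos + 1L]) -
        dfun(ord[pos], ord[pos + 1L])
      if (expansion > expansion_cap) return("map_expansion")
    }
    ord <<- append(ord, m, after = pos)
    NULL
  }
  deferred <- list()
  for (m in rest) {
    why <- try_insert(m)
    if (!is.null(why)) deferred[[m]] <- why
  }
  # a marker without a confident position early on may gain one once its
  # neighbours are placed; retry until a full pass places nothing
  repeat {
    placed_any <- FALSE
    for (m in names(deferred)) {
      why <- try_insert(m)
      if (is.null(why)) {
        deferred[[m]] <- NULL
        placed_any <- TRUE
      } else deferred[[m]] <- why
    }
    if (!placed_any || length(deferred) == 0L) break
  }
  if (length(deferred) > 0L)
    unplaced <- rbind(unplaced,
                      data.frame(marker = names(deferred),
                                 reason = unlist(deferred)))
  list(order = ord, unplaced = unplaced,
       score = .order_score(ord, tp, "female"))
}

# all permutations of 1..n (deterministic order)
.perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in .perms(n - 1L)) for (at in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = at)
  out
}

#' Refine a marker order by window permutations
#'
#' Slides a window of `window` markers along the order, evaluates every
#' permutation of the window against the combined female + male adjacency
#' criterion, and accepts any strict improvement; passes repeat until a
#' full pass changes nothing.  Deterministic.
#'
#' @param order initial marker order.
#' @param grid a `tm_grid` (both sexes).
#' @param window window size (2..5 sensible; cost grows as window!).
#' @return the improved order.
#' @export
improve_order <- function(order, grid, window = 4L) {
  n <- length(order)
  if (n < 2L) return(order)
  window <- min(window, n)
  tp <- .tp_cache(grid)
  perms <- .perms(window)
  edge <- function(a, b) .adj_ll(tp(a, b), "both")
  repeat {
    changed <- FALSE
    for (start in seq_len(n - window + 1L)) {
      idx <- start:(start + window - 1L)
      seg <- order[idx]
      left <- if (start > 1L) order[start - 1L] else NA
      right <- if (start + window <= n) order[start + window] else NA
      score_seg <- function(s) {
        tot <- 0
        if (!is.na(left)) tot <- tot + edge(left, s[1L])
        for (i in seq_len(window - 1L)) tot <- tot + edge(s[i], s[i + 1L])
        if (!is.na(right)) tot <- tot + edge(s[window], right)
        tot
      }
      base <- score_seg(seg)
      best <- base; best_seg <- seg
      for (p in perms) {
        cand <- seg[p]
        if (identical(cand, seg)) next
        sc <- score_seg(cand)
        if (sc > best + 1e-9) { best <- sc; best_seg <- cand }
      }
      if (!identical(best_seg, seg)) {
        order[idx] <- best_seg
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  order
}
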