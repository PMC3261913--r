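#' Grandparental-origin phase strings
#'
#' For each meiosis, assigns a grandparental-origin symbol at every ordered
#' marker: `0`/`1` for the two (arbitrarily labelled) parental haplotypes,
#' `-` where the cell is uninformative.  The parent's phase along the order
#' is resolved greedily: marker by marker, the orientation minimizing the
#' number of origin switches against each meiosis's most recent informative
#' marker is chosen (ties keep the current orientation), which maximizes
#' the adjacent-interval likelihood for any recombination fraction below
#' one half.  Switches between adjacent informative symbols mark
#' crossovers; an isolated single-marker switch (a double recombinant over
#' a short interval) is the signature of a genotyping error.
#'
#' @param order ordered marker ids.
#' @param grid a `tm_grid`.
#' @param sex optional `"F"` or `"M"` to restrict to one parental sex.
#' @return list with `strings` (named character vector per meiosis),
#'   `symbols` (meioses x markers matrix of 0/1/NA after orientation) and
#'   `meioses` (the meiosis table used).
#' @export
phase_strings <- function(order, grid, sex = NULL) {
  keep <- rep(TRUE, nrow(grid$meioses))
  if (!is.null(sex)) keep <- grid$meioses$parent_sex == sex
  cells <- grid$cells[keep, order, drop = FALSE]
  meio <- grid$meioses[keep, , drop = FALSE]
  out <- matrix(NA_integer_, nrow(cells), ncol(cells),
                dimnames = dimnames(cells))
  for (par in unique(meio$parent)) {
    rows <- which(meio$parent == par)
    sub <- cells[rows, , drop = FALSE]
    last_val <- rep(NA_integer_, length(rows))
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      ok <- !is.na(v) & !is.na(last_val)
      flip <- FALSE
      if (any(ok)) {
        d <- sum(v[ok] != last_val[ok])
        flip <- d > sum(ok) - d
      }
      if (flip) v <- 1L - v
      out[rows, j] <- v
      last_val[!is.na(v)] <- v[!is.na(v)]
    }
  }
  strings <- apply(out, 1L, function(z)
    paste(ifelse(is.na(z), "-", as.character(z)), collapse = ""))
  list(strings = strings, symbols = out, meioses = meio)
}

# crossover count of one symbol row: switches between adjacent informative
# symbols
.phase_switch_count <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) < 2L) return(0L)
  sum(diff(z) != 0L)
}

#' Identify and blank double-recombinant genotyping errors
#'
#' An informative phase symbol differing from both flanking informative
#' symbols implies two crossovers in a short span -- overwhelmingly more
#' likely a genotyping error than a true double recombinant when the
#' flanking markers lie within `max_span_cM`.  Such cells have the
#' underlying genotype call (the offspring's call at that marker; for an
#' MSV-5 pseudo-marker, the MSV-5 call itself) set missing in a single
#' correction pass; maps should be re-estimated afterwards.
#'
#' @param order ordered marker ids.
#' @param grid a `tm_grid`.
#' @param map current map estimate: data frame with `marker`, `pos_female`,
#'   `pos_male` (used for the flanking-span check, by parent sex).
#' @param calls long call table to correct.
#' @param max_span_cM maximum span between the flanking informative
#'   markers.
#' @return list with `calls` (corrected), `grid` (cells blanked) and
#'   `changes` (data frame `marker`, `sample`, `parent`).
#' @export
correct_double_recombinants <- function(order, grid, map, calls,
                                        max_span_cM = 10) {
  changes <- list()
  posF <- setNames(map$pos_female, map$marker)
  posM <- setNames(map$pos_male, map$marker)
  for (sx in c("F", "M")) {
    ph <- phase_strings(order, grid, sex = sx)
    pos <- if (sx == "F") posF[order] else posM[order]
    sym <- ph$symbols
    for (i in seq_len(nrow(sym))) {
      z <- sym[i, ]
      idx <- which(!is.na(z))
      if (length(idx) < 3L) next
      v <- z[idx]
      mid <- 2:(length(idx) - 1L)
      island <- v[mid] != v[mid - 1L] & v[mid] != v[mid + 1L] &
        v[mid - 1L] == v[mid + 1L]
      span_ok <- (pos[idx[mid + 1L]] - pos[idx[mid - 1L]]) <= max_span_cM
      hit <- mid[island & span_ok]
      for (h in hit) {
        changes[[length(changes) + 1L]] <- data.frame(
          marker = order[idx[h]], sample = ph$meioses$offspring[i],
          parent = ph$meioses$parent[i])
      }
    }
  }
  if (length(changes) == 0L)
    return(list(calls = calls, grid = grid,
                changes = data.frame(marker = character(),
                                     sample = character(),
                                     parent = character())))
  changes <- unique(do.call(rbind, changes))
  base_marker <- sub("_L[12]$", "", changes$marker)
  for (i in seq_len(nrow(changes))) {
    sel <- calls$marker_id == base_marker[i] &
      calls$sample_id == changes$sample[i]
    calls$dosage[sel] <- NA_integer_
    # blank every grid column derived from this genotype for this offspring
    cols <- which(sub("_L[12]$", "", colnames(grid$cells)) == base_marker[i])
    rows <- which(grid$meioses$offspring == changes$sample[i])
    grid$cells[rows, cols] <- NA_integer_
  }
  rownames(changes) <- NULL
  list(calls = calls, grid = grid, changes = changes)
}

#' Sex-specific multipoint map positions
#'
#' Estimates the recombination fraction of every adjacent interval per sex
#' (phase profiled per parent, as in [estimate_twopoint()]), converts to cM
#' with the chosen mapping function and accumulates positions from 0 at the
#' first marker.  Intervals with no doubly-informative meioses in a sex get
#' distance 0 and are flagged.
#'
#' @param order ordered marker ids.
#' @param grid a `tm_grid`.
#' @param mapfn `"kosambi"` (default) or `"haldane"`.
#' @return data frame `marker`, `index`, `pos_female`, `pos_male`,
#'   `n_meioses`, with attributes `mapfn` and `imputed_intervals`.
#' @export
estimate_sex_maps <- function(order, grid, mapfn = "kosambi") {
  tp <- .tp_cache(grid)
  nF <- 0; nM <- 0
  dF <- numeric(0); dM <- numeric(0); imputed <- character(0)
  if (length(order) > 1L) {
    for (i in seq_len(length(order) - 1L)) {
      res <- tp(order[i], order[i + 1L])
      if (is.na(res$r_female)) {
        dF <- c(dF, 0)
        imputed <- c(imputed, sprintf("%s:%s:F", order[i], order[i + 1L]))
      } else dF <- c(dF, rf_to_cM(res$r_female, mapfn))
      if (is.na(res$r_male)) {
        dM <- c(dM, 0)
        imputed <- c(imputed, sprintf("%s:%s:M", order[i], order[i + 1L]))
      } else dM <- c(dM, rf_to_cM(res$r_male, mapfn))
    }
  }
  out <- data.frame(marker = order, index = seq_along(order),
                    pos_female = c(0, cumsum(dF)), pos_male = c(0, cumsum(dM)),
                    n_meioses = colSums(!is.na(grid$cells[, order,
                                                          drop = FALSE])))
  rownames(out) <- NULL
  attr(out, "mapfn") <- mapfn
  attr(out, "imputed_intervals") <- imputed
  out
}

#' Summarize per-chromosome maps in the published-table layout
#'
#' Accepts either a named list of maps from [estimate_sex_maps()] or a
#' pre-tabulated data frame with columns `chromosome`, `n_markers`,
#' `female_length`, `male_length`.  Lengths are rendered to 1 decimal,
#' ratios to 2 decimals, and a `Total` row sums the displayed columns with
#' the overall ratio = total female / total male.
#'
#' @param maps list of maps or a summary data frame.
#' @return data frame `chromosome`, `n_markers`, `female_length`,
#'   `male_length`, `ratio` with a final `Total` row.
#' @export
summarize_maps <- function(maps) {
  if (is.data.frame(maps)) {
    tab <- maps
  } else {
    tab <- do.call(rbind, lapply(names(maps), function(cc) {
      m <- maps[[cc]]
      data.frame(chromosome = cc, n_markers = nrow(m),
                 female_length = if (nrow(m)) max(m$pos_female) else 0,
                 male_length = if (nrow(m)) max(m$pos_male) else 0)
    }))
  }
  if (is.null(tab) || nrow(tab) == 0L)
    return(data.frame(chromosome = character(), n_markers = integer(),
                      female_length = numeric(), male_length = numeric(),
                      ratio = numeric()))
  tab$female_length <- round(tab$female_length, 1)
  tab$male_length <- round(tab$male_length, 1)
  tab$ratio <- ifelse(tab$male_length > 0,
                      round(tab$female_length / tab$male_length, 2), NA_real_)
  totF <- sum(tab$female_length); totM <- sum(tab$male_length)
  total <- data.frame(chromosome = "Total", n_markers = sum(tab$n_markers),
                      female_length = totF, male_length = totM,
                      ratio = if (totM > 0) round(totF / totM, 2) else NA_real_)
  out <- rbind(tab[, c("chromosome", "n_markers", "female_length",
                       "male_length", "ratio")], total)
  rownames(out) <- NULL
  out
}

#' Telomeric localization of male recombination
#'
#' Measures, per chromosome end, the fraction of male crossovers falling in
#' the distal `distal_frac` of the female-map span (crossovers located at
#' the midpoint between the flanking informative markers of each phase
#' switch).  An end is flagged "elevated" when its fraction exceeds
#' `factor` times the uniform expectation.  Female phase strings run
#' through the same index give ~`distal_frac` per end under a uniform
#' landscape.
#'
#' @param map a map from [estimate_sex_maps()] (female positions used).
#' @param grid a `tm_grid`.
#' @param sex parental sex whose crossovers are indexed (default male).
#' @param distal_frac distal window as a fraction of the span.
#' @param factor flagging multiple of the uniform expectation.
#' @return list with `ends` (data frame `end`, `n_crossovers`, `fraction`,
#'   `flagged`), `n_flagged` and `n_crossovers`.
#' @export
recombination_localization <- function(map, grid, sex = "M",
                                       distal_frac = 0.2, factor = 2) {
  ph <- phase_strings(map$marker, grid, sex = sex)
  pos <- setNames(map$pos_female, map$marker)
  span <- max(map$pos_female)
  mids <- numeric(0)
  for (i in seq_len(nrow(ph$symbols))) {
    z <- ph$symbols[i, ]
    idx <- which(!is.na(z))
    if (length(idx) < 2L) next
    sw <- which(diff(z[idx]) != 0L)
    if (length(sw) > 0L)
      mids <- c(mids, (pos[map$marker[idx[sw]]] +
                         pos[map$marker[idx[sw + 1L]]]) / 2)
  }
  n <- length(mids)
  fr_left <- if (n > 0) mean(mids <= distal_frac * span) else 0
  fr_right <- if (n > 0) mean(mids >= (1 - distal_frac) * span) else 0
  ends <- data.frame(end = c("left", "right"), n_crossovers = n,
                     fraction = c(fr_left, fr_right),
                     flagged = c(fr_left, fr_right) > factor * distal_frac)
  list(ends = ends, n_flagged = sum(ends$flagged), n_crossovers = n)
}
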