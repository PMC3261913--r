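.BASES <- c("A", "C", "G", "T")

# i.i.d. uniform nucleotide sequences
.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(.BASES, len, replace = TRUE), collapse = ""), "")
}

# site-wise substitution: each site independently replaced, with probability
# `divergence`, by a base drawn uniformly from the three other bases.  A
# mutated site therefore always differs from the original, so the expected
# pairwise identity is exactly 1 - divergence (no multiple-hit correction
# is needed for this single-round model).
.mutate_dna <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < divergence
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(.BASES, b), 1L), "")
  }
  paste(ch, collapse = "")
}

#' Generate marker flanking sequences and a synthetic outgroup genome
#'
#' Every marker receives a random flanking sequence.  MSV markers
#' additionally receive a paralogous copy mutated at their homeolog pair's
#' divergence rate.  The synthetic outgroup genome contains, per chromosome
#' arm carrying markers, a syntenic segment holding copies of that arm's
#' marker flanks in map order, mutated at `outgroup_divergence`; the two
#' arms of a homeolog pair share a single outgroup chromosome (one ancestral
#' copy region), emulating conserved synteny with a pre-duplication
#' outgroup.
#'
#' @param genome a `tm_genome`.
#' @param markers marker truth table (see [sim_markers()]).
#' @param seq_len flank length in bp.
#' @param outgroup_divergence substitutions/site between salmon flanks and
#'   their outgroup copies.
#' @param spacer_len random spacer length between planted copies.
#' @return list with `flanks` and `paralogs` (named character vectors),
#'   `outgroup` (named character vector of outgroup chromosome sequences)
#'   and `anchors` (data frame `marker_id`, `outgroup_chrom`, `outgroup_pos`
#'   -- 1-based start of the planted copy).
#' @export
generate_sequences <- function(genome, markers, seq_len = 500,
                               outgroup_divergence = 0.1, spacer_len = 100) {
  n <- nrow(markers)
  flanks <- setNames(.random_dna(n, seq_len), markers$id)
  is_msv <- markers$klass %in% c("MSV3", "MSV5")
  paralogs <- setNames(character(0), character(0))
  if (any(is_msv)) {
    div <- setNames(genome$homeolog_pairs$divergence,
                    paste(genome$homeolog_pairs$arm_a,
                          genome$homeolog_pairs$arm_b))
    pd <- vapply(which(is_msv), function(i) {
      key1 <- paste(markers$arm[i], markers$paralog_arm[i])
      key2 <- paste(markers$paralog_arm[i], markers$arm[i])
      d <- if (key1 %in% names(div)) div[[key1]] else div[[key2]]
      .mutate_dna(flanks[[i]], d)
    }, "")
    paralogs <- setNames(pd, markers$id[is_msv])
  }

  # outgroup: one chromosome per homeolog pair, one per unpaired arm
  pairs <- genome$homeolog_pairs
  arm2og <- list()
  if (nrow(pairs) > 0) for (i in seq_len(nrow(pairs))) {
    og <- sprintf("og_%s_%s", pairs$arm_a[i], pairs$arm_b[i])
    arm2og[[pairs$arm_a[i]]] <- og
    arm2og[[pairs$arm_b[i]]] <- og
  }
  for (a in unique(markers$arm))
    if (is.null(arm2og[[a]])) arm2og[[a]] <- sprintf("og_%s", a)

  og_names <- unique(unlist(arm2og))
  outgroup <- setNames(rep("", length(og_names)), og_names)
  anchors <- data.frame(marker_id = character(), outgroup_chrom = character(),
                        outgroup_pos = integer())
  for (og in og_names) {
    arms <- names(arm2og)[vapply(arm2og, identical, TRUE, og)]
    seqp <- character(); poss <- integer(); ids <- character(); at <- 0L
    for (a in sort(arms)) {
      sel <- which(markers$arm == a)
      sel <- sel[order(markers$u[sel])]
      for (i in sel) {
        sp <- .random_dna(1L, spacer_len)
        copy <- .mutate_dna(flanks[[i]], outgroup_divergence)
        seqp <- c(seqp, sp, copy)
        at <- at + spacer_len
        poss <- c(poss, at + 1L); ids <- c(ids, markers$id[i])
        at <- at + nchar(copy)
      }
    }
    seqp <- c(seqp, .random_dna(1L, spacer_len))
    outgroup[[og]] <- paste(seqp, collapse = "")
    anchors <- rbind(anchors, data.frame(marker_id = ids, outgroup_chrom = og,
                                         outgroup_pos = poss))
  }
  list(flanks = flanks, paralogs = paralogs, outgroup = outgroup,
       anchors = anchors)
}
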