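# --- internal k-mer seeded ungapped aligner ---------------------------------
# Deterministic replacement for an external megablast step: exact k-mer
# seeds define diagonals; each candidate (query, subject) pair is scored by
# ungapped comparison along its best-seeded diagonal.  An adapter for
# pre-computed tabular hits from an external aligner is provided by
# read_tabular_hits().

# all k-mers of a set of sequences: data.frame(seq = index, pos, kmer)
.kmerize <- function(seqs, k) {
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[[i]])
    if (n < k) next
    pos <- seq_len(n - k + 1L)
    out[[i]] <- data.frame(seq = i, pos = pos,
                           kmer = substring(seqs[[i]], pos, pos + k - 1L))
  }
  do.call(rbind, out)
}

# ungapped comparison of query i vs subject j at offset off (subject
# coordinate of query position 1 minus 1)
.diag_align <- function(q, s, off) {
  qlen <- nchar(q); slen <- nchar(s)
  i1 <- max(1L, 1L - off); i2 <- min(qlen, slen - off)
  if (i2 < i1) return(NULL)
  qa <- utf8ToInt(substring(q, i1, i2))
  sa <- utf8ToInt(substring(s, i1 + off, i2 + off))
  matches <- sum(qa == sa)
  len <- i2 - i1 + 1L
  list(identity = matches / len, length = len, score = matches,
       qstart = i1, sstart = i1 + off)
}

# candidate (query, subject, diagonal) triples sharing >= 1 exact k-mer;
# per (query, subject) the diagonal with most seeds is kept.  `self = TRUE`
# marks an all-vs-all comparison (qk == sk): only k-mers occurring more
# than once can seed a cross hit, and self pairs are dropped.
.seed_candidates <- function(qk, sk, self = FALSE) {
  empty <- data.frame(q = integer(), s = integer(), off = integer(),
                      seeds = integer())
  if (self) {
    common <- unique(qk$kmer[duplicated(qk$kmer)])
  } else {
    common <- intersect(unique(qk$kmer), unique(sk$kmer))
  }
  if (length(common) == 0L) return(empty)
  qk2 <- qk[qk$kmer %in% common, , drop = FALSE]
  sk2 <- if (self) qk2 else sk[sk$kmer %in% common, , drop = FALSE]
  cand <- merge(qk2, sk2, by = "kmer", suffixes = c(".q", ".s"))
  cand <- data.frame(q = cand$seq.q, s = cand$seq.s,
                     off = cand$pos.s - cand$pos.q)
  if (self) cand <- cand[cand$q != cand$s, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  key <- paste(cand$q, cand$s, cand$off)
  cnt <- table(key)
  cand <- cand[!duplicated(key), , drop = FALSE]
  cand$seeds <- as.integer(cnt[paste(cand$q, cand$s, cand$off)])
  ord <- order(cand$q, cand$s, -cand$seeds, cand$off)
  cand <- cand[ord, , drop = FALSE]
  cand[!duplicated(paste(cand$q, cand$s)), , drop = FALSE]
}

#' Find paralogous sequence hits among marker flanks
#'
#' All-vs-all comparison of flanking sequences by exact k-mer seeding and
#' ungapped extension along the best-seeded diagonal.  Hits between
#' sequences assigned to the same chromosome arm, and self hits, are
#' excluded; retained hits must reach `min_ident` identity over at least
#' `min_len` bp (hits are intrinsically reciprocal: each unordered pair is
#' evaluated once).
#'
#' @param flanks named character vector (or FASTA path) of sequences.
#' @param arm_assignment named character vector: sequence id -> arm label.
#'   Sequences without an assignment are skipped.
#' @param k seed length.
#' @param min_ident minimum identity fraction.
#' @param min_len minimum ungapped match length in bp.
#' @return data frame `marker_a`, `marker_b`, `identity`, `match_length`,
#'   `arm_a`, `arm_b`.
#' @export
find_paralog_hits <- function(flanks, arm_assignment, k = 16L,
                              min_ident = 0.85, min_len = 100L) {
  if (is.character(flanks) && length(flanks) == 1L && file.exists(flanks))
    flanks <- .read_fasta(flanks)
  if (anyDuplicated(names(flanks)))
    .tm_stop("duplicate sequence id(s): %s",
             names(flanks)[duplicated(names(flanks))][1])
  keep <- names(flanks) %in% names(arm_assignment)
  flanks <- flanks[keep]
  ids <- names(flanks)
  if (length(flanks) < 2L)
    return(data.frame(marker_a = character(), marker_b = character(),
                      identity = numeric(), match_length = integer(),
                      arm_a = character(), arm_b = character()))
  kk <- .kmerize(flanks, k)
  cand <- .seed_candidates(kk, kk, self = TRUE)
  cand <- cand[cand$q < cand$s, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    qi <- cand$q[i]; si <- cand$s[i]
    arm_q <- arm_assignment[[ids[qi]]]; arm_s <- arm_assignment[[ids[si]]]
    if (identical(arm_q, arm_s)) next
    al <- .diag_align(flanks[[qi]], flanks[[si]], cand$off[i])
    if (is.null(al) || al$length < min_len || al$identity < min_ident) next
    rows[[length(rows) + 1L]] <- data.frame(
      marker_a = ids[qi], marker_b = ids[si], identity = al$identity,
      match_length = al$length, arm_a = arm_q, arm_b = arm_s)
  }
  if (length(rows) == 0L)
    return(data.frame(marker_a = character(), marker_b = character(),
                      identity = numeric(), match_length = integer(),
                      arm_a = character(), arm_b = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Anchor marker flanks on an outgroup genome
#'
#' Aligns each flank against the outgroup chromosomes with the same k-mer
#' seeded ungapped aligner.  A marker is anchored only when its best hit
#' outscores the second best by more than `margin` (fractional score gap),
#' safeguarding against duplicated outgroup regions; the anchor position is
#' the 1-based subject start of the best alignment.
#'
#' @param flanks named character vector (or FASTA path).
#' @param outgroup named character vector (or FASTA path) of outgroup
#'   chromosome sequences.
#' @param k seed length.
#' @param min_ident,min_len hit thresholds as in [find_paralog_hits()].
#' @param margin required fractional score gap between best and second-best
#'   hit.
#' @return data frame `marker_id`, `outgroup_chrom`, `outgroup_pos`,
#'   `identity`, `score_margin`.
#' @export
map_anchor_hits <- function(flanks, outgroup, k = 16L, min_ident = 0.85,
                            min_len = 100L, margin = 0.1) {
  if (is.character(flanks) && length(flanks) == 1L && file.exists(flanks))
    flanks <- .read_fasta(flanks)
  if (is.character(outgroup) && length(outgroup) == 1L &&
      file.exists(outgroup))
    outgroup <- .read_fasta(outgroup)
  empty <- data.frame(marker_id = character(), outgroup_chrom = character(),
                      outgroup_pos = integer(), identity = numeric(),
                      score_margin = numeric())
  if (length(outgroup) == 0L) {
    warning("empty outgroup: no anchors computed")
    return(empty)
  }
  qk <- .kmerize(flanks, k)
  sk <- .kmerize(outgroup, k)
  if (is.null(qk) || is.null(sk)) return(empty)
  cand <- .seed_candidates(qk, sk)
  rows <- list()
  for (qi in unique(cand$q)) {
    sub <- cand[cand$q == qi, , drop = FALSE]
    hits <- list()
    for (i in seq_len(nrow(sub))) {
      al <- .diag_align(flanks[[qi]], outgroup[[sub$s[i]]], sub$off[i])
      if (is.null(al) || al$length < min_len || al$identity < min_ident) next
      hits[[length(hits) + 1L]] <- data.frame(
        s = sub$s[i], score = al$score, identity = al$identity,
        sstart = al$sstart)
    }
    if (length(hits) == 0L) next
    hits <- do.call(rbind, hits)
    hits <- hits[order(-hits$score), , drop = FALSE]
    gap <- if (nrow(hits) == 1L) Inf
           else (hits$score[1L] - hits$score[2L]) / hits$score[1L]
    if (gap <= margin) next
    rows[[length(rows) + 1L]] <- data.frame(
      marker_id = names(flanks)[qi],
      outgroup_chrom = names(outgroup)[hits$s[1L]],
      outgroup_pos = hits$sstart[1L], identity = hits$identity[1L],
      score_margin = gap)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read pre-computed tabular alignment hits
#'
#' Adapter accepting 12-column tabular output from an external aligner
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, evalue, bitscore) for real-data use
#' in place of the internal aligner.
#'
#' @param path tab-separated hits file without header.
#' @return data frame with the 12 standard columns.
#' @export
read_tabular_hits <- function(path) {
  h <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(h) != 12L)
    .tm_stop("expected 12 tabular columns, found %d", ncol(h))
  names(h) <- c("query", "subject", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")
  h
}
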