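# headered TSV writers/readers.  Comment lines starting with '#' carry
# run metadata (version, seed, thresholds) and are skipped on read, so
# every writer round-trips through its reader.
.write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s=%s", names(meta),
                       vapply(meta, function(x) paste(format(x), collapse = ","), "")),
               con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, comment.char = "#", na.strings = c("", "NA"),
             stringsAsFactors = FALSE)
}

.write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

.read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Published per-chromosome linkage-map summary (fixture)
#'
#' Machine-readable copy of the published per-chromosome map summary for
#' the 29 Atlantic salmon chromosomes: SNP counts and sex-specific map
#' lengths in cM, with the published female:male ratio.
#'
#' @return data frame with columns `chromosome`, `n_snps`, `female_cM`,
#'   `male_cM`, `ratio`.
#' @export
table1_fixture <- function() {
  .read_tsv(system.file("extdata", "salmon_map_summary.tsv",
                        package = "tetramap", mustWork = TRUE))
}

#' Published homeologous-region evidence table (fixture)
#'
#' Machine-readable copy of the published table of 25 homeologous
#' chromosome-region pairs in Atlantic salmon with evidence counts from
#' three sources: dual-locus MSV-5 mapping, within-salmon sequence
#' alignment (paralog hits) and alignment against the stickleback genome
#' (outgroup anchors), plus previously reported pairs.
#'
#' @return data frame with columns `pair`, `msv5`, `salmon_blast`,
#'   `stickleback_blast`, `previous`.  Absent evidence is `NA`.
#' @export
table2_fixture <- function() {
  .read_tsv(system.file("extdata", "salmon_homeologies.tsv",
                        package = "tetramap", mustWork = TRUE))
}
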