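#' Write paired FASTQ files
#'
#' Writes `<prefix>_R1.fastq` / `<prefix>_R2.fastq` (phred+33, 4-line
#' records), or one pair of files per sample when `per_sample = TRUE`
#' (`<sample>_R1.fastq` etc.). Records are written in input order, so output
#' is byte-stable for a fixed input.
#'
#' @param reads Tibble with `fwd_seq`, `fwd_qual`, `rev_seq`, `rev_qual` and
#'   optionally `read_id`, `sample_id`.
#' @param dir Output directory (created if missing).
#' @param prefix File prefix for the pooled layout (default `"pool"`).
#' @param per_sample Write one file pair per sample (default FALSE).
#' @return Character vector of written paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, dir, prefix = "pool", per_sample = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- as_tibble(reads)
  ids <- reads$read_id %||% sprintf("read%07d", seq_len(nrow(reads)))
  wrt <- function(ids, seqs, quals, path) {
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
    path
  }
  if (per_sample) {
    paths <- purrr::imap(split(seq_len(nrow(reads)), reads$sample_id),
                         function(idx, s) {
      c(wrt(ids[idx], reads$fwd_seq[idx], reads$fwd_qual[idx],
            file.path(dir, paste0(s, "_R1.fastq"))),
        wrt(ids[idx], reads$rev_seq[idx], reads$rev_qual[idx],
            file.path(dir, paste0(s, "_R2.fastq"))))
    })
    return(invisible(unlist(paths)))
  }
  invisible(c(
    wrt(ids, reads$fwd_seq, reads$fwd_qual,
        file.path(dir, paste0(prefix, "_R1.fastq"))),
    wrt(ids, reads$rev_seq, reads$rev_qual,
        file.path(dir, paste0(prefix, "_R2.fastq")))))
}

#' Read paired FASTQ files
#'
#' @param r1,r2 Paths to the forward/reverse FASTQ (gzip transparent when
#'   Biostrings is available).
#' @return Tibble `read_id`, `fwd_seq`, `fwd_qual`, `rev_seq`, `rev_qual`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  rd <- function(path) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      # Biostrings warns about dropping (empty) metadata columns here
      x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
      tibble(read_id = sub("\\s.*$", "", names(x)),
             seq = unname(as.character(x)),
             qual = unname(as.character(Biostrings::quality(x))))
    } else {
      lines <- readLines(path)
      stopifnot(length(lines) %% 4 == 0)
      tibble(read_id = sub("\\s.*$", "", sub("^@", "", lines[c(TRUE, FALSE, FALSE, FALSE)])),
             seq = lines[c(FALSE, TRUE, FALSE, FALSE)],
             qual = lines[c(FALSE, FALSE, FALSE, TRUE)])
    }
  }
  f <- rd(r1); r <- rd(r2)
  if (!identical(f$read_id, r$read_id)) {
    abort("R1/R2 read ids do not match pairwise")
  }
  tibble(read_id = f$read_id, fwd_seq = f$seq, fwd_qual = f$qual,
         rev_seq = r$seq, rev_qual = r$qual)
}

#' Read a barcode table TSV (`sample_id <TAB> barcode`)
#'
#' @param path TSV path with a header line.
#' @return Validated barcode tibble.
#' @export
read_barcodes <- function(path) {
  validate_barcodes(as_tibble(read.delim(path, colClasses = "character")))
}
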