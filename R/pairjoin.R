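#' Overlap-merge parameters
#'
#' @param min_overlap Minimum overlap length considered (default 10).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction within the
#'   overlap (default 0.25).
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(min_overlap = 10L, max_mismatch_frac = 0.25) {
  stopifnot(min_overlap >= 1, max_mismatch_frac >= 0, max_mismatch_frac < 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_frac = max_mismatch_frac),
            class = "merge_params")
}

#' Merge overlapping read pairs
#'
#' Scans candidate overlaps between the 3' end of the forward read and the 5'
#' end of the reverse-complemented reverse read. The longest overlap of length
#' `>= min_overlap` whose mismatch fraction is `<= max_mismatch_frac` wins;
#' within the overlap each position takes the base with the higher quality
#' (tie: forward base). Pairs with no qualifying overlap return `NA`.
#'
#' @param fwd,rev Character vectors of forward / reverse sequences (reverse
#'   given in its sequenced orientation; it is reverse-complemented here).
#' @param fwd_qual,rev_qual Matching phred+33 quality strings.
#' @param params A [merge_params()] object.
#' @return Tibble with columns `merged` (NA when no qualifying overlap) and
#'   `overlap` (chosen overlap length).
#' @export
merge_overlap <- function(fwd, rev, fwd_qual = strrep("I", nchar(fwd)),
                          rev_qual = strrep("I", nchar(rev)),
                          params = merge_params()) {
  res <- cpp_merge_overlap(fwd, revcomp(rev), fwd_qual,
                           stringi::stri_reverse(rev_qual),
                           params$min_overlap, params$max_mismatch_frac)
  tibble(merged = as.character(res$merged), overlap = res$overlap)
}

#' Artificially join a non-overlapping pair
#'
#' Concatenates the forward read and the reverse-complemented reverse read
#' with no separator; the junction index records where the forward part ends
#' (0-based offset of the first reverse-derived base).
#'
#' @param fwd,rev Character vectors (trimmed to the target lengths).
#' @return Character vector of joined sequences of length
#'   `nchar(fwd) + nchar(rev)`.
#' @export
join_pair <- function(fwd, rev) paste0(fwd, revcomp(rev))

#' Pad a merged sequence to the uniform joined length
#'
#' Merged overlapping pairs are shorter than artificially joined pairs; they
#' are extended at the 3' end with `A`s so all reads in a run share one
#' uniform length (a prerequisite of stack clustering).
#'
#' @param merged_seq Character vector of merged sequences.
#' @param l_uniform Target uniform length.
#' @return Tibble with `sequence` (NA where the merged sequence exceeded
#'   `l_uniform`; such reads are artifacts and are dropped) and `pad_len`.
#' @export
pad_to_length <- function(merged_seq, l_uniform) {
  pad <- l_uniform - nchar(merged_seq)
  seq <- ifelse(pad >= 0, paste0(merged_seq, strrep("A", pmax(pad, 0))), NA_character_)
  tibble(sequence = seq, pad_len = ifelse(pad >= 0, pad, NA_integer_))
}

#' Convert trimmed read pairs into uniform-length joined reads
#'
#' Each pair is first checked against the expected trimmed lengths (pairs with
#' a short mate are dropped pairwise), then overlap-merged where possible and
#' A-padded to the joined length, otherwise artificially joined
#' (forward + reverse-complemented reverse, no separator). All emitted reads
#' have length `target_len_fwd + target_len_rev`.
#'
#' @param reads Trimmed pairs from [trim_equalize()]; columns `sample_id`,
#'   `fwd_seq`, `fwd_qual`, `rev_seq`, `rev_qual` (plus optional `read_id`).
#' @param target_len_fwd,target_len_rev Expected trimmed lengths. Default:
#'   taken from the attributes [trim_equalize()] left on `reads`.
#' @param merge Attempt overlap merging before joining (default TRUE).
#' @param params A [merge_params()] object.
#' @return Tibble with columns `sample_id`, `read_id` (if present),
#'   `sequence`, `kind` (`"merged"` or `"joined"`), `junction_index` (0-based,
#'   `NA` for merged reads) and `pad_len` (0 for joined reads). Attribute
#'   `n_dropped` counts pairs removed for length violations or over-long
#'   merges.
#' @export
join_reads <- function(reads,
                       target_len_fwd = attr(reads, "target_len_fwd"),
                       target_len_rev = attr(reads, "target_len_rev"),
                       merge = TRUE, params = merge_params()) {
  reads <- as_tibble(reads)
  if (is.null(target_len_fwd) || is.null(target_len_rev)) {
    abort("target lengths missing: pass target_len_fwd/target_len_rev")
  }
  ok <- nchar(reads$fwd_seq) == target_len_fwd & nchar(reads$rev_seq) == target_len_rev
  n_dropped <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  l_uniform <- target_len_fwd + target_len_rev

  merged <- rep(NA_character_, nrow(reads))
  if (merge && nrow(reads)) {
    merged <- merge_overlap(reads$fwd_seq, reads$rev_seq,
                            reads$fwd_qual, reads$rev_qual, params)$merged
  }
  is_merged <- !is.na(merged)
  sequence <- character(nrow(reads))
  pad_len <- integer(nrow(reads))
  junction <- rep(NA_integer_, nrow(reads))
  if (any(is_merged)) {
    padded <- pad_to_length(merged[is_merged], l_uniform)
    sequence[is_merged] <- padded$sequence
    pad_len[is_merged] <- padded$pad_len
  }
  if (any(!is_merged)) {
    sequence[!is_merged] <- join_pair(reads$fwd_seq[!is_merged],
                                      reads$rev_seq[!is_merged])
    junction[!is_merged] <- as.integer(target_len_fwd)
  }
  keep_cols <- intersect(c("sample_id", "read_id", "barcode"), names(reads))
  out <- bind_cols(reads[keep_cols],
                   tibble(sequence = sequence,
                          kind = ifelse(is_merged, "merged", "joined"),
                          junction_index = junction,
                          pad_len = pad_len))
  # merged sequence longer than the joined length is geometrically impossible
  # for a true overlap; treat as artifact and drop
  bad <- is.na(out$sequence)
  n_dropped <- n_dropped + sum(bad)
  out <- out[!bad, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  attr(out, "l_uniform") <- as.integer(l_uniform)
  attr(out, "target_len_fwd") <- as.integer(target_len_fwd)
  out
}
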