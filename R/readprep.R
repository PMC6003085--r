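#' Validate a barcode table
#'
#' @param barcodes A data frame with columns `sample_id` and `barcode`
#'   (5-10 nt, unique, alphabet ACGT).
#' @return The validated table as a tibble, invisibly usable downstream.
#' @export
validate_barcodes <- function(barcodes) {
  barcodes <- as_tibble(barcodes)
  if (!all(c("sample_id", "barcode") %in% names(barcodes))) {
    abort("barcode table needs columns 'sample_id' and 'barcode'")
  }
  if (anyDuplicated(barcodes$barcode)) {
    abort("duplicate barcodes in barcode table")
  }
  if (anyDuplicated(barcodes$sample_id)) {
    abort("duplicate sample ids in barcode table")
  }
  len <- nchar(barcodes$barcode)
  if (any(len < 5 | len > 10)) abort("barcode lengths must be within [5, 10]")
  check_dna(barcodes$barcode, "barcode")
  if (any(grepl("N", barcodes$barcode, fixed = TRUE))) {
    abort("barcodes may not contain N")
  }
  barcodes
}

#' Demultiplex paired-end GBS reads by inline barcode
#'
#' A forward read is assigned to a sample when it begins with that sample's
#' barcode immediately followed by the rare-cutter remnant (PstI `TGCAG` by
#' default). Barcodes are matched exactly, longest first, so prefix-nested
#' barcodes resolve to the longest match. Reverse reads are not checked for a
#' restriction site. Pairs failing the check (including any `N` in the
#' barcode/remnant window) are rejected.
#'
#' @param pairs A data frame of read pairs with columns `fwd_seq`, `fwd_qual`,
#'   `rev_seq`, `rev_qual` and optionally `read_id`.
#' @param barcodes Barcode table (`sample_id`, `barcode`), see
#'   [validate_barcodes()].
#' @param site_remnant Restriction-site remnant expected right after the
#'   barcode (default `"TGCAG"`, the PstI remnant).
#' @return A tibble of assigned pairs with `sample_id` and `barcode` columns
#'   prepended. Attributes: `rejects` (tibble of unassigned pairs) and
#'   `summary` (per-sample assigned counts plus a `<rejected>` row).
#' @export
demultiplex <- function(pairs, barcodes, site_remnant = "TGCAG") {
  barcodes <- validate_barcodes(barcodes)
  pairs <- as_tibble(pairs)
  # any pre-existing assignment columns (e.g. simulation truth) are replaced
  pairs <- pairs[setdiff(names(pairs), c("sample_id", "barcode"))]
  if (nrow(pairs) == 0) {
    warn("demultiplex: empty input")
    out <- bind_cols(tibble(sample_id = character(), barcode = character()), pairs)
    attr(out, "rejects") <- pairs
    attr(out, "summary") <- tibble(sample_id = character(), n = integer())
    return(out)
  }
  rl <- nchar(site_remnant)
  sample_id <- rep(NA_character_, nrow(pairs))
  barcode <- rep(NA_character_, nrow(pairs))
  for (bl in sort(unique(nchar(barcodes$barcode)), decreasing = TRUE)) {
    open <- which(is.na(sample_id))
    if (!length(open)) break
    bset <- filter(barcodes, nchar(.data$barcode) == bl)
    hit <- match(substr(pairs$fwd_seq[open], 1L, bl), bset$barcode)
    ok <- !is.na(hit) &
      substr(pairs$fwd_seq[open], bl + 1L, bl + rl) == site_remnant
    sample_id[open[ok]] <- bset$sample_id[hit[ok]]
    barcode[open[ok]] <- bset$barcode[hit[ok]]
  }
  keep <- !is.na(sample_id)
  out <- bind_cols(tibble(sample_id = sample_id[keep], barcode = barcode[keep]),
                   pairs[keep, , drop = FALSE])
  smry <- count(out, .data$sample_id)
  smry <- bind_rows(smry, tibble(sample_id = "<rejected>", n = sum(!keep)))
  attr(out, "rejects") <- pairs[!keep, , drop = FALSE]
  attr(out, "summary") <- smry
  out
}

#' Trimming parameters
#'
#' @param site_remnant Rare-cutter remnant on the forward read (removed).
#' @param tail_trim Fixed number of error-prone bases removed from the 3' end
#'   of every read (default 5).
#' @param target_len_fwd,target_len_rev Uniform lengths all forward/reverse
#'   reads are equalised to. `NULL` derives them from the data: raw length
#'   minus the longest barcode, remnant and tail (forward), raw length minus
#'   tail (reverse).
#' @param second_remnant Length of a second-enzyme remnant to strip from the
#'   5' end of reverse reads (default 0: reverse reads are not site-checked).
#' @return A list of class `trim_params`.
#' @export
trim_params <- function(site_remnant = "TGCAG", tail_trim = 5L,
                        target_len_fwd = NULL, target_len_rev = NULL,
                        second_remnant = 0L) {
  stopifnot(nchar(site_remnant) > 0, tail_trim >= 0, second_remnant >= 0)
  structure(list(site_remnant = site_remnant, tail_trim = as.integer(tail_trim),
                 target_len_fwd = target_len_fwd, target_len_rev = target_len_rev,
                 second_remnant = as.integer(second_remnant)),
            class = "trim_params")
}

#' Trim demultiplexed pairs to uniform lengths
#'
#' Forward reads lose the barcode, the restriction-site remnant, the 3' tail
#' and any equalisation bases so every forward read ends up `target_len_fwd`
#' long regardless of barcode length; reverse reads lose the 3' tail (and a
#' second-enzyme remnant if configured) down to `target_len_rev`. Qualities
#' are trimmed in lockstep. Pairs too short for the required trims are dropped
#' pairwise and counted.
#'
#' @param reads Output of [demultiplex()] (must carry a `barcode` column).
#' @param params A [trim_params()] object.
#' @return Tibble of trimmed pairs. Attributes: `n_dropped`, and the resolved
#'   `target_len_fwd` / `target_len_rev`.
#' @export
trim_equalize <- function(reads, params = trim_params()) {
  reads <- as_tibble(reads)
  stopifnot("barcode" %in% names(reads))
  rl <- nchar(params$site_remnant)
  bl <- nchar(reads$barcode)
  tf <- params$target_len_fwd %||%
    (min(nchar(reads$fwd_seq) - bl) - rl - params$tail_trim)
  tr <- params$target_len_rev %||%
    (min(nchar(reads$rev_seq)) - params$second_remnant - params$tail_trim)
  if (tf <= 0 || tr <= 0) abort("trim targets must be positive")
  ok <- (nchar(reads$fwd_seq) - bl - rl - params$tail_trim >= tf) &
    (nchar(reads$rev_seq) - params$second_remnant - params$tail_trim >= tr)
  dropped <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  bl <- bl[ok]
  f0 <- bl + rl + 1L
  out <- mutate(reads,
    fwd_seq = substr(.data$fwd_seq, f0, f0 + tf - 1L),
    fwd_qual = substr(.data$fwd_qual, f0, f0 + tf - 1L),
    rev_seq = substr(.data$rev_seq, params$second_remnant + 1L,
                     params$second_remnant + tr),
    rev_qual = substr(.data$rev_qual, params$second_remnant + 1L,
                      params$second_remnant + tr))
  attr(out, "n_dropped") <- dropped
  attr(out, "target_len_fwd") <- as.integer(tf)
  attr(out, "target_len_rev") <- as.integer(tr)
  out
}
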