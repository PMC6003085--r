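# Genotype-code algebra.
#
# F2 genotype codes carry allele-set semantics over the three true genotype
# classes {P1 homozygote, heterozygote, P2 homozygote}, encoded as a bitmask
# P1hom = 1, het = 2, P2hom = 4:
#   A = {P1hom}, B = {P2hom}, H = {het}, D = {P1hom, het} (ambiguous A-or-H),
#   C = {P2hom, het} (ambiguous B-or-H), '-' = anything, F = conflict.
# Consolidation of codes is set intersection; an empty intersection is the
# conflict flag F. As an *input* to set operations F carries no information
# and is treated like '-' (missing).

GENO_CODES <- c("A", "H", "B", "D", "C", "-", "F")

.code_to_mask <- c(A = 1L, H = 2L, B = 4L, D = 3L, C = 6L, `-` = 7L, F = 7L)
.mask_to_code <- c("F", "A", "H", "D", "B", NA, "C", "-")  # index = mask + 1

#' Convert genotype codes to allele-set bitmasks
#'
#' The bitmask encodes which true F2 genotype classes a code is compatible
#' with: P1 homozygote = 1, heterozygote = 2, P2 homozygote = 4. `C` and `D`
#' are the ambiguous codes, `-` (and the conflict flag `F`, once flagged) are
#' compatible with everything.
#'
#' @param codes Character vector of codes in `{A,B,H,C,D,-,F}`.
#' @return Integer vector of bitmasks in `1:7`.
#' @export
code_mask <- function(codes) {
  m <- unname(.code_to_mask[codes])
  if (anyNA(m)) {
    bad <- codes[is.na(m)]
    abort(sprintf("unknown genotype code: '%s'", bad[1]))
  }
  m
}

#' Convert allele-set bitmasks back to genotype codes
#'
#' The inverse of [code_mask()]; mask 0 (the empty set) maps to the conflict
#' flag `F`. Mask 5 ({P1hom, P2hom}) is not representable and errors.
#'
#' @param masks Integer vector of bitmasks in `0:7`.
#' @return Character vector of codes.
#' @export
mask_code <- function(masks) {
  if (any(masks == 5L)) abort("mask 5 ({P1hom, P2hom}) has no genotype code")
  .mask_to_code[masks + 1L]
}

#' Flip marker polarity (parent-1 <-> parent-2 allele)
#'
#' Swaps A with B and C with D so that `A` always denotes the parent-1 allele.
#' `H`, `-` and `F` are unchanged. Flipping twice is the identity.
#'
#' @param codes Character vector of genotype codes.
#' @return Character vector with polarity flipped.
#' @export
flip_codes <- function(codes) {
  chartr("ABCD", "BADC", codes)
}
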