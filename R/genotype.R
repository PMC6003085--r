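#' Count allelic depths by aligning joined reads to the reference
#'
#' A desk-scale, ungapped stand-in for an external aligner + variant caller:
#' each read is assigned to the unique nearest reference tag within
#' `max_mismatches` Hamming distance (ties across tags discard the read).
#' Per tag, a column is a variant site when at least two bases reach pooled
#' depth `min_site_depth` and the most frequent non-reference base accounts
#' for at least `min_alt_frac` of the pooled column depth (a caller-like
#' prefilter against raw sequencing error; the genuine allele-frequency filter
#' is [filter_af()]). At each site the reference allele is the tag's base and
#' the alternate allele the most frequent other base.
#'
#' @param reads Joined reads for all samples (columns `sample_id`, `sequence`).
#' @param reference Reference tags ([build_reference()]).
#' @param max_mismatches Maximum Hamming distance for read assignment
#'   (default 3).
#' @param min_site_depth Pooled depth each of two bases must reach (default 2).
#' @param min_alt_frac Minimum pooled fraction of the alternate base
#'   (default 0.05).
#' @return Long tibble of allelic depths: `tag_id`, `offset` (0-based),
#'   `ref_allele`, `alt_allele`, `sample_id`, `ad_ref`, `ad_alt`. Attributes:
#'   `n_unassigned` (reads with no unique tag within range), `samples`.
#' @export
count_alleles <- function(reads, reference, max_mismatches = 3L,
                          min_site_depth = 2L, min_alt_frac = 0.05) {
  reads <- as_tibble(reads)
  if (length(unique(nchar(reference$sequence))) > 1 ||
      (nrow(reads) && any(nchar(reads$sequence) != nchar(reference$sequence[1])))) {
    abort("reads and reference tags must share one uniform length")
  }
  samples <- sort(unique(reads$sample_id))
  asg <- cpp_assign_nearest(reads$sequence, reference$sequence, max_mismatches)
  res <- cpp_count_alleles(reads$sequence, asg$idx,
                           match(reads$sample_id, samples),
                           reference$sequence, length(samples),
                           as.integer(min_site_depth), min_alt_frac)
  n_sites <- length(res$tag_idx)
  out <- tibble(
    tag_id = rep(reference$tag_id[res$tag_idx], each = length(samples)),
    offset = rep(res$offset, each = length(samples)),
    ref_allele = rep(as.character(res$ref), each = length(samples)),
    alt_allele = rep(as.character(res$alt), each = length(samples)),
    sample_id = rep(samples, times = n_sites),
    ad_ref = as.integer(t(res$ad_ref)),
    ad_alt = as.integer(t(res$ad_alt)))
  attr(out, "n_unassigned") <- sum(is.na(asg$idx))
  attr(out, "samples") <- samples
  out
}

#' Ingest allelic depths from VCF files
#'
#' Reads one or more VCF v4.x files whose CHROM values are reference tag ids
#' and converts biallelic records (SNPs and anchored indels alike) to the long
#' allelic-depth format, shifting 1-based POS to 0-based offsets. Multiallelic
#' and symbolic-allele records are dropped and counted. Sites from multiple
#' files are unioned by (tag, offset, alleles); the first file providing a
#' site wins.
#'
#' @param paths Character vector of VCF paths (FORMAT/AD mandatory).
#' @return Long allelic-depth tibble as in [count_alleles()]. Attribute
#'   `n_dropped_multiallelic`.
#' @export
ingest_vcf <- function(paths) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("ingest_vcf requires the vcfR package")
  }
  n_multi <- 0L
  parts <- purrr::map(paths, function(p) {
    v <- vcfR::read.vcfR(p, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    bial <- !grepl(",", fix$ALT, fixed = TRUE) &
      !grepl("[<>*]", fix$ALT) & !grepl("[<>*]", fix$REF) &
      !is.na(fix$ALT) & fix$ALT != "."
    n_multi <<- n_multi + sum(!bial)
    if (!any(bial)) return(NULL)
    if (is.null(v@gt) || !"FORMAT" %in% colnames(v@gt)) {
      abort(sprintf("%s carries no FORMAT/genotype columns", p))
    }
    has_ad <- vapply(strsplit(unname(v@gt[bial, "FORMAT"]), ":", fixed = TRUE),
                     function(f) "AD" %in% f, logical(1))
    if (!all(has_ad)) {
      i <- which(!has_ad)[1]
      abort(sprintf("record %s:%s in %s has no FORMAT/AD field",
                    fix$CHROM[bial][i], fix$POS[bial][i], p))
    }
    ad <- vcfR::extract.gt(v, element = "AD")[bial, , drop = FALSE]
    smp <- colnames(ad)
    ref_n <- suppressWarnings(
      matrix(as.integer(vapply(strsplit(as.vector(ad), ",", fixed = TRUE),
                               function(x) x[1], character(1))), nrow = nrow(ad)))
    alt_n <- suppressWarnings(
      matrix(as.integer(vapply(strsplit(as.vector(ad), ",", fixed = TRUE),
                               function(x) if (length(x) >= 2) x[2] else NA_character_,
                               character(1))), nrow = nrow(ad)))
    ref_n[is.na(ref_n)] <- 0L  # "." genotypes carry no depth
    alt_n[is.na(alt_n)] <- 0L
    tibble(tag_id = rep(fix$CHROM[bial], times = length(smp)),
           offset = rep(as.integer(fix$POS[bial]) - 1L, times = length(smp)),
           ref_allele = rep(fix$REF[bial], times = length(smp)),
           alt_allele = rep(fix$ALT[bial], times = length(smp)),
           sample_id = rep(smp, each = sum(bial)),
           ad_ref = as.integer(ref_n), ad_alt = as.integer(alt_n))
  })
  out <- bind_rows(parts)
  out <- distinct(out, .data$tag_id, .data$offset, .data$ref_allele,
                  .data$alt_allele, .data$sample_id, .keep_all = TRUE)
  attr(out, "n_dropped_multiallelic") <- n_multi
  attr(out, "samples") <- sort(unique(out$sample_id))
  out
}

#' Filter sites by pooled allele frequency
#'
#' Retains sites whose pooled (across-sample) alternate-allele frequency lies
#' within `[af_min, af_max]`, boundaries inclusive. Sites with zero pooled
#' depth are dropped.
#'
#' @param ad Long allelic-depth tibble.
#' @param af_min,af_max Frequency bounds (defaults 0.10 and 0.90).
#' @return Filtered tibble.
#' @export
filter_af <- function(ad, af_min = 0.10, af_max = 0.90) {
  keep <- summarise(group_by(ad, .data$tag_id, .data$offset),
                    af = sum(.data$ad_alt) / (sum(.data$ad_ref) + sum(.data$ad_alt)),
                    .groups = "drop")
  keep <- filter(keep, !is.nan(.data$af), .data$af >= af_min, .data$af <= af_max)
  semi_join(ad, keep, by = c("tag_id", "offset"))
}

#' Remove adjacent SNPs
#'
#' Any site with another site at offset distance exactly 1 on the same tag is
#' removed — both members of each adjacent pair, and whole runs. Adjacent
#' calls are typically misalignment artifacts (e.g. small deletions read
#' through the forward/reverse junction). Idempotent.
#'
#' @param ad Long allelic-depth tibble.
#' @return Filtered tibble.
#' @export
remove_adjacent <- function(ad) {
  sites <- distinct(ad, .data$tag_id, .data$offset)
  sites <- group_by(arrange(sites, .data$tag_id, .data$offset), .data$tag_id)
  sites <- ungroup(mutate(sites,
    adj = (!is.na(lag(.data$offset)) & .data$offset - lag(.data$offset) == 1L) |
          (!is.na(lead(.data$offset)) & lead(.data$offset) - .data$offset == 1L)))
  anti_join(ad, filter(sites, .data$adj), by = c("tag_id", "offset"))
}

#' Remove SNPs flanking the forward/reverse junction
#'
#' For artificially joined tags, sites at the last forward-read offset
#' (`junction_index - 1`) and the first reverse-read offset (`junction_index`)
#' are removed: reads from alleles carrying a deletion extend past the
#' junction and generate spurious calls exactly there. Merged tags are
#' unaffected.
#'
#' @param ad Long allelic-depth tibble.
#' @param reference Reference tags carrying `kind` and `junction_index`.
#' @return Filtered tibble.
#' @export
remove_junction_flanking <- function(ad, reference) {
  jx <- filter(as_tibble(reference), .data$kind == "joined",
               !is.na(.data$junction_index))
  bad <- bind_rows(
    tibble(tag_id = jx$tag_id, offset = jx$junction_index - 1L),
    tibble(tag_id = jx$tag_id, offset = jx$junction_index))
  anti_join(ad, bad, by = c("tag_id", "offset"))
}

#' Genotype-scoring parameters
#'
#' @param min_total_depth Minimum total allelic depth to call anything
#'   (default 8; below it the cell is missing `-`).
#' @param r_a Ratio at or above which a call is `A` (default 10).
#' @param r_b Ratio at or below which a call is `B` (default 0.10).
#' @param d_band,c_band Open intervals of the ratio mapped to the ambiguous
#'   codes `D` (A-or-H, default (4, 10)) and `C` (B-or-H, default (0.1, 0.25)).
#' @return A list of class `score_params`.
#' @export
score_params <- function(min_total_depth = 8L, r_a = 10, r_b = 0.10,
                         d_band = c(4, 10), c_band = c(0.1, 0.25)) {
  stopifnot(min_total_depth >= 1, r_a >= d_band[2],
            d_band[1] < d_band[2], c_band[1] < c_band[2])
  structure(list(min_total_depth = as.integer(min_total_depth), r_a = r_a,
                 r_b = r_b, d_band = d_band, c_band = c_band),
            class = "score_params")
}

#' Score genotype codes from allelic depths
#'
#' With `r = AD_ref / AD_alt` (both depths integer; `AD_alt == 0` gives
#' `r = Inf`): total depth below `min_total_depth` is missing `-`; `r >= 10`
#' is `A`; `r <= 0.10` is `B`; `4 < r < 10` is `D`; `0.1 < r < 0.25` is `C`;
#' every other ratio is `H`. Boundaries are evaluated exactly on the integer
#' cross-products, so e.g. `r == 4` and `r == 0.25` fall to `H` and
#' `r == 0.10` to `B`.
#'
#' @param ad_ref,ad_alt Integer vectors of reference/alternate depths.
#' @param params A [score_params()] object.
#' @return Character vector of codes in `{A,B,H,C,D,-}`.
#' @export
score_genotype <- function(ad_ref, ad_alt, params = score_params()) {
  total <- ad_ref + ad_alt
  out <- rep("H", length(total))
  # exact boundary arithmetic: compare cross-products, never the quotient
  out[ad_ref >= params$r_a * ad_alt & ad_ref > 0] <- "A"
  out[ad_ref <= params$r_b * ad_alt & ad_alt > 0] <- "B"
  d <- ad_ref > params$d_band[1] * ad_alt & ad_ref < params$d_band[2] * ad_alt
  out[d] <- "D"
  cc <- ad_ref > params$c_band[1] * ad_alt & ad_ref < params$c_band[2] * ad_alt
  out[cc] <- "C"
  out[total < params$min_total_depth] <- "-"
  out
}

#' Build the genotype matrix from allelic depths
#'
#' Applies [score_genotype()] to every site x sample cell and pivots to a wide
#' markers-by-samples tibble. Marker ids are `tag_id:offset`.
#'
#' @param ad Long allelic-depth tibble.
#' @param params A [score_params()] object.
#' @return Wide tibble: `marker_id`, `tag_id`, `offset`, then one column per
#'   sample with codes in `{A,B,H,C,D,-}`.
#' @export
score_matrix <- function(ad, params = score_params()) {
  ad <- mutate(ad, code = score_genotype(.data$ad_ref, .data$ad_alt, params),
               marker_id = paste0(.data$tag_id, ":", .data$offset))
  wide <- tidyr::pivot_wider(
    ad[, c("marker_id", "tag_id", "offset", "sample_id", "code")],
    names_from = "sample_id", values_from = "code", values_fill = "-")
  arrange(wide, .data$tag_id, .data$offset)
}

# sample columns of a genotype matrix
geno_samples <- function(geno) {
  setdiff(names(geno), c("marker_id", "tag_id", "offset"))
}

#' Keep markers segregating between the parents and fix polarity
#'
#' Retains markers where the two parents are homozygous for different alleles
#' ({A, B}); markers where parent 1 carries the alternate allele are
#' polarity-flipped (A<->B, C<->D) so that `A` always means the parent-1
#' allele.
#'
#' @param geno Wide genotype matrix ([score_matrix()]).
#' @param parent1,parent2 Parent column names.
#' @return Filtered (and possibly flipped) genotype matrix.
#' @export
select_by_parents <- function(geno, parent1, parent2) {
  if (!all(c(parent1, parent2) %in% names(geno))) {
    abort("parent column(s) missing from the genotype matrix")
  }
  p1 <- geno[[parent1]]; p2 <- geno[[parent2]]
  keep <- (p1 == "A" & p2 == "B") | (p1 == "B" & p2 == "A")
  geno <- geno[keep, , drop = FALSE]
  flip <- geno[[parent1]] == "B"
  scols <- geno_samples(geno)
  geno[flip, scols] <- lapply(geno[flip, scols, drop = FALSE], flip_codes)
  geno
}

#' Filter markers and samples by missingness and allele balance
#'
#' Drops markers missing in more than `max_missing` of the samples or whose
#' definitive-call balance `nA / (nA + nB)` falls outside `[ab_min, ab_max]`
#' (boundaries kept), then drops samples missing in more than `max_missing`
#' of the surviving markers.
#'
#' @param geno Wide genotype matrix.
#' @param max_missing Missing-fraction ceiling (default 0.30).
#' @param ab_min,ab_max Allele-balance bounds (defaults 0.10, 0.90).
#' @param samples Sample columns to consider (default: all).
#' @return Filtered matrix. Attributes `dropped_markers`, `dropped_samples`.
#' @export
filter_markers_samples <- function(geno, max_missing = 0.30,
                                   ab_min = 0.10, ab_max = 0.90,
                                   samples = NULL) {
  scols <- samples %||% geno_samples(geno)
  m <- as.matrix(geno[, scols, drop = FALSE])
  miss <- rowMeans(m == "-" | m == "F")
  nA <- rowSums(m == "A"); nB <- rowSums(m == "B")
  ab <- nA / (nA + nB)
  keep <- miss <= max_missing & !is.nan(ab) & ab >= ab_min & ab <= ab_max
  dropped_markers <- geno$marker_id[!keep]
  geno <- geno[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  smiss <- colMeans(m == "-" | m == "F")
  bad_samples <- scols[smiss > max_missing]
  geno <- geno[, setdiff(names(geno), bad_samples), drop = FALSE]
  if (nrow(geno) == 0) warn("all markers removed by filtering")
  attr(geno, "dropped_markers") <- dropped_markers
  attr(geno, "dropped_samples") <- bad_samples
  geno
}

#' Write / read a genotype matrix TSV
#'
#' @param geno Wide genotype matrix.
#' @param path TSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_geno <- function(geno, path) {
  write.table(geno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno
#' @export
read_geno <- function(path) {
  out <- as_tibble(read.delim(path, check.names = FALSE,
                              colClasses = "character"))
  if ("offset" %in% names(out)) out$offset <- as.integer(out$offset)
  out
}
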