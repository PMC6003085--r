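#' Consolidate genotype codes for one sample across one tag's SNPs
#'
#' Codes carry allele-set semantics (see [code_mask()]); consolidation is the
#' intersection of all sets. A combination like {A, D, -} therefore
#' consolidates to A, {B, C, -} to B, {H, C, D, -} to H, while conflicting
#' combinations (A with B, A with C, A with H, B with H, B with D) have an
#' empty intersection and are flagged `F`. Commutative, associative and
#' idempotent.
#'
#' @param codes Character vector of codes observed at one sample across the
#'   SNPs of one tag.
#' @return A single consolidated code (possibly `"F"`).
#' @export
consolidate_cell <- function(codes) {
  if (!length(codes)) abort("consolidate_cell: no codes")
  mask_code(Reduce(bitwAnd, code_mask(codes)))
}

#' Consolidate a genotype matrix to one marker per tag
#'
#' Applies [consolidate_cell()] per sample within each `tag_id` group. The
#' output keeps conflict flags `F` so that conflicted tags can be screened
#' with [remove_conflicted_tags()]; `F` is treated as missing downstream.
#'
#' @param geno Wide genotype matrix with a `tag_id` column.
#' @return Wide matrix with one row per tag (`marker_id == tag_id`).
#' @export
consolidate_matrix <- function(geno) {
  scols <- geno_samples(geno)
  masks <- vapply(geno[scols], code_mask, integer(nrow(geno)))
  if (nrow(geno) == 1L) masks <- matrix(masks, nrow = 1, dimnames = list(NULL, scols))
  grp <- factor(geno$tag_id, levels = unique(geno$tag_id))
  cons <- matrix(0L, nlevels(grp), length(scols))
  for (s in seq_along(scols)) {
    cons[, s] <- vapply(split(masks[, s], grp), function(m) Reduce(bitwAnd, m),
                        integer(1))
  }
  out <- tibble(marker_id = levels(grp), tag_id = levels(grp))
  out[scols] <- lapply(seq_along(scols), function(s) mask_code(cons[, s]))
  out
}

#' Remove tags with widespread conflicting scores
#'
#' Drops consolidated tag markers whose conflict-flag (`F`) fraction across
#' the progeny is at or above `max_conflict_frac` (boundary removed: "20% or
#' more"); surviving `F` cells are converted to missing `-`.
#'
#' @param geno Consolidated matrix ([consolidate_matrix()]).
#' @param max_conflict_frac Conflict-fraction threshold (default 0.20).
#' @param progeny Sample columns counted as progeny (default: all samples).
#' @return Filtered matrix with `F` converted to `-`. Attribute
#'   `dropped_tags`.
#' @export
remove_conflicted_tags <- function(geno, max_conflict_frac = 0.20,
                                   progeny = NULL) {
  scols <- progeny %||% geno_samples(geno)
  m <- as.matrix(geno[, scols, drop = FALSE])
  frac <- rowMeans(m == "F")
  dropped <- geno$marker_id[frac >= max_conflict_frac]
  geno <- geno[frac < max_conflict_frac, , drop = FALSE]
  all_s <- geno_samples(geno)
  geno[all_s] <- lapply(geno[all_s], function(x) replace(x, x == "F", "-"))
  attr(geno, "dropped_tags") <- dropped
  geno
}

#' Merge duplicated samples
#'
#' Replicate columns are merged with the consolidation rules: per marker the
#' merged cell is the allele-set intersection of the two replicates; an empty
#' intersection (e.g. A vs B) is a disagreement, entered as missing `-` and
#' counted.
#'
#' @param geno Wide genotype matrix.
#' @param replicate_pairs Data frame with columns `keep` and `drop`: the
#'   replicate column `drop` is merged into `keep` and removed.
#' @return Matrix with merged columns. Attribute `disagreement_rate`
#'   (disagreements / compared cells, where both cells informative).
#' @export
merge_duplicate_samples <- function(geno, replicate_pairs) {
  replicate_pairs <- as_tibble(replicate_pairs)
  missing_cols <- setdiff(c(replicate_pairs$keep, replicate_pairs$drop), names(geno))
  if (length(missing_cols)) {
    abort(sprintf("unknown replicate column: %s", missing_cols[1]))
  }
  n_disagree <- 0L; n_compared <- 0L
  for (k in seq_len(nrow(replicate_pairs))) {
    a <- geno[[replicate_pairs$keep[k]]]
    b <- geno[[replicate_pairs$drop[k]]]
    mk <- bitwAnd(code_mask(a), code_mask(b))
    merged <- rep("-", length(mk))
    merged[mk > 0] <- mask_code(mk[mk > 0])
    n_compared <- n_compared + length(mk)
    n_disagree <- n_disagree + sum(mk == 0L)
    geno[[replicate_pairs$keep[k]]] <- merged
  }
  geno <- geno[, setdiff(names(geno), replicate_pairs$drop), drop = FALSE]
  attr(geno, "disagreement_rate") <-
    if (n_compared > 0) n_disagree / n_compared else NA_real_
  geno
}

#' Penalty score of marker genotype vectors
#'
#' Ambiguous codes `C`/`D` cost 1, missing `-` (and the conflict flag `F`,
#' treated as missing) cost 2; definitive codes cost 0.
#'
#' @param codes Character vector of genotype codes for one marker.
#' @param ambiguous_penalty,missing_penalty Penalty weights (defaults 1, 2).
#' @return Integer penalty (sum over samples).
#' @export
marker_penalty <- function(codes, ambiguous_penalty = 1L, missing_penalty = 2L) {
  sum((codes %in% c("C", "D")) * ambiguous_penalty +
      (codes %in% c("-", "F")) * missing_penalty)
}

#' Deduplicate cosegregating markers
#'
#' Markers are sorted by ascending penalty (ties by marker id) and scanned
#' greedily: each marker joins the first representative whose genotype vector
#' is compatible with its own (allele-set intersection non-empty at every
#' sample), otherwise it becomes a new representative. Because of the scan
#' order, each representative has the smallest penalty in its class. Two
#' markers differing by a definitive A-vs-B call at any sample are never
#' merged. The membership map allows cosegregating markers to be re-attached
#' after mapping.
#'
#' @param geno Wide genotype matrix.
#' @param samples Sample columns used for comparison (default: all).
#' @return List: `representatives` (matrix rows of the representatives) and
#'   `membership` (tibble `representative_id`, `member_id`, including the
#'   representative itself).
#' @export
dedup_cosegregating <- function(geno, samples = NULL) {
  scols <- samples %||% geno_samples(geno)
  m <- as.matrix(geno[, scols, drop = FALSE])
  pen <- apply(m, 1, marker_penalty)
  ord <- order(pen, geno$marker_id, method = "radix")
  masks <- matrix(code_mask(m), nrow = nrow(m))[ord, , drop = FALSE]
  ids <- geno$marker_id[ord]
  rep_rows <- integer(0)            # row indices (into ord) of representatives
  rep_of <- character(length(ids))
  rep_masks <- NULL                 # matrix reps x samples
  for (i in seq_along(ids)) {
    if (length(rep_rows)) {
      inter <- matrix(bitwAnd(as.integer(rep_masks),
                              rep(masks[i, ], each = nrow(rep_masks))),
                      nrow = nrow(rep_masks))
      compat <- which(rowSums(inter == 0L) == 0)
      if (length(compat)) {
        rep_of[i] <- ids[rep_rows[compat[1]]]
        next
      }
    }
    rep_rows <- c(rep_rows, i)
    rep_masks <- rbind(rep_masks, masks[i, ])
    rep_of[i] <- ids[i]
  }
  reps <- geno[match(ids[rep_rows], geno$marker_id), , drop = FALSE]
  list(representatives = reps,
       membership = tibble(representative_id = rep_of, member_id = ids))
}
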