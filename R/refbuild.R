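#' Filter cross-sample clusters by sample presence
#'
#' Keeps clusters present in at least `presence_pct` percent of samples
#' (boundary equality retained: tags present in *less than* the threshold are
#' removed).
#'
#' @param clusters Tibble with a `presence_count` column ([asustacks()]).
#' @param n_samples_total Total number of samples in the run.
#' @param presence_pct Presence threshold in percent (study values 50 and 70).
#' @return Filtered tibble.
#' @export
filter_by_presence <- function(clusters, n_samples_total, presence_pct = 50) {
  if (n_samples_total == 0) abort("n_samples_total must be positive")
  stopifnot(presence_pct > 0, presence_pct <= 100)
  if (any(clusters$presence_count > n_samples_total)) {
    abort("presence_count exceeds n_samples_total")
  }
  filter(clusters, .data$presence_count / n_samples_total >= presence_pct / 100)
}

# Percent identity between two tags. Equal lengths: matches / length.
# Unequal lengths: end-free (overlap) alignment, matches / alignment columns.
pair_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    return(100 * (nchar(a) - cpp_hamming(a, b)) / nchar(a))
  }
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for identity between unequal-length tags")
  }
  al <- Biostrings::pairwiseAlignment(a, b, type = "overlap")
  100 * Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Collapse near-identical reference tags
#'
#' Computes pairwise identity between tags and builds a graph with edges where
#' identity is at or above `identity_pct`; within each connected component a
#' single tag is retained — the one with the highest `presence_count`, ties
#' broken by the alphabetically smallest `tag_id`. Collapsing is transitive
#' (component-wise), so chains A~B~C collapse to one tag even when A and C
#' fall below the threshold. This removes allelic tags that would otherwise
#' split heterozygous loci into two apparent homozygous loci.
#'
#' @param tags Tibble with columns `tag_id`, `sequence`, `presence_count`.
#' @param identity_pct Identity threshold in percent (study value 98).
#' @return The retained tags. Attribute `collapse_map`: tibble
#'   (`kept_id`, `removed_id`) recording what was collapsed where.
#' @export
collapse_similar <- function(tags, identity_pct = 98) {
  stopifnot(identity_pct > 50, identity_pct <= 100)
  tags <- as_tibble(tags)
  if (nrow(tags) == 0) abort("collapse_similar: no tags")
  lens <- nchar(tags$sequence)
  if (length(unique(lens)) == 1) {
    max_d <- floor(lens[1] * (1 - identity_pct / 100) + 1e-9)
    edges <- cpp_hamming_edges(tags$sequence, max_d)[, 1:2, drop = FALSE]
  } else {
    n <- nrow(tags)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- vapply(seq_len(nrow(pairs)), function(k) {
      pair_identity(tags$sequence[pairs[k, 1]], tags$sequence[pairs[k, 2]]) >=
        identity_pct
    }, logical(1))
    edges <- pairs[keep, , drop = FALSE]
  }
  comp <- components_from_edges(nrow(tags), edges)
  comp_f <- factor(comp, levels = seq_len(max(comp)))
  keep_idx <- vapply(split(seq_len(nrow(tags)), comp_f), function(idx) {
    idx[order(-tags$presence_count[idx], tags$tag_id[idx])][1]
  }, integer(1))
  removed <- setdiff(seq_len(nrow(tags)), keep_idx)
  cmap <- tibble(kept_id = tags$tag_id[keep_idx[comp[removed]]],
                 removed_id = tags$tag_id[removed])
  out <- arrange(tags[sort(keep_idx), , drop = FALSE], .data$tag_id)
  attr(out, "collapse_map") <- cmap
  out
}

#' Build a GBS reference from cross-sample clusters
#'
#' Assigns stable tag ids, applies the sample-presence filter and the
#' identity collapse, and attaches junction metadata (joined tags carry the
#' forward/reverse junction offset; merged tags do not).
#'
#' @param clusters [asustacks()] output.
#' @param n_samples_total Total samples in the run.
#' @param junction_index 0-based junction offset for joined tags (the uniform
#'   forward length, e.g. the `target_len_fwd` attribute of [join_reads()]).
#' @param presence_pct,identity_pct Filter thresholds (defaults 50 and 98).
#' @return Tibble of reference tags: `tag_id`, `sequence`, `presence_count`,
#'   `n_samples_total`, `kind`, `junction_index` (`NA` for merged tags).
#' @export
build_reference <- function(clusters, n_samples_total, junction_index,
                            presence_pct = 50, identity_pct = 98) {
  clusters <- arrange(as_tibble(clusters), .data$consensus)
  tags <- tibble(tag_id = sprintf("tag%06d", seq_len(nrow(clusters))),
                 sequence = clusters$consensus,
                 presence_count = clusters$presence_count,
                 n_samples_total = as.integer(n_samples_total),
                 kind = clusters$kind)
  tags <- mutate(tags, junction_index = ifelse(.data$kind == "joined",
                                               as.integer(junction_index),
                                               NA_integer_))
  tags <- filter_by_presence(tags, n_samples_total, presence_pct)
  collapse_similar(tags, identity_pct)
}

#' Write a GBS reference (FASTA + sidecar TSV)
#'
#' Records are ordered by `tag_id` so output is byte-stable. The sidecar TSV
#' carries `tag_id`, `kind`, `junction_index` and `presence_count` — the
#' metadata needed to excise junction-flanking SNPs later.
#'
#' @param tags Reference tags ([build_reference()]).
#' @param fasta,sidecar Output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_reference <- function(tags, fasta, sidecar) {
  if (anyDuplicated(tags$tag_id)) abort("duplicate tag_id")
  if (nrow(tags) == 0) warn("writing an empty reference")
  tags <- arrange(as_tibble(tags), .data$tag_id)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(setNames(tags$sequence, tags$tag_id))
    Biostrings::writeXStringSet(x, fasta)
  } else {
    writeLines(paste0(">", tags$tag_id, "\n", tags$sequence), fasta)
  }
  write.table(tags[, c("tag_id", "kind", "junction_index", "presence_count")],
              sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, sidecar = sidecar))
}

#' Read a GBS reference written by [write_reference()]
#'
#' @param fasta,sidecar Paths written by [write_reference()].
#' @return Reference tag tibble.
#' @export
read_reference <- function(fasta, sidecar) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(fasta)
    seqs <- setNames(as.character(x), names(x))
  } else {
    lines <- readLines(fasta)
    hd <- grepl("^>", lines)
    ids <- sub("^>", "", lines[hd])
    seqs <- setNames(tapply(lines[!hd], cumsum(hd)[!hd], paste0, collapse = ""),
                     ids)
  }
  meta <- as_tibble(read.delim(sidecar, colClasses = c(tag_id = "character",
                                                       kind = "character")))
  mutate(meta, sequence = unname(seqs[.data$tag_id]), .after = "tag_id")
}
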