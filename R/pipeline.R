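#' Run the full GBS pipeline in memory
#'
#' Chains the stages: demultiplex -> trim -> join -> within-sample stacks ->
#' across-sample clusters -> reference (presence filter + identity collapse)
#' -> allelic-depth counting -> site filters (allele frequency, adjacent,
#' junction-flanking) -> genotype scoring -> parent selection -> marker/sample
#' filters -> tag consolidation -> conflicted-tag removal -> cosegregation
#' dedup -> linkage map, and (when progenitor reads are given) subgenome
#' assignment. Every stage appends a manifest row with record counts.
#'
#' @param reads Raw read pairs (e.g. `simulate_gbs()$reads` or
#'   [read_fastq_pairs()]).
#' @param barcodes Barcode table (`sample_id`, `barcode`).
#' @param parent1,parent2 Parent sample ids (default `"P1"`, `"P2"`).
#' @param progenitor_reads Optional raw read pairs of diploid progenitor
#'   accessions (same barcode table).
#' @param site_remnant Rare-cutter remnant (default `"TGCAG"`).
#' @param trim,merge,cluster,score,map Parameter objects ([trim_params()],
#'   [merge_params()], [cluster_params()], [score_params()], [map_params()]).
#' @param presence_pct,identity_pct Reference filters (defaults 50, 98).
#' @param max_mismatches Read-to-tag assignment radius (default 3).
#' @param progenitor_mismatch Progenitor hit radius (default 4).
#' @param replicate_pairs Optional duplicated-sample table (`keep`, `drop`).
#' @param subgenome_args List of extra arguments for [assign_subgenome()].
#' @return Object of class `gbs_run`: list with `reference`, `ad`, `geno`
#'   (post-filter SNP matrix), `consolidated`, `dedup`, `map` (`gbs_map`),
#'   `subgenome` (or NULL), `progenitor_presence`, `depth` (per consolidated
#'   tag total AD, long), `site_log` (sites dropped by each filter, with
#'   reason codes), `manifest`, `samples`, `progeny`, `params`.
#' @export
run_gbs_pipeline <- function(reads, barcodes,
                             parent1 = "P1", parent2 = "P2",
                             progenitor_reads = NULL,
                             site_remnant = "TGCAG",
                             trim = trim_params(site_remnant = site_remnant),
                             merge = merge_params(),
                             cluster = cluster_params(),
                             presence_pct = 50, identity_pct = 98,
                             max_mismatches = 3L,
                             progenitor_mismatch = 4L,
                             score = score_params(),
                             map = map_params(),
                             replicate_pairs = NULL,
                             subgenome_args = list()) {
  manifest <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    manifest[[length(manifest) + 1L]] <<-
      tibble(stage = stage, n_in = n_in, n_out = n_out,
             n_dropped = n_in - n_out, detail = detail)
  }

  # uniform trim targets shared by population and progenitor reads
  max_bl <- max(nchar(barcodes$barcode))
  rl_f <- min(nchar(reads$fwd_seq))
  rl_r <- min(nchar(reads$rev_seq))
  trim$target_len_fwd <- trim$target_len_fwd %||%
    (rl_f - max_bl - nchar(trim$site_remnant) - trim$tail_trim)
  trim$target_len_rev <- trim$target_len_rev %||%
    (rl_r - trim$second_remnant - trim$tail_trim)

  prep <- function(raw, label) {
    dmx <- demultiplex(raw, barcodes, site_remnant)
    note(paste0("demultiplex_", label), nrow(raw), nrow(dmx))
    trm <- trim_equalize(dmx, trim)
    note(paste0("trim_", label), nrow(dmx), nrow(trm))
    jn <- join_reads(trm, trim$target_len_fwd, trim$target_len_rev,
                     merge = TRUE, params = merge)
    note(paste0("join_", label), nrow(trm), nrow(jn))
    jn
  }
  joined <- prep(reads, "population")
  samples <- sort(unique(joined$sample_id))
  progeny <- setdiff(samples, c(parent1, parent2))

  stacks <- build_stacks(joined, cluster)
  note("stacks", nrow(joined), sum(stacks$depth))
  clusters <- asustacks(stacks, M = cluster$M)
  note("asustacks", nrow(stacks), nrow(clusters))
  reference <- build_reference(clusters, n_samples_total = length(samples),
                               junction_index = trim$target_len_fwd,
                               presence_pct = presence_pct,
                               identity_pct = identity_pct)
  note("reference", nrow(clusters), nrow(reference))

  ad <- count_alleles(joined, reference, max_mismatches = max_mismatches)
  n_sites0 <- nrow(distinct(ad, .data$tag_id, .data$offset))
  note("count_alleles", nrow(reference), n_sites0,
       sprintf("unassigned_reads=%d", attr(ad, "n_unassigned")))
  site_log <- list()
  log_drop <- function(before, after, reason) {
    gone <- anti_join(distinct(before, .data$tag_id, .data$offset),
                      distinct(after, .data$tag_id, .data$offset),
                      by = c("tag_id", "offset"))
    if (nrow(gone)) {
      site_log[[length(site_log) + 1L]] <<- mutate(gone, reason = reason)
    }
    nrow(distinct(after, .data$tag_id, .data$offset))
  }
  ad1 <- filter_af(ad)
  n1 <- log_drop(ad, ad1, "allele_frequency")
  note("filter_af", n_sites0, n1)
  ad2 <- remove_adjacent(ad1)
  n2 <- log_drop(ad1, ad2, "adjacent_snp")
  note("remove_adjacent", n1, n2)
  ad <- remove_junction_flanking(ad2, reference)
  n3 <- log_drop(ad2, ad, "junction_flanking")
  note("remove_junction", n2, n3)

  geno <- score_matrix(ad, score)
  geno <- select_by_parents(geno, parent1, parent2)
  note("select_by_parents", n3, nrow(geno))
  site_log <- bind_rows(site_log)
  if (nrow(site_log) == 0) {
    site_log <- tibble(tag_id = character(), offset = integer(),
                       reason = character())
  }
  if (!is.null(replicate_pairs)) {
    geno <- merge_duplicate_samples(geno, replicate_pairs)
    note("merge_duplicates", nrow(geno), nrow(geno),
         sprintf("disagreement_rate=%.4f", attr(geno, "disagreement_rate")))
    progeny <- setdiff(progeny, replicate_pairs$drop)
  }
  n_before <- nrow(geno)
  geno <- filter_markers_samples(geno, samples = progeny)
  progeny <- setdiff(progeny, attr(geno, "dropped_samples"))
  note("filter_markers_samples", n_before, nrow(geno),
       sprintf("dropped_samples=%d", length(attr(geno, "dropped_samples"))))

  consolidated <- consolidate_matrix(geno)
  note("consolidate", nrow(geno), nrow(consolidated))
  consolidated <- remove_conflicted_tags(consolidated, progeny = progeny)
  note("remove_conflicted", nrow(consolidated) +
         length(attr(consolidated, "dropped_tags")), nrow(consolidated))

  dedup <- dedup_cosegregating(consolidated, samples = progeny)
  note("dedup_cosegregating", nrow(consolidated), nrow(dedup$representatives))
  lmap <- build_linkage_map(dedup$representatives, samples = progeny,
                            params = map, membership = dedup$membership)
  note("linkage_map", nrow(dedup$representatives), nrow(lmap$map))

  # per consolidated tag total allelic depth (for dosage analyses)
  depth <- summarise(group_by(ad, .data$tag_id, .data$sample_id),
                     depth = sum(.data$ad_ref + .data$ad_alt), .groups = "drop")
  depth <- rename(depth, marker_id = "tag_id")

  subg <- NULL; presence <- NULL
  if (!is.null(progenitor_reads) && nrow(progenitor_reads)) {
    pjoined <- prep(progenitor_reads, "progenitor")
    hits <- progenitor_hits(pjoined, reference, progenitor_mismatch)
    presence <- classify_presence(hits)
    subg <- do.call(assign_subgenome,
                    c(list(lmap, presence), subgenome_args))
    note("subgenome", nrow(lmap$map), nrow(subg))
  }

  structure(list(reference = reference, ad = ad, geno = geno,
                 consolidated = consolidated, dedup = dedup, map = lmap,
                 subgenome = subg, progenitor_presence = presence,
                 depth = depth, site_log = site_log,
                 manifest = bind_rows(manifest),
                 samples = samples, progeny = progeny,
                 params = list(trim = trim, merge = merge, cluster = cluster,
                               presence_pct = presence_pct,
                               identity_pct = identity_pct, score = score,
                               map = map)),
            class = "gbs_run")
}

#' @export
print.gbs_run <- function(x, ...) {
  cat("GBS pipeline run\n")
  cat(sprintf("  samples: %d (%d progeny)\n", length(x$samples), length(x$progeny)))
  cat(sprintf("  reference tags: %d\n", nrow(x$reference)))
  cat(sprintf("  SNP markers after filtering: %d\n", nrow(x$geno)))
  cat(sprintf("  consolidated tag markers: %d\n", nrow(x$consolidated)))
  print(x$map)
  if (!is.null(x$subgenome)) {
    cat("  subgenome calls:\n")
    print(as_tibble(x$subgenome)[, c("group_id", "call", "present_fraction",
                                     "n_informative")])
  }
  invisible(x)
}

#' @export
glance.gbs_run <- function(x, ...) {
  bind_cols(tibble(n_samples = length(x$samples),
                   n_reference_tags = nrow(x$reference),
                   n_snp_markers = nrow(x$geno),
                   n_tag_markers = nrow(x$consolidated)),
            glance(x$map))
}
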