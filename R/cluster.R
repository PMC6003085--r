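#' Stack-clustering parameters
#'
#' Mirrors the ustacks-style parameters: `m` is the minimum number of
#' identical reads required to seed a primary stack, `M` the maximum mismatch
#' count for merging primary stacks, `N` the maximum mismatch count for
#' attaching leftover (secondary) reads to a stack.
#'
#' @param m,M,N Integers, `m >= 1`, `M >= 0`, `N >= M`.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(m = 2L, M = 1L, N = 1L) {
  stopifnot(m >= 1, M >= 0, N >= M)
  structure(list(m = as.integer(m), M = as.integer(M), N = as.integer(N)),
            class = "cluster_params")
}

# Core within-sample clustering on a character vector of equal-length reads.
# Returns a tibble (consensus, depth, n_primary, n_secondary, kind).
stack_one_sample <- function(seqs, kinds, params) {
  if (length(unique(nchar(seqs))) > 1) abort("mixed read lengths in one sample")
  # canonical ordering before any tie-break: unique sequences sorted
  tab <- table(seqs)
  u <- sort(names(tab), method = "radix")
  cnt <- as.integer(tab[u])
  # modal kind per unique sequence (depth-weighted later)
  kind_u <- vapply(split(kinds, match(seqs, u)), function(k) {
    t <- sort(table(k), decreasing = TRUE)
    if (length(t) > 1 && t[1] == t[2]) "joined" else names(t)[1]
  }, character(1))[as.character(seq_along(u))]

  prim <- cnt >= params$m
  if (!any(prim)) {
    return(tibble(consensus = character(), depth = integer(),
                  n_primary = integer(), n_secondary = integer(),
                  kind = character(),
                  n_discarded = sum(cnt[!prim])))
  }
  pu <- u[prim]; pc <- cnt[prim]; pk <- kind_u[prim]
  edges <- cpp_hamming_edges(pu, params$M)
  comp <- components_from_edges(length(pu), edges[, 1:2, drop = FALSE])
  cons <- unname(vapply(split(seq_along(pu), comp), function(idx) {
    majority_consensus(pu[idx], pc[idx])
  }, character(1)))
  depth_p <- as.integer(rowsum(pc, comp))
  kind_c <- unname(vapply(split(seq_along(pu), comp), function(idx) {
    w <- rowsum(pc[idx], pk[idx])
    k <- rownames(w)[w[, 1] == max(w[, 1])]
    if (length(k) > 1) "joined" else k
  }, character(1)))

  n_sec <- integer(length(cons))
  discarded <- 0L
  if (any(!prim)) {
    su <- u[!prim]; sc <- cnt[!prim]
    hit <- cpp_assign_nearest(su, cons, params$N)$idx
    ok <- !is.na(hit)
    discarded <- sum(sc[!ok])
    if (any(ok)) {
      add <- rowsum(sc[ok], hit[ok])
      n_sec[as.integer(rownames(add))] <- as.integer(add[, 1])
    }
  }
  ord <- order(cons, method = "radix")
  tibble(consensus = cons[ord],
         depth = depth_p[ord] + n_sec[ord],
         n_primary = depth_p[ord],
         n_secondary = n_sec[ord],
         kind = kind_c[ord],
         n_discarded = discarded)
}

#' Cluster joined reads into within-sample stacks
#'
#' ustacks-style stack building, one sample at a time: identical reads are
#' grouped; groups with at least `m` reads become primary stacks; primary
#' stacks within Hamming distance `M` of each other are merged by
#' single-linkage connected components, with the consensus recomputed as the
#' per-position majority over member reads (ties to the alphabetically
#' smallest base); remaining reads are attached as secondary members to the
#' unique nearest stack within Hamming distance `N` (distance ties discard the
#' read). Deterministic and input-order independent.
#'
#' @param reads Joined reads ([join_reads()]): columns `sample_id`,
#'   `sequence`, and optionally `kind`.
#' @param params A [cluster_params()] object (defaults `m=2, M=1, N=1`).
#' @return Tibble of stacks: `sample_id`, `stack_id`, `consensus`, `depth`,
#'   `n_primary`, `n_secondary`, `kind`. Attribute `n_discarded` counts reads
#'   not placed in any stack, per sample.
#' @export
build_stacks <- function(reads, params = cluster_params()) {
  reads <- as_tibble(reads)
  if (length(unique(nchar(reads$sequence))) > 1) {
    abort("all joined reads must share one uniform length")
  }
  if (!"kind" %in% names(reads)) reads$kind <- "joined"
  parts <- split(reads, reads$sample_id)
  res <- purrr::imap(parts, function(df, sid) {
    st <- stack_one_sample(df$sequence, df$kind, params)
    disc <- if (nrow(st)) st$n_discarded[1] else sum(!is.na(df$sequence))
    st$n_discarded <- NULL
    st <- bind_cols(tibble(sample_id = rep(sid, nrow(st)),
                           stack_id = sprintf("%s_s%04d", sid, seq_len(nrow(st)))), st)
    list(stacks = st, discarded = tibble(sample_id = sid, n_discarded = disc))
  })
  out <- bind_rows(purrr::map(res, "stacks"))
  attr(out, "n_discarded") <- bind_rows(purrr::map(res, "discarded"))
  out
}

#' Cluster per-sample stack consensuses across samples
#'
#' The across-sample analogue of [build_stacks()]: all samples' consensus
#' sequences are pooled and clustered with the same algorithm at `m = 1`
#' (every consensus seeds a stack) and mismatch threshold `M`. Each resulting
#' cross-sample cluster records which samples contributed to it.
#'
#' @param stacks Output of [build_stacks()].
#' @param M Maximum mismatches for merging consensuses across samples
#'   (default 1).
#' @return Tibble of clusters: `cluster_id`, `consensus`, `presence_count`,
#'   `samples_present` (list column), `kind`, `depth` (summed member stack
#'   depths).
#' @export
asustacks <- function(stacks, M = 1L) {
  stacks <- as_tibble(stacks)
  if (nrow(stacks) == 0) {
    return(tibble(cluster_id = character(), consensus = character(),
                  presence_count = integer(), samples_present = list(),
                  kind = character(), depth = integer()))
  }
  ord <- order(stacks$consensus, stacks$sample_id, method = "radix")
  stacks <- stacks[ord, , drop = FALSE]
  u <- sort(unique(stacks$consensus), method = "radix")
  grp <- match(stacks$consensus, u)
  w <- as.integer(rowsum(rep(1L, nrow(stacks)), grp))  # multiplicity per unique seq
  edges <- cpp_hamming_edges(u, M)
  comp <- components_from_edges(length(u), edges[, 1:2, drop = FALSE])
  comp_of_stack <- comp[grp]
  cl <- purrr::map(split(seq_len(nrow(stacks)), comp_of_stack), function(idx) {
    uniq_idx <- unique(grp[idx])
    list(consensus = majority_consensus(u[uniq_idx], w[uniq_idx]),
         samples = sort(unique(stacks$sample_id[idx])),
         depth = sum(stacks$depth[idx]),
         kind = {
           kw <- rowsum(stacks$depth[idx], stacks$kind[idx])
           k <- rownames(kw)[kw[, 1] == max(kw[, 1])]
           if (length(k) > 1) "joined" else k
         })
  })
  out <- tibble(consensus = unname(purrr::map_chr(cl, "consensus")),
                samples_present = unname(purrr::map(cl, "samples")),
                kind = unname(purrr::map_chr(cl, "kind")),
                depth = unname(purrr::map_int(cl, ~ as.integer(.x$depth))))
  out <- mutate(out, presence_count = unname(lengths(.data$samples_present)))
  out <- arrange(out, .data$consensus)
  out <- mutate(out, cluster_id = sprintf("cl%06d", row_number()), .before = 1)
  select(out, "cluster_id", "consensus", "presence_count", "samples_present",
         "kind", "depth")
}

#' Export stacks as an artificial FASTQ
#'
#' Writes one record per stack, named `sampleID_stackID`, with a quality line
#' of all `E`s — the interoperability format used to feed per-sample consensus
#' sequences back into a read-clustering tool.
#'
#' @param stacks Output of [build_stacks()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
export_stacks_fastq <- function(stacks, path) {
  recs <- paste0("@", stacks$stack_id, "\n", stacks$consensus, "\n+\n",
                 strrep("E", nchar(stacks$consensus)))
  writeLines(recs, path)
  invisible(path)
}
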