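#' Simulation configuration for a synthetic allotetraploid F2 GBS experiment
#'
#' Defines an AABB allotetraploid cross: an A subgenome, a diverged B
#' subgenome (`d_ab`), two inbred parents differing at `parental_snp_rate`,
#' diploid (AA) progenitor accessions at `progenitor_divergence` from the A
#' subgenome, a PstI/MspI restriction digest with size selection, and an F2
#' population read-simulated at `mean_depth` with substitution errors.
#'
#' @param seed Integer seed; all outputs are byte-identical under a fixed
#'   seed.
#' @param n_chrom_pairs Number of homoeologous A/B chromosome pairs
#'   (default 2).
#' @param chrom_len_bp Chromosome length in bp (default 1e6).
#' @param d_ab A-vs-B subgenome divergence (substitution rate, default 0.05).
#' @param parental_snp_rate Parent1-vs-parent2 substitution rate
#'   (default 0.002).
#' @param progenitor_divergence Progenitor-vs-A-subgenome rate (default 0.01).
#' @param enzymes Named character vector of restriction motifs; the first is
#'   the rare cutter carrying the barcoded adapter (default PstI `CTGCAG` and
#'   MspI `CCGG`).
#' @param fragment_window Retained fragment lengths in bp (default
#'   `c(300, 800)`).
#' @param read_len Read length (default 150, paired-end).
#' @param n_progeny F2 population size (default 60).
#' @param mean_depth Mean read depth per locus per sample (default 30).
#' @param error_rate Per-base substitution error rate (default 0.002).
#' @param map_length_cm Genetic length per chromosome in cM; crossovers per
#'   gamete are Poisson with mean `map_length_cm / 100` (default 150).
#' @param n_progenitors Number of diploid progenitor accessions (default 3).
#' @param barcodes Optional barcode table; by default parents get 10-nt and
#'   all other samples 5-nt barcodes, generated deterministically.
#' @param translocation Optional reciprocal homoeologous translocation:
#'   `list(pair =, breakpoint_frac =, carrier =)` with carrier one of
#'   `"both"`, `"parent1"`, `"parent2"`. `"both"` models a lineage-level
#'   rearrangement relative to the progenitor (fixed in the cross).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom_pairs = 2L, chrom_len_bp = 1e6,
                       d_ab = 0.05, parental_snp_rate = 0.002,
                       progenitor_divergence = 0.01,
                       enzymes = c(pstI = "CTGCAG", mspI = "CCGG"),
                       fragment_window = c(300L, 800L), read_len = 150L,
                       n_progeny = 60L, mean_depth = 30, error_rate = 0.002,
                       map_length_cm = 150, n_progenitors = 3L,
                       barcodes = NULL, translocation = NULL) {
  stopifnot(n_chrom_pairs >= 1, chrom_len_bp >= 1000,
            d_ab >= 0, d_ab < 1, parental_snp_rate >= 0, parental_snp_rate < 1,
            progenitor_divergence >= 0, progenitor_divergence < 1,
            length(enzymes) >= 1, fragment_window[1] < fragment_window[2],
            read_len >= 50, n_progeny >= 1, mean_depth > 0,
            error_rate >= 0, error_rate < 1, map_length_cm >= 0)
  if (!is.null(translocation)) {
    stopifnot(translocation$pair %in% seq_len(n_chrom_pairs),
              translocation$breakpoint_frac > 0, translocation$breakpoint_frac < 1,
              translocation$carrier %in% c("both", "parent1", "parent2"))
  }
  cfg <- list(seed = as.integer(seed), n_chrom_pairs = as.integer(n_chrom_pairs),
              chrom_len_bp = as.integer(chrom_len_bp), d_ab = d_ab,
              parental_snp_rate = parental_snp_rate,
              progenitor_divergence = progenitor_divergence,
              enzymes = enzymes, fragment_window = as.integer(fragment_window),
              read_len = as.integer(read_len), n_progeny = as.integer(n_progeny),
              mean_depth = mean_depth, error_rate = error_rate,
              map_length_cm = map_length_cm,
              n_progenitors = as.integer(n_progenitors),
              translocation = translocation)
  cfg$samples <- c("P1", "P2", sprintf("F2_%03d", seq_len(cfg$n_progeny)))
  cfg$progenitor_samples <- sprintf("EI%d", seq_len(cfg$n_progenitors))
  cfg$barcodes <- barcodes %||%
    default_barcodes(c(cfg$samples, cfg$progenitor_samples))
  validate_barcodes(cfg$barcodes)
  structure(cfg, class = "sim_config")
}

# Deterministic barcode table: 10-nt barcodes for the two parents (exercising
# length equalisation), 5-nt codes with a checksum base for everything else.
# The checksum makes pairwise Hamming distance >= 2, so a single sequencing
# error never converts one valid barcode into another (the read is rejected
# instead of misassigned).
default_barcodes <- function(sample_ids) {
  if (length(sample_ids) > 1024) abort("default barcode set supports <= 1024 samples")
  bases <- c("A", "C", "G", "T")
  nd <- if (length(sample_ids) <= 256) 4L else 5L  # data digits + 1 checksum
  enc <- function(i) {
    digits <- integer(nd)
    for (k in seq_len(nd)) { digits[k] <- i %% 4L; i <- i %/% 4L }
    digits <- c(digits, sum(digits) %% 4L)
    paste0(bases[digits + 1L], collapse = "")
  }
  bc <- vapply(seq_along(sample_ids), enc, character(1))
  if (length(sample_ids) >= 2 && all(c("P1", "P2") %in% sample_ids)) {
    bc[sample_ids == "P1"] <- "AACCGGTTAC"
    bc[sample_ids == "P2"] <- "AACCGGTTCA"
  }
  tibble(sample_id = sample_ids, barcode = bc)
}

random_seq <- function(n) {
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# substitute bases at `rate`; substitutions always change the base
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  braw <- as.raw(c(65L, 67L, 71L, 84L))
  r <- charToRaw(seq)
  idx <- match(r[pos], braw)
  r[pos] <- braw[((idx - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L]
  rawToChar(r)
}

swap_tails <- function(genome, a_chrom, b_chrom, frac) {
  len <- nchar(genome[[a_chrom]])
  bp <- floor(frac * len)
  a_tail <- substr(genome[[a_chrom]], bp + 1L, len)
  b_tail <- substr(genome[[b_chrom]], bp + 1L, len)
  genome[[a_chrom]] <- paste0(substr(genome[[a_chrom]], 1L, bp), b_tail)
  genome[[b_chrom]] <- paste0(substr(genome[[b_chrom]], 1L, bp), a_tail)
  genome
}

#' Simulate parental and progenitor genomes
#'
#' The A subgenome is random; B is A mutated at `d_ab`; parent 2 is parent 1
#' mutated at `parental_snp_rate`; progenitor accessions are the A subgenome
#' mutated at `progenitor_divergence`. Substitution-only mutation keeps all
#' genomes coordinate-aligned, so fragment loci are comparable across genomes.
#' An optional reciprocal homoeologous translocation swaps chromosome tails
#' between one A/B pair in the configured carrier(s).
#'
#' @param config A [sim_config()].
#' @return List: `parent1`, `parent2` (named chromosome vectors `A1..`,
#'   `B1..`), `progenitors` (named list of A-genome chromosome vectors).
#' @export
simulate_genomes <- function(config) {
  set_portable_seed(config$seed)
  n <- config$n_chrom_pairs
  a <- setNames(vapply(seq_len(n), function(i) random_seq(config$chrom_len_bp),
                       character(1)), paste0("A", seq_len(n)))
  b <- setNames(vapply(a, mutate_seq, character(1), rate = config$d_ab),
                paste0("B", seq_len(n)))
  parent1 <- c(a, b)
  parent2 <- vapply(parent1, mutate_seq, character(1),
                    rate = config$parental_snp_rate)
  progenitors <- setNames(lapply(seq_len(config$n_progenitors), function(i) {
    vapply(a, mutate_seq, character(1), rate = config$progenitor_divergence)
  }), config$progenitor_samples)
  tr <- config$translocation
  if (!is.null(tr)) {
    ac <- paste0("A", tr$pair); bc <- paste0("B", tr$pair)
    if (tr$carrier %in% c("both", "parent1")) {
      parent1 <- swap_tails(parent1, ac, bc, tr$breakpoint_frac)
    }
    if (tr$carrier %in% c("both", "parent2")) {
      parent2 <- swap_tails(parent2, ac, bc, tr$breakpoint_frac)
    }
  }
  list(parent1 = parent1, parent2 = parent2, progenitors = progenitors)
}

# cut geometry after end repair / adapter fill-in, relative to the 1-based
# motif start p: the downstream fragment starts at p + right_off, the upstream
# fragment ends at p + left_off.
cut_offsets <- function(motif) {
  switch(motif,
         CTGCAG = c(right = 1L, left = 4L),   # PstI: fragments read TGCAG...
         CCGG   = c(right = 1L, left = 2L),   # MspI: fragments read CGG...
         c(right = 0L, left = nchar(motif) - 1L))
}

#' Digest a genome and select size-window fragments with a rare-cutter end
#'
#' Scans each chromosome for the restriction motifs, forms fragments between
#' consecutive cut sites, keeps those with at least one rare-cutter (first
#' enzyme) end and a length inside the size-selection window, and orients each
#' fragment 5'->3' from its rare-cutter end (strand `-` fragments are
#' reverse-complemented on extraction).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param enzymes Named motif vector; first entry is the rare cutter.
#' @param window Length-2 numeric, retained fragment lengths (inclusive).
#' @return Tibble: `locus_id`, `chrom`, `start`, `end`, `length`, `strand`,
#'   `enz5`, `enz3` (enzymes at the fragment's genomic left/right ends).
#' @export
digest_and_select <- function(genome, enzymes = c(pstI = "CTGCAG", mspI = "CCGG"),
                              window = c(300, 800)) {
  stopifnot(length(enzymes) >= 1)
  rare <- names(enzymes)[1]
  per_chrom <- purrr::imap(genome, function(seq, chrom) {
    sites <- purrr::imap(as.list(enzymes), function(motif, enz) {
      p <- gregexpr(motif, seq, fixed = TRUE)[[1]]
      if (p[1] == -1) return(NULL)
      off <- cut_offsets(motif)
      tibble(pos = as.integer(p), enzyme = enz,
             right_start = as.integer(p) + off[["right"]],
             left_end = as.integer(p) + off[["left"]])
    })
    sites <- arrange(bind_rows(sites), .data$pos)
    if (nrow(sites) < 2) return(NULL)
    k <- seq_len(nrow(sites) - 1L)
    frag <- tibble(chrom = chrom,
                   start = sites$right_start[k],
                   end = sites$left_end[k + 1L],
                   enz5 = sites$enzyme[k],
                   enz3 = sites$enzyme[k + 1L])
    frag <- mutate(frag, length = .data$end - .data$start + 1L)
    frag <- filter(frag, .data$length >= window[1], .data$length <= window[2],
                   .data$enz5 == rare | .data$enz3 == rare)
    mutate(frag, strand = ifelse(.data$enz5 == rare, "+", "-"))
  })
  out <- bind_rows(per_chrom)
  if (nrow(out) == 0) {
    return(tibble(locus_id = character(), chrom = character(), start = integer(),
                  end = integer(), length = integer(), strand = character(),
                  enz5 = character(), enz3 = character()))
  }
  out <- mutate(out,
                locus_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end))
  select(arrange(out, .data$chrom, .data$start),
         "locus_id", "chrom", "start", "end", "length", "strand", "enz5", "enz3")
}

# extract fragment sequences, oriented 5'->3' from the rare-cutter end
fragment_seqs <- function(genome, frags) {
  s <- substring(genome[frags$chrom], frags$start, frags$end)
  ifelse(frags$strand == "-", revcomp(s), s)
}

#' Simulate F2 meiosis
#'
#' Each progeny receives two recombinant gametes per chromosome; crossovers
#' per gamete are Poisson with mean `map_length_cm / 100`, positions uniform,
#' no interference (Haldane model), and the starting parental origin of each
#' gamete is random.
#'
#' @param config A [sim_config()].
#' @param chroms Chromosome names (default `A1.. B1..` from the config).
#' @return Tibble: `progeny`, `chrom`, `gamete` (1/2), `start_src` (1/2),
#'   `xo` (list of crossover positions in bp).
#' @export
simulate_f2 <- function(config, chroms = NULL) {
  chroms <- chroms %||% c(paste0("A", seq_len(config$n_chrom_pairs)),
                          paste0("B", seq_len(config$n_chrom_pairs)))
  set_portable_seed(config$seed + 1L)
  rows <- expand.grid(gamete = 1:2, chrom = chroms,
                      progeny = sprintf("F2_%03d", seq_len(config$n_progeny)),
                      stringsAsFactors = FALSE)[, 3:1]
  lambda <- config$map_length_cm / 100
  n_xo <- rpois(nrow(rows), lambda)
  xo <- lapply(n_xo, function(k) sort(runif(k, 0, config$chrom_len_bp)))
  start_src <- sample(1:2, nrow(rows), replace = TRUE)
  as_tibble(rows) |>
    mutate(start_src = start_src, xo = xo)
}

# parental origin (1/2) of gamete segments at positions `pos`
src_at <- function(start_src, xo, pos) {
  ((start_src - 1L + findInterval(pos, xo)) %% 2L) + 1L
}

#' True genotypes of the F2 population at given positions
#'
#' @param f2 [simulate_f2()] output.
#' @param chrom Chromosome name.
#' @param pos Numeric vector of bp positions.
#' @return Integer matrix (positions x progeny): number of parent-2 alleles
#'   (0 = P1 homozygote, 1 = heterozygote, 2 = P2 homozygote).
#' @export
f2_genotype_at <- function(f2, chrom, pos) {
  fc <- filter(f2, .data$chrom == !!chrom)
  progs <- unique(fc$progeny)
  out <- matrix(0L, length(pos), length(progs),
                dimnames = list(NULL, progs))
  for (p in progs) {
    g1 <- fc[fc$progeny == p & fc$gamete == 1L, ]
    g2 <- fc[fc$progeny == p & fc$gamete == 2L, ]
    out[, p] <- (src_at(g1$start_src, g1$xo[[1]], pos) == 2L) +
                (src_at(g2$start_src, g2$xo[[1]], pos) == 2L)
  }
  out
}

# vectorised substitution-error injection (errors always change the base)
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  bases <- c("A", "C", "G", "T")
  wave <- 1L
  while (any(n_err >= wave)) {
    sel <- which(n_err >= wave)
    pos <- ceiling(runif(length(sel)) * lens[sel])
    cur <- substr(seqs[sel], pos, pos)
    new <- bases[((match(cur, bases) - 1L +
                   sample.int(3L, length(sel), replace = TRUE)) %% 4L) + 1L]
    # reads may already contain N-free bases only; guard regardless
    new[is.na(new)] <- "A"
    x <- seqs[sel]
    substr(x, pos, pos) <- new
    seqs[sel] <- x
    wave <- wave + 1L
  }
  seqs
}

# reads for one homozygous template set: depth copies of fwd/rev per locus
emit_reads <- function(sample_id, locus_id, src, fwd_templ, rev_templ, depth,
                       qual_char = "I") {
  keep <- depth > 0
  if (!any(keep)) return(NULL)
  idx <- rep(which(keep), depth[keep])
  copy <- sequence(depth[keep])
  fwd <- fwd_templ[idx]
  rev <- rev_templ[idx]
  tibble(sample_id = sample_id,
         read_id = sprintf("%s|%s|P%d|%d", sample_id, locus_id[idx], src, copy),
         fwd_seq = fwd, fwd_qual = strrep(qual_char, nchar(fwd)),
         rev_seq = rev, rev_qual = strrep(qual_char, nchar(rev)))
}

#' Simulate GBS reads for the mapping population
#'
#' Digests both parental genomes, takes the union fragment catalog (a
#' haplotype yields reads for a fragment only when its own parent's digest
#' retains it, so cut-site polymorphisms become presence/absence), draws
#' per-haplotype depths as Poisson(`mean_depth / 2`), builds barcoded
#' paired-end reads from the fragment ends and injects substitution errors.
#' Read ids encode sample, fragment and haplotype for audit.
#'
#' @param config A [sim_config()].
#' @param genomes [simulate_genomes()] output.
#' @param f2 [simulate_f2()] output.
#' @return List: `reads` (tibble of read pairs for parents + progeny) and
#'   `truth` (fragment catalog with per-parent presence, allele sequences and
#'   SNP counts; plus the loci x progeny genotype matrix).
#' @export
simulate_reads <- function(config, genomes, f2) {
  set_portable_seed(config$seed + 2L)
  cat1 <- digest_and_select(genomes$parent1, config$enzymes, config$fragment_window)
  cat2 <- digest_and_select(genomes$parent2, config$enzymes, config$fragment_window)
  loci <- full_join(mutate(cat1, in1 = TRUE),
                    mutate(cat2, in2 = TRUE),
                    by = c("locus_id", "chrom", "start", "end", "length",
                           "strand", "enz5", "enz3"))
  loci <- arrange(loci, .data$chrom, .data$start, .data$strand)
  loci <- mutate(loci,
                 in1 = !is.na(.data$in1), in2 = !is.na(.data$in2),
                 seq1 = fragment_seqs(genomes$parent1, loci),
                 seq2 = fragment_seqs(genomes$parent2, loci),
                 midpoint = (.data$start + .data$end) / 2)
  loci$n_snps <- mapply(function(a, b) cpp_hamming(a, b), loci$seq1, loci$seq2)

  # truth genotypes at locus midpoints
  geno <- matrix(0L, nrow(loci), config$n_progeny,
                 dimnames = list(loci$locus_id,
                                 sprintf("F2_%03d", seq_len(config$n_progeny))))
  for (ch in unique(loci$chrom)) {
    sel <- loci$chrom == ch
    geno[sel, ] <- f2_genotype_at(f2, ch, loci$midpoint[sel])
  }

  bc <- setNames(config$barcodes$barcode, config$barcodes$sample_id)
  rl <- config$read_len
  templ <- function(seqs, barcode) {
    list(fwd = paste0(barcode, substr(seqs, 1L, rl - nchar(barcode))),
         rev = revcomp(substr(seqs, nchar(seqs) - rl + 1L, nchar(seqs))))
  }
  half <- config$mean_depth / 2
  n_loci <- nrow(loci)
  parts <- vector("list", length(config$samples))
  names(parts) <- config$samples
  for (s in config$samples) {
    if (s == "P1") { src1 <- rep(1L, n_loci); src2 <- src1 }
    else if (s == "P2") { src1 <- rep(2L, n_loci); src2 <- src1 }
    else { g <- geno[, s]; src1 <- 1L + as.integer(g >= 1); src2 <- 1L + as.integer(g == 2) }
    amp <- cbind(ifelse(src1 == 1L, loci$in1, loci$in2),
                 ifelse(src2 == 1L, loci$in1, loci$in2))
    d1 <- rpois(n_loci, half) * amp[, 1]
    d2 <- rpois(n_loci, half) * amp[, 2]
    depth_p1 <- d1 * (src1 == 1L) + d2 * (src2 == 1L)
    depth_p2 <- d1 * (src1 == 2L) + d2 * (src2 == 2L)
    t1 <- templ(loci$seq1, bc[[s]])
    t2 <- templ(loci$seq2, bc[[s]])
    parts[[s]] <- bind_rows(
      emit_reads(s, loci$locus_id, 1L, t1$fwd, t1$rev, depth_p1),
      emit_reads(s, loci$locus_id, 2L, t2$fwd, t2$rev, depth_p2))
  }
  reads <- bind_rows(parts)
  reads$fwd_seq <- inject_errors(reads$fwd_seq, config$error_rate)
  reads$rev_seq <- inject_errors(reads$rev_seq, config$error_rate)
  list(reads = reads,
       truth = list(loci = select(loci, -"midpoint"), geno = geno))
}

#' Simulate GBS reads for the diploid progenitor accessions
#'
#' Each (homozygous) progenitor genome is digested with its own catalog, so
#' restriction-site polymorphisms relative to the A subgenome naturally drop
#' fragments; depth per locus is Poisson(`mean_depth`).
#'
#' @param config A [sim_config()].
#' @param genomes [simulate_genomes()] output.
#' @return Tibble of read pairs (samples `EI1..`).
#' @export
simulate_progenitor_reads <- function(config, genomes) {
  set_portable_seed(config$seed + 3L)
  bc <- setNames(config$barcodes$barcode, config$barcodes$sample_id)
  rl <- config$read_len
  parts <- purrr::imap(genomes$progenitors, function(gen, acc) {
    cat_k <- digest_and_select(gen, config$enzymes, config$fragment_window)
    if (nrow(cat_k) == 0) return(NULL)
    seqs <- fragment_seqs(gen, cat_k)
    fwd <- paste0(bc[[acc]], substr(seqs, 1L, rl - nchar(bc[[acc]])))
    rev <- revcomp(substr(seqs, nchar(seqs) - rl + 1L, nchar(seqs)))
    emit_reads(acc, cat_k$locus_id, 1L, fwd, rev,
               rpois(nrow(cat_k), config$mean_depth))
  })
  reads <- bind_rows(parts)
  reads$fwd_seq <- inject_errors(reads$fwd_seq, config$error_rate)
  reads$rev_seq <- inject_errors(reads$rev_seq, config$error_rate)
  reads
}

#' Run the full synthetic-data generator
#'
#' Genomes, F2 meiosis, population reads and progenitor reads under one seed.
#'
#' @param config A [sim_config()].
#' @return List: `reads`, `progenitor_reads`, `truth` (fragment catalog,
#'   genotype matrix, genomes, crossovers, config).
#' @export
simulate_gbs <- function(config = sim_config()) {
  genomes <- simulate_genomes(config)
  f2 <- simulate_f2(config)
  pop <- simulate_reads(config, genomes, f2)
  prog <- simulate_progenitor_reads(config, genomes)
  list(reads = pop$reads,
       progenitor_reads = prog,
       truth = c(pop$truth, list(genomes = genomes, f2 = f2, config = config)))
}

#' The printed 12-scenario consolidation fixture
#'
#' Three SNPs on one reference tag scored across twelve samples, together with
#' the expected consolidated row. Columns S9-S12 are the conflict scenarios:
#' they consolidate to the flag `F` and are shown as missing (`-`) in the
#' expected row.
#'
#' @return List: `geno` (wide 3-marker matrix on one tag), `expected`
#'   (named character vector: the consolidated row as printed, `-` for
#'   conflicts), `expected_flags` (same but with `F` retained).
#' @export
table1_fixture <- function() {
  samples <- sprintf("S%d", 1:12)
  rows <- list(
    SNP1 = c("-", "B", "-", "C", "D", "A", "B", "H", "A", "B", "H", "A"),
    SNP2 = c("A", "-", "-", "-", "-", "D", "C", "C", "A", "D", "A", "A"),
    SNP3 = c("-", "-", "H", "-", "-", "A", "C", "D", "C", "B", "A", "B"))
  geno <- tibble(marker_id = paste0("tag1:", 0:2), tag_id = "tag1",
                 offset = 0:2)
  for (s in seq_along(samples)) {
    geno[[samples[s]]] <- unname(vapply(rows, `[[`, character(1), s))
  }
  flags <- c("A", "B", "H", "C", "D", "A", "B", "H", "F", "F", "F", "F")
  list(geno = geno,
       expected = setNames(replace(flags, flags == "F", "-"), samples),
       expected_flags = setNames(flags, samples))
}

#' Impose a copy-number change on a depth table
#'
#' Scales one progeny's depths over a marker region by a copy factor,
#' emulating the compensated deletion (`copies = 0`) or duplication
#' (`copies = 2`) of a homoeologous segment that segregating translocations
#' produce.
#'
#' @param depth Long tibble `marker_id`, `sample_id`, `depth`.
#' @param region_markers Marker ids of the affected region.
#' @param sample Progeny sample id.
#' @param copies Copy factor relative to normal (0, 1 or 2).
#' @return The modified depth tibble.
#' @export
simulate_dosage_variant <- function(depth, region_markers, sample, copies) {
  sel <- depth$marker_id %in% region_markers & depth$sample_id == sample
  depth$depth[sel] <- as.integer(round(depth$depth[sel] * copies))
  depth
}
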