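test_that("simulated genomes honour divergence settings and determinism", {
  cfg0 <- quick_cfg(d_ab = 0)
  g0 <- simulate_genomes(cfg0)
  expect_equal(g0$parent1[["A1"]], g0$parent1[["B1"]])

  cfg <- quick_cfg()
  g1 <- simulate_genomes(cfg)
  g2 <- simulate_genomes(cfg)
  expect_identical(g1, g2)

  # A-vs-B mismatch fraction ~ d_ab within 3 binomial sigmas
  d <- hamming(g1$parent1[["A1"]], g1$parent1[["B1"]])
  n <- cfg$chrom_len_bp
  expect_lt(abs(d / n - cfg$d_ab), 3 * sqrt(cfg$d_ab / n) + 1e-4)
  # parental polymorphism and progenitor divergence likewise
  dp <- hamming(g1$parent1[["A1"]], g1$parent2[["A1"]])
  expect_lt(abs(dp / n - cfg$parental_snp_rate),
            3 * sqrt(cfg$parental_snp_rate / n) + 1e-4)
  dq <- hamming(g1$parent1[["A1"]], g1$progenitors$EI1[["A1"]])
  expect_lt(abs(dq / n - cfg$progenitor_divergence),
            3 * sqrt(cfg$progenitor_divergence / n) + 1e-4)
})

test_that("digest_and_select equals a hand-enumerated toy digest", {
  #           1         2         3         4         5         6
  #  1234567890123456789012345678901234567890123456789012345678901234
  s <- "AAAACTGCAGAAAAAAAAAACCGGTTTTTTTTTTTTTTTTCTGCAGGGGGGGGGGGGGGCCGG"
  frags <- digest_and_select(c(chrZ = s), window = c(1, 100))
  # PstI at 5, MspI at 21, PstI at 41, MspI at 61
  # cut geometry: PstI right_start p+1 / left_end p+4; MspI q+1 / q+3... (q+2)
  expect_equal(frags$start, c(6, 22, 42))
  expect_equal(frags$end, c(23, 45, 62))
  expect_equal(frags$strand, c("+", "-", "+"))
  expect_equal(frags$enz5, c("pstI", "mspI", "pstI"))
  # every fragment reads TGCAG... from its rare-cutter end
  seqs <- with(frags, ifelse(strand == "-",
                             revcomp(substring(s, start, end)),
                             substring(s, start, end)))
  expect_true(all(startsWith(seqs, "TGCAG")))
  # window boundaries: a 17-nt fragment vanishes under a [18, x] window
  expect_equal(nrow(digest_and_select(c(chrZ = s), window = c(19, 100))), 2)
  # no rare-cutter site -> no fragments
  expect_equal(nrow(digest_and_select(c(chrY = strrep("CCGGAA", 60)))), 0)
})

test_that("F2 meiosis yields 1:2:1 genotypes and Poisson crossovers", {
  cfg <- sim_config(seed = 5, n_progeny = 300L, n_chrom_pairs = 1L,
                    chrom_len_bp = 10000L)
  f2 <- simulate_f2(cfg)
  xo_mean <- mean(lengths(f2$xo))
  expect_lt(abs(xo_mean - 1.5), 3 * sqrt(1.5 / nrow(f2)))
  g <- f2_genotype_at(f2, "A1", 5000)
  counts <- table(factor(g, levels = 0:2))
  n <- 300
  expect_lt(abs(counts[[1]] / n - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(counts[[2]] / n - 0.50), 3 * sqrt(0.25 / n))
  # zero map length -> no crossovers
  f2_0 <- simulate_f2(sim_config(seed = 5, map_length_cm = 0,
                                 n_progeny = 20L, n_chrom_pairs = 1L))
  expect_true(all(lengths(f2_0$xo) == 0))
})

test_that("read simulation is deterministic and truth-linked", {
  cfg <- quick_cfg(seed = 19)
  a <- simulate_gbs(cfg)
  b <- simulate_gbs(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$progenitor_reads, b$progenitor_reads)
  # read ids encode sample | fragment | haplotype
  expect_true(all(grepl("^[^|]+\\|[^|]+\\|P[12]\\|\\d+$", a$reads$read_id)))
  first <- strsplit(a$reads$read_id[1], "|", fixed = TRUE)[[1]]
  expect_equal(first[1], a$reads$sample_id[1])
  expect_true(first[2] %in% a$truth$loci$locus_id)
  # fragment catalog equals a direct regex re-scan of the genome
  loci_a1 <- dplyr::filter(a$truth$loci, chrom == "A1", in1)
  rescan <- digest_and_select(a$truth$genomes$parent1["A1"],
                              cfg$enzymes, cfg$fragment_window)
  expect_setequal(loci_a1$locus_id, rescan$locus_id)
})

test_that("error-free reads at depth recover homozygous truth end to end", {
  cfg <- quick_cfg(seed = 23, error_rate = 0, n_progeny = 8L)
  sim <- simulate_gbs(cfg)
  run <- run_gbs_pipeline(sim$reads, cfg$barcodes)
  tags <- run$consolidated
  t1 <- truth_tagify(sim$truth$loci$seq1)
  t2 <- truth_tagify(sim$truth$loci$seq2)
  locus <- rep(seq_len(nrow(sim$truth$loci)), 2)[
    match(run$reference$sequence[match(tags$tag_id, run$reference$tag_id)],
          c(t1, t2))]
  expect_false(anyNA(locus))
  prog <- run$progeny
  truth_code <- matrix(c("A", "H", "B")[sim$truth$geno[locus, prog] + 1],
                       nrow = length(locus))
  obs <- as.matrix(tags[, prog])
  hom <- truth_code %in% c("A", "B")
  called <- obs != "-"
  expect_true(all(obs[hom & called] == truth_code[hom & called]))
  # heterozygous truth at adequate depth is never called a pure homozygote
  het <- truth_code == "H" & obs %in% c("A", "B")
  expect_equal(sum(het), 0)
})

test_that("the consolidation fixture matches its printed columns", {
  fx <- table1_fixture()
  expect_equal(fx$geno$S5, c("D", "-", "-"))
  expect_equal(fx$geno$S12, c("A", "A", "B"))
  expect_equal(dim(fx$geno), c(3L, 15L))
})
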