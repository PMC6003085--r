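test_that("score_genotype reproduces the printed ratio rules", {
  expect_equal(score_genotype(20, 1), "A")
  expect_equal(score_genotype(0, 12), "B")
  expect_equal(score_genotype(9, 2), "D")
  expect_equal(score_genotype(2, 11), "C")
  expect_equal(score_genotype(6, 6), "H")
  expect_equal(score_genotype(4, 3), "-")    # total 7 < 8
  expect_equal(score_genotype(8, 2), "H")    # r = 4 exactly -> "other ratios"
  expect_equal(score_genotype(12, 0), "A")   # r = +Inf
})

test_that("score_genotype boundary ratios land exactly as printed", {
  expect_equal(score_genotype(1, 10), "B")   # r = 0.10 -> B (<=)
  expect_equal(score_genotype(3, 30), "B")
  expect_equal(score_genotype(2, 8), "H")    # r = 0.25 is NOT inside (0.1, 0.25)
  expect_equal(score_genotype(10, 1), "A")   # r = 10 -> A (>=)
  expect_equal(score_genotype(40, 4), "A")
})

test_that("score_genotype equals the literal-rule oracle on a depth grid", {
  grid <- expand.grid(ref = 0:25, alt = 0:25)
  got <- score_genotype(grid$ref, grid$alt)
  want <- oracle_score_genotype(grid$ref, grid$alt)
  expect_equal(got, unname(want))
})

test_that("count_alleles finds variant sites from assigned reads", {
  tag <- strrep("ACGTTGCAGT", 4)  # 40 nt
  alt <- tag; substr(alt, 8, 8) <- "T"
  reads <- tibble::tibble(sample_id = rep(c("S1", "S2"), each = 10),
                          sequence = rep(c(tag, alt), times = 10))
  ref <- tibble::tibble(tag_id = "tag1", sequence = tag, kind = "joined",
                        junction_index = 20L)
  ad <- count_alleles(reads, ref)
  sites <- dplyr::distinct(ad, tag_id, offset, ref_allele, alt_allele)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$offset, 7L)             # 0-based
  expect_equal(sites$ref_allele, "A")
  expect_equal(sites$alt_allele, "T")
  pooled <- dplyr::summarise(ad, r = sum(ad_ref), a = sum(ad_alt))
  expect_equal(c(pooled$r, pooled$a), c(10L, 10L))

  # a read equidistant from two tags is discarded
  ref2 <- tibble::tibble(tag_id = c("t1", "t2"),
                         sequence = c("AAAAAAAA", "AACCAAAA"),
                         kind = "joined", junction_index = 4L)
  rd2 <- tibble::tibble(sample_id = "S1", sequence = "AACAAAAA")
  ad2 <- count_alleles(rd2, ref2)
  expect_equal(attr(ad2, "n_unassigned"), 1L)

  # a singleton mismatch never reaches the depth-2 site threshold
  rd3 <- tibble::tibble(sample_id = "S1", sequence = c(rep(tag, 9), alt))
  expect_equal(nrow(count_alleles(rd3, ref)), 0)
})

test_that("pooled allele-frequency filter keeps inclusive boundaries", {
  ad <- tibble::tibble(tag_id = "t", offset = c(0L, 3L, 6L),
                       ref_allele = "A", alt_allele = "C",
                       sample_id = "S1",
                       ad_ref = c(90L, 95L, 50L), ad_alt = c(10L, 5L, 50L))
  out <- filter_af(ad)
  expect_equal(sort(unique(out$offset)), c(0L, 6L))  # AF 0.10 kept, 0.05 dropped
  # AF 0.90 boundary kept, above dropped; zero-depth sites dropped
  ad2 <- tibble::tibble(tag_id = "t", offset = c(0L, 3L, 6L),
                        ref_allele = "A", alt_allele = "C", sample_id = "S1",
                        ad_ref = c(10L, 5L, 0L), ad_alt = c(90L, 95L, 0L))
  expect_equal(filter_af(ad2)$offset, 0L)
})

test_that("remove_adjacent removes pairs and runs, and is idempotent", {
  mk <- function(offsets) tibble::tibble(tag_id = "t", offset = offsets,
                                         ref_allele = "A", alt_allele = "C",
                                         sample_id = "S1", ad_ref = 5L, ad_alt = 5L)
  expect_equal(remove_adjacent(mk(c(10L, 11L, 40L)))$offset, 40L)
  expect_equal(remove_adjacent(mk(c(10L, 12L)))$offset, c(10L, 12L))
  expect_equal(nrow(remove_adjacent(mk(c(5L, 6L, 7L)))), 0)
  once <- remove_adjacent(mk(c(3L, 4L, 9L, 20L, 21L, 30L)))
  expect_equal(remove_adjacent(once), once)
})

test_that("junction-flanking sites are removed for joined tags only", {
  ref <- tibble::tibble(tag_id = c("tj", "tm"), kind = c("joined", "merged"),
                        junction_index = c(130L, NA))
  mk <- function(tag, offsets) tibble::tibble(tag_id = tag, offset = offsets,
                                              ref_allele = "A", alt_allele = "C",
                                              sample_id = "S1", ad_ref = 5L,
                                              ad_alt = 5L)
  out <- remove_junction_flanking(mk("tj", c(129L, 130L, 131L)), ref)
  expect_equal(out$offset, 131L)
  out2 <- remove_junction_flanking(mk("tm", c(129L, 130L)), ref)
  expect_equal(nrow(out2), 2)
  out3 <- remove_junction_flanking(mk("tj", c(5L, 50L)), ref)
  expect_equal(nrow(out3), 2)
})

test_that("select_by_parents keeps A/B markers and fixes polarity", {
  g <- tibble::tibble(marker_id = c("m1", "m2", "m3", "m4"),
                      tag_id = c("t1", "t2", "t3", "t4"), offset = 0L,
                      P1 = c("A", "B", "A", "A"),
                      P2 = c("B", "A", "H", "-"),
                      F2_001 = c("H", "C", "A", "B"),
                      F2_002 = c("A", "D", "B", "H"))
  out <- select_by_parents(g, "P1", "P2")
  expect_equal(out$marker_id, c("m1", "m2"))
  # m2 was (B, A): flipped so A means the parent-1 allele
  expect_equal(out$F2_001, c("H", "D"))
  expect_equal(out$F2_002, c("A", "C"))
  expect_equal(out$P1[2], "A")
  # flipping twice is the identity
  expect_equal(flip_codes(flip_codes(c("A", "B", "C", "D", "H", "-", "F"))),
               c("A", "B", "C", "D", "H", "-", "F"))
  expect_error(select_by_parents(g, "P1", "nope"), "missing")
})

test_that("marker/sample filters use the printed boundaries", {
  n <- 100
  mk_row <- function(codes) {
    g <- tibble::tibble(marker_id = "m", tag_id = "t", offset = 0L)
    g[sprintf("S%03d", seq_along(codes))] <- as.list(codes)
    g
  }
  # 31% missing -> dropped; 30% kept
  g31 <- mk_row(c(rep("-", 31), rep("A", 35), rep("B", 34)))
  g30 <- mk_row(c(rep("-", 30), rep("A", 35), rep("B", 35)))
  expect_warning(expect_equal(nrow(filter_markers_samples(g31)), 0), "removed")
  expect_equal(nrow(filter_markers_samples(g30)), 1)
  # allele balance: 5/95 dropped, 10/90 kept (boundary inclusive)
  g5 <- mk_row(c(rep("A", 5), rep("B", 95)))
  g10 <- mk_row(c(rep("A", 10), rep("B", 90)))
  expect_warning(expect_equal(nrow(filter_markers_samples(g5)), 0), "removed")
  expect_equal(nrow(filter_markers_samples(g10)), 1)
})

write_test_vcf <- function(path, extra_records = character()) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "tag7\t12\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:20,5\t./.:.",
    "tag7\t30\t.\tC\tG,T\t50\tPASS\t.\tGT:AD\t1/2:1,2,3\t0/0:9,0,0",
    "tag8\t5\t.\tA\tAT\t50\tPASS\t.\tGT:AD\t0/1:7,8\t1/1:0,22",
    extra_records), path)
}

test_that("ingest_vcf converts biallelic records and drops multiallelic ones", {
  skip_if_not_installed("vcfR")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f)
  ad <- ingest_vcf(f)
  expect_equal(attr(ad, "n_dropped_multiallelic"), 1L)
  s1 <- dplyr::filter(ad, tag_id == "tag7", sample_id == "S1")
  expect_equal(s1$offset, 11L)               # POS 12 -> 0-based 11
  expect_equal(c(s1$ad_ref, s1$ad_alt), c(20L, 5L))
  smiss <- dplyr::filter(ad, tag_id == "tag7", sample_id == "S2")
  expect_equal(c(smiss$ad_ref, smiss$ad_alt), c(0L, 0L))  # "." -> (0,0)
  indel <- dplyr::filter(ad, tag_id == "tag8", sample_id == "S2")
  expect_equal(indel$alt_allele, "AT")       # indels treated like SNPs
  expect_equal(indel$ad_alt, 22L)

  # union across files: first file wins for duplicated sites
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(readLines(f)[1:4],
               "tag7\t12\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/0:99,0\t0/0:99,0",
               "tag9\t2\t.\tG\tC\t50\tPASS\t.\tGT:AD\t0/1:4,4\t0/1:6,6"), f2)
  both <- ingest_vcf(c(f, f2))
  dup <- dplyr::filter(both, tag_id == "tag7", offset == 11L, sample_id == "S1")
  expect_equal(dup$ad_ref, 20L)
  expect_true("tag9" %in% both$tag_id)
})

test_that("ingest_vcf errors when FORMAT/AD is absent", {
  skip_if_not_installed("vcfR")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "tag1\t3\t.\tA\tG\t50\tPASS\t.\tGT\t0/1"), f)
  expect_error(ingest_vcf(f), "AD")
})
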