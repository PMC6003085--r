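joined_tbl <- function(seqs, sample_id = "S1") {
  tibble::tibble(sample_id = sample_id, sequence = seqs, kind = "joined")
}

test_that("build_stacks merges near-identical stacks with majority consensus", {
  # two 3-read groups one mismatch apart merge; position-4 tie A:3 vs T:3 -> A
  st <- build_stacks(joined_tbl(c(rep("AAAA", 3), rep("AAAT", 3))),
                     cluster_params(m = 2, M = 1, N = 1))
  expect_equal(nrow(st), 1)
  expect_equal(st$consensus, "AAAA")
  expect_equal(st$depth, 6L)

  # distance 4 > M: two stacks
  st2 <- build_stacks(joined_tbl(c(rep("AAAA", 3), rep("TTTT", 3))),
                      cluster_params(m = 2, M = 1, N = 1))
  expect_equal(nrow(st2), 2)

  # singleton attached as secondary within N
  st3 <- build_stacks(joined_tbl(c(rep("AAAA", 3), "AAAG")),
                      cluster_params(m = 2, M = 1, N = 1))
  expect_equal(st3$depth, 4L)
  expect_equal(st3$n_secondary, 1L)

  # secondary equidistant from two stacks is discarded
  st4 <- build_stacks(joined_tbl(c(rep("AAAA", 3), rep("AATT", 3), "AAAT")),
                      cluster_params(m = 2, M = 0, N = 1))
  expect_equal(sum(st4$depth), 6L)
  expect_equal(attr(st4, "n_discarded")$n_discarded, 1L)
})

test_that("build_stacks errors on mixed read lengths and is order-independent", {
  expect_error(build_stacks(joined_tbl(c("AAAA", "AAA"))), "uniform")
  set.seed(31)
  reads <- rand_reads(40, 12)
  a <- build_stacks(joined_tbl(reads), cluster_params(2, 1, 1))
  b <- build_stacks(joined_tbl(rev(reads)), cluster_params(2, 1, 1))
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("build_stacks matches the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(5:30, 1); L <- sample(6:20, 1)
    m <- sample(1:2, 1); M <- sample(0:2, 1); N <- max(M, sample(0:2, 1))
    reads <- rand_reads(n, L)
    got <- build_stacks(joined_tbl(reads), cluster_params(m, M, N))
    want <- oracle_stacks(reads, m, M, N)
    got <- got[order(got$consensus, got$depth, got$n_primary),
               c("consensus", "depth", "n_primary", "n_secondary")]
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE,
                 info = sprintf("instance %d (n=%d L=%d m=%d M=%d N=%d)",
                                i, n, L, m, M, N))
    # depth conservation
    expect_equal(sum(got$depth) +
                   attr(build_stacks(joined_tbl(reads), cluster_params(m, M, N)),
                        "n_discarded")$n_discarded, n)
  }
})

test_that("asustacks pools consensuses across samples with union presence", {
  st <- dplyr::bind_rows(
    tibble::tibble(sample_id = "S1", stack_id = "a", consensus = "ACGTACGT",
                   depth = 5L, kind = "joined"),
    tibble::tibble(sample_id = "S2", stack_id = "b", consensus = "ACGTACGT",
                   depth = 3L, kind = "joined"),
    tibble::tibble(sample_id = "S3", stack_id = "c", consensus = "ACGTACGT",
                   depth = 2L, kind = "joined"))
  cl <- asustacks(st, M = 1)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$presence_count, 3L)

  # one mismatch -> merged cluster with union of samples
  st2 <- dplyr::bind_rows(st[1:2, ],
                          tibble::tibble(sample_id = "S3", stack_id = "c",
                                         consensus = "ACGTACGA", depth = 2L,
                                         kind = "joined"))
  cl2 <- asustacks(st2, M = 1)
  expect_equal(nrow(cl2), 1)
  expect_setequal(cl2$samples_present[[1]], c("S1", "S2", "S3"))

  # two mismatches -> separate clusters
  st3 <- dplyr::bind_rows(st[1, ],
                          tibble::tibble(sample_id = "S2", stack_id = "b",
                                         consensus = "ACGTACAA", depth = 2L,
                                         kind = "joined"))
  expect_equal(nrow(asustacks(st3, M = 1)), 2)
})

test_that("adding a sample never decreases a cluster's presence count", {
  set.seed(17)
  base <- tibble::tibble(sample_id = rep(c("S1", "S2"), each = 4),
                         stack_id = sprintf("x%d", 1:8),
                         consensus = rep(rand_reads(4, 10), 2),
                         depth = 2L, kind = "joined")
  before <- asustacks(base, M = 1)
  extra <- dplyr::bind_rows(base,
                            tibble::tibble(sample_id = "S3", stack_id = "y1",
                                           consensus = base$consensus[1],
                                           depth = 2L, kind = "joined"))
  after <- asustacks(extra, M = 1)
  m <- match(before$consensus, after$consensus)
  expect_true(all(after$presence_count[m] >= before$presence_count))
})

test_that("artificial FASTQ export writes E qualities and stack names", {
  st <- build_stacks(joined_tbl(rep("ACGTACGT", 3)), cluster_params(2, 1, 1))
  f <- withr::local_tempfile(fileext = ".fastq")
  export_stacks_fastq(st, f)
  lines <- readLines(f)
  expect_equal(length(lines), 4)
  expect_match(lines[1], "^@S1_s")
  expect_equal(lines[4], strrep("E", 8))
})
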