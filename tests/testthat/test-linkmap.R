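test_that("kosambi_cm matches the closed form and is strictly monotone", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.2), 25 * log(1.4 / 0.6), tolerance = 1e-12)
  expect_equal(kosambi_cm(0.2), 21.18, tolerance = 0.01 / 21.18)
  expect_gt(kosambi_cm(0.3), kosambi_cm(0.2))
  rs <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(kosambi_cm(rs)) > 0))
  expect_error(kosambi_cm(-0.01), "outside")
  expect_error(kosambi_cm(0.51), "outside")
  expect_warning(kosambi_cm(0.5), "clamp")
})

test_that("two-point estimate is 0 for identical informative vectors", {
  set.seed(21)
  g <- sample(c("A", "H", "B"), 50, replace = TRUE, prob = c(.25, .5, .25))
  res <- estimate_two_point(g, g)
  expect_equal(res$r_hat, 0)
  expect_gt(res$lod, 6)
  expect_equal(res$n_informative, 50L)
})

test_that("unlinked markers estimate r near 0.5 with LOD near 0", {
  set.seed(22)
  rhat <- lod <- numeric(20)
  for (i in 1:20) {
    p <- sim_code_pair(200, 0.5)
    res <- estimate_two_point(p$g1, p$g2)
    rhat[i] <- res$r_hat; lod[i] <- res$lod
  }
  expect_gt(mean(rhat), 0.45)
  expect_lt(median(lod), 1)
})

test_that("the maximised likelihood beats a 1001-point grid oracle", {
  set.seed(23)
  codes <- c("A", "H", "B", "C", "D", "-")
  for (i in 1:15) {
    n <- sample(30:80, 1)
    r <- runif(1, 0, 0.5)
    p <- sim_code_pair(n, r)
    # sprinkle ambiguity and missingness
    idx <- sample(n, round(n / 5))
    p$g1[idx] <- sample(codes, length(idx), replace = TRUE)
    res <- estimate_two_point(p$g1, p$g2)
    grid <- oracle_grid_max(p$g1, p$g2)
    ll_hat <- oracle_pair_loglik(p$g1, p$g2, res$r_hat)
    expect_gte(ll_hat, grid$loglik - 1e-6)
  }
})

test_that("two_point_all agrees with the single-pair estimator", {
  set.seed(24)
  g <- tibble::tibble(marker_id = sprintf("m%d", 1:6), tag_id = sprintf("m%d", 1:6))
  for (s in sprintf("S%02d", 1:60)) {
    g[[s]] <- sample(c("A", "H", "B", "-", "C", "D"), 6, replace = TRUE,
                     prob = c(.22, .4, .22, .06, .05, .05))
  }
  tp <- two_point_all(g)
  for (k in sample(nrow(tp), 5)) {
    i <- match(tp$m1[k], g$marker_id); j <- match(tp$m2[k], g$marker_id)
    scols <- sprintf("S%02d", 1:60)
    one <- estimate_two_point(unlist(g[i, scols]), unlist(g[j, scols]))
    expect_equal(tp$r_hat[k], one$r_hat, tolerance = 1e-3)
    expect_equal(tp$lod[k], one$lod, tolerance = 1e-3)
  }
})

test_that("group_markers forms single-linkage chains and reports singletons", {
  tp <- tibble::tibble(m1 = c("a", "b", "a", "a", "b", "c"),
                       m2 = c("b", "c", "c", "d", "d", "d"),
                       r_hat = c(0.05, 0.05, 0.30, 0.49, 0.49, 0.49),
                       lod = c(10, 10, 2, 0.1, 0.1, 0.1),
                       n_informative = 60L)
  grp <- group_markers(tp)
  expect_equal(grp$group_id[grp$marker_id %in% c("a", "b", "c")],
               rep("LG1", 3))
  expect_true(is.na(grp$group_id[grp$marker_id == "d"]))
  expect_equal(attr(grp, "singletons"), "d")
})

test_that("double-recombination counts follow the crossover-delta rule", {
  mk <- function(...) {
    cols <- list(...)
    g <- tibble::tibble(marker_id = sprintf("m%d", seq_along(cols[[1]])),
                        tag_id = sprintf("m%d", seq_along(cols[[1]])))
    for (s in seq_along(cols)) g[[sprintf("S%d", s)]] <- cols[[s]]
    g
  }
  ord <- sprintf("m%d", 1:3)
  expect_equal(count_double_recomb(mk(c("A", "H", "A")), ord)$n_double_recomb,
               c(0L, 1L, 0L))
  expect_equal(count_double_recomb(mk(c("A", "-", "A")), ord)$n_double_recomb,
               c(0L, 0L, 0L))
  expect_equal(count_double_recomb(mk(c("A", "D", "A")), ord)$n_double_recomb,
               c(0L, 0L, 0L))
})

test_that("double-recombination counts equal the exhaustive oracle on small cases", {
  set.seed(25)
  codes <- c("A", "H", "B", "-")
  for (i in 1:200) {
    n <- sample(3:5, 1)
    v <- sample(codes, n, replace = TRUE)
    g <- tibble::tibble(marker_id = sprintf("m%d", 1:n),
                        tag_id = sprintf("m%d", 1:n), S1 = v)
    got <- count_double_recomb(g, g$marker_id)$n_double_recomb
    expect_equal(got, oracle_double_recomb(v),
                 info = paste(v, collapse = ","))
  }
})

test_that("pruning removes noisy markers until all counts are within bounds", {
  set.seed(26)
  n <- 40
  # ten fully cosegregating markers (a tight bin): no events anywhere
  base <- sample(c("A", "H", "B"), n, replace = TRUE, prob = c(.25, .5, .25))
  g <- tibble::tibble(marker_id = sprintf("m%02d", 1:10),
                      tag_id = sprintf("m%02d", 1:10))
  for (s in seq_len(n)) g[[sprintf("S%02d", s)]] <- rep(base[s], 10)
  ord <- g$marker_id
  kept <- prune_double_recomb(g, ord, 4)
  expect_equal(as.character(kept), ord)
  expect_length(attr(kept, "removed"), 0)
  # corrupt one interior marker with shuffled genotypes: it alone is pruned
  g2 <- g
  g2[5, sprintf("S%02d", 1:n)] <- as.list(sample(base))
  kept2 <- prune_double_recomb(g2, ord, 4)
  expect_equal(attr(kept2, "removed"), "m05")
  expect_setequal(as.character(kept2), setdiff(ord, "m05"))
})

test_that("order recovery: simulated groups come back in true order", {
  set.seed(27)
  n <- 200; n_mark <- 8
  pos <- sort(runif(n_mark, 0, 60))  # cM positions
  # simulate genotypes marker by marker along the chromosome (two gametes)
  gam <- function() {
    src <- integer(n_mark); src[1] <- sample(1:2, 1)
    for (k in 2:n_mark) {
      r <- 0.5 * (1 - exp(-2 * (pos[k] - pos[k - 1]) / 100))  # Haldane
      src[k] <- if (runif(1) < r) 3L - src[k - 1] else src[k - 1]
    }
    src
  }
  g <- tibble::tibble(marker_id = sprintf("m%02d", 1:n_mark),
                      tag_id = sprintf("m%02d", 1:n_mark))
  for (s in sprintf("S%03d", 1:n)) {
    gt <- (gam() == 2) + (gam() == 2)
    g[[s]] <- c("A", "H", "B")[gt + 1]
  }
  tp <- two_point_all(g)
  ord <- order_greedy(g$marker_id, tp)
  got <- match(ord$marker_id, g$marker_id)
  expect_true(identical(got, 1:n_mark) || identical(got, n_mark:1))
  # adjacent r estimates near truth
  r_true <- 0.5 * (1 - exp(-2 * diff(pos) / 100))
  r_est <- if (got[1] == 1) ord$r_adj[-1] else rev(ord$r_adj[-1])
  expect_lt(max(abs(r_est - r_true)), 0.06)
  # map length invariant under reversal: positions nondecreasing
  expect_true(all(diff(ord$position_cm) >= 0))
})

test_that("cosegregation bins split only at observed recombination", {
  g <- tibble::tibble(marker_id = c("m1", "m2", "m3"),
                      tag_id = c("m1", "m2", "m3"),
                      S1 = c("A", "A", "H"), S2 = c("H", "H", "H"),
                      S3 = c("B", "-", "B"))
  bins <- bin_cosegregating(g, g$marker_id)
  expect_equal(bins$bin_id, c(1L, 1L, 2L))  # m2->m3: S1 A vs H disjoint
})

test_that("segregation screen flags distorted markers only", {
  set.seed(28)
  g <- tibble::tibble(marker_id = c("ok", "skewed"), tag_id = c("ok", "skewed"))
  for (s in sprintf("S%03d", 1:120)) {
    g[[s]] <- NA_character_
  }
  scols <- sprintf("S%03d", 1:120)
  g[1, scols] <- as.list(sample(c(rep("A", 30), rep("H", 60), rep("B", 30))))
  g[2, scols] <- as.list(sample(c(rep("A", 100), rep("H", 10), rep("B", 10))))
  sc <- segregation_screen(g)
  expect_false(sc$distorted[1])
  expect_true(sc$distorted[2])
})
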