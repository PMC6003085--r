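#' Linkage-mapping parameters
#'
#' @param lod_min Minimum LOD for a linkage edge (default 6).
#' @param r_max Maximum recombination fraction for a linkage edge
#'   (default 0.35).
#' @param max_double_recomb Maximum tolerated double-recombination events per
#'   marker (default 4; markers above it are pruned iteratively).
#' @param em_tolerance Convergence tolerance of the likelihood maximisation
#'   (default 1e-6).
#' @param min_informative Pairs with fewer jointly informative samples are
#'   flagged unreliable (default 10).
#' @return A list of class `map_params`.
#' @export
map_params <- function(lod_min = 6, r_max = 0.35, max_double_recomb = 4L,
                       em_tolerance = 1e-6, min_informative = 10L) {
  stopifnot(lod_min > 0, r_max > 0, r_max <= 0.5, max_double_recomb >= 0)
  structure(list(lod_min = lod_min, r_max = r_max,
                 max_double_recomb = as.integer(max_double_recomb),
                 em_tolerance = em_tolerance,
                 min_informative = as.integer(min_informative)),
            class = "map_params")
}

#' Joint F2 genotype probabilities for two loci
#'
#' The standard two-locus F2 table at recombination fraction `r` under no
#' interference, built by enumerating the four gamete haplotypes of two
#' independent meioses. Rows/columns are ordered (P1 homozygote, heterozygote,
#' P2 homozygote).
#'
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return 3x3 probability matrix summing to 1.
#' @export
f2_joint_prob <- function(r) {
  hap <- expand.grid(a = 1:2, b = 1:2)  # parental origin at locus 1, locus 2
  hp <- ifelse(hap$a == hap$b, (1 - r) / 2, r / 2)
  T <- matrix(0, 3, 3)
  for (g1 in seq_len(4)) for (g2 in seq_len(4)) {
    i <- (hap$a[g1] == 2) + (hap$a[g2] == 2) + 1L
    j <- (hap$b[g1] == 2) + (hap$b[g2] == 2) + 1L
    T[i, j] <- T[i, j] + hp[g1] * hp[g2]
  }
  T
}

# 49 x 9 indicator: which of the 9 joint genotype classes each ordered pair of
# codes (7 x 7, order GENO_CODES) marginalises over.
combo_indicator <- function() {
  bits <- c(1L, 2L, 4L)
  sets <- lapply(code_mask(GENO_CODES), function(m) which(bitwAnd(m, bits) > 0))
  M <- matrix(0, 49, 9)
  for (a in 1:7) for (b in 1:7) {
    k <- (a - 1L) * 7L + b
    for (i in sets[[a]]) for (j in sets[[b]]) M[k, (j - 1L) * 3L + i] <- 1
  }
  M
}

# Every marginalised combo probability is a quadratic in r; cache the 49
# coefficient triples (a + b r + c r^2) so likelihood evaluation is one fma.
.combo_quad <- NULL
get_combo_quad <- function() {
  if (is.null(.combo_quad)) {
    M <- combo_indicator()
    p0 <- as.vector(M %*% as.vector(f2_joint_prob(0)))
    p1 <- as.vector(M %*% as.vector(f2_joint_prob(0.25)))
    p2 <- as.vector(M %*% as.vector(f2_joint_prob(0.5)))
    cc <- (p2 - 2 * p1 + p0) / 0.125      # second difference at step 0.25
    bb <- (p1 - p0) / 0.25 - cc * 0.25
    utils::assignInMyNamespace(".combo_quad", list(a = p0, b = bb, c = cc))
  }
  .combo_quad
}

combo_prob <- function(r) {
  q <- get_combo_quad()
  pmax(q$a + r * (q$b + r * q$c), 0)
}

# counts of the 49 ordered code combos for a pair of code vectors
pair_counts <- function(c1, c2) {
  a <- match(c1, GENO_CODES); b <- match(c2, GENO_CODES)
  tabulate((a - 1L) * 7L + b, nbins = 49L)
}

pair_loglik <- function(counts, r) {
  p <- combo_prob(r)
  used <- counts > 0
  if (any(p[used] <= 0)) return(-Inf)
  sum(counts[used] * log(p[used]))
}

# maximise the two-point likelihood for one 49-count vector
maximize_two_point <- function(counts, tol = 1e-6) {
  f <- function(r) pair_loglik(counts, r)
  opt <- optimize(f, c(1e-9, 0.5), maximum = TRUE, tol = tol)
  ll_half <- f(0.5)
  cand_r <- c(0, opt$maximum, 0.5)
  cand_ll <- c(f(0), opt$objective, ll_half)
  best <- which.max(cand_ll)
  list(r_hat = min(max(cand_r[best], 0), 0.5), loglik = cand_ll[best],
       lod = max((cand_ll[best] - ll_half) / log(10), 0))
}

#' Two-point recombination estimate for a marker pair
#'
#' Maximum-likelihood recombination fraction over the standard F2 two-locus
#' genotype table (no interference), marginalising each ambiguous code over
#' its allele set (`C` over {B,H}, `D` over {A,H}, `-`/`F` over everything).
#' The LOD is the log10 likelihood ratio against independence (r = 0.5).
#'
#' @param g1,g2 Equal-length character vectors of genotype codes.
#' @param params A [map_params()] object.
#' @return One-row tibble: `r_hat`, `lod`, `n_informative`, `reliable`.
#' @export
estimate_two_point <- function(g1, g2, params = map_params()) {
  stopifnot(length(g1) == length(g2))
  inf <- !(g1 %in% c("-", "F")) & !(g2 %in% c("-", "F"))
  res <- maximize_two_point(pair_counts(g1, g2), params$em_tolerance)
  tibble(r_hat = res$r_hat, lod = res$lod,
         n_informative = sum(inf),
         reliable = sum(inf) >= params$min_informative)
}

#' All-pairs two-point estimates for a genotype matrix
#'
#' Same estimator as [estimate_two_point()], evaluated for every marker pair:
#' combo counts are tabulated per pair, likelihoods screened on a coarse
#' recombination grid by one matrix product, and each pair's maximum refined
#' by local maximisation around the best grid point.
#'
#' @param geno Wide genotype matrix.
#' @param samples Sample columns (default: all).
#' @param params A [map_params()] object.
#' @return Tibble: `m1`, `m2`, `r_hat`, `lod`, `n_informative`.
#' @export
two_point_all <- function(geno, samples = NULL, params = map_params()) {
  scols <- samples %||% geno_samples(geno)
  m <- as.matrix(geno[, scols, drop = FALSE])
  ids <- geno$marker_id
  n <- nrow(m)
  if (n < 2) {
    return(tibble(m1 = character(), m2 = character(), r_hat = numeric(),
                  lod = numeric(), n_informative = integer()))
  }
  code_i <- matrix(match(m, GENO_CODES), nrow = n)
  pr <- t(utils::combn(n, 2))
  np <- nrow(pr)
  counts <- matrix(0L, np, 49L)
  for (k in seq_len(np)) {
    counts[k, ] <- tabulate((code_i[pr[k, 1], ] - 1L) * 7L + code_i[pr[k, 2], ],
                            nbins = 49L)
  }
  grid <- seq(0.0025, 0.5, by = 0.0025)
  logp <- vapply(grid, function(r) log(pmax(combo_prob(r), 1e-300)), numeric(49))
  ll <- counts %*% logp                 # pairs x G
  best <- max.col(ll, ties.method = "last")
  ll_half <- ll[, length(grid)]
  r_hat <- numeric(np); lod <- numeric(np)
  for (k in seq_len(np)) {
    ck <- counts[k, ]
    f <- function(r) pair_loglik(ck, r)
    lo <- if (best[k] > 1) grid[best[k] - 1L] else 1e-9
    hi <- grid[min(best[k] + 1L, length(grid))]
    opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = params$em_tolerance)
    cand_r <- c(0, opt$maximum, 0.5)
    cand_ll <- c(f(0), opt$objective, ll_half[k])
    b <- which.max(cand_ll)
    r_hat[k] <- cand_r[b]
    lod[k] <- max((cand_ll[b] - ll_half[k]) / log(10), 0)
  }
  inf <- (code_i != 6L) & (code_i != 7L)
  n_inf <- vapply(seq_len(np), function(k) sum(inf[pr[k, 1], ] & inf[pr[k, 2], ]),
                  integer(1))
  tibble(m1 = ids[pr[, 1]], m2 = ids[pr[, 2]],
         r_hat = r_hat, lod = lod, n_informative = n_inf)
}

#' Split markers into linkage groups
#'
#' Single-linkage connected components over edges with
#' `lod >= lod_min & r_hat <= r_max`. Groups are labelled `LG1`, `LG2`, ... by
#' decreasing size; singletons get `group_id = NA` and are reported in the
#' `singletons` attribute.
#'
#' @param tp Two-point table ([two_point_all()]).
#' @param params A [map_params()] object.
#' @return Tibble `marker_id`, `group_id`.
#' @export
group_markers <- function(tp, params = map_params()) {
  ids <- sort(unique(c(tp$m1, tp$m2)))
  sel <- tp$lod >= params$lod_min & tp$r_hat <= params$r_max
  edges <- cbind(match(tp$m1[sel], ids), match(tp$m2[sel], ids))
  comp <- components_from_edges(length(ids), edges)
  sz <- table(comp)
  singleton <- sz[as.character(comp)] == 1
  ord <- order(-as.integer(sz), as.integer(names(sz)))
  lab <- setNames(rep(NA_character_, length(sz)), names(sz)[ord])
  big <- names(sz)[ord][sz[ord] > 1]
  lab[big] <- sprintf("LG%d", seq_along(big))
  out <- tibble(marker_id = ids, group_id = unname(lab[as.character(comp)]))
  attr(out, "singletons") <- ids[singleton]
  out
}

#' Kosambi map distance
#'
#' `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans. `r` must lie in
#' `[0, 0.5]`; values within `1e-9` of 0.5 (including 0.5 itself, as produced
#' by a capped estimator) are clamped with a warning.
#'
#' @param r Recombination fraction(s).
#' @return Distance(s) in cM.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r > 0.5)) abort("recombination fraction outside [0, 0.5]")
  if (any(r >= 0.5 - 1e-9)) {
    warn("recombination fraction at 0.5 clamped for Kosambi transform")
    r <- pmin(r, 0.5 - 1e-9)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

# r_hat lookup matrix for a set of markers from the two-point table
r_matrix <- function(ids, tp) {
  n <- length(ids)
  R <- matrix(0.5, n, n, dimnames = list(ids, ids))
  diag(R) <- 0
  i <- match(tp$m1, ids); j <- match(tp$m2, ids)
  sel <- !is.na(i) & !is.na(j)
  R[cbind(i[sel], j[sel])] <- tp$r_hat[sel]
  R[cbind(j[sel], i[sel])] <- tp$r_hat[sel]
  R
}

# all permutations of 1..k (deterministic order)
perm_rows <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_rows(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}

# 2-opt segment reversal: reversing ord[i:j] changes only the two boundary
# edges; repeat first-improvement sweeps until stable. Fixes end segments the
# greedy insertion assembled in the wrong orientation.
two_opt <- function(ord, R) {
  n <- length(ord)
  if (n < 4) return(ord)
  improved <- TRUE; guard <- 0L
  while (improved && guard < 50L) {
    improved <- FALSE; guard <- guard + 1L
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        before <- (if (i > 1) R[ord[i - 1L], ord[i]] else 0) +
                  (if (j < n) R[ord[j], ord[j + 1L]] else 0)
        after <- (if (i > 1) R[ord[i - 1L], ord[j]] else 0) +
                 (if (j < n) R[ord[i], ord[j + 1L]] else 0)
        if (after < before - 1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
  }
  ord
}

# sliding-window local improvement with local cost deltas (a ripple-like pass)
ripple_window <- function(ord, R, w = 3L) {
  if (length(ord) < w) return(ord)
  perms <- perm_rows(w)
  local_cost <- function(prev, win, nxt) {
    (if (is.na(prev)) 0 else R[prev, win[1]]) +
      sum(R[cbind(win[-w], win[-1])]) +
      (if (is.na(nxt)) 0 else R[win[w], nxt])
  }
  improved <- TRUE; guard <- 0L
  while (improved && guard < 25L) {
    improved <- FALSE; guard <- guard + 1L
    for (s in seq_len(length(ord) - w + 1L)) {
      prev <- if (s > 1) ord[s - 1L] else NA
      nxt <- if (s + w <= length(ord)) ord[s + w] else NA
      win <- ord[s:(s + w - 1L)]
      costs <- vapply(seq_len(nrow(perms)),
                      function(p) local_cost(prev, win[perms[p, ]], nxt),
                      numeric(1))
      b <- which.min(costs)
      if (b != 1L && costs[b] < costs[1] - 1e-12) {
        ord[s:(s + w - 1L)] <- win[perms[b, ]]
        improved <- TRUE
      }
    }
  }
  ord
}

#' Greedy seriation of one linkage group
#'
#' A deterministic stand-in for multipoint ordering: the two markers at
#' maximal estimated recombination fraction seed the path ends, remaining
#' markers are repeatedly placed at their cheapest insertion point (minimising
#' the sum of adjacent r estimates), and 2-opt segment reversals plus window-3
#' and window-4 ripple passes polish the order. Orientation is canonical (first marker id < last marker id).
#' Positions are cumulative Kosambi distances over adjacent r.
#'
#' @param ids Marker ids of the group (length >= 2).
#' @param tp Two-point table covering the group.
#' @return Tibble `marker_id`, `position_cm`, `r_adj` (r to previous marker).
#' @export
order_greedy <- function(ids, tp) {
  stopifnot(length(ids) >= 2)
  ids <- sort(ids)
  R <- r_matrix(ids, tp)
  n <- length(ids)
  if (n == 2) {
    ord <- 1:2
  } else {
    far <- which(R == max(R[upper.tri(R)]), arr.ind = TRUE)
    far <- far[far[, 1] < far[, 2], , drop = FALSE]
    far <- far[order(ids[far[, 1]], ids[far[, 2]]), , drop = FALSE][1, ]
    ord <- c(far[[1]], far[[2]])
    left <- setdiff(seq_len(n), ord)
    while (length(left)) {
      best <- NULL
      for (x in left) {
        # insertion costs at positions 0..len(ord)
        mid <- if (length(ord) > 1) {
          R[ord[-length(ord)], x] + R[x, ord[-1]] -
            R[cbind(ord[-length(ord)], ord[-1])]
        } else numeric(0)
        costs <- c(R[x, ord[1]], mid, R[ord[length(ord)], x])
        pos <- which.min(costs)
        if (is.null(best) || costs[pos] < best$cost - 1e-12 ||
            (abs(costs[pos] - best$cost) <= 1e-12 && ids[x] < ids[best$x])) {
          best <- list(x = x, pos = pos - 1L, cost = costs[pos])
        }
      }
      ord <- append(ord, best$x, after = best$pos)
      left <- setdiff(left, best$x)
    }
    ord <- two_opt(ord, R)
    ord <- ripple_window(ripple_window(ord, R, 3L), R, 4L)
  }
  if (ids[ord[1]] > ids[ord[length(ord)]]) ord <- rev(ord)
  r_adj <- c(NA, R[cbind(ord[-n], ord[-1])])
  pos <- cumsum(c(0, suppressWarnings(kosambi_cm(pmin(r_adj[-1], 0.5)))))
  tibble(marker_id = ids[ord], position_cm = pos, r_adj = r_adj)
}

#' Count double-recombination events per marker
#'
#' For each progeny the minimal number of crossovers needed to explain the
#' ordered genotype codes is computed by dynamic programming over the allele
#' sets (transition cost between true genotypes = difference in parent-2
#' allele count). An interior marker shows a double-recombination event in a
#' progeny when deleting it reduces that minimal crossover count by two — the
#' signature of two crossovers in a short interval, almost always a
#' genotyping error. Missing and ambiguous codes compatible with the
#' neighbourhood are never counted.
#'
#' @param geno Wide genotype matrix.
#' @param order Character vector of marker ids in map order.
#' @param samples Sample columns (default: all).
#' @return Tibble `marker_id`, `n_double_recomb`.
#' @export
count_double_recomb <- function(geno, order, samples = NULL) {
  scols <- samples %||% geno_samples(geno)
  m <- as.matrix(geno[match(order, geno$marker_id), scols, drop = FALSE])
  masks <- matrix(code_mask(m), nrow = length(order))
  n <- length(order)
  counts <- integer(n)
  if (n < 3) return(tibble(marker_id = order, n_double_recomb = counts))
  a2 <- c(0, 1, 2)                       # parent-2 allele count per genotype
  trans <- abs(outer(a2, a2, "-"))       # min crossovers between genotypes
  for (s in seq_along(scols)) {
    v <- masks[, s]
    allowed <- vapply(0:2, function(g) bitwAnd(v, bitwShiftL(1L, g)) > 0,
                      logical(n))        # n x 3
    F <- matrix(Inf, n, 3); B <- matrix(Inf, n, 3)
    F[1, allowed[1, ]] <- 0
    for (i in 2:n) for (g in which(allowed[i, ])) {
      F[i, g] <- min(F[i - 1, ] + trans[, g])
    }
    B[n, allowed[n, ]] <- 0
    for (i in (n - 1):1) for (g in which(allowed[i, ])) {
      B[i, g] <- min(trans[g, ] + B[i + 1, ])
    }
    for (i in 2:(n - 1)) {
      with_i <- min(F[i, ] + B[i, ])
      gap <- outer(F[i - 1, ], B[i + 1, ], "+") + trans
      without_i <- min(gap)
      if (is.finite(with_i) && with_i - without_i >= 2) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  tibble(marker_id = order, n_double_recomb = counts)
}

#' Iteratively prune markers with excess double recombinations
#'
#' Removes the worst marker with more than `max_double_recomb` events (ties:
#' alphabetically smallest id), recounts, and repeats until every marker is at
#' or below the threshold.
#'
#' @inheritParams count_double_recomb
#' @param max_double_recomb Threshold (default 4).
#' @return Character vector: the surviving marker order. Attribute `removed`.
#' @export
prune_double_recomb <- function(geno, order, max_double_recomb = 4L,
                                samples = NULL) {
  removed <- character(0)
  order <- as.character(order)
  repeat {
    if (length(order) < 3) break
    dr <- count_double_recomb(geno, order, samples)
    bad <- filter(dr, .data$n_double_recomb > max_double_recomb)
    if (nrow(bad) == 0) break
    worst <- arrange(bad, desc(.data$n_double_recomb), .data$marker_id)$marker_id[1]
    removed <- c(removed, worst)
    order <- setdiff(order, worst)
  }
  attr(order, "removed") <- removed
  order
}

#' Bin markers not separated by observed recombination
#'
#' Consecutive markers in map order share a bin unless at least one progeny
#' carries codes with disjoint allele sets at the two markers (an observed
#' recombination event). The first marker of each bin is its representative.
#'
#' @param geno Wide genotype matrix.
#' @param order Marker ids in map order.
#' @param samples Sample columns (default: all).
#' @return Tibble `marker_id`, `bin_id` (integer, consecutive from 1).
#' @export
bin_cosegregating <- function(geno, order, samples = NULL) {
  scols <- samples %||% geno_samples(geno)
  m <- as.matrix(geno[match(order, geno$marker_id), scols, drop = FALSE])
  masks <- matrix(code_mask(m), nrow = length(order))
  bin <- integer(length(order))
  if (length(order)) bin[1] <- 1L
  for (i in seq_len(length(order) - 1L)) {
    recomb <- any(bitwAnd(masks[i, ], masks[i + 1L, ]) == 0L)
    bin[i + 1L] <- bin[i] + recomb
  }
  tibble(marker_id = order, bin_id = bin)
}

#' Chi-square screen for segregation distortion
#'
#' Tests each marker's definitive calls against the F2 expectation
#' 1 A : 2 H : 1 B. Ambiguous codes are excluded from the test. Flagged
#' markers can be held out of grouping/ordering and re-added afterwards.
#'
#' @param geno Wide genotype matrix.
#' @param alpha Significance level (default 0.01).
#' @param samples Sample columns (default: all).
#' @return Tibble `marker_id`, `p_value`, `distorted`.
#' @export
segregation_screen <- function(geno, alpha = 0.01, samples = NULL) {
  scols <- samples %||% geno_samples(geno)
  m <- as.matrix(geno[, scols, drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(i) {
    obs <- c(sum(m[i, ] == "A"), sum(m[i, ] == "H"), sum(m[i, ] == "B"))
    if (sum(obs) < 8) return(NA_real_)
    suppressWarnings(chisq.test(obs, p = c(0.25, 0.5, 0.25))$p.value)
  }, numeric(1))
  tibble(marker_id = geno$marker_id, p_value = p,
         distorted = !is.na(p) & p < alpha)
}

#' Build a linkage map end to end
#'
#' Runs two-point analysis, linkage grouping, greedy ordering, iterative
#' double-recombination pruning, Kosambi positioning and cosegregation binning
#' for every group with at least two markers.
#'
#' @param geno Wide genotype matrix (typically deduplicated representatives).
#' @param samples Sample columns used for estimation (default: all).
#' @param params A [map_params()] object.
#' @param membership Optional dedup membership map
#'   ([dedup_cosegregating()]); members are re-attached to their
#'   representative's position and bin.
#' @return Object of class `gbs_map`: list with `map` (tibble `group_id`,
#'   `marker_id`, `bin_id`, `position_cm`, `r_adj`, `cosegregating_with`),
#'   `two_point`, `groups`, `singletons`, `pruned`, `params`.
#' @export
build_linkage_map <- function(geno, samples = NULL, params = map_params(),
                              membership = NULL) {
  scols <- samples %||% geno_samples(geno)
  tp <- two_point_all(geno, scols, params)
  grp <- group_markers(tp, params)
  pruned <- character(0)
  maps <- purrr::map(sort(unique(stats::na.omit(grp$group_id))), function(g) {
    ids <- grp$marker_id[!is.na(grp$group_id) & grp$group_id == g]
    ord0 <- order_greedy(ids, tp)$marker_id
    ord <- prune_double_recomb(geno, ord0, params$max_double_recomb, scols)
    pruned <<- c(pruned, attr(ord, "removed"))
    ord_tbl <- if (length(ord) >= 2) order_greedy(ord, tp) else
      tibble(marker_id = as.character(ord), position_cm = 0, r_adj = NA_real_)
    bins <- bin_cosegregating(geno, ord_tbl$marker_id, scols)
    mutate(left_join(ord_tbl, bins, by = "marker_id"), group_id = g, .before = 1)
  })
  map <- bind_rows(maps)
  if (nrow(map) == 0) {
    map <- tibble(group_id = character(), marker_id = character(),
                  position_cm = numeric(), r_adj = numeric(),
                  bin_id = integer())
  }
  map$cosegregating_with <- rep(NA_character_, nrow(map))
  if (!is.null(membership) && nrow(map)) {
    extra <- filter(as_tibble(membership),
                    .data$member_id != .data$representative_id,
                    .data$representative_id %in% map$marker_id)
    if (nrow(extra)) {
      add <- left_join(extra, map, by = c(representative_id = "marker_id"))
      add <- tibble(group_id = add$group_id, marker_id = add$member_id,
                    position_cm = add$position_cm, r_adj = NA_real_,
                    bin_id = add$bin_id,
                    cosegregating_with = add$representative_id)
      map <- arrange(bind_rows(map, add), .data$group_id, .data$position_cm,
                     !is.na(.data$cosegregating_with), .data$marker_id)
    }
  }
  structure(list(map = map, two_point = tp, groups = grp,
                 singletons = attr(grp, "singletons"),
                 pruned = pruned, params = params),
            class = "gbs_map")
}

#' @export
print.gbs_map <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("GBS linkage map: %d groups, %d markers (%d pruned, %d singletons), %.1f cM total\n",
              g$n_groups, g$n_markers, g$n_pruned, g$n_singletons, g$total_cm))
  cat("(greedy two-point ordering: an approximation of multipoint ML ordering)\n")
  invisible(x)
}

#' @export
tidy.gbs_map <- function(x, ...) x$map

#' @export
glance.gbs_map <- function(x, ...) {
  by_g <- summarise(group_by(x$map, .data$group_id),
                    len = if (dplyr::n() > 0) max(.data$position_cm) else 0,
                    .groups = "drop")
  tibble(n_groups = nrow(by_g), n_markers = nrow(x$map),
         n_pruned = length(x$pruned), n_singletons = length(x$singletons),
         total_cm = sum(by_g$len))
}

#' Write a linkage map TSV
#'
#' @param map A `gbs_map` object or its `map` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (inherits(map, "gbs_map")) map <- map$map
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
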