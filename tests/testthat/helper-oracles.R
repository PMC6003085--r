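# Independent oracles implementing the stated rules literally (brute force).
# They are deliberately written without reusing package internals.

# --- genotype scoring: literal rule with quotient comparisons ---------------
oracle_score_genotype <- function(ad_ref, ad_alt, min_total = 8) {
  mapply(function(rf, al) {
    if (rf + al < min_total) return("-")
    r <- if (al == 0) Inf else rf / al
    if (r >= 10) return("A")
    if (r <= 0.10) return("B")
    if (r > 4 && r < 10) return("D")
    if (r > 0.1 && r < 0.25) return("C")
    "H"
  }, ad_ref, ad_alt)
}

# --- clustering: literal single-linkage + weighted majority -----------------
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

oracle_consensus <- function(seqs, w) {
  m <- do.call(rbind, strsplit(seqs, ""))
  paste0(apply(m, 2, function(col) {
    t <- tapply(w, col, sum)
    names(t)[t == max(t)][1]  # tapply sorts names, so ties -> smallest base
  }), collapse = "")
}

oracle_stacks <- function(seqs, m, M, N) {
  tab <- table(seqs)
  u <- sort(names(tab))
  cnt <- as.integer(tab[u])
  prim <- which(cnt >= m)
  if (!length(prim)) {
    return(data.frame(consensus = character(), depth = integer(),
                      n_primary = integer(), n_secondary = integer()))
  }
  np <- length(prim)
  adj <- diag(TRUE, np)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (oracle_hamming(u[prim[i]], u[prim[j]]) <= M) adj[i, j] <- TRUE
  }
  # transitive closure
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, np)
  cid <- 0L
  for (i in seq_len(np)) {
    if (is.na(comp[i])) { cid <- cid + 1L; comp[which(adj[i, ])] <- cid }
  }
  cons <- vapply(seq_len(cid), function(k) {
    idx <- prim[comp == k]
    oracle_consensus(u[idx], cnt[idx])
  }, character(1))
  depth_p <- vapply(seq_len(cid), function(k) sum(cnt[prim[comp == k]]), integer(1))
  n_sec <- integer(cid)
  for (i in setdiff(seq_along(u), prim)) {
    d <- vapply(cons, function(cs) oracle_hamming(u[i], cs), integer(1))
    dm <- min(d)
    if (dm <= N && sum(d == dm) == 1) {
      n_sec[which.min(d)] <- n_sec[which.min(d)] + cnt[i]
    }
  }
  out <- data.frame(consensus = cons, depth = depth_p + n_sec,
                    n_primary = depth_p, n_secondary = n_sec)
  out[order(out$consensus, out$depth, out$n_primary), , drop = FALSE]
}

rand_reads <- function(n, L, alphabet_bias = 0.7) {
  # draw reads around a few centroids so clusters actually form
  k <- sample(1:3, 1)
  centroids <- replicate(k, paste0(sample(c("A", "C", "G", "T"), L, TRUE),
                                   collapse = ""))
  vapply(seq_len(n), function(i) {
    s <- strsplit(sample(centroids, 1), "")[[1]]
    nmut <- rbinom(1, L, 1 - alphabet_bias) %% (L)
    if (nmut > 0) {
      pos <- sample.int(L, min(nmut, L))
      s[pos] <- sample(c("A", "C", "G", "T"), length(pos), TRUE)
    }
    paste0(s, collapse = "")
  }, character(1))
}

# --- two-point likelihood: independent grid oracle --------------------------
oracle_joint_f2 <- function(r) {
  # direct closed-form F2 two-locus table (coupling), rows/cols = (P1hom, het, P2hom)
  cc <- (1 - r) / 2; rr <- r / 2
  g <- c(cc, rr, rr, cc)  # haplotype probs: 11, 12, 21, 22
  idx <- expand.grid(h1 = 1:4, h2 = 1:4)
  loc1 <- c(1, 1, 2, 2); loc2 <- c(1, 2, 1, 2)  # parental origin per locus
  T <- matrix(0, 3, 3)
  for (k in seq_len(nrow(idx))) {
    a <- (loc1[idx$h1[k]] == 2) + (loc1[idx$h2[k]] == 2) + 1
    b <- (loc2[idx$h1[k]] == 2) + (loc2[idx$h2[k]] == 2) + 1
    T[a, b] <- T[a, b] + g[idx$h1[k]] * g[idx$h2[k]]
  }
  T
}

oracle_sets <- list(A = 1, H = 2, B = 3, D = c(1, 2), C = c(2, 3),
                    `-` = 1:3, F = 1:3)

oracle_pair_loglik <- function(g1, g2, r) {
  T <- oracle_joint_f2(r)
  sum(log(mapply(function(a, b) {
    sum(T[oracle_sets[[a]], oracle_sets[[b]]])
  }, g1, g2)))
}

oracle_grid_max <- function(g1, g2, grid = seq(0, 0.5, length.out = 1001)) {
  ll <- vapply(grid, function(r) oracle_pair_loglik(g1, g2, r), numeric(1))
  list(r = grid[which.max(ll)], loglik = max(ll), grid = grid, ll = ll)
}

# sample joint F2 codes for two loci at recombination fraction r
sim_code_pair <- function(n, r) {
  T <- oracle_joint_f2(r)
  cls <- sample(9, n, replace = TRUE, prob = as.vector(T))
  codes <- c("A", "H", "B")
  list(g1 = codes[(cls - 1) %% 3 + 1], g2 = codes[(cls - 1) %/% 3 + 1])
}

# --- double recombination: exhaustive minimal-crossover oracle --------------
oracle_min_crossovers <- function(codes) {
  sets <- oracle_sets[codes]
  grids <- expand.grid(sets)
  if (nrow(grids) == 0) return(0)
  min(apply(grids, 1, function(g) sum(abs(diff(as.numeric(g) - 1)))))
}

oracle_double_recomb <- function(codes) {
  # per interior marker: does deleting it reduce the crossover count by >= 2?
  n <- length(codes)
  out <- integer(n)
  if (n < 3) return(out)
  full <- oracle_min_crossovers(codes)
  for (i in 2:(n - 1)) {
    out[i] <- as.integer(full - oracle_min_crossovers(codes[-i]) >= 2)
  }
  out
}

# --- small simulation configs for fast tests --------------------------------
quick_cfg <- function(seed = 11, chrom_len_bp = 150000L, n_progeny = 12L,
                      n_chrom_pairs = 1L, ...) {
  sim_config(seed = seed, chrom_len_bp = chrom_len_bp, n_progeny = n_progeny,
             n_chrom_pairs = n_chrom_pairs, ...)
}

# joined-read construction used by the generator (fragment -> reference tag)
truth_tagify <- function(seq, tf = 130L, tr = 145L, remnant = 5L) {
  L <- nchar(seq)
  paste0(substr(seq, remnant + 1L, remnant + tf), substr(seq, L - tr + 1L, L))
}
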