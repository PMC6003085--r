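#' Reverse-complement DNA sequences
#'
#' Vectorised over character sequences; `N` is preserved.
#'
#' @param x Character vector of DNA sequences (alphabet `ACGTN`).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "AACC"))
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCAtgcaN", x))
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Character scalars of equal length.
#' @return Integer mismatch count.
#' @export
hamming <- function(a, b) cpp_hamming(a, b)

# Connected components by union-find. `n` nodes, `edges` a 2-column integer
# matrix of 1-based pairs. Returns integer component labels 1..k, numbered by
# first node appearance (deterministic).
components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(edges) && nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Per-position majority consensus over equal-length sequences with integer
# weights; ties resolved to the alphabetically smallest base.
majority_consensus <- function(seqs, weights = rep(1L, length(seqs))) {
  if (length(seqs) == 1L) return(seqs)
  L <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  out <- character(L)
  for (j in seq_len(L)) {
    w <- rowsum(weights, m[, j])
    # rowsum returns groups in sorted order, so which.max takes the
    # alphabetically smallest base on ties
    out[j] <- rownames(w)[which.max(w[, 1])]
  }
  paste0(out, collapse = "")
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N} (first offender: %s)",
                  what, x[which(bad)[1]]))
  }
  invisible(x)
}

# Portable seeding: fix all RNG kinds so streams are stable across platforms
# and R versions that share these generators.
set_portable_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}
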