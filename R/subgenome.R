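#' Tag presence in diploid-progenitor accessions
#'
#' A tag is "hit" by a progenitor accession when at least one of that
#' accession's joined reads lies within `max_mismatch` Hamming distance of the
#' tag (reads equidistant from two tags are discarded, as in allele counting).
#'
#' @param progenitor_reads Joined reads of the progenitor accessions
#'   (columns `sample_id` = accession, `sequence`).
#' @param reference Reference tags.
#' @param max_mismatch Maximum Hamming distance for a hit (default 4).
#' @return Wide tibble: `tag_id`, then one 0/1 column per accession.
#' @export
progenitor_hits <- function(progenitor_reads, reference, max_mismatch = 4L) {
  reads <- as_tibble(progenitor_reads)
  accs <- sort(unique(reads$sample_id))
  asg <- cpp_assign_nearest(reads$sequence, reference$sequence, max_mismatch)
  hit <- tibble(tag_id = reference$tag_id[asg$idx], accession = reads$sample_id)
  hit <- distinct(filter(hit, !is.na(.data$tag_id)))
  out <- tibble(tag_id = reference$tag_id)
  for (a in accs) {
    out[[a]] <- as.integer(out$tag_id %in% hit$tag_id[hit$accession == a])
  }
  out
}

#' Classify tag presence across progenitor accessions
#'
#' Present: hit in at least two accessions. Absent: hit in none. A single hit
#' is ambiguous and excluded from subgenome-assignment evidence.
#'
#' @param hits Wide hits table ([progenitor_hits()]): `tag_id` plus one 0/1
#'   column per accession.
#' @return Tibble `tag_id`, `n_hits`, `class` in
#'   `{"present","absent","ambiguous"}`.
#' @export
classify_presence <- function(hits) {
  accs <- setdiff(names(hits), "tag_id")
  if (!length(accs)) abort("hits table has no accession columns")
  n <- rowSums(as.matrix(hits[accs]))
  tibble(tag_id = hits$tag_id, n_hits = as.integer(n),
         class = case_when(n >= 2 ~ "present", n == 0 ~ "absent",
                           TRUE ~ "ambiguous"))
}

#' Detect presence/absence change points along a linkage group
#'
#' Single change-point binary segmentation minimising the Bernoulli deviance
#' of the 0/1 presence sequence, recursing into segments (at most
#' `max_breakpoints` accepted). A split is accepted when both segments have at
#' least `min_seg` informative tags and their presence fractions differ by at
#' least `min_diff`. Breakpoints are reported as the cM midpoint between the
#' flanking tags.
#'
#' @param present Integer/logical vector (1 = present, 0 = absent), ordered by
#'   map position.
#' @param pos_cm Matching cM positions.
#' @param min_seg Minimum informative tags per segment (default 5).
#' @param min_diff Minimum difference in segment fractions (default 0.25).
#' @param max_breakpoints Recursion cap (default 2).
#' @return Numeric vector of breakpoint positions (possibly empty), sorted.
#' @export
detect_breakpoint <- function(present, pos_cm, min_seg = 5L, min_diff = 0.25,
                              max_breakpoints = 2L) {
  present <- as.integer(present)
  stopifnot(length(present) == length(pos_cm))
  bern_dev <- function(x) {
    n <- length(x); k <- sum(x)
    if (n == 0 || k == 0 || k == n) return(0)
    p <- k / n
    -2 * (k * log(p) + (n - k) * log(1 - p))
  }
  split_one <- function(idx) {
    x <- present[idx]
    n <- length(x)
    if (n < 2 * min_seg) return(NULL)
    ks <- min_seg:(n - min_seg)
    dev <- vapply(ks, function(k) bern_dev(x[1:k]) + bern_dev(x[(k + 1):n]),
                  numeric(1))
    k <- ks[which.min(dev)]
    p1 <- mean(x[1:k]); p2 <- mean(x[(k + 1):n])
    if (abs(p1 - p2) < min_diff) return(NULL)
    if (dev[which.min(dev)] >= bern_dev(x) - 1e-12) return(NULL)
    list(k = k, bp = (pos_cm[idx[k]] + pos_cm[idx[k + 1]]) / 2)
  }
  out <- numeric(0)
  queue <- list(seq_along(present))
  while (length(queue) && length(out) < max_breakpoints) {
    idx <- queue[[1]]; queue <- queue[-1]
    sp <- split_one(idx)
    if (is.null(sp)) next
    out <- c(out, sp$bp)
    if (length(out) < max_breakpoints) {
      queue <- c(queue, list(idx[1:sp$k]), list(idx[(sp$k + 1):length(idx)]))
    }
  }
  sort(out)
}

#' Assign linkage groups to subgenomes
#'
#' For each linkage group the fraction of informative tags present in the
#' diploid progenitor is computed (ambiguous single-hit tags are excluded) and
#' the ordered presence pattern is scanned for change points. Groups with
#' progenitor tags along their entire length (`f >= tau_a`, no accepted
#' change point) are called the A subgenome, groups uniformly devoid of them
#' (`f <= tau_b`) the B subgenome; everything else — including any group whose
#' presence pattern switches along the map, the signature of a homoeologous
#' translocation — is `mixed`, with the change points reported as breakpoints.
#'
#' @param map A `gbs_map` object or its `map` tibble (tag-level markers:
#'   `marker_id` must equal the tag id).
#' @param presence [classify_presence()] output.
#' @param tau_a,tau_b Call thresholds on the present fraction (defaults 0.30
#'   and 0.05; the thresholds are operating points for a visual criterion and
#'   are configurable).
#' @param min_informative Minimum informative tags to call a group
#'   (default 10; below it the call is `mixed` with a warning).
#' @param ... Passed to [detect_breakpoint()].
#' @return Object of class `gbs_subgenome`: tibble `group_id`, `call`,
#'   `present_fraction`, `n_informative`, `breakpoints` (list column), with
#'   the per-tag scatter data in attribute `scatter`.
#' @export
assign_subgenome <- function(map, presence, tau_a = 0.30, tau_b = 0.05,
                             min_informative = 10L, ...) {
  if (inherits(map, "gbs_map")) map <- map$map
  dat <- inner_join(map, presence, by = c(marker_id = "tag_id"))
  if (nrow(dat) == 0) {
    warn("no mapped tags with presence information; no subgenome calls")
    out <- tibble(group_id = character(), call = character(),
                  present_fraction = numeric(), n_informative = integer(),
                  breakpoints = list())
    attr(out, "scatter") <- tibble(group_id = character(),
                                   marker_id = character(),
                                   position_cm = numeric(), y = integer(),
                                   class = character())
    class(out) <- c("gbs_subgenome", class(out))
    return(out)
  }
  dat <- filter(dat, .data$class %in% c("present", "absent"))
  dat <- mutate(dat, y = ifelse(.data$class == "present", 2L, 0L))
  dat <- arrange(dat, .data$group_id, .data$position_cm, .data$marker_id)
  res <- purrr::map(split(dat, dat$group_id), function(d) {
    n <- nrow(d)
    f <- mean(d$class == "present")
    # a change point in the presence pattern overrides the overall fraction:
    # an A (or B) call requires the pattern to hold along the whole group
    bp <- if (n >= 20) {
      detect_breakpoint(d$class == "present", d$position_cm, ...)
    } else numeric(0)
    if (n < min_informative) {
      warn(sprintf("group %s: only %d informative tags; call is 'mixed'",
                   d$group_id[1], n))
      call <- "mixed"
    } else if (length(bp)) call <- "mixed"
    else if (f >= tau_a) call <- "A"
    else if (f <= tau_b) call <- "B"
    else call <- "mixed"
    tibble(group_id = d$group_id[1], call = call, present_fraction = f,
           n_informative = n, breakpoints = list(bp))
  })
  out <- bind_rows(res)
  attr(out, "scatter") <- select(dat, "group_id", "marker_id", "position_cm",
                                 "y", "class")
  class(out) <- c("gbs_subgenome", class(out))
  out
}

#' Per-tag presence scatter data (plot export)
#'
#' The plotting data behind the presence/absence charts: informative tags by
#' map position, with class 2 (present in >= 2 accessions) or 0 (absent from
#' all).
#'
#' @param x A `gbs_subgenome` object.
#' @return Tibble `group_id`, `marker_id`, `position_cm`, `y`.
#' @export
subgenome_scatter <- function(x) attr(x, "scatter")

#' Classify dosage of a map region from read depths
#'
#' For each progeny, the median total allelic depth over the region's markers
#' is compared with the cohort's per-marker median depths. A progeny is
#' `deleted` when its ratio falls to 0.25 or below (or at least 80% of region
#' markers have no reads at all), `duplicated` at 1.75 or above — the
#' compensated deletion/duplication pattern produced when a translocation
#' heterozygote segregates — and `normal` otherwise.
#'
#' @param depth Long tibble `marker_id`, `sample_id`, `depth` (total AD per
#'   marker and sample).
#' @param region_markers Marker ids defining the region (at least 5).
#' @param progeny Samples to classify (default: all in `depth`).
#' @param del_ratio,dup_ratio Ratio thresholds (defaults 0.25 and 1.75).
#' @param max_missing Missing-marker fraction that also flags deletion
#'   (default 0.8).
#' @return Tibble `sample_id`, `ratio`, `frac_missing`, `call`.
#' @export
detect_dosage <- function(depth, region_markers, progeny = NULL,
                          del_ratio = 0.25, dup_ratio = 1.75,
                          max_missing = 0.8) {
  if (length(region_markers) < 5) abort("dosage region needs >= 5 markers")
  d <- filter(as_tibble(depth), .data$marker_id %in% region_markers)
  progeny <- progeny %||% sort(unique(d$sample_id))
  cohort <- summarise(group_by(d, .data$marker_id),
                      med = median(.data$depth, na.rm = TRUE), .groups = "drop")
  denom <- median(cohort$med)
  res <- purrr::map(progeny, function(s) {
    ds <- filter(d, .data$sample_id == s)
    miss <- mean(is.na(ds$depth) | ds$depth == 0)
    num <- median(ds$depth, na.rm = TRUE)
    ratio <- if (denom > 0) num / denom else NA_real_
    call <- if (is.na(ratio)) "undefined"
      else if (ratio <= del_ratio || miss >= max_missing) "deleted"
      else if (ratio >= dup_ratio) "duplicated"
      else "normal"
    tibble(sample_id = s, ratio = ratio, frac_missing = miss, call = call)
  })
  out <- bind_rows(res)
  if (denom == 0) warn("cohort median depth is zero; dosage undefined")
  out
}
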