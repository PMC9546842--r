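#' Chao1 richness estimator
#'
#' Classic Chao1: S_obs + F1^2 / (2 F2) with F1 singletons and F2 doubletons;
#' when F2 = 0 the bias-corrected form S_obs + F1 (F1 - 1) / (2 (F2 + 1)) is
#' used to avoid division by zero.
#'
#' @param counts non-negative integer abundance vector (one sample).
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  counts <- check_abundances(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Gini-Simpson diversity index
#'
#' 1 - sum p_i^2: the probability that two reads drawn at random belong to
#' different taxa. The inverse-Simpson form 1 / sum p_i^2 is available via
#' `inverse = TRUE`.
#'
#' @param counts abundance vector.
#' @param inverse if `TRUE` return inverse Simpson instead.
#' @return Diversity in \[0, 1) (Gini-Simpson) or \[1, S\] (inverse).
#' @export
gini_simpson <- function(counts, inverse = FALSE) {
  counts <- check_abundances(counts)
  p <- counts / sum(counts)
  d <- sum(p^2)
  if (inverse) 1 / d else 1 - d
}

#' Pielou evenness
#'
#' Shannon entropy (natural log) divided by log(observed richness). Undefined
#' for single-taxon samples. The Simpson-based evenness
#' (inverse Simpson / richness) is available via `variant = "simpson"`.
#'
#' @param counts abundance vector with at least two positive entries.
#' @param variant `"pielou"` (default) or `"simpson"`.
#' @return Evenness in \[0, 1\].
#' @export
pielou_evenness <- function(counts, variant = c("pielou", "simpson")) {
  variant <- match.arg(variant)
  counts <- check_abundances(counts)
  s <- sum(counts > 0)
  if (s < 2L) stop("evenness is undefined for a single-taxon sample (log 1 = 0)")
  if (variant == "simpson") return(gini_simpson(counts, inverse = TRUE) / s)
  p <- counts[counts > 0] / sum(counts)
  h <- -sum(p * log(p))
  h / log(s)
}

check_abundances <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("abundances must be non-negative integers")
  if (sum(counts) == 0) stop("empty sample: all abundances are zero")
  counts
}

#' Rarefy a count table to a common sequencing depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads, standardizing uneven sequencing depth before diversity comparisons.
#' Deterministic per seed.
#'
#' @param table a [count_table].
#' @param depth target depth (reads per sample).
#' @param seed RNG seed.
#' @param drop_small if `TRUE`, samples with fewer than `depth` reads are
#'   dropped with a warning instead of raising an error.
#' @return A rarefied [count_table].
#' @export
rarefy_counts <- function(table, depth, seed = 1L, drop_small = FALSE) {
  stopifnot(inherits(table, "count_table"))
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  set.seed(seed)
  rec <- table$records
  totals <- tapply(rec$count, rec$sample_id, sum)
  small <- names(totals)[totals < depth]
  if (length(small)) {
    if (!drop_small)
      stop("sample(s) below the target depth ", depth, ": ",
           paste(small, collapse = ", "))
    warning("dropping ", length(small), " sample(s) below depth ", depth)
    rec <- rec[!rec$sample_id %in% small, , drop = FALSE]
  }
  keep_samples <- setdiff(unique(rec$sample_id), small)
  pieces <- lapply(keep_samples, function(s) {
    r <- rec[rec$sample_id == s, , drop = FALSE]
    if (sum(r$count) == depth) return(r)
    reads <- rep(seq_len(nrow(r)), r$count)
    sub <- sample(reads, depth, replace = FALSE)
    r$count <- as.integer(tabulate(sub, nbins = nrow(r)))
    r[r$count > 0, , drop = FALSE]
  })
  rec <- do.call(rbind, pieces)
  meta <- table$metadata[table$metadata$sample_id %in% keep_samples, , drop = FALSE]
  count_table(rec, meta)
}

#' Expected rarefaction curve of observed richness
#'
#' By default uses the closed-form hypergeometric expectation
#' E\[S(d)\] = sum_i (1 - choose(N - N_i, d) / choose(N, d)), which is exact,
#' non-decreasing and concave in depth. With `replicates > 0` a Monte-Carlo
#' mean over random subsamples is returned instead.
#'
#' @param counts abundance vector of one sample.
#' @param depths subsampling depths (each <= total reads).
#' @param replicates Monte-Carlo replicates (0 = closed form, the default).
#' @param seed RNG seed for the Monte-Carlo path.
#' @return data.frame with columns `depth` and `richness`.
#' @export
rarefaction_curve <- function(counts, depths, replicates = 0L, seed = 1L) {
  counts <- check_abundances(counts)
  counts <- counts[counts > 0]
  total <- sum(counts)
  depths <- as.integer(depths)
  if (any(depths < 1L) || any(depths > total))
    stop("depths must lie in [1, total reads]")
  if (replicates == 0L) {
    rich <- vapply(depths, function(d) {
      # P(taxon i missed) = choose(N - N_i, d) / choose(N, d), in log space
      lp_miss <- lchoose(total - counts, d) - lchoose(total, d)
      sum(1 - exp(lp_miss))
    }, 0)
  } else {
    set.seed(seed)
    reads <- rep(seq_along(counts), counts)
    rich <- vapply(depths, function(d) {
      mean(vapply(seq_len(replicates), function(r)
        length(unique(sample(reads, d, replace = FALSE))), 0))
    }, 0)
  }
  data.frame(depth = depths, richness = rich)
}

#' Per-sample alpha-diversity summary
#'
#' Computes Chao1 richness, Pielou evenness and Gini-Simpson diversity for
#' every sample, optionally after rarefying all samples to a common depth.
#'
#' @param table a [count_table].
#' @param rarefy_depth optional common depth; if supplied, samples are
#'   rarefied (without replacement) first.
#' @param seed seed for rarefaction.
#' @param drop_small passed to [rarefy_counts].
#' @return data.frame with one row per sample: sample_id, chao1, evenness,
#'   simpson, depth_used (single-taxon samples get NA evenness).
#' @export
alpha_diversity <- function(table, rarefy_depth = NULL, seed = 1L,
                            drop_small = FALSE) {
  stopifnot(inherits(table, "count_table"))
  if (!is.null(rarefy_depth))
    table <- rarefy_counts(table, rarefy_depth, seed = seed,
                           drop_small = drop_small)
  rec <- table$records[table$records$count > 0, , drop = FALSE]
  samples <- unique(rec$sample_id)
  rows <- lapply(samples, function(s) {
    x <- rec$count[rec$sample_id == s]
    data.frame(sample_id = s,
               chao1 = chao1(x),
               evenness = if (sum(x > 0) >= 2) pielou_evenness(x) else NA_real_,
               simpson = gini_simpson(x),
               depth_used = sum(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
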