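#' Ground truth for a simulated factorial count dataset
#'
#' Collects the generating values of the latent-Gaussian count model: the
#' fixed effects `b_true` on the log-count scale, per-block random-effect
#' variances `sigma2_true` (named `u1..u4` plus `e`), optionally the realized
#' block effects `u_true`, a structural-zero probability `pi_zero`, the
#' observation family and the root seed.
#'
#' @param b_true numeric fixed-effect vector (intercept first, log scale), or
#'   a single intercept value.
#' @param sigma2_true named numeric vector of log-scale variances; any of
#'   `u1`, `u2`, `u3`, `u4`, `e` (missing entries default to 0).
#' @param pi_zero structural-zero probability in \[0, 1\].
#' @param family generating family (see [normalize_family]).
#' @param seed integer root seed.
#' @param u_true optional named list of realized block effects (filled in by
#'   [simulate_dataset]).
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(b_true = log(5), sigma2_true = c(u1 = 1, e = 0.25),
                         pi_zero = 0, family = "poisson", seed = 1L,
                         u_true = NULL) {
  family <- normalize_family(family)
  s2 <- c(u1 = 0, u2 = 0, u3 = 0, u4 = 0, e = 0)
  if (length(sigma2_true)) {
    if (is.null(names(sigma2_true)))
      stop("sigma2_true must be a named vector")
    bad <- setdiff(names(sigma2_true), names(s2))
    if (length(bad)) stop("unknown variance component(s): ",
                          paste(bad, collapse = ", "))
    if (any(sigma2_true < 0)) stop("variances must be >= 0")
    s2[names(sigma2_true)] <- sigma2_true
  }
  if (pi_zero < 0 || pi_zero > 1) stop("pi_zero must lie in [0, 1]")
  structure(list(b_true = as.numeric(b_true), sigma2_true = s2,
                 pi_zero = pi_zero, family = family,
                 seed = as.integer(seed), u_true = u_true),
            class = "truth_record")
}

## Derive independent per-stage seeds (< 2^31) from the root seed so that
## individual stages can be re-simulated stably.
stage_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Simulate a factorial taxon-count dataset with known ground truth
#'
#' Draws data from the model the package fits: block effects
#' u_k ~ N(0, sigma2_k I), log-scale error e ~ N(0, sigma2_e I), latent
#' predictor l = X b + sum_k Z_k u_k + e and counts y ~ family(exp(l)).
#' With `pi_zero > 0` the `zip` family replaces each count by a structural
#' zero with probability `pi_zero`, while `hurdle` draws a zero with
#' probability `pi_zero` and otherwise a zero-truncated Poisson count.
#' Fully reproducible from `truth$seed`.
#'
#' @param n_taxa number of taxa.
#' @param n_replicates replicates per inoculant-by-period cell.
#' @param inoculants,periods factor levels to simulate (defaults: the full
#'   CTRL/Inoc1/Inoc2 by 0/3/7/21/90/360-day grid).
#' @param truth a [truth_record]; its `b_true` must either match the implied
#'   fixed-effect dimension or be a single intercept (other effects 0).
#' @param grain grain label written into the metadata.
#' @return A list with elements `table` (a [count_table]) and `truth` (the
#'   input truth with realized `u_true` filled in).
#' @export
simulate_dataset <- function(n_taxa, n_replicates,
                             inoculants = INOCULANT_LEVELS,
                             periods = PERIOD_LEVELS,
                             truth = truth_record(),
                             grain = "corn") {
  stopifnot(inherits(truth, "truth_record"),
            n_taxa >= 1, n_replicates >= 1)
  inoculants <- match.arg(inoculants, INOCULANT_LEVELS, several.ok = TRUE)
  periods <- as.integer(periods)
  if (length(setdiff(periods, PERIOD_LEVELS)))
    stop("periods must be drawn from {", paste(PERIOD_LEVELS, collapse = ", "), "}")

  meta <- expand.grid(inoculant = inoculants, period_days = periods,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  meta$grain <- grain
  meta$sample_id <- sprintf("%s_%s_d%03d_r%d", substr(grain, 1, 1),
                            meta$inoculant, meta$period_days, meta$replicate)
  meta <- meta[, c("sample_id", "grain", "inoculant", "period_days", "replicate")]

  taxa <- sprintf("OTU%03d", seq_len(n_taxa))
  rec <- expand.grid(taxon_id = taxa, sample_id = meta$sample_id,
                     stringsAsFactors = FALSE)
  rec$count <- 0L
  tab0 <- count_table(rec, meta)
  design <- build_design(tab0, densify = FALSE)

  p <- ncol(design$X)
  b <- truth$b_true
  if (length(b) == 1L) b <- c(b, rep(0, p - 1L))
  if (length(b) != p)
    stop("b_true has length ", length(b), " but the design implies ", p,
         " fixed effects")

  seeds <- stage_seeds(truth$seed, 3L)
  s2 <- truth$sigma2_true

  set.seed(seeds[1])
  u <- truth$u_true
  if (is.null(u)) {
    u <- lapply(names(design$Z), function(k)
      stats::rnorm(ncol(design$Z[[k]]), 0, sqrt(s2[[k]])))
    names(u) <- names(design$Z)
  } else {
    for (k in names(design$Z))
      if (length(u[[k]]) != ncol(design$Z[[k]]))
        stop("u_true$", k, " length does not match the design")
  }

  set.seed(seeds[2])
  l <- drop(design$X %*% b)
  for (k in names(design$Z)) l <- l + u[[k]][design$index[[k]]]
  l <- l + stats::rnorm(design$n, 0, sqrt(s2[["e"]]))

  set.seed(seeds[3])
  n <- design$n
  lambda <- exp(l)
  y <- switch(truth$family,
    poisson = stats::rpois(n, lambda),
    # identity link: the raw-count mean is l itself
    normal = round(pmax(stats::rnorm(n, l, sqrt(max(s2[["e"]], 1))), 0)),
    zip = {
      yy <- stats::rpois(n, lambda)
      yy[stats::runif(n) < truth$pi_zero] <- 0L
      yy
    },
    hurdle = {
      zero <- stats::runif(n) < truth$pi_zero
      # zero-truncated Poisson via inverse-CDF on the positive tail
      yy <- stats::qpois(stats::ppois(0, lambda) +
                           stats::runif(n) * (1 - stats::ppois(0, lambda)),
                         lambda)
      yy <- pmax(yy, 1L)
      yy[zero] <- 0L
      yy
    })
  if (truth$family %in% c("poisson") && truth$pi_zero > 0)
    y[stats::runif(n) < truth$pi_zero] <- 0L

  rec <- design$obs[, c("taxon_id", "sample_id")]
  rec$count <- as.integer(y)
  truth$u_true <- u
  truth$b_true <- b
  list(table = count_table(rec, meta), truth = truth)
}

#' Preset simulation scenarios
#'
#' Named presets sized to the factorial study layout (3 inoculants by 6
#' fermentation periods, 3 replicates):
#' \itemize{
#'   \item `corn-like`: 6 taxa, Poisson counts around a mean of ~5 reads with
#'     taxon heterogeneity (sigma2_u1 = 1) and mild period/inoculant effects.
#'   \item `sorghum-like`: as corn-like with a higher baseline (~22 reads).
#'   \item `zero-heavy`: zip counts with structural-zero fraction 0.4.
#'   \item `null`: all variances and all non-intercept fixed effects zero.
#' }
#'
#' @param name preset name.
#' @param seed root seed.
#' @param n_taxa,n_replicates grid size (defaults 6 and 3).
#' @return A list with `table` and `truth`, as [simulate_dataset].
#' @export
scenario <- function(name, seed = 1L, n_taxa = 6L, n_replicates = 3L) {
  name <- match.arg(name, c("corn-like", "sorghum-like", "zero-heavy", "null"))
  p <- 1L + 5L + 2L  # intercept + 5 period contrasts + 2 inoculant contrasts
  truth <- switch(name,
    "corn-like" = truth_record(
      b_true = c(log(5.2), 0.1, -0.05, 0.05, 0.15, -0.1, 0.1, -0.1),
      sigma2_true = c(u1 = 1, u2 = 0.25, u3 = 0.25, u4 = 0.1, e = 0.25),
      family = "poisson", seed = seed),
    "sorghum-like" = truth_record(
      b_true = c(log(22), 0.1, -0.05, 0.05, 0.15, -0.1, 0.1, -0.1),
      sigma2_true = c(u1 = 1, u2 = 0.25, u3 = 0.25, u4 = 0.1, e = 0.25),
      family = "poisson", seed = seed),
    "zero-heavy" = truth_record(
      b_true = c(log(5.2), 0.1, -0.05, 0.05, 0.15, -0.1, 0.1, -0.1),
      sigma2_true = c(u1 = 1, u2 = 0.25, u3 = 0.25, u4 = 0.1, e = 0.25),
      pi_zero = 0.4, family = "zip", seed = seed),
    "null" = truth_record(
      b_true = c(log(5), rep(0, p - 1L)),
      sigma2_true = c(u1 = 0, u2 = 0, u3 = 0, u4 = 0, e = 0),
      family = "poisson", seed = seed))
  grain <- if (name == "sorghum-like") "sorghum" else "corn"
  simulate_dataset(n_taxa, n_replicates, truth = truth, grain = grain)
}
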