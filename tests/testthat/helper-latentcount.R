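# Shared fixtures, built in code at test time.

tiny_metadata <- function() {
  data.frame(
    sample_id = c("s1", "s2"),
    grain = "corn",
    inoculant = c("CTRL", "Inoc1"),
    period_days = c(0L, 0L),
    replicate = c(1L, 1L),
    stringsAsFactors = FALSE
  )
}

tiny_table <- function() {
  rec <- expand.grid(taxon_id = c("t1", "t2", "t3"),
                     sample_id = c("s1", "s2"),
                     stringsAsFactors = FALSE)
  rec$count <- c(5L, 0L, 2L, 1L, 3L, 4L)
  count_table(rec, tiny_metadata())
}

# Full-grid table: n_taxa x 3 inoculants x n_periods x n_reps, given counts
grid_table <- function(n_taxa = 2, periods = c(0L, 3L), n_reps = 2,
                       counts = NULL, seed = 1,
                       inoculants = c("CTRL", "Inoc1", "Inoc2")) {
  truth <- truth_record(b_true = log(5), sigma2_true = c(e = 0),
                        family = "poisson", seed = seed)
  sim <- simulate_dataset(n_taxa, n_reps, inoculants = inoculants,
                          periods = periods, truth = truth)
  if (!is.null(counts)) {
    stopifnot(length(counts) == nrow(sim$table$records))
    sim$table$records$count <- as.integer(counts)
  }
  sim$table
}

# Build a chain_result by hand from explicit draws (for inference/DIC tests
# whose oracles are deterministic).
fake_chain <- function(design, b_draws, u_draws = NULL, l_draws = NULL,
                       sigma2_draws = NULL, pi_draws = NULL,
                       family = "poisson",
                       include_blocks = names(design$Z)) {
  nd <- nrow(b_draws)
  blocks <- names(design$Z)
  if (is.null(u_draws))
    u_draws <- lapply(design$Z, function(Z) matrix(0, nd, ncol(Z)))
  if (is.null(l_draws)) l_draws <- matrix(0, nd, design$n)
  if (is.null(sigma2_draws)) {
    sigma2_draws <- matrix(1, nd, length(blocks) + 1L)
    colnames(sigma2_draws) <- c(blocks, "e")
  }
  colnames(b_draws) <- colnames(design$X)
  structure(list(
    draws = list(b = b_draws, u = u_draws, sigma2 = sigma2_draws,
                 l = l_draws, pi = pi_draws),
    config = sampler_config(iterations = nd * 10 + 100, burn_in = 100,
                            thin = 10, seed = 1),
    spec = model_spec(family, include_blocks = include_blocks),
    design = design, family = family,
    acceptance_rate = 0.44, seed = 1L), class = "chain_result")
}

# Weak-error-prior model spec used throughout the fitting tests
weak_spec <- function(family = "poisson", include_blocks = "u1") {
  model_spec(family, include_blocks = include_blocks,
             hyper = list(e = c(0.001, 0.001)))
}

quick_config <- function(iterations = 4000, burn_in = 1000, thin = 4,
                         seed = 1) {
  sampler_config(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = seed)
}

# Two-sample Kolmogorov-Smirnov comparison used by the conjugacy checks
expect_same_distribution <- function(x, y, alpha = 0.01) {
  p <- suppressWarnings(stats::ks.test(x, y)$p.value)
  expect_gt(p, alpha)
}
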