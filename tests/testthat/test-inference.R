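test_that("cell draws reduce to the intercept under a constant model", {
  tab <- scenario("null", seed = 51, n_taxa = 2, n_replicates = 1)$table
  d <- build_design(tab)
  nd <- 150
  res <- fake_chain(d, b_draws = cbind(rep(log(5), nd),
                                       matrix(0, nd, ncol(d$X) - 1L)))
  dr <- cell_draws(res, scale = "response")
  expect_equal(ncol(dr), 18)  # 3 inoculants x 6 periods
  expect_true(all(abs(dr - 5) < 1e-12))
  cells <- attr(dr, "cells")
  expect_setequal(unique(cells$inoculant), c("CTRL", "Inoc1", "Inoc2"))

  # latent-scale self-difference is identically zero
  lat <- cell_draws(res, scale = "latent")
  expect_true(all(lat[, 1] - lat[, 1] == 0))
})

test_that("cell draws place each random-effect level in the right cell", {
  tab <- scenario("null", seed = 52, n_taxa = 2, n_replicates = 1)$table
  d <- build_design(tab)
  nd <- 50
  # give taxon 1 a +1 taxon-by-period effect only at the 3rd period level
  u2 <- matrix(0, nd, ncol(d$Z$u2))
  P <- length(d$period_levels)
  u2[, (1 - 1) * P + 3] <- 1
  res <- fake_chain(d, b_draws = matrix(0, nd, ncol(d$X)),
                    u_draws = list(u1 = matrix(0, nd, ncol(d$Z$u1)), u2 = u2,
                                   u3 = matrix(0, nd, ncol(d$Z$u3)),
                                   u4 = matrix(0, nd, ncol(d$Z$u4))))
  lat <- cell_draws(res, scale = "latent")
  cells <- attr(lat, "cells")
  third <- cells$period_days == d$period_levels[3]
  # averaged over the 2 taxa the cell shift is 1/2, only at period 3
  expect_true(all(abs(lat[, third] - 0.5) < 1e-12))
  expect_true(all(abs(lat[, !third]) < 1e-12))
  # cross-check the arithmetic level layout against the design labels
  expect_equal(d$level_labels$u2[(1 - 1) * P + 3],
               paste(d$taxa[1], d$period_levels[3], sep = "."))
})

test_that("response-scale means dominate exponentiated latent means (Jensen)", {
  tab <- scenario("null", seed = 53, n_taxa = 2, n_replicates = 1)$table
  d <- build_design(tab, include_blocks = "u1")
  nd <- 400
  set.seed(53)
  res <- fake_chain(d, b_draws = cbind(rnorm(nd, 1, 0.6),
                                       matrix(0, nd, ncol(d$X) - 1L)),
                    u_draws = list(u1 = matrix(0, nd, 2)),
                    include_blocks = "u1")
  resp <- colMeans(cell_draws(res, scale = "response"))
  lat <- colMeans(cell_draws(res, scale = "latent"))
  expect_true(all(resp >= exp(lat)))
})

test_that("pairwise separation flags well-separated cells and only those", {
  set.seed(54)
  nd <- 2000
  draws <- cbind(A = rnorm(nd, 7.2, 0.01), B = rnorm(nd, 5.1, 0.01),
                 C = rnorm(nd, 5.1, 0.01))
  ps <- pairwise_separate(draws, level = 0.95)
  expect_true(ps$flags["A", "B"])
  expect_true(ps$flags["A", "C"])
  expect_false(ps$flags["B", "C"])
  expect_equal(ps$flags, t(ps$flags))

  # identical cells: interval centered at zero, no difference
  same <- cbind(X = draws[, 2], Y = draws[, 2])
  ps2 <- pairwise_separate(same)
  expect_false(ps2$pairs$different)
  expect_equal(ps2$pairs$diff_mean, 0)
  expect_lte(ps2$pairs$lower, 0)
  expect_gte(ps2$pairs$upper, 0)

  expect_error(pairwise_separate(draws, level = 1.2), "level")
  expect_error(pairwise_separate(draws[, 1, drop = FALSE]), "at least 2")
})

test_that("letter displays reproduce the classic a/b/b separation pattern", {
  # three cells, first different from both others: (a, b, b)
  means <- c(7.22, 5.12, 5.12)
  flags <- matrix(FALSE, 3, 3)
  flags[1, 2] <- flags[2, 1] <- TRUE
  flags[1, 3] <- flags[3, 1] <- TRUE
  expect_equal(letter_display(means, flags), c("a", "b", "b"))

  # no differences: all "a"; all different: a, b, c
  none <- matrix(FALSE, 3, 3)
  expect_equal(letter_display(means, none), c("a", "a", "a"))
  all_diff <- !diag(3) > 0
  diag(all_diff) <- FALSE
  expect_equal(letter_display(c(9, 5, 1), all_diff), c("a", "b", "c"))

  # inconsistent flags rejected
  bad <- matrix(FALSE, 2, 2); bad[1, 2] <- TRUE
  expect_error(letter_display(c(1, 2), bad), "symmetric")
})

test_that("letter displays agree with a brute-force grouping oracle", {
  # Exhaustive over all flag graphs with <= 5 cells: cells share a letter
  # iff they are not flagged different (maximal-clique semantics).
  for (k in 2:5) {
    n_pairs <- k * (k - 1) / 2
    pair_idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    n_graphs <- 2^n_pairs
    graphs <- if (n_graphs <= 128) seq_len(n_graphs) - 1L else {
      set.seed(55 + k); sample.int(n_graphs, 128) - 1L
    }
    means <- rev(seq_len(k))
    for (g in graphs) {
      bits <- as.integer(intToBits(g))[seq_len(n_pairs)]
      flags <- matrix(FALSE, k, k)
      for (e in seq_len(n_pairs)) {
        if (bits[e] == 1L) {
          flags[pair_idx[e, 1], pair_idx[e, 2]] <- TRUE
          flags[pair_idx[e, 2], pair_idx[e, 1]] <- TRUE
        }
      }
      lets <- letter_display(means, flags)
      share <- function(i, j)
        length(intersect(strsplit(lets[i], "")[[1]],
                         strsplit(lets[j], "")[[1]])) > 0
      for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
        if (flags[i, j]) {
          expect_false(share(i, j),
                       label = sprintf("k=%d g=%d pair (%d,%d) separated", k, g, i, j))
        } else {
          expect_true(share(i, j),
                      label = sprintf("k=%d g=%d pair (%d,%d) shares a letter", k, g, i, j))
        }
      }
    }
  }
})

test_that("posterior CV follows the sample-sd convention and scale freedom", {
  expect_equal(posterior_cv(rep(3, 50)), 0)
  expect_equal(posterior_cv(c(1, 3)), sqrt(2) / 2)
  set.seed(56)
  x <- rgamma(500, 4, 1)
  expect_equal(posterior_cv(10 * x), posterior_cv(x))
  expect_error(posterior_cv(c(-1, 1)), "zero")
})

test_that("cell summary tables letter within the requested direction", {
  tab <- scenario("null", seed = 57, n_taxa = 2, n_replicates = 1)$table
  d <- build_design(tab, include_blocks = "u1")
  nd <- 600
  set.seed(57)
  # strong Inoc1 fixed effect, zero elsewhere, tiny posterior noise
  b <- matrix(rnorm(nd * ncol(d$X), 0, 0.005), nd, ncol(d$X))
  b[, 1] <- b[, 1] + log(5)
  i1 <- match("inoculantInoc1", colnames(d$X))
  b[, i1] <- b[, i1] + 1
  res <- fake_chain(d, b_draws = b, u_draws = list(u1 = matrix(0, nd, 2)),
                    include_blocks = "u1")
  st <- cell_summary_table(res, "inoculants-within-period")
  expect_equal(nrow(st), 18)
  for (p in unique(st$period_days)) {
    rows <- st[st$period_days == p, ]
    expect_equal(rows$letters[rows$inoculant == "Inoc1"], "a")
    expect_setequal(rows$letters[rows$inoculant != "Inoc1"], "b")
  }
  # the other direction letters within each inoculant (periods all equal here)
  st2 <- cell_summary_table(res, "periods-within-inoculant")
  expect_true(all(st2$letters == "a"))
})
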