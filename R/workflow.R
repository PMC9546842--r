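## End-to-end workflow functions: each writes an output directory containing
## its results plus a run manifest (command, config snapshot, input digests,
## seed, package version, timestamp). These functions, together with the thin
## dispatcher in inst/cli/latentcount.R, form the command-line surface.

write_manifest <- function(dir, command, config, inputs = character()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(command = command,
                   config = config,
                   input_digests = digests,
                   package_version = as.character(utils::packageVersion("latentcount")),
                   timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"))
}

#' Simulate a dataset and write it to a directory
#'
#' Writes `counts.tsv`, `metadata.tsv`, `truth.json` (every ground-truth
#' field) and `manifest.json`.
#'
#' @param out_dir output directory (created if needed).
#' @param scenario_name preset name for [scenario].
#' @param seed root seed.
#' @param n_taxa,n_replicates grid size.
#' @return The output directory, invisibly.
#' @export
workflow_simulate <- function(out_dir, scenario_name = "corn-like", seed = 1L,
                              n_taxa = 6L, n_replicates = 3L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- scenario(scenario_name, seed = seed, n_taxa = n_taxa,
                  n_replicates = n_replicates)
  write_count_table(sim$table, file.path(out_dir, "counts.tsv"),
                    file.path(out_dir, "metadata.tsv"))
  truth <- sim$truth
  truth_json <- list(b_true = truth$b_true,
                     sigma2_true = as.list(truth$sigma2_true),
                     pi_zero = truth$pi_zero, family = truth$family,
                     seed = truth$seed, u_true = truth$u_true)
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "simulate",
                 list(scenario = scenario_name, seed = seed, n_taxa = n_taxa,
                      n_replicates = n_replicates))
  invisible(out_dir)
}

#' Fit the latent-Gaussian count model to a dataset directory
#'
#' Reads `counts.tsv`/`metadata.tsv`, fits one chain per grain present, and
#' writes per-grain draw CSVs, a Geweke report TSV, `meta.json` and the run
#' manifest. `full_protocol = TRUE` uses the full-length protocol
#' (2,000,000 iterations, 100,000 burn-in, thin 10) instead of the supplied
#' iteration counts.
#'
#' @param dataset_dir directory written by [workflow_simulate] (or containing
#'   compatible TSVs).
#' @param out_dir output directory.
#' @param family observation family.
#' @param include_blocks random-effect blocks.
#' @param iterations,burn_in,thin,seed sampler settings.
#' @param hyper hyperparameter overrides for [model_spec].
#' @param full_protocol use the full 2e6/1e5/10 protocol.
#' @param strict if `TRUE`, error when any finite Geweke |z| exceeds
#'   `z_threshold`.
#' @param z_threshold convergence threshold for `strict` (default 1.96).
#' @return Named list of `chain_result` objects (one per grain), invisibly;
#'   results are also written to `out_dir`.
#' @export
workflow_fit <- function(dataset_dir, out_dir, family = "poisson",
                         include_blocks = c("u1", "u2", "u3", "u4"),
                         iterations = 20000, burn_in = 4000, thin = 8,
                         seed = 1L, hyper = list(), full_protocol = FALSE,
                         strict = FALSE, z_threshold = 1.96) {
  counts_path <- file.path(dataset_dir, "counts.tsv")
  meta_path <- file.path(dataset_dir, "metadata.tsv")
  table <- read_count_table(counts_path, meta_path)
  if (full_protocol) { iterations <- 2e6; burn_in <- 1e5; thin <- 10 }
  spec <- model_spec(family = family, include_blocks = include_blocks,
                     hyper = hyper)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  grains <- sort(unique(table$metadata$grain))
  results <- list()
  for (g in grains) {
    meta_g <- table$metadata[table$metadata$grain == g, , drop = FALSE]
    rec_g <- table$records[table$records$sample_id %in% meta_g$sample_id, ,
                           drop = FALSE]
    tab_g <- count_table(rec_g, meta_g)
    config <- sampler_config(iterations = iterations, burn_in = burn_in,
                             thin = thin, seed = seed)
    res <- run_chain(tab_g, spec, config)
    results[[g]] <- res
    gdir <- file.path(out_dir, g)
    dir.create(gdir, showWarnings = FALSE)
    utils::write.csv(res$draws$b, file.path(gdir, "b.csv"), row.names = FALSE)
    utils::write.csv(res$draws$sigma2, file.path(gdir, "sigma2.csv"),
                     row.names = FALSE)
    if (!is.null(res$draws$pi))
      utils::write.csv(data.frame(pi = res$draws$pi),
                       file.path(gdir, "pi.csv"), row.names = FALSE)
    gw <- geweke_report(res)
    utils::write.table(gw, file.path(gdir, "geweke.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(grain = g, family = family, include_blocks = include_blocks,
           iterations = iterations, burn_in = burn_in, thin = thin,
           seed = seed, acceptance_rate = res$acceptance_rate,
           n_retained = nrow(res$draws$b)),
      file.path(gdir, "meta.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    if (strict && any(abs(gw$z) > z_threshold, na.rm = TRUE))
      stop("Geweke diagnostic exceeds |z| = ", z_threshold, " for grain ", g)
  }
  write_manifest(out_dir, "fit",
                 list(family = family, include_blocks = include_blocks,
                      iterations = iterations, burn_in = burn_in, thin = thin,
                      seed = seed),
                 inputs = c(counts_path, meta_path))
  invisible(results)
}

#' Rank fitted models by DIC
#'
#' Computes the DIC of each fitted chain (marginal variant by default, the
#' appropriate one for comparing observation families) and writes a ranking
#' TSV plus a winner marker file.
#'
#' @param results named list (>= 2) of `chain_result` objects fitted to the
#'   same data.
#' @param out_dir output directory.
#' @param conditioning DIC variant (see [compute_dic]); family screening uses
#'   the marginal variant, which is the default here.
#' @return The [select_model] result, invisibly.
#' @export
workflow_compare <- function(results, out_dir,
                             conditioning = c("marginal", "latent")) {
  conditioning <- match.arg(conditioning)
  if (length(results) < 2L)
    stop("workflow_compare needs at least 2 fitted chains")
  ys <- lapply(results, function(r) r$design$y)
  if (!all(vapply(ys, identical, TRUE, ys[[1]])))
    stop("chains were fitted to different datasets; refusing to compare")
  reports <- lapply(results, compute_dic, conditioning = conditioning)
  sel <- select_model(reports)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sel$ranking, file.path(out_dir, "dic_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0(sel$winner$family, " [",
                    paste(sel$winner$include_blocks, collapse = ","), "]"),
             file.path(out_dir, "winner.txt"))
  write_manifest(out_dir, "compare", list(n_models = length(results)))
  invisible(sel)
}

#' Write posterior cell summary tables for a fitted chain
#'
#' Produces the two mean-separation layouts (inoculants within each period,
#' and periods within each inoculant) as TSVs with letters appended.
#'
#' @param result a `chain_result`.
#' @param out_dir output directory.
#' @param level credibility level.
#' @param scale `"response"` or `"latent"`.
#' @return Named list of the two summary data.frames, invisibly.
#' @export
workflow_summarize <- function(result, out_dir, level = 0.95,
                               scale = "response") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (dir_ in c("inoculants-within-period", "periods-within-inoculant")) {
    tab <- cell_summary_table(result, direction = dir_, level = level,
                              scale = scale)
    tab$display <- sprintf("%.2f^%s", tab$mean, tab$letters)
    utils::write.table(tab, file.path(out_dir, paste0(dir_, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out[[dir_]] <- tab
  }
  write_manifest(out_dir, "summarize", list(level = level, scale = scale))
  invisible(out)
}

#' Compute per-sample alpha diversity for a dataset directory
#'
#' @param dataset_dir directory with `counts.tsv` and `metadata.tsv`.
#' @param out_dir output directory for `diversity.tsv` and the manifest.
#' @param rarefy_depth optional common depth for standardization.
#' @param seed rarefaction seed.
#' @return The diversity data.frame, invisibly.
#' @export
workflow_diversity <- function(dataset_dir, out_dir, rarefy_depth = NULL,
                               seed = 1L) {
  counts_path <- file.path(dataset_dir, "counts.tsv")
  meta_path <- file.path(dataset_dir, "metadata.tsv")
  table <- read_count_table(counts_path, meta_path)
  div <- alpha_diversity(table, rarefy_depth = rarefy_depth, seed = seed,
                         drop_small = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "diversity",
                 list(rarefy_depth = rarefy_depth, seed = seed),
                 inputs = c(counts_path, meta_path))
  invisible(div)
}
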