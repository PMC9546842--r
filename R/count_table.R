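#' @keywords internal
"_PACKAGE"

## Declared factor levels for the factorial layout: two grains, a control plus
## two bacterial inoculants, and six fermentation periods (days after ensiling).
GRAIN_LEVELS <- c("corn", "sorghum")
INOCULANT_LEVELS <- c("CTRL", "Inoc1", "Inoc2")
PERIOD_LEVELS <- c(0L, 3L, 7L, 21L, 90L, 360L)

#' Construct a validated taxon-by-sample count table
#'
#' A `count_table` holds long-format read counts (one row per taxon/sample
#' pair) together with the factorial metadata of each sample: grain
#' (corn or sorghum), inoculant treatment (CTRL, Inoc1, Inoc2), fermentation
#' period in days (0, 3, 7, 21, 90 or 360) and replicate number.
#'
#' @param records data.frame with columns `taxon_id`, `sample_id`, `count`
#'   (non-negative integers).
#' @param metadata data.frame with columns `sample_id`, `grain`, `inoculant`,
#'   `period_days`, `replicate`; one row per sample.
#' @return An object of class `count_table`: a list with elements `records`
#'   and `metadata`.
#' @export
count_table <- function(records, metadata) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  need_rec <- c("taxon_id", "sample_id", "count")
  need_met <- c("sample_id", "grain", "inoculant", "period_days", "replicate")
  miss <- setdiff(need_rec, names(records))
  if (length(miss))
    stop("count records are missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_met, names(metadata))
  if (length(miss))
    stop("sample metadata is missing column(s): ", paste(miss, collapse = ", "))

  cnt <- suppressWarnings(as.numeric(records$count))
  if (anyNA(cnt))
    stop("counts must be numeric; found non-numeric value(s)")
  if (any(cnt < 0))
    stop("counts must be non-negative integers; found negative value(s)")
  if (any(cnt != floor(cnt)))
    stop("counts must be integers; found fractional value(s)")
  records$count <- as.integer(cnt)
  records$taxon_id <- as.character(records$taxon_id)
  records$sample_id <- as.character(records$sample_id)

  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicated sample_id in metadata")
  bad <- setdiff(unique(metadata$grain), GRAIN_LEVELS)
  if (length(bad))
    stop("unknown grain level(s) ", paste(bad, collapse = ", "),
         "; allowed: {", paste(GRAIN_LEVELS, collapse = ", "), "}")
  bad <- setdiff(unique(metadata$inoculant), INOCULANT_LEVELS)
  if (length(bad))
    stop("unknown inoculant level(s) ", paste(bad, collapse = ", "),
         "; allowed: {", paste(INOCULANT_LEVELS, collapse = ", "), "}")
  per <- suppressWarnings(as.integer(metadata$period_days))
  bad <- setdiff(unique(per), PERIOD_LEVELS)
  if (anyNA(per) || length(bad))
    stop("unknown period_days level(s); allowed: {",
         paste(PERIOD_LEVELS, collapse = ", "), "}")
  metadata$period_days <- per
  rep_ <- suppressWarnings(as.integer(metadata$replicate))
  if (anyNA(rep_) || any(rep_ < 1))
    stop("replicate must be a positive integer")
  metadata$replicate <- rep_
  if (anyDuplicated(metadata[, c("grain", "inoculant", "period_days", "replicate")]))
    stop("(grain, inoculant, period_days, replicate) must be jointly unique")

  # rebuild as plain data.frames (drops expand.grid attributes etc.)
  records <- data.frame(taxon_id = records$taxon_id,
                        sample_id = records$sample_id,
                        count = records$count, stringsAsFactors = FALSE)
  metadata <- metadata[, need_met, drop = FALSE]
  rownames(records) <- NULL
  rownames(metadata) <- NULL

  orphan <- setdiff(unique(records$sample_id), metadata$sample_id)
  if (length(orphan))
    stop("sample(s) present in counts but absent from metadata: ",
         paste(orphan, collapse = ", "))
  if (anyDuplicated(records[, c("taxon_id", "sample_id")]))
    stop("at most one record per (taxon_id, sample_id) pair is allowed")

  structure(list(records = records, metadata = metadata),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", length(unique(x$records$taxon_id)), "taxa x",
      nrow(x$metadata), "samples,", nrow(x$records), "records\n")
  cat("  grains:", paste(sort(unique(x$metadata$grain)), collapse = ", "), "\n")
  cat("  inoculants:", paste(sort(unique(x$metadata$inoculant)), collapse = ", "), "\n")
  cat("  periods (days):", paste(sort(unique(x$metadata$period_days)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a count table and its sample metadata from TSV files
#'
#' The counts file must have header `taxon_id  sample_id  count`; the metadata
#' file `sample_id  grain  inoculant  period_days  replicate` (tab-separated,
#' UTF-8). All validation of `count_table()` applies.
#'
#' @param counts_path,metadata_path paths to the two TSV files.
#' @return A [count_table].
#' @export
read_count_table <- function(counts_path, metadata_path) {
  records <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                                colClasses = "character")
  count_table(records, metadata)
}

#' Write a count table to a pair of TSV files
#'
#' @param table a [count_table].
#' @param counts_path,metadata_path output paths.
#' @return Invisibly, the input table.
#' @export
write_count_table <- function(table, counts_path, metadata_path) {
  stopifnot(inherits(table, "count_table"))
  utils::write.table(table$records, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}

## Expand a count table to the dense taxon x sample grid, filling absent
## (taxon, sample) pairs with zero counts (OTU tables imply zeros).
densify_records <- function(table) {
  taxa <- sort(unique(table$records$taxon_id))
  samples <- table$metadata$sample_id
  grid <- expand.grid(taxon_id = taxa, sample_id = samples,
                      stringsAsFactors = FALSE)
  key <- paste(table$records$taxon_id, table$records$sample_id, sep = "\r")
  m <- match(paste(grid$taxon_id, grid$sample_id, sep = "\r"), key)
  grid$count <- ifelse(is.na(m), 0L, table$records$count[m])
  grid
}

#' Build fixed-effect and random-effect incidence matrices for the factorial model
#'
#' Constructs the observation-level design of the latent linear predictor
#' l = Xb + Z1 u1 + Z2 u2 + Z3 u3 + Z4 u4 + e: `X` holds an intercept plus
#' reference-coded fermentation-period and inoculant contrasts (reference:
#' first observed period and CTRL); `Z1..Z4` are 0/1 incidence matrices mapping
#' each observation to its taxon, taxon-by-period, taxon-by-inoculant and
#' taxon-by-period-by-inoculant level. Absent (taxon, sample) pairs enter as
#' explicit zero counts unless `densify = FALSE`.
#'
#' @param table a [count_table] (typically restricted to a single grain).
#' @param include_blocks character subset of `c("u1","u2","u3","u4")`.
#' @param densify if `TRUE` (default) missing taxon/sample pairs become zeros.
#' @return An object of class `factorial_design` with elements `X` (dense
#'   matrix), `Z` (named list of sparse incidence matrices), `index` (named
#'   list of integer level indices, one per observation), `level_labels`,
#'   `y` (observed counts), `obs` (observation-level data.frame) and `n`.
#' @export
build_design <- function(table, include_blocks = c("u1", "u2", "u3", "u4"),
                         densify = TRUE) {
  stopifnot(inherits(table, "count_table"))
  if (length(include_blocks))
    include_blocks <- match.arg(include_blocks, c("u1", "u2", "u3", "u4"),
                                several.ok = TRUE)
  if (nrow(table$records) == 0L) stop("empty count table")
  if (("u2" %in% include_blocks || "u4" %in% include_blocks) &&
      length(unique(table$metadata$period_days)) < 1L)
    stop("period factor required")

  rec <- if (densify) densify_records(table) else table$records
  meta <- table$metadata
  m <- match(rec$sample_id, meta$sample_id)
  obs <- data.frame(
    taxon_id = rec$taxon_id,
    sample_id = rec$sample_id,
    count = rec$count,
    inoculant = factor(meta$inoculant[m],
                       levels = intersect(INOCULANT_LEVELS, meta$inoculant)),
    period_days = factor(meta$period_days[m],
                         levels = intersect(PERIOD_LEVELS, meta$period_days)),
    stringsAsFactors = FALSE
  )
  obs$taxon <- factor(obs$taxon_id, levels = sort(unique(obs$taxon_id)))
  n <- nrow(obs)

  P <- nlevels(obs$period_days)
  I <- nlevels(obs$inoculant)
  terms <- c("~ 1",
             if (P > 1L) "period_days",
             if (I > 1L) "inoculant")
  X <- stats::model.matrix(stats::as.formula(paste(terms, collapse = " + ")),
                           data = obs)
  if (qr(X)$rank < ncol(X))
    stop("degenerate design: fixed-effect matrix is rank deficient")

  lev_int <- function(f) as.integer(f)
  cross <- function(...) interaction(..., drop = FALSE, lex.order = TRUE)
  index <- list()
  level_labels <- list()
  if ("u1" %in% include_blocks) {
    index$u1 <- lev_int(obs$taxon)
    level_labels$u1 <- levels(obs$taxon)
  }
  if ("u2" %in% include_blocks) {
    f <- cross(obs$taxon, obs$period_days)
    index$u2 <- lev_int(f); level_labels$u2 <- levels(f)
  }
  if ("u3" %in% include_blocks) {
    f <- cross(obs$taxon, obs$inoculant)
    index$u3 <- lev_int(f); level_labels$u3 <- levels(f)
  }
  if ("u4" %in% include_blocks) {
    f <- cross(obs$taxon, obs$period_days, obs$inoculant)
    index$u4 <- lev_int(f); level_labels$u4 <- levels(f)
  }
  Z <- lapply(index, function(ix) {
    nl <- max(ix)
    Matrix::sparseMatrix(i = seq_len(n), j = ix, x = 1, dims = c(n, nl))
  })

  structure(list(X = X, Z = Z, index = index, level_labels = level_labels,
                 y = obs$count, obs = obs, n = n,
                 period_levels = levels(obs$period_days),
                 inoculant_levels = levels(obs$inoculant),
                 taxa = levels(obs$taxon)),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat("factorial_design:", x$n, "observations;",
      ncol(x$X), "fixed-effect columns;",
      "blocks:", paste(sprintf("%s(%d)", names(x$Z),
                               vapply(x$Z, ncol, 0L)), collapse = ", "), "\n")
  invisible(x)
}

#' Export the dimensions and level labels of a design as JSON
#'
#' @param design a `factorial_design`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
design_to_json <- function(design, path = NULL) {
  stopifnot(inherits(design, "factorial_design"))
  desc <- list(
    n = design$n,
    fixed_effects = colnames(design$X),
    blocks = lapply(design$Z, ncol),
    level_labels = design$level_labels,
    period_levels = design$period_levels,
    inoculant_levels = design$inoculant_levels,
    taxa = design$taxa
  )
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}
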