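#' Floor scanned intensities
#'
#' Raw scanned intensities below the floor are replaced by the floor value
#' (default 5.0) before any normalization, so that near-background probes do
#' not produce extreme ratios.
#'
#' @param m an `ExpressionMatrix` on intensity scale.
#' @param floor minimum retained intensity.
#' @return The floored `ExpressionMatrix`, still on intensity scale.
#' @export
floor_intensities <- function(m, floor = 5.0) {
  if (m$scale != "intensity")
    stop("floor_intensities expects an intensity-scale matrix, got ", m$scale)
  m$values <- pmax(m$values, floor)
  m
}

#' Per-chip (within-array) normalization
#'
#' Each array is divided by its own 50th percentile, so every column's median
#' becomes 1 and the values become relative ratios.
#'
#' @param m an `ExpressionMatrix` on intensity scale with positive values.
#' @param probs percentile used for centering; the default is the median.
#' @param type quantile interpolation type passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return An `ExpressionMatrix` on ratio scale.
#' @export
per_chip_normalize <- function(m, probs = 0.5, type = 7) {
  if (m$scale != "intensity")
    stop("per_chip_normalize expects an intensity-scale matrix, got ", m$scale)
  med <- apply(m$values, 2L, stats::quantile, probs = probs, type = type,
               names = FALSE)
  if (any(med <= 0)) {
    bad <- sample_ids(m)[which(med <= 0)[1L]]
    stop("non-positive 50th percentile for sample '", bad, "'")
  }
  m$values <- sweep(m$values, 2L, med, "/")
  m$scale <- "ratio"
  m
}

#' Per-gene (between-array) normalization
#'
#' Each gene's row is divided by its median across samples, so per-row
#' medians become 1 and genes are comparable across the experiment.
#'
#' @inheritParams per_chip_normalize
#' @param m an `ExpressionMatrix` on ratio scale.
#' @return An `ExpressionMatrix` on ratio scale with unit per-gene medians.
#' @export
per_gene_normalize <- function(m, type = 7) {
  if (m$scale != "ratio")
    stop("per_gene_normalize expects a ratio-scale matrix, got ", m$scale)
  med <- apply(m$values, 1L, stats::quantile, probs = 0.5, type = type,
               names = FALSE)
  if (any(med <= 0)) {
    bad <- gene_ids(m)[which(med <= 0)[1L]]
    stop("non-positive median for gene '", bad, "'")
  }
  m$values <- sweep(m$values, 1L, med, "/")
  m
}

#' Present-flag filter
#'
#' Keeps probes called present on at least `min_fraction` of the arrays
#' (inclusive threshold), in their original order.
#'
#' @param m an `ExpressionMatrix` with flags attached.
#' @param min_fraction minimum fraction of present calls (default 0.5).
#' @return The filtered `ExpressionMatrix`.
#' @export
presence_filter <- function(m, min_fraction = 0.5) {
  if (is.null(m$flags))
    stop("presence_filter requires a flag matrix; none attached")
  keep <- rowMeans(m$flags) >= min_fraction
  em_subset(m, genes = which(keep))
}

#' Sample quality filter by mean inter-sample correlation
#'
#' For each array, the mean Pearson correlation with all other arrays is
#' computed on log2 values; arrays whose mean correlation falls below
#' `min_mean_r` are dropped. Exclusion is decided in a single pass over the
#' original correlation matrix (not iteratively), so the result does not
#' depend on sample order.
#'
#' @param m an `ExpressionMatrix` (any scale; values are log2-transformed
#'   internally unless already on log2 scale).
#' @param min_mean_r minimum mean Pearson correlation (default 0.8).
#' @return A list with elements `matrix` (the retained samples) and
#'   `excluded` (character vector of dropped sample ids).
#' @export
sample_qc_filter <- function(m, min_mean_r = 0.8) {
  if (ncol(m$values) < 3L)
    stop("sample_qc_filter needs at least 3 samples")
  if (nrow(m$values) < 3L)
    stop("sample_qc_filter needs at least 3 genes")
  v <- m$values
  if (m$scale != "log2") {
    if (any(v <= 0)) stop("values must be positive to log2-transform for QC")
    v <- log2(v)
  }
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("sample '", sample_ids(m)[which(sds == 0)[1L]],
         "' has zero variance; correlation undefined")
  r <- stats::cor(v)
  diag(r) <- NA
  mean_r <- rowMeans(r, na.rm = TRUE)
  excluded <- sample_ids(m)[mean_r < min_mean_r]
  if (length(excluded) == ncol(m$values))
    stop("every sample falls below the QC threshold; check the input scale")
  list(matrix = em_subset(m, samples = which(mean_r >= min_mean_r)),
       excluded = excluded, mean_r = mean_r)
}

#' Log2 transformation
#'
#' @param m an `ExpressionMatrix` on intensity or ratio scale, all positive.
#' @return An `ExpressionMatrix` on log2 scale.
#' @export
log2_transform <- function(m) {
  if (m$scale == "log2") stop("matrix is already on log2 scale")
  if (any(m$values <= 0)) {
    idx <- which(m$values <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive value at gene '%s', sample '%s'",
                 gene_ids(m)[idx[1L]], sample_ids(m)[idx[2L]]))
  }
  m$values <- log2(m$values)
  m$scale <- "log2"
  m
}

#' Full preprocessing chain
#'
#' Runs floor -> per-chip normalization -> sample QC -> per-gene
#' normalization -> presence filter -> log2, and reports what each stage
#' removed. Sample QC runs before per-gene normalization on purpose: the
#' mean inter-array correlation that the filter thresholds is carried by the
#' shared gene-abundance profile (bright genes bright everywhere), which
#' per-gene centering removes; after per-gene normalization even perfect
#' replicate arrays correlate near zero and the filter would reject
#' everything.
#'
#' @param m an `ExpressionMatrix` on intensity scale (with flags if the
#'   presence filter is to run).
#' @param floor intensity floor.
#' @param min_fraction present-call fraction; set `NA` to skip the presence
#'   filter (e.g. when no flags are available).
#' @param min_mean_r sample QC threshold; set `NA` to skip QC.
#' @return A list: `matrix` (log2 scale), `excluded_samples`,
#'   `n_genes_in`, `n_genes_kept`, `log` (character vector of stage notes).
#' @export
normalize_pipeline <- function(m, floor = 5.0, min_fraction = 0.5,
                               min_mean_r = 0.8) {
  n_in <- nrow(m$values)
  log <- character()
  m <- floor_intensities(m, floor)
  m <- per_chip_normalize(m)
  excluded <- character()
  if (!is.na(min_mean_r)) {
    qc <- sample_qc_filter(m, min_mean_r)
    m <- qc$matrix
    excluded <- qc$excluded
    if (length(excluded))
      log <- c(log, paste("excluded samples:", paste(excluded, collapse = ", ")))
  }
  m <- per_gene_normalize(m)
  if (!is.na(min_fraction) && !is.null(m$flags)) {
    m <- presence_filter(m, min_fraction)
    log <- c(log, sprintf("presence filter kept %d of %d genes",
                          nrow(m$values), n_in))
  }
  m <- log2_transform(m)
  list(matrix = m, excluded_samples = excluded,
       n_genes_in = n_in, n_genes_kept = nrow(m$values), log = log)
}
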