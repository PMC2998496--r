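#' Expression matrix container
#'
#' A genes-by-samples matrix of microarray intensities (or derived ratio /
#' log2 values) with optional per-probe present/absent flags. The measurement
#' scale is carried along so that stages which only make sense on one scale
#' (flooring, log transformation, ...) can refuse inappropriate input.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are the gene and sample identifiers and must be unique.
#' @param scale one of `"intensity"`, `"ratio"`, `"log2"`.
#' @param flags optional logical matrix of the same shape: `TRUE` where the
#'   probe was called present on that array.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, scale = c("intensity", "ratio", "log2"),
                              flags = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  if (!is.null(flags)) {
    if (!is.logical(flags) || !identical(dim(flags), dim(values)))
      stop("'flags' must be a logical matrix with the same shape as 'values'")
    dimnames(flags) <- dimnames(values)
  }
  structure(list(values = values, scale = scale, flags = flags),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale%s)\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$flags)) "" else ", with flags"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param m an `ExpressionMatrix`.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

# internal: subset genes/samples keeping flags in step
em_subset <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  f <- m$flags
  if (!is.null(genes)) {
    v <- v[genes, , drop = FALSE]
    if (!is.null(f)) f <- f[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    if (!is.null(f)) f <- f[, samples, drop = FALSE]
  }
  expression_matrix(v, scale = m$scale, flags = f)
}

parse_flag_token <- function(tok) {
  if (tok %in% c("P", "1")) return(TRUE)
  if (tok %in% c("A", "0")) return(FALSE)
  NA
}

#' Read an expression matrix from a tab-delimited file
#'
#' Expected layout: first row holds sample identifiers (first cell is a
#' corner label such as `gene_id`), each following row is a gene identifier
#' and one numeric value per sample. An optional flag file of the same
#' layout carries present/absent calls coded `P`/`A` or `1`/`0`.
#'
#' @param path path to the expression TSV.
#' @param flag_path optional path to a flag TSV of identical layout.
#' @param scale measurement scale of the stored values.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, flag_path = NULL,
                                   scale = c("intensity", "ratio", "log2")) {
  scale <- match.arg(scale)
  tab <- read_tsv_table(path)
  vals <- suppressWarnings(
    matrix(as.numeric(tab$body), nrow = nrow(tab$body),
           dimnames = list(tab$row_ids, tab$col_ids)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-numeric value '%s' at gene '%s', sample '%s'",
                 path, tab$body[idx[1L], idx[2L]],
                 tab$row_ids[idx[1L]], tab$col_ids[idx[2L]]))
  }
  flags <- NULL
  if (!is.null(flag_path)) {
    ftab <- read_tsv_table(flag_path)
    if (!identical(dim(ftab$body), dim(vals)) ||
        !identical(ftab$row_ids, tab$row_ids) ||
        !identical(ftab$col_ids, tab$col_ids))
      stop(sprintf("flag file %s does not match the shape/ids of %s",
                   flag_path, path))
    flags <- matrix(vapply(ftab$body, parse_flag_token, NA),
                    nrow = nrow(ftab$body),
                    dimnames = dimnames(vals))
    if (anyNA(flags)) {
      idx <- which(is.na(flags), arr.ind = TRUE)[1L, ]
      stop(sprintf("%s: flag value '%s' at gene '%s', sample '%s' is not P/A or 1/0",
                   flag_path, ftab$body[idx[1L], idx[2L]],
                   tab$row_ids[idx[1L]], tab$col_ids[idx[2L]]))
    }
  }
  expression_matrix(vals, scale = scale, flags = flags)
}

# internal TSV reader with shape validation and precise error messages
read_tsv_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop(path, ": expected a header row and at least one gene row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  n_col <- length(header) - 1L
  if (n_col < 1L) stop(path, ": header row has no sample columns")
  col_ids <- header[-1L]
  if (anyDuplicated(col_ids))
    stop(path, ": duplicated sample id: ", col_ids[duplicated(col_ids)][1L])
  body_cells <- cells[-1L]
  widths <- lengths(body_cells)
  if (any(widths != n_col + 1L)) {
    bad <- which(widths != n_col + 1L)[1L]
    stop(sprintf("%s: row %d has %d fields, expected %d",
                 path, bad + 1L, widths[bad], n_col + 1L))
  }
  row_ids <- vapply(body_cells, `[[`, "", 1L)
  if (anyDuplicated(row_ids))
    stop(path, ": duplicated gene id: ", row_ids[duplicated(row_ids)][1L])
  body <- t(vapply(body_cells, function(r) r[-1L], character(n_col)))
  if (n_col == 1L) body <- matrix(body, ncol = 1L)
  list(row_ids = row_ids, col_ids = col_ids, body = body)
}

#' Write an expression matrix as a tab-delimited file
#'
#' Canonical formatting: first cell `gene_id`, 17 significant digits so that
#' a write/read/write cycle is byte-stable.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output file path.
#' @param flag_path optional path for the flag matrix (written as `P`/`A`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, flag_path = NULL) {
  body <- apply(m$values, 2L, function(col) sprintf("%.17g", col))
  if (nrow(m$values) == 1L) body <- matrix(body, nrow = 1L)
  lines <- c(paste(c("gene_id", sample_ids(m)), collapse = "\t"),
             paste(gene_ids(m), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  if (!is.null(flag_path)) {
    if (is.null(m$flags)) stop("no flags attached to write")
    fbody <- ifelse(m$flags, "P", "A")
    flines <- c(paste(c("gene_id", sample_ids(m)), collapse = "\t"),
                paste(gene_ids(m), apply(fbody, 1L, paste, collapse = "\t"),
                      sep = "\t"))
    writeLines(flines, flag_path)
  }
  invisible(path)
}

#' Read a sample-design table
#'
#' Tab-delimited with columns `sample_id`, `system`, `compound`, `dose`,
#' `time_h`, `replicate`, `is_control`.
#'
#' @param path path to the design TSV.
#' @return A validated design `data.frame`.
#' @export
read_study_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_study_design(d)
}

#' Validate a sample-design table
#'
#' @param d data.frame with one row per sample.
#' @return `d`, with `is_control` coerced to logical.
#' @export
as_study_design <- function(d) {
  need <- c("sample_id", "system", "compound", "dose", "time_h",
            "replicate", "is_control")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample_id in design: ",
         d$sample_id[duplicated(d$sample_id)][1L])
  d$is_control <- as.logical(d$is_control)
  if (anyNA(d$is_control)) stop("is_control must be TRUE/FALSE")
  if (!is.numeric(d$dose) || !is.numeric(d$time_h))
    stop("dose and time_h must be numeric")
  d
}

#' Write a design table
#' @param design a design `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: check a design covers the matrix samples one-to-one
match_design <- function(m, design) {
  design <- as_study_design(design)
  missing <- setdiff(sample_ids(m), design$sample_id)
  if (length(missing))
    stop("design has no row for sample(s): ", paste(missing, collapse = ", "))
  design[match(sample_ids(m), design$sample_id), , drop = FALSE]
}
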