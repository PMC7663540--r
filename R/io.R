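#' Construct an omics matrix object
#'
#' An `omics_matrix` wraps one omics layer: a numeric samples-by-variables
#' matrix with sample IDs as rownames, variable names as colnames, a short
#' layer label (e.g. `"D"` for DNA methylation, `"MR"` for mRNA, `"MI"` for
#' miRNA) and a flag recording whether its columns have been standardized.
#'
#' @param values numeric matrix, samples in rows, variables in columns;
#'   must carry rownames (sample IDs) and colnames (variable names).
#' @param layer_id short character label for the omics layer.
#' @param standardized logical; `TRUE` only if every column has mean 0 and
#'   sample variance 1.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, layer_id, standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (sample IDs) and colnames (variable names)")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated variable names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values))
    stop("missing values are not supported; impute before loading")
  structure(list(layer_id = as.character(layer_id),
                 sample_ids = rownames(values),
                 variable_names = colnames(values),
                 values = values,
                 standardized = isTRUE(standardized)),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix '%s': %d samples x %d variables (%s)\n",
              x$layer_id, nrow(x$values), ncol(x$values),
              if (x$standardized) "standardized" else "raw"))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

guess_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Load an omics matrix from a delimited text file
#'
#' Expected layout: a header row of variable names, first column of sample
#' IDs, numeric body. The delimiter is taken from the file extension
#' (`.csv` = comma, anything else = tab) unless given explicitly.
#'
#' @param path path to a TSV/CSV file.
#' @param layer_id short layer label attached to the result.
#' @param delim optional explicit field delimiter.
#' @return an unstandardized [omics_matrix()].
#' @export
load_omics_matrix <- function(path, layer_id, delim = NULL) {
  delim <- guess_delim(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2) stop("expected a sample-ID column plus at least one variable")
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]) & body[[j]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at sample '%s', variable '%s' in %s",
                   body[[j]][bad[1]], ids[bad[1]], colnames(body)[j], path))
    vals[, j] <- v
  }
  omics_matrix(vals, layer_id = layer_id, standardized = FALSE)
}

#' Write an omics matrix to a delimited text file
#'
#' Inverse of [load_omics_matrix()]: full-precision values, header row of
#' variable names, first column `sample`.
#'
#' @param m an [omics_matrix()].
#' @param path output path; delimiter from extension unless `delim` given.
#' @param delim optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path, delim = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  delim <- guess_delim(path, delim)
  df <- data.frame(sample = m$sample_ids, m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Column-standardize an omics matrix
#'
#' Centers every column to mean 0 and scales to unit sample variance
#' (divisor n-1), so a singleton variable cluster has homogeneity exactly 1.
#' Constant columns are rejected rather than silently dropped.
#'
#' @param m an [omics_matrix()].
#' @return the standardized [omics_matrix()].
#' @export
standardize <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  x <- m$values
  if (nrow(x) < 3) stop("standardization needs at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "),
         " -- remove or impute before standardizing")
  x <- scale(x, center = TRUE, scale = sds)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  omics_matrix(x, layer_id = m$layer_id, standardized = TRUE)
}

#' Survival outcome table
#'
#' @param sample_ids character vector of subject identifiers.
#' @param time positive follow-up times (consistent units).
#' @param event 0/1 indicator, 1 = observed event, 0 = right-censored.
#' @return an object of class `survival_outcome`.
#' @export
survival_outcome <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample IDs in survival table")
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    stop("sample_ids, time and event must have equal length")
  if (anyNA(time) || any(time <= 0)) stop("all survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  structure(list(sample_ids = sample_ids, time = time, event = event),
            class = "survival_outcome")
}

#' Load a survival table from a delimited text file
#'
#' Columns `sample`, `time`, `status` (header required; extra columns are
#' ignored).
#'
#' @inheritParams load_omics_matrix
#' @return a [survival_outcome()].
#' @export
load_survival <- function(path, delim = NULL) {
  delim <- guess_delim(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, comment.char = "")
  need <- c("sample", "time", "status")
  if (!all(need %in% colnames(df)))
    stop("survival file must have columns: ", paste(need, collapse = ", "))
  survival_outcome(df$sample, df$time, df$status)
}

#' Write a survival table
#' @param s a [survival_outcome()].
#' @param path output path.
#' @param delim optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_survival <- function(s, path, delim = NULL) {
  stopifnot(inherits(s, "survival_outcome"))
  delim <- guess_delim(path, delim)
  df <- data.frame(sample = s$sample_ids, time = s$time, status = s$event)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict omics layers and survival to their common samples
#'
#' Keeps the intersection of sample IDs across all layers and the survival
#' table, in sorted-ID order so downstream results do not depend on input
#' row order.
#'
#' @param matrices list of [omics_matrix()] objects.
#' @param survival a [survival_outcome()].
#' @return list with elements `matrices` (same length, aligned) and
#'   `survival`.
#' @export
align_samples <- function(matrices, survival) {
  stopifnot(length(matrices) >= 1, inherits(survival, "survival_outcome"))
  ids <- Reduce(intersect, c(lapply(matrices, `[[`, "sample_ids"),
                             list(survival$sample_ids)))
  if (length(ids) == 0)
    stop("no samples shared by all omics layers and the survival table")
  ids <- sort(ids)
  mats <- lapply(matrices, function(m) {
    # dropping samples invalidates column means/variances
    still_std <- m$standardized && length(ids) == length(m$sample_ids)
    omics_matrix(m$values[ids, , drop = FALSE], layer_id = m$layer_id,
                 standardized = still_std)
  })
  idx <- match(ids, survival$sample_ids)
  surv <- survival_outcome(ids, survival$time[idx], survival$event[idx])
  list(matrices = mats, survival = surv)
}
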