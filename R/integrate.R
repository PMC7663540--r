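#' Parallel integration of per-layer component scores
#'
#' Column-binds the component score vectors of every layer into one
#' samples-by-components dataset, keeping provenance (layer, block,
#' nonzero-loading support) per column. All layers must share the aligned
#' sample set of the survival table; scores are not re-standardized, so
#' downstream Cox coefficients are on the component score scale.
#'
#' @param per_layer list of per-layer component lists (each a list of
#'   `sparse_component`s from [extract_all()], carrying sample order via
#'   the matrices they came from).
#' @param survival a [survival_outcome()] giving the sample order.
#' @param sample_ids list of per-layer sample ID vectors (one per layer,
#'   each matching its components' score order).
#' @return an object of class `integrated_dataset`: `sample_ids`, `labels`
#'   (component labels, layer order then block order), `scores` (n x K*
#'   matrix), `provenance` (named list label -> list(layer_id, block_index,
#'   block_size, support, loadings)).
#' @export
merge_components <- function(per_layer, survival, sample_ids = NULL) {
  stopifnot(length(per_layer) >= 1, inherits(survival, "survival_outcome"))
  n <- length(survival$sample_ids)
  if (!is.null(sample_ids)) {
    for (ids in sample_ids) {
      if (!identical(as.character(ids), survival$sample_ids))
        stop("layer sample set does not match the survival table; align first")
    }
  }
  comps <- unlist(per_layer, recursive = FALSE)
  labels <- vapply(comps, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate component labels across layers: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  scores <- vapply(comps, function(cmp) {
    if (length(cmp$scores) != n)
      stop("component ", cmp$label, " has ", length(cmp$scores),
           " scores but the survival table has ", n, " samples")
    cmp$scores
  }, numeric(n))
  dimnames(scores) <- list(survival$sample_ids, labels)
  prov <- stats::setNames(lapply(comps, function(cmp) {
    list(layer_id = cmp$layer_id, block_index = cmp$block_index,
         block_size = length(cmp$loadings), support = cmp$support,
         loadings = cmp$loadings[cmp$loadings != 0])
  }), labels)
  structure(list(sample_ids = survival$sample_ids, labels = labels,
                 scores = scores, provenance = prov),
            class = "integrated_dataset")
}

#' @export
print.integrated_dataset <- function(x, ...) {
  cat(sprintf("integrated_dataset: %d samples x %d components (%s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Export the integrated score matrix as TSV
#' @param data an `integrated_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_integrated <- function(data, path) {
  stopifnot(inherits(data, "integrated_dataset"))
  df <- data.frame(sample = data$sample_ids, data$scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
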