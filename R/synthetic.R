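# Synthetic multi-omics generator with known block structure and
# proportional-hazards survival, providing ground truth for every stage of
# the pipeline: each block of variables loads on one latent factor, blocks
# are mutually independent (within and across layers), and the log-hazard
# is linear in a subset of the block factors.

#' Configuration for the synthetic multi-omics generator
#'
#' @param n number of samples.
#' @param block_sizes list of integer vectors, one per omics layer; each
#'   entry is the size of one block.
#' @param a within-block factor loading in (0, 1): each variable is
#'   `a * factor + sqrt(1 - a^2) * noise`, so any two variables of the same
#'   block have correlation `a^2`.
#' @param beta per-block log-hazard coefficients, recycled or a vector over
#'   all blocks (layer order, then block order); zero entries make a block
#'   irrelevant to survival.
#' @param h0 constant baseline hazard rate (> 0).
#' @param censoring target right-censoring fraction in [0, 1).
#' @param layer_ids labels for the layers (default L1, L2, ...).
#' @param seed integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n = 300, block_sizes = list(c(30, 30, 30)),
                             a = 0.9, beta = 0, h0 = 1,
                             censoring = 0.2, layer_ids = NULL, seed = 1L) {
  stopifnot(n >= 2, a > 0, a < 1, h0 > 0, censoring >= 0, censoring < 1)
  if (!is.list(block_sizes)) block_sizes <- list(block_sizes)
  stopifnot(all(unlist(block_sizes) >= 1))
  n_blocks <- sum(lengths(block_sizes))
  beta <- rep_len(beta, n_blocks)
  if (is.null(layer_ids)) layer_ids <- paste0("L", seq_along(block_sizes))
  stopifnot(length(layer_ids) == length(block_sizes))
  structure(list(n = as.integer(n), block_sizes = block_sizes, a = a,
                 beta = beta, h0 = h0, censoring = censoring,
                 layer_ids = as.character(layer_ids), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Load a synthetic-study configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]. YAML 1.1 parses a
#' bare `n` key as a boolean, so both `n` and the unambiguous alias
#' `n_samples` are accepted for the sample count.
#'
#' @param path YAML file path.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  names(y)[names(y) %in% c("FALSE", "n_samples")] <- "n"
  do.call(synthetic_config,
          y[intersect(names(y), names(formals(synthetic_config)))])
}

#' Generate multi-omics layers with known block structure
#'
#' For block k a latent factor `f_k ~ N(0, 1)` is drawn per sample and
#' each of its variables is `a * f_k + sqrt(1 - a^2) * eps` with
#' independent standard-normal noise; blocks are independent.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `layers` (list of unstandardized [omics_matrix()]),
#'   `partitions` (list of named integer vectors: true variable -> block
#'   within each layer), and `factors` (n x total-blocks matrix of latent
#'   factors, columns in layer order then block order).
#' @export
generate_multiomics <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  sample_ids <- sprintf("S%04d", seq_len(n))
  total_blocks <- sum(lengths(cfg$block_sizes))
  factors <- matrix(stats::rnorm(n * total_blocks), n, total_blocks)
  rownames(factors) <- sample_ids
  colnames(factors) <- paste0("F", seq_len(total_blocks))

  layers <- list(); partitions <- list()
  bk <- 0L
  for (j in seq_along(cfg$block_sizes)) {
    sizes <- cfg$block_sizes[[j]]
    p <- sum(sizes)
    x <- matrix(NA_real_, n, p)
    assign <- integer(p)
    col <- 0L
    for (b in seq_along(sizes)) {
      bk <- bk + 1L
      f <- factors[, bk]
      for (v in seq_len(sizes[b])) {
        col <- col + 1L
        x[, col] <- cfg$a * f + sqrt(1 - cfg$a^2) * stats::rnorm(n)
        assign[col] <- b
      }
    }
    vars <- sprintf("%s_V%03d", cfg$layer_ids[j], seq_len(p))
    dimnames(x) <- list(sample_ids, vars)
    layers[[j]] <- omics_matrix(x, layer_id = cfg$layer_ids[j])
    partitions[[j]] <- stats::setNames(assign, vars)
  }
  names(layers) <- names(partitions) <- cfg$layer_ids
  list(layers = layers, partitions = partitions, factors = factors)
}

#' Generate survival outcomes from the latent block factors
#'
#' Event times are exponential with subject rate
#' `h0 * exp(sum_k beta_k f_ik)`; censoring times are exponential with a
#' rate calibrated (by bisection against the subjects' realized hazard
#' rates) so the expected censoring fraction matches the target. Observed
#' time is the minimum; event = 1 when the event came first.
#'
#' @param factors latent factor matrix from [generate_multiomics()].
#' @param cfg the same [synthetic_config()].
#' @return a [survival_outcome()].
#' @export
generate_survival <- function(factors, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"),
            ncol(factors) == length(cfg$beta))
  n <- nrow(factors)
  rate <- cfg$h0 * exp(as.vector(factors %*% cfg$beta))
  t_event <- stats::rexp(n, rate = rate)
  if (cfg$censoring <= 0) {
    return(survival_outcome(rownames(factors), t_event, rep(1, n)))
  }
  # P(C < T | rates) = mean(c / (c + rate)) for independent exponentials;
  # monotone increasing in c, solved by bisection
  target <- cfg$censoring
  pcens <- function(c) mean(c / (c + rate))
  lo <- 1e-12; hi <- max(rate) * 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (pcens(mid) < target) lo <- mid else hi <- mid
  }
  c_rate <- sqrt(lo * hi)
  t_cens <- stats::rexp(n, rate = c_rate)
  survival_outcome(rownames(factors),
                   pmin(t_event, t_cens),
                   as.numeric(t_event <= t_cens))
}

#' Generate a complete synthetic multi-omics survival study
#'
#' Convenience wrapper: draws the layers and the survival table in one
#' call.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `layers`, `partitions`, `factors`, `survival`.
#' @export
generate_study <- function(cfg) {
  out <- generate_multiomics(cfg)
  out$survival <- generate_survival(out$factors, cfg)
  out
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in study$layers) {
    write_omics_matrix(m, file.path(dir, paste0("layer_", m$layer_id, ".tsv")))
  }
  write_survival(study$survival, file.path(dir, "survival.tsv"))
  for (id in names(study$partitions)) {
    df <- data.frame(variable = names(study$partitions[[id]]),
                     block = unname(study$partitions[[id]]))
    utils::write.table(df, file.path(dir, paste0("true_blocks_", id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
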