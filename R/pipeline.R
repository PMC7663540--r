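# End-to-end orchestration: standardize -> cluster -> block components ->
# parallel integration -> stepwise Cox -> evaluation -> chart, with all
# artifacts written to an output directory. Besides the block-sparse-PC
# method itself, two PCA comparison variants are available: ordinary first
# PCs within blocks, and ordinary leading PCs of each whole layer without
# clustering (using as many PCs as the block method would).

#' Pipeline configuration
#'
#' @param layers list of layer specs; each a list with `path` (TSV/CSV as
#'   read by [load_omics_matrix()]) or `matrix` (an in-memory
#'   [omics_matrix()]), `label`, and `K` (block count, or `"auto"` to use
#'   [suggest_block_count()]).
#' @param survival path to the survival table, or a [survival_outcome()].
#' @param variant `"bspc"` (block sparse PCs), `"pca_blocks"` (ordinary
#'   first PC per block) or `"pca_noclust"` (leading PCs of the whole
#'   layer, as many as blocks).
#' @param fraction sparsity fraction for the `bspc` variant.
#' @param ridge ridge penalty for sparse components.
#' @param eval_time `"km_median"` or an explicit positive time.
#' @param ties Cox tie correction.
#' @param k_max cap for `"auto"` block counts.
#' @param seed integer seed (chart jitter and any stochastic stage).
#' @param out output directory; `NULL` to skip writing artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(layers, survival,
                            variant = c("bspc", "pca_blocks", "pca_noclust"),
                            fraction = 0.10, ridge = 1e-6,
                            eval_time = "km_median", ties = "efron",
                            k_max = 20L, seed = 1L, out = NULL) {
  variant <- match.arg(variant)
  stopifnot(length(layers) >= 1, fraction > 0, fraction <= 1)
  structure(list(layers = layers, survival = survival, variant = variant,
                 fraction = fraction, ridge = ridge, eval_time = eval_time,
                 ties = ties, k_max = as.integer(k_max),
                 seed = as.integer(seed), out = out),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `layers` is
#' a list of `{path, label, K}` entries.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

# components for the PCA comparison variants share the sparse_component
# container; loadings are dense (ordinary PCs)
dense_pc_component <- function(loadings, scores, layer_id, block_index, label) {
  structure(list(loadings = loadings, support = names(loadings),
                 scores = scores, k = length(loadings), ridge = 0,
                 explained_variance = stats::var(scores),
                 layer_id = layer_id, block_index = block_index,
                 label = label),
            class = "sparse_component")
}

# leading K ordinary PCs of a whole standardized layer (no clustering)
layer_components_noclust <- function(m, K) {
  e <- eigen(crossprod(m$values) / (nrow(m$values) - 1), symmetric = TRUE)
  lapply(seq_len(K), function(k) {
    ld <- stats::setNames(e$vectors[, k], m$variable_names)
    orient_component(dense_pc_component(ld, as.vector(m$values %*% ld),
                                        m$layer_id, k, paste0(m$layer_id, k)))
  })
}

# ordinary (dense) first PC per block
layer_components_blocks <- function(partition, m) {
  lapply(seq_len(partition$K), function(b) {
    vars <- names(partition$assignment)[partition$assignment == b]
    sub <- m$values[, vars, drop = FALSE]
    e <- leading_eigen(crossprod(sub) / (nrow(sub) - 1))
    ld <- stats::setNames(if (length(vars) == 1) 1 else e$vector, vars)
    orient_component(dense_pc_component(ld, as.vector(sub %*% ld),
                                        m$layer_id, b, paste0(m$layer_id, b)))
  })
}

#' Run the full pipeline
#'
#' Stages: load -> align -> standardize -> variable clustering (skipped
#' for `pca_noclust`) -> component extraction per the variant -> parallel
#' integration -> stepwise AIC Cox -> CD-ROC / concordance evaluation ->
#' polar chart (`bspc` only). When `cfg$out` is set, writes
#' `blocks_<layer>.tsv`, `scree_<layer>.tsv`, `loadings.tsv`,
#' `integrated.tsv`, `cox_table.tsv`, `metrics.json`, `mpchart.svg`,
#' `mpchart.json` and `run.log` there.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `integrated`, `selection` (labels + final `cox_fit`),
#'   `table`, `metrics` (`auc`, `c_index`, `t_eval`), `evaluation`,
#'   `chart_spec` (bspc only), `partitions`, `trees`, `config`, `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- c(sprintf("variant=%s fraction=%g ridge=%g ties=%s seed=%d",
                   cfg$variant, cfg$fraction, cfg$ridge, cfg$ties, cfg$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  mats <- stage("load", lapply(cfg$layers, function(ly) {
    if (!is.null(ly$matrix)) ly$matrix
    else load_omics_matrix(ly$path, layer_id = ly$label)
  }))
  surv <- stage("load", if (inherits(cfg$survival, "survival_outcome"))
    cfg$survival else load_survival(cfg$survival))
  al <- stage("align", align_samples(mats, surv))
  mats <- lapply(al$matrices, standardize)
  surv <- al$survival
  log <- c(log, sprintf("aligned samples: %d", length(surv$sample_ids)))

  per_layer <- list(); partitions <- list(); trees <- list()
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    Kspec <- cfg$layers[[i]]$K
    needs_tree <- identical(Kspec, "auto") || is.null(Kspec)
    tree <- if (needs_tree || cfg$variant != "pca_noclust")
      stage("cluster", agglomerate(m)) else NULL
    K <- if (needs_tree) {
      sug <- suggest_block_count(tree, cfg$k_max)
      log <- c(log, sprintf("layer %s: auto K=%d%s", m$layer_id, sug$K,
                            if (sug$low_confidence) " (low confidence)" else ""))
      sug$K
    } else as.integer(Kspec)
    res <- stage("components", {
      if (cfg$variant == "pca_noclust") {
        list(components = layer_components_noclust(m, K), partition = NULL)
      } else {
        partition <- cut_tree(tree, K, m)
        comps <- if (cfg$variant == "bspc") {
          extract_all(partition, m, fraction = cfg$fraction, ridge = cfg$ridge)
        } else {
          layer_components_blocks(partition, m)
        }
        list(components = comps, partition = partition)
      }
    })
    per_layer[[m$layer_id]] <- res$components
    partitions[[m$layer_id]] <- res$partition
    trees[[m$layer_id]] <- tree
    log <- c(log, sprintf("layer %s: %d blocks -> %d components",
                          m$layer_id, K, length(res$components)))
  }

  integrated <- stage("integrate",
                      merge_components(per_layer, surv,
                                       sample_ids = lapply(mats, `[[`, "sample_ids")))
  log <- c(log, sprintf("integrated: %d components", ncol(integrated$scores)))

  selection <- stage("cox", stepwise_aic(integrated, surv, ties = cfg$ties))
  log <- c(log, sprintf("stepwise selected %d components (AIC %.4f): %s",
                        length(selection$labels), selection$fit$aic,
                        paste(selection$labels, collapse = ", ")),
           attr(selection, "path"))

  t_eval <- if (identical(cfg$eval_time, "km_median")) NULL
            else as.numeric(cfg$eval_time)
  ev <- stage("evaluate", evaluate_model(selection$fit, integrated, surv,
                                         t = t_eval))
  metrics <- list(auc = ev$auc, c_index = ev$c_index, t_eval = ev$t_eval)
  log <- c(log, sprintf("evaluation: t=%g AUC=%.4f C=%.4f",
                        ev$t_eval, ev$auc, ev$c_index))

  chart_spec <- NULL
  if (cfg$variant == "bspc" && length(selection$labels) > 0) {
    chart_spec <- stage("chart", build_mpchart_spec(selection$fit,
                                                    integrated$provenance,
                                                    seed = cfg$seed))
  }
  tab <- stage("report", report_table(selection$fit, integrated$provenance))

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(cfg$out, f)
    for (id in names(partitions)) {
      if (!is.null(partitions[[id]]))
        write_blocks(partitions[[id]], o(paste0("blocks_", id, ".tsv")))
      if (!is.null(trees[[id]]))
        write_scree(trees[[id]], o(paste0("scree_", id, ".tsv")))
    }
    write_loadings(unlist(per_layer, recursive = FALSE), o("loadings.tsv"))
    write_integrated(integrated, o("integrated.tsv"))
    if (!is.null(tab))
      utils::write.table(tab, o("cox_table.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    jsonlite::write_json(metrics, o("metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_roc(ev$roc, o("roc.tsv"))
    if (!is.null(chart_spec)) {
      render_mpchart(chart_spec, o("mpchart.svg"))
      write_mpchart_spec(chart_spec, o("mpchart.json"))
    }
    model <- list(labels = selection$labels,
                  coefficients = as.list(selection$fit$coefficients),
                  se = as.list(selection$fit$se),
                  aic = selection$fit$aic, loglik = selection$fit$loglik)
    jsonlite::write_json(model, o("model.json"), auto_unbox = TRUE, digits = NA)
    log <- c(log, sprintf("R %s, bspcox %s", getRversion(),
                          as.character(utils::packageVersion("bspcox"))))
    writeLines(log, o("run.log"))
  }

  list(integrated = integrated, selection = selection, table = tab,
       metrics = metrics, evaluation = ev, chart_spec = chart_spec,
       partitions = partitions, trees = trees, config = cfg, log = log)
}
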