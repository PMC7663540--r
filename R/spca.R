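# First sparse principal component per block.
#
# The component solves an elastic-net-style reconstruction problem: find
# unit-norm alpha and sparse beta minimizing
#   sum_i || x_i - alpha beta' x_i ||^2 + ridge ||beta||^2
# with the sparsity expressed directly as a nonzero-count budget k.
# Alternating steps: given beta, alpha is the leading left factor of the
# rank-1 fit; given alpha, beta is the ridge solution hard-thresholded to
# its top-k magnitudes and re-solved on that support. The component score
# is X beta / ||beta||.

#' Nonzero-loading budget for a block
#'
#' The sparsity budget is a fixed fraction (default 10%) of the block's
#' variable count, rounded half to even, with a floor of one variable so
#' every block keeps a representative.
#'
#' @param p_block number of variables in the block.
#' @param fraction fraction of variables retained, in (0, 1].
#' @return integer nonzero count k, 1 <= k <= p_block.
#' @export
nonzero_count <- function(p_block, fraction = 0.10) {
  stopifnot(p_block >= 1, fraction > 0, fraction <= 1)
  # round() in R is round-half-to-even (IEC 60559)
  max(1L, as.integer(round(fraction * p_block)))
}

# alternating elastic-net updates on X'X = G: given beta, alpha is the
# leading left factor of the rank-1 fit; given alpha, beta is the ridge
# solution hard-thresholded to its top-k magnitudes and re-solved on that
# support; returns the unit-norm beta and its support (column indices)
alternate_spca <- function(G, k, ridge, max_iter, tol, init) {
  p <- ncol(G)
  beta <- init
  support <- sort(order(abs(beta), decreasing = TRUE)[seq_len(k)])
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    galpha <- G %*% beta
    na <- sqrt(sum(galpha^2))
    if (na == 0) break
    alpha <- as.vector(galpha) / na
    b_full <- solve(G + diag(ridge, p), G %*% alpha)
    new_support <- sort(order(abs(b_full), decreasing = TRUE)[seq_len(k)])
    b <- numeric(p)
    Gs <- G[new_support, new_support, drop = FALSE]
    b[new_support] <- solve(Gs + diag(ridge, k),
                            G[new_support, , drop = FALSE] %*% alpha)
    nb <- sqrt(sum(b^2))
    if (nb == 0) break
    b <- b / nb
    if (identical(new_support, support) &&
        min(sum((b - beta)^2), sum((b + beta)^2)) < tol^2 && iter > 1) {
      beta <- b; converged <- TRUE; break
    }
    beta <- b
    support <- new_support
  }
  list(beta = beta, support = support, converged = converged)
}

# largest eigenvalue of the correlation submatrix on a support
support_lambda1 <- function(R, S) {
  if (length(S) == 1) return(R[S, S])
  eigen(R[S, S], symmetric = TRUE, only.values = TRUE)$values[1]
}

# deterministic 1-swap local search maximizing support_lambda1
swap_refine <- function(R, S) {
  p <- ncol(R)
  S <- sort(S)
  best <- support_lambda1(R, S)
  if (length(S) == p) return(S)
  repeat {
    improved <- FALSE
    for (i in seq_along(S)) {
      for (j in setdiff(seq_len(p), S)) {
        S2 <- sort(c(S[-i], j))
        v <- support_lambda1(R, S2)
        if (v > best + 1e-12) {
          S <- S2; best <- v; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  S
}

# greedy forward construction of a size-k support seeded at variable j0
forward_support <- function(R, k, j0) {
  p <- ncol(R)
  S <- j0
  while (length(S) < k) {
    cand <- setdiff(seq_len(p), S)
    vals <- vapply(cand, function(j) support_lambda1(R, c(S, j)), numeric(1))
    S <- c(S, cand[which.max(vals)])
  }
  sort(S)
}

#' First sparse principal component of a block
#'
#' Alternating optimization of the elastic-net reconstruction objective
#' proposes a support; because the hard-threshold iteration can stall in a
#' local optimum of the implied support-selection problem, the support is
#' then refined by a deterministic 1-swap local search on the leading
#' eigenvalue of the support's correlation submatrix (on small blocks,
#' `p <= 12`, additionally seeded by greedy forward construction from every
#' variable). The returned loadings are the alternating fixed point on the
#' final support.
#'
#' @param block standardized numeric matrix (n samples x p_block
#'   variables) with column names.
#' @param k number of nonzero loadings, 1 <= k <= p_block.
#' @param ridge ridge penalty on the loading vector (default 1e-6).
#' @param max_iter,tol convergence controls for the alternating updates.
#' @return an object of class `sparse_component`: `loadings` (unit-norm
#'   p_block-vector with exactly k nonzeros, named), `support` (names of
#'   the nonzero loadings), `scores` (n-vector, `block %*% loadings`),
#'   `k`, `ridge`, `explained_variance` (sample variance of the scores).
#'   Labels (`layer_id`, `block_index`, `label`) are attached by
#'   [extract_all()].
#' @export
first_sparse_pc <- function(block, k, ridge = 1e-6,
                            max_iter = 500L, tol = 1e-8) {
  block <- as.matrix(block)
  n <- nrow(block); p <- ncol(block)
  if (k < 1 || k > p) stop("k must be between 1 and the block size")
  if (is.null(colnames(block))) colnames(block) <- paste0("V", seq_len(p))

  G <- crossprod(block)
  R <- G / (n - 1)
  init <- leading_eigen(R)$vector            # deterministic PC1 start
  alt <- alternate_spca(G, k, ridge, max_iter, tol, init)
  if (!alt$converged && max_iter > 1)
    warning("sparse PC alternation did not converge in ", max_iter,
            " iterations; refining from the last iterate")

  support <- swap_refine(R, alt$support)
  if (p <= 12 && k < p) {
    best <- support_lambda1(R, support)
    for (j0 in seq_len(p)) {
      Sj <- swap_refine(R, forward_support(R, k, j0))
      vj <- support_lambda1(R, Sj)
      if (vj > best + 1e-12) {
        support <- Sj; best <- vj
      }
    }
  }

  # final loadings: alternating fixed point restricted to the support,
  # i.e. the constrained first PC of the support's correlation submatrix
  # (the ridge rescales but does not rotate it)
  beta <- numeric(p)
  sub <- alternate_spca(G[support, support, drop = FALSE],
                        length(support), ridge, max_iter, tol,
                        leading_eigen(R[support, support, drop = FALSE])$vector)
  beta[support] <- sub$beta

  loadings <- stats::setNames(beta, colnames(block))
  scores <- as.vector(block %*% loadings)
  comp <- structure(list(loadings = loadings,
                         support = colnames(block)[support],
                         scores = scores,
                         k = as.integer(k), ridge = ridge,
                         explained_variance = stats::var(scores),
                         layer_id = NA_character_,
                         block_index = NA_integer_,
                         label = NA_character_),
                    class = "sparse_component")
  orient_component(comp)
}

#' Fix the sign of a sparse component
#'
#' Eigen-style solutions are defined up to sign; orient so the loading of
#' largest absolute value is positive, flipping the scores consistently.
#'
#' @param comp a `sparse_component`.
#' @return the component with canonical sign.
#' @export
orient_component <- function(comp) {
  stopifnot(inherits(comp, "sparse_component"))
  top <- which.max(abs(comp$loadings))
  if (comp$loadings[top] < 0) {
    comp$loadings <- -comp$loadings
    comp$scores <- -comp$scores
  }
  comp
}

#' @export
print.sparse_component <- function(x, ...) {
  cat(sprintf("sparse_component %s: %d of %d loadings nonzero, score variance %.4f\n",
              if (is.na(x$label)) "(unlabelled)" else x$label,
              x$k, length(x$loadings), x$explained_variance))
  invisible(x)
}

#' Extract one sparse component per block of a partitioned layer
#'
#' @param partition a `block_partition` from [cut_tree()].
#' @param m the standardized [omics_matrix()] the partition is defined on.
#' @param fraction sparsity fraction passed to [nonzero_count()].
#' @param ridge ridge penalty passed to [first_sparse_pc()].
#' @return list of oriented `sparse_component`s, labelled
#'   `<layer_id><block index>` (e.g. `"D4"`), in block order.
#' @export
extract_all <- function(partition, m, fraction = 0.10, ridge = 1e-6) {
  stopifnot(inherits(partition, "block_partition"), inherits(m, "omics_matrix"))
  if (!m$standardized) stop("standardize the matrix before extraction")
  if (!setequal(names(partition$assignment), m$variable_names))
    stop("partition variables do not match the matrix")
  if (partition$K < 1) stop("empty partition")
  lapply(seq_len(partition$K), function(b) {
    vars <- names(partition$assignment)[partition$assignment == b]
    blockmat <- m$values[, vars, drop = FALSE]
    comp <- first_sparse_pc(blockmat, k = nonzero_count(length(vars), fraction),
                            ridge = ridge)
    comp$layer_id <- m$layer_id
    comp$block_index <- b
    comp$label <- paste0(m$layer_id, b)
    comp
  })
}

#' Export nonzero loadings in long format
#'
#' @param components list of `sparse_component`s.
#' @param path output TSV path (`component`, `variable`, `loading`).
#' @return `path`, invisibly.
#' @export
write_loadings <- function(components, path) {
  rows <- do.call(rbind, lapply(components, function(cmp) {
    nz <- cmp$loadings[cmp$loadings != 0]
    data.frame(component = cmp$label, variable = names(nz),
               loading = unname(nz))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
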