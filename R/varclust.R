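# Variable clustering by the first-eigenvalue homogeneity criterion.
#
# The homogeneity of a cluster of standardized variables is the largest
# eigenvalue lambda1 of their correlation matrix; it equals the summed
# squared correlations of the member variables with the cluster's synthetic
# variable (the first principal component). Agglomeration greedily merges
# the pair of clusters with the smallest homogeneity loss
#   d(A, B) = lambda1(A) + lambda1(B) - lambda1(A union B) >= 0.

# largest eigenvalue + eigenvector of a symmetric PSD matrix; dense
# eigendecomposition up to `dense_limit`, power iteration above it
leading_eigen <- function(S, dense_limit = 512L, tol = 1e-10, max_iter = 1000L) {
  m <- nrow(S)
  if (m == 1L) return(list(value = S[1, 1], vector = 1))
  if (m <= dense_limit) {
    e <- eigen(S, symmetric = TRUE)
    return(list(value = e$values[1], vector = e$vectors[, 1]))
  }
  v <- rep(1 / sqrt(m), m)
  lambda <- 0
  for (i in seq_len(max_iter)) {
    w <- S %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(list(value = 0, vector = v))
    w <- as.vector(w) / nw
    lambda_new <- as.numeric(crossprod(w, S %*% w))
    if (abs(lambda_new - lambda) < tol && sum((w - v)^2) < tol) {
      return(list(value = lambda_new, vector = w))
    }
    v <- w
    lambda <- lambda_new
  }
  warning("power iteration did not converge to tolerance ", tol)
  list(value = lambda, vector = v)
}

check_standardized <- function(x, tol = 1e-6) {
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  if (any(abs(mu) > tol) || any(abs(v - 1) > tol))
    stop("input columns must be standardized (mean 0, variance 1)")
  invisible(TRUE)
}

#' Homogeneity of a variable cluster
#'
#' For a set of standardized variables, homogeneity is the largest
#' eigenvalue of their correlation matrix, which equals the summed squared
#' Pearson correlations between the variables and the cluster's synthetic
#' variable (first principal component scores).
#'
#' @param columns standardized numeric matrix, n samples x m cluster
#'   variables.
#' @return list with `lambda1` (homogeneity) and `scores` (n-vector of
#'   synthetic-variable scores, oriented so the variable most correlated
#'   with the component correlates positively).
#' @export
cluster_homogeneity <- function(columns) {
  columns <- as.matrix(columns)
  check_standardized(columns)
  n <- nrow(columns)
  R <- crossprod(columns) / (n - 1)
  e <- leading_eigen(R)
  scores <- as.vector(columns %*% e$vector)
  r <- suppressWarnings(as.vector(stats::cor(columns, scores)))
  if (all(is.na(r))) r <- rep(0, ncol(columns))
  top <- which.max(abs(r))
  if (!is.na(r[top]) && r[top] < 0) scores <- -scores
  list(lambda1 = e$value, scores = scores)
}

lambda1_of <- function(x, idx) {
  n <- nrow(x)
  sub <- x[, idx, drop = FALSE]
  leading_eigen(crossprod(sub) / (n - 1))$value
}

#' Dissimilarity between two disjoint variable clusters
#'
#' The loss in total homogeneity incurred by merging:
#' `d = lambda1(A) + lambda1(B) - lambda1(A union B)`, always nonnegative
#' for standardized variables.
#'
#' @param x standardized matrix holding all variables.
#' @param a,b integer or character column indices of the two clusters.
#' @return nonnegative scalar dissimilarity.
#' @export
dissimilarity <- function(x, a, b) {
  x <- as.matrix(x)
  if (is.character(a)) a <- match(a, colnames(x))
  if (is.character(b)) b <- match(b, colnames(x))
  if (length(intersect(a, b)) > 0) stop("clusters must be disjoint")
  check_standardized(x[, union(a, b), drop = FALSE])
  lambda1_of(x, a) + lambda1_of(x, b) - lambda1_of(x, c(a, b))
}

#' Agglomerative variable clustering on the homogeneity criterion
#'
#' Starts from singleton clusters and greedily merges the pair with the
#' smallest homogeneity loss until one cluster remains, recording the full
#' merge history. Ties (within 1e-12 of the minimum) are broken by the
#' lowest smallest member index, then the lowest second index, so the tree
#' is deterministic.
#'
#' @param m a standardized [omics_matrix()] with at least 2 variables.
#' @return an object of class `variable_tree` with fields `merge` (p-1 x 2,
#'   `hclust` convention: negative entries are leaves), `height` (merge
#'   dissimilarities, in merge order), `labels`, `order` (leaf order for
#'   dendrogram display), and `layer_id`.
#' @export
agglomerate <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!m$standardized) stop("standardize the matrix before clustering")
  x <- m$values
  p <- ncol(x)
  if (p < 2) stop("clustering needs at least 2 variables")

  # active clusters as lists of leaf indices; id: 1..p leaves, then p+step
  members <- as.list(seq_len(p))
  lambda <- rep(1, p)          # singleton homogeneity is exactly 1
  node_id <- -seq_len(p)       # hclust convention
  active <- seq_len(p)
  min_leaf <- seq_len(p)

  # pairwise dissimilarity cache over active cluster slots; for two
  # standardized singletons lambda1 = 1 + |r|, so d = 1 - |r|
  R <- crossprod(x) / (nrow(x) - 1)
  d <- 1 - abs(R)
  d[lower.tri(d, diag = TRUE)] <- Inf

  merge <- matrix(0L, p - 1, 2)
  height <- numeric(p - 1)
  merged_members <- vector("list", p - 1)

  for (step in seq_len(p - 1)) {
    act <- active
    dm <- d[act, act, drop = FALSE]
    dmin <- min(dm[upper.tri(dm)])
    cand <- which(upper.tri(dm) & dm <= dmin + 1e-12, arr.ind = TRUE)
    # tie-break: smallest min-leaf index, then smallest second min-leaf
    key1 <- pmin(min_leaf[act[cand[, 1]]], min_leaf[act[cand[, 2]]])
    key2 <- pmax(min_leaf[act[cand[, 1]]], min_leaf[act[cand[, 2]]])
    pick <- order(key1, key2)[1]
    ia <- act[min(cand[pick, ])]; ib <- act[max(cand[pick, ])]

    new_members <- c(members[[ia]], members[[ib]])
    new_lambda <- lambda1_of(x, new_members)
    height[step] <- lambda[ia] + lambda[ib] - new_lambda
    merge[step, ] <- sort(c(node_id[ia], node_id[ib]),
                          decreasing = FALSE)
    merged_members[[step]] <- new_members

    # reuse slot ia for the merged cluster, retire ib
    members[[ia]] <- new_members
    lambda[ia] <- new_lambda
    node_id[ia] <- step
    min_leaf[ia] <- min(min_leaf[ia], min_leaf[ib])
    active <- setdiff(active, ib)
    for (k in setdiff(active, ia)) {
      dd <- lambda[ia] + lambda[k] -
        lambda1_of(x, c(members[[ia]], members[[k]]))
      d[min(ia, k), max(ia, k)] <- dd
    }
  }

  structure(list(merge = merge, height = height,
                 labels = colnames(x),
                 order = merged_members[[p - 1]],
                 merged_members = merged_members,
                 layer_id = m$layer_id, p = p),
            class = "variable_tree")
}

#' @export
print.variable_tree <- function(x, ...) {
  cat(sprintf("variable_tree ('%s'): %d variables, %d merges, height range [%.4g, %.4g]\n",
              x$layer_id, x$p, length(x$height),
              min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a variable tree to an hclust object
#'
#' The merge heights of the homogeneity criterion are not guaranteed to be
#' monotone, so dendrogram plots may show inversions (as with centroid
#' linkage).
#'
#' @param x a `variable_tree`.
#' @param ... unused.
#' @return an object of class `hclust`.
#' @export
as.hclust.variable_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "homogeneity",
                 call = match.call(), dist.method = "homogeneity loss"),
            class = "hclust")
}

partition_assignment <- function(tree, K) {
  p <- tree$p
  if (K < 1 || K > p) stop("K must be between 1 and the number of variables")
  assign <- seq_len(p)
  if (K < p) {
    # replay the first p - K merges with union-find style relabeling
    for (step in seq_len(p - K)) {
      mem <- tree$merged_members[[step]]
      assign[mem] <- min(assign[mem])
    }
  }
  # renumber blocks 1..K in order of first appearance
  as.integer(factor(assign, levels = unique(assign)))
}

#' Cut a variable tree into K blocks
#'
#' Undoes the final K-1 merges of the agglomeration, yielding a partition
#' into K disjoint blocks, and computes each block's homogeneity and
#' synthetic-variable scores.
#'
#' @param tree a `variable_tree` from [agglomerate()].
#' @param K number of blocks, between 1 and p.
#' @param m the standardized [omics_matrix()] the tree was built from.
#' @return an object of class `block_partition` with fields `K`,
#'   `assignment` (named integer vector, variable -> block), `lambda1`
#'   (per-block homogeneity), `scores` (n x K synthetic-variable score
#'   matrix), `homogeneity` (total, sum of `lambda1`), `layer_id`.
#' @export
cut_tree <- function(tree, K, m) {
  stopifnot(inherits(tree, "variable_tree"), inherits(m, "omics_matrix"))
  if (!m$standardized) stop("standardize the matrix before cutting")
  if (!identical(colnames(m$values), tree$labels))
    stop("matrix variables do not match the tree's labels")
  assign <- partition_assignment(tree, K)
  names(assign) <- tree$labels
  lambda1 <- numeric(K)
  scores <- matrix(NA_real_, nrow(m$values), K,
                   dimnames = list(m$sample_ids, paste0("block", seq_len(K))))
  for (k in seq_len(K)) {
    h <- cluster_homogeneity(m$values[, assign == k, drop = FALSE])
    lambda1[k] <- h$lambda1
    scores[, k] <- h$scores
  }
  structure(list(K = K, assignment = assign, lambda1 = lambda1,
                 scores = scores, homogeneity = sum(lambda1),
                 layer_id = m$layer_id),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("block_partition ('%s'): %d blocks over %d variables, total homogeneity %.4f\n",
              x$layer_id, x$K, length(x$assignment), x$homogeneity))
  cat("block sizes:", paste(tabulate(x$assignment, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Suggest a block count from the merge-height scree
#'
#' Examines the scree of merge heights indexed by cluster count and returns
#' the K (in 2..k_max) with the largest drop between consecutive scree
#' values. When the scree is nearly flat (no drop clearly dominates), the
#' result carries a low-confidence flag and the scree is returned for
#' manual inspection; an explicit K chosen from the dendrogram is always
#' preferable in that case.
#'
#' @param tree a `variable_tree`.
#' @param k_max largest block count to consider (capped at p - 1).
#' @return list with `K`, `low_confidence` flag, and `scree` (data frame of
#'   cluster count vs merge height).
#' @export
suggest_block_count <- function(tree, k_max = 20L) {
  p <- tree$p
  k_max <- min(as.integer(k_max), p - 1L)
  if (k_max < 2L) stop("k_max must be at least 2")
  # the merge that reduces K clusters to K - 1 is merge number p - K + 1,
  # so the scree value at K clusters is height[p - K + 1], K in 2..p
  scree_k <- 2:min(k_max + 1L, p)
  scree_h <- tree$height[p - scree_k + 1L]
  ks <- 2:k_max
  drops <- scree_h[match(ks, scree_k)] - scree_h[match(ks + 1L, scree_k)]
  drops[is.na(drops)] <- -Inf
  K <- ks[which.max(drops)]
  # the suggestion is decisive only when the best drop clearly dominates
  # the runner-up; on a flat (structureless) scree the largest and
  # second-largest drops are of the same order
  finite <- sort(drops[is.finite(drops)], decreasing = TRUE)
  second <- if (length(finite) > 1) max(finite[2], 0) else 0
  low_conf <- length(finite) == 0 || finite[1] < 1e-8 ||
    finite[1] <= 3 * second
  list(K = K, low_confidence = low_conf,
       scree = data.frame(clusters = scree_k, height = scree_h))
}

#' Export block assignments as a two-column table
#'
#' @param partition a `block_partition`.
#' @param path output TSV path (`variable`, `block`).
#' @return `path`, invisibly.
#' @export
write_blocks <- function(partition, path) {
  stopifnot(inherits(partition, "block_partition"))
  df <- data.frame(variable = names(partition$assignment),
                   block = unname(partition$assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export merge heights for scree plotting
#' @param tree a `variable_tree`.
#' @param path output TSV path (`clusters`, `height`).
#' @return `path`, invisibly.
#' @export
write_scree <- function(tree, path) {
  stopifnot(inherits(tree, "variable_tree"))
  p <- tree$p
  df <- data.frame(clusters = seq(p - 1L, 1L), height = tree$height)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
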