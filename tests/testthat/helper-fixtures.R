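# shared fixtures: all synthetic, built in code at test time

# standardize a plain matrix (mean 0, sd 1 with n-1 divisor), drop attrs
std_mat <- function(x) {
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  x
}

# random standardized matrix with mild latent structure and column names
random_std_matrix <- function(n, p, n_factors = 2, seed = 1) {
  set.seed(seed)
  L <- matrix(stats::rnorm(p * n_factors), p, n_factors)
  x <- matrix(stats::rnorm(n * n_factors), n, n_factors) %*% t(L) +
    matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- paste0("V", seq_len(p))
  rownames(x) <- paste0("S", seq_len(n))
  std_mat(x)
}

# omics_matrix wrapper around a standardized random matrix
random_omics <- function(n, p, layer_id = "X", seed = 1) {
  omics_matrix(random_std_matrix(n, p, seed = seed), layer_id = layer_id,
               standardized = TRUE)
}

# two exact duplicate pairs: (V1,V2) and (V3,V4)
duplicate_pairs_matrix <- function(n = 30, seed = 5) {
  set.seed(seed)
  a <- stats::rnorm(n); b <- stats::rnorm(n)
  x <- cbind(V1 = a, V2 = a, V3 = b, V4 = b)
  rownames(x) <- paste0("S", seq_len(n))
  std_mat(x)
}

# largest eigenvalue of the correlation matrix of selected columns
lam1_cols <- function(x, idx) {
  n <- nrow(x)
  sub <- x[, idx, drop = FALSE]
  if (length(idx) == 1) return(1)
  eigen(crossprod(sub) / (n - 1), symmetric = TRUE, only.values = TRUE)$values[1]
}

# independent greedy agglomeration oracle: recomputes every candidate
# dissimilarity by dense eigendecomposition at every step, no caching
oracle_agglomerate <- function(x) {
  p <- ncol(x)
  clusters <- as.list(seq_len(p))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    dbest <- Inf; pick <- NULL
    for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) {
      d <- lam1_cols(x, clusters[[i]]) + lam1_cols(x, clusters[[j]]) -
        lam1_cols(x, c(clusters[[i]], clusters[[j]]))
      better <- d < dbest - 1e-12
      tie <- abs(d - dbest) <= 1e-12 && !is.null(pick) &&
        (min(clusters[[i]], clusters[[j]]) < min(clusters[[pick[1]]], clusters[[pick[2]]]))
      if (better || tie) { dbest <- d; pick <- c(i, j) }
    }
    merged <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    merges[[length(merges) + 1]] <- sort(merged)
    heights <- c(heights, dbest)
    clusters <- c(clusters[-pick], list(merged))
  }
  list(merges = merges, heights = heights)
}

# simple exact survival fixture
tiny_survival <- function(time, event, ids = NULL) {
  if (is.null(ids)) ids <- paste0("S", seq_along(time))
  survival_outcome(ids, time, event)
}

# Mann-Whitney AUC of marker for group membership (ties count 1/2)
mw_auc <- function(marker_cases, marker_controls) {
  num <- 0
  for (mc in marker_cases)
    num <- num + sum(mc > marker_controls) + 0.5 * sum(mc == marker_controls)
  num / (length(marker_cases) * length(marker_controls))
}

# small integrated dataset + survival with known signal in component 1
simulated_integrated <- function(n, betas, seed = 1, censoring = 0) {
  set.seed(seed)
  K <- length(betas)
  scores <- matrix(stats::rnorm(n * K), n, K,
                   dimnames = list(paste0("S", seq_len(n)),
                                   paste0("C", seq_len(K))))
  rate <- exp(as.vector(scores %*% betas))
  t_ev <- stats::rexp(n, rate)
  if (censoring > 0) {
    t_c <- stats::rexp(n, censoring * mean(rate) / (1 - censoring))
    time <- pmin(t_ev, t_c); event <- as.numeric(t_ev <= t_c)
  } else {
    time <- t_ev; event <- rep(1, n)
  }
  prov <- stats::setNames(lapply(seq_len(K), function(k)
    list(layer_id = "C", block_index = k, block_size = 1,
         support = paste0("C", k),
         loadings = stats::setNames(1, paste0("C", k)))),
    colnames(scores))
  data <- structure(list(sample_ids = rownames(scores),
                         labels = colnames(scores), scores = scores,
                         provenance = prov),
                    class = "integrated_dataset")
  list(data = data,
       survival = survival_outcome(rownames(scores), time, event))
}
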