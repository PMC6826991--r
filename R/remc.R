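# Recursive expectation-maximization clustering (REMc) of interaction
# z-score profiles.
#
# A Gaussian mixture with diagonal covariances is fitted by EM for a range
# of component counts; the BIC-best model hard-assigns rows, and clustering
# recurses into each cluster until the selected model is a single
# component, the cluster is too small, or the maximum depth is reached.
# Cluster names encode the lineage (root "1", children "1-0", "1-0-2", ...).

# log N(x | m, diag(v)) summed over dimensions, for one component
.log_dens_diag <- function(X, m, v) {
  -0.5 * sum(log(2 * pi * v)) -
    0.5 * colSums((t(X) - m)^2 / v)
}

# one EM run from a given seed; returns NULL if the run degenerates
.em_gmm_once <- function(X, k, seed, max_iter = 300, tol = 1e-8) {
  n <- nrow(X); d <- ncol(X)
  var_floor <- 1e-6 * mean(apply(X, 2, stats::var)) + 1e-10
  init <- with_seed(seed, {
    km <- tryCatch(stats::kmeans(X, k, nstart = 1, iter.max = 20),
                   error = function(e) NULL)
    if (!is.null(km)) list(m = km$centers)
    else list(m = X[sample(n, k), , drop = FALSE])
  })
  means <- matrix(init$m, nrow = k)
  vars <- matrix(rep(pmax(apply(X, 2, stats::var), var_floor), each = k),
                 nrow = k)
  weights <- rep(1 / k, k)

  trace <- numeric()
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    logp <- vapply(seq_len(k), function(j)
      log(weights[j]) + .log_dens_diag(X, means[j, ], vars[j, ]),
      numeric(n))
    if (is.null(dim(logp))) logp <- matrix(logp, nrow = n)
    mx <- apply(logp, 1, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logp - lse)
    if (iter > 1 && ll - trace[iter - 1] < tol * (1 + abs(ll))) break
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)  # emptied component
    weights <- nk / n
    means <- t(resp) %*% X / nk
    for (j in seq_len(k)) {
      vars[j, ] <- pmax(colSums(resp[, j] * (X - matrix(
        means[j, ], n, d, byrow = TRUE))^2) / nk[j], var_floor)
    }
  }
  npar <- (k - 1) + 2 * k * d
  list(k = k, means = means, vars = vars, weights = weights,
       responsibilities = resp,
       assignment = max.col(resp, ties.method = "first"),
       loglik = trace[length(trace)], trace = trace,
       bic = 2 * trace[length(trace)] - npar * log(n))
}

#' Fit a Gaussian mixture by EM with BIC model selection
#'
#' Diagonal-covariance Gaussian mixtures are fitted by EM for each
#' candidate component count, with `n_init` restarts per count (k-means /
#' random initializations derived deterministically from `seed`); the
#' number of components maximizing BIC is selected and rows are
#' hard-assigned by maximum posterior responsibility. Candidate counts are
#' capped at `floor(nrow/2)` so every component can hold at least two rows.
#'
#' @param X numeric matrix (rows = genes, columns = z-score profile).
#' @param k_candidates integer vector of component counts to try.
#' @param n_init EM restarts per candidate count.
#' @param seed integer seed; identical seeds give identical models.
#' @return list with `assignment` (integer vector), `chosen_k`, `model`
#'   (means, vars, weights, loglik, trace, bic of the selected fit),
#'   `bic_table` (data.table: k, loglik, bic) and `all_traces` (the
#'   log-likelihood trace of every EM run attempted, for convergence
#'   diagnostics).
#' @export
em_cluster <- function(X, k_candidates = 1:10, n_init = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 rows to cluster")
  k_candidates <- k_candidates[k_candidates <= max(1, n %/% 2)]
  if (!length(k_candidates)) k_candidates <- 1L
  fits <- list()
  all_traces <- list()
  for (k in sort(unique(k_candidates))) {
    if (k == 1) {
      m <- colMeans(X)
      v <- pmax(apply(X, 2, stats::var) * (n - 1) / n,
                1e-6 * mean(apply(X, 2, stats::var)) + 1e-10)
      ll <- sum(vapply(seq_len(ncol(X)), function(j)
        sum(stats::dnorm(X[, j], m[j], sqrt(v[j]), log = TRUE)),
        numeric(1)))
      fits[[as.character(k)]] <- list(
        k = 1L, means = matrix(m, 1), vars = matrix(v, 1), weights = 1,
        responsibilities = matrix(1, n, 1), assignment = rep(1L, n),
        loglik = ll, trace = ll, bic = 2 * ll - 2 * ncol(X) * log(n))
      next
    }
    best <- NULL
    for (i in seq_len(n_init)) {
      f <- .em_gmm_once(X, k, seed = seed + 1000L * k + i)
      if (is.null(f)) next
      all_traces[[paste0("k", k, "_init", i)]] <- f$trace
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    if (!is.null(best)) fits[[as.character(k)]] <- best
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  sel <- fits[[which.max(bics)]]
  list(assignment = sel$assignment, chosen_k = sel$k,
       model = sel[c("means", "vars", "weights", "loglik", "trace", "bic")],
       bic_table = data.table::data.table(
         k = as.integer(names(fits)),
         loglik = vapply(fits, `[[`, numeric(1), "loglik"),
         bic = bics),
       all_traces = all_traces)
}

#' Recursive EM clustering of a profile matrix
#'
#' Applies [em_cluster()] to the full matrix and then recursively to every
#' resulting cluster. Recursion stops in a branch when the selected model
#' has one component, fewer than `min_size` members remain, or `max_depth`
#' is reached. Every node carries a lineage-encoded name: the root is
#' `"1"`, its children `"1-0", "1-1", ...`, their children `"1-0-0"`, and
#' so on.
#'
#' @param X numeric matrix with row names (genes) and z-score columns, or
#'   the data.table from [profile_matrix()] (its `z_` columns are used;
#'   shift columns never enter the model).
#' @param k_candidates,n_init,seed passed to [em_cluster()].
#' @param min_size minimum cluster size eligible for further splitting.
#' @param max_depth maximum recursion depth.
#' @return the root `ClusterNode`: a list with `name`, `members`, `depth`,
#'   `model` (`NULL` for unsplit leaves), `children` (list of nodes, empty
#'   at leaves). Use [remc_membership()] to flatten leaves to a table.
#' @export
remc <- function(X, k_candidates = 1:10, n_init = 5L, seed = 1L,
                 min_size = 8L, max_depth = 4L) {
  X <- as_profile_matrix(X)
  build <- function(rows, name, depth) {
    node <- list(name = name, members = sort(rows), depth = depth,
                 model = NULL, children = list())
    if (length(rows) < max(min_size, 4L) || depth >= max_depth)
      return(node)
    fit <- em_cluster(X[rows, , drop = FALSE], k_candidates = k_candidates,
                      n_init = n_init,
                      seed = seed + string_seed(name) %% 100000L)
    node$model <- fit$model
    node$chosen_k <- fit$chosen_k
    if (fit$chosen_k == 1) return(node)
    for (c in seq_len(fit$chosen_k)) {
      sub <- rows[fit$assignment == c]
      node$children[[c]] <- build(sub, paste0(name, "-", c - 1L), depth + 1L)
    }
    node
  }
  build(rownames(X), "1", 0L)
}

# accept a matrix or a profile_matrix() data.table
as_profile_matrix <- function(X) {
  if (data.table::is.data.table(X) || is.data.frame(X)) {
    dt <- data.table::as.data.table(X)
    zc <- grep("^z_", names(dt), value = TRUE)
    if (!length(zc)) stop("no z_ columns found in profile table")
    m <- as.matrix(dt[, zc, with = FALSE])
    rownames(m) <- dt$strain %||% dt$gene
    return(m)
  }
  m <- as.matrix(X)
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  m
}

#' Flatten a REMc tree to leaf memberships
#'
#' @param node root node from [remc()].
#' @return data.table: `gene`, `cluster_name`, `depth`. Leaves partition
#'   the input genes.
#' @export
remc_membership <- function(node) {
  if (!length(node$children))
    return(data.table::data.table(gene = node$members,
                                  cluster_name = node$name,
                                  depth = node$depth))
  data.table::rbindlist(lapply(node$children, remc_membership))
}

#' Order cluster members for heatmap display
#'
#' Members are ordered by average-linkage hierarchical clustering on the
#' Euclidean distance between their z-profiles, as done for visualization
#' after mixture clustering. Members are pre-sorted lexicographically so
#' ties (identical profiles) keep a deterministic, name-ordered layout.
#'
#' @param node a `ClusterNode` from [remc()].
#' @param X the profile matrix (or [profile_matrix()] table) the tree was
#'   built from.
#' @return character vector of member genes in display order.
#' @export
order_for_display <- function(node, X) {
  X <- as_profile_matrix(X)
  members <- sort(node$members)
  if (length(members) < 3) return(members)
  d <- stats::dist(X[members, , drop = FALSE])
  if (max(d) == 0) return(members)  # identical profiles: keep name order
  h <- stats::hclust(d, method = "average")
  members[h$order]
}

#' Optional heatmap hook for REMc results
#'
#' Draws a z-score heatmap of one cluster's members (display-ordered) when
#' the pheatmap package is available; otherwise returns `NULL` invisibly.
#' Figure rendering is a convenience, not part of the analysis contract.
#'
#' @param node a `ClusterNode`.
#' @param X profile matrix or [profile_matrix()] table.
#' @param filename optional path forwarded to [pheatmap::pheatmap()].
#' @return the pheatmap object, or `NULL` when pheatmap is unavailable.
#' @export
remc_heatmap <- function(node, X, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) return(invisible(NULL))
  X <- as_profile_matrix(X)
  ord <- order_for_display(node, X)
  pheatmap::pheatmap(X[ord, , drop = FALSE], cluster_rows = FALSE,
                     cluster_cols = FALSE, main = node$name,
                     filename = filename)
}
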