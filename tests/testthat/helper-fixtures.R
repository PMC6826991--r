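# Shared fixtures and independent oracles, all built in code.

# small noise-free experiment used by the interaction identity tests
tiny_config <- function(seed = 7, n_mut = 5, n_ref = 8, noise = 0,
                        planted = NULL, ...) {
  simulation_config(seed = seed, n_mutant_strains = n_mut,
                    n_reference_cultures = n_ref, noise_sd = noise,
                    planted_effects = planted, ...)
}

# independent least-squares oracle: normal equations solved directly
ols_oracle <- function(d, y) {
  X <- cbind(1, d)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))  # (A, B)
}

# exact hypergeometric upper tail by combinatorial counting (doubles are
# exact here: all products stay far below 2^53 for N <= 25)
hyper_tail_oracle <- function(k, M, N, n) {
  js <- k:min(n, M)
  sum(choose(M, js) * choose(N - M, n - js)) / choose(N, n)
}

# brute-force subset enumeration of the same tail (small N only)
hyper_tail_enumerate <- function(k, M, N, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= M) >= k)  # first M elements carry the term
}

# adjusted Rand index, direct from the pair-counting definition
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# published per-gene interaction z-scores used for worked examples
published_scores <- function() {
  read_tsv_table(system.file("extdata", "published_interaction_zscores.tsv",
                             package = "phenodgi"))
}

# planted 4-group z-profile hierarchy: three coarse groups, one of which
# splits in two; separation in units of the within-group SD
hierarchy_profiles <- function(seed, n_per = 40, sep = 5, sd = 1) {
  centers <- rbind(c(0, 0, 0, 0),
                   c(sep, 0, 0, 0),
                   c(0, sep, 0, 0),
                   c(0, sep, sep, 0)) * sd
  labels <- rep(1:4, each = n_per)
  X <- withr::with_seed(seed, centers[labels, ] +
                          matrix(rnorm(length(labels) * 4, 0, sd),
                                 ncol = 4))
  rownames(X) <- sprintf("g%03d", seq_along(labels))
  list(X = X, labels = labels)
}
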