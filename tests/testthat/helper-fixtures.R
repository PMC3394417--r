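# Shared fixtures built in code: tiny networks and seeded expression data.

chain_network <- function(n = 3L) {
  gene_network(paste0("g", seq_len(n - 1L)), paste0("g", 2L:n),
               order = "first-seen")
}

# Random small directed network (no self-loops, deduplicated).
random_network <- function(n_genes, n_edges, seed = 1L) {
  set.seed(seed)
  from <- sample(paste0("g", seq_len(n_genes)), n_edges * 3L, replace = TRUE)
  to <- sample(paste0("g", seq_len(n_genes)), n_edges * 3L, replace = TRUE)
  ok <- from != to
  suppressWarnings(gene_network(head(from[ok], n_edges), head(to[ok], n_edges),
                                genes = paste0("g", seq_len(n_genes))))
}

# Two-group data with chosen per-group mean shifts for some genes.
# shifts_*: named vectors of mean differences applied to the non-control side.
make_data <- function(genes, n = 20L, mu = 7, sd = 1, shifts_A = NULL,
                      shifts_B = NULL, seed = 1L) {
  set.seed(seed)
  M <- length(genes)
  mk <- function() matrix(rnorm(M * n, mu, sd), M, dimnames = list(genes, NULL))
  nA <- mk(); nB <- mk()
  if (!is.null(shifts_A)) nA[names(shifts_A), ] <- nA[names(shifts_A), ] + shifts_A
  if (!is.null(shifts_B)) nB[names(shifts_B), ] <- nB[names(shifts_B), ] + shifts_B
  two_group_data(mk(), nA, mk(), nB)
}

# Brute-force quadrature oracle for the hierarchical Gaussian marginal.
# Integrates exp(log f - C) around the posterior mode so neither underflow
# nor integrate()'s absolute tolerance can corrupt tiny likelihoods.
quadrature_loglik <- function(z, mu0, sigma, tau) {
  n <- length(z)
  logf <- function(m) sum(dnorm(z, m, sigma, log = TRUE)) + dnorm(m, mu0, tau, log = TRUE)
  post_mean <- (tau^2 * sum(z) + sigma^2 * mu0) / (n * tau^2 + sigma^2)
  post_sd <- sqrt(sigma^2 * tau^2 / (n * tau^2 + sigma^2))
  C <- logf(post_mean)
  g <- function(mu) vapply(mu, function(m) exp(logf(m) - C), numeric(1))
  val <- stats::integrate(g, post_mean - 12 * post_sd, post_mean + 12 * post_sd,
                          rel.tol = 1e-10, abs.tol = 0, subdivisions = 500L)$value
  C + log(val)
}

# Table of the 16 interaction values exactly as printed: for each value the
# regulation pair it encodes and the five unary feature values.
unary_feature_table <- function() {
  tab <- rbind(
    c(1, 0, 0, 1, 1, 1),
    c(2, 1, 0, 0, 1, 0),
    c(3, 0, 1, 0, 1, 0),
    c(4, 0, 0, 1, 1, 1),
    c(5, 0, 0, 1, 0, 1),
    c(6, 0, 0, 1, 0, 0),
    c(7, 0, 0, 1, 0, 0),
    c(8, 0, 0, 1, 0, 1),
    c(9, 0, 0, 1, 0, 1),
    c(10, 0, 0, 1, 0, 0),
    c(11, 0, 0, 1, 0, 0),
    c(12, 0, 0, 1, 0, 1),
    c(13, 0, 0, 1, 1, 1),
    c(14, 0, 0, 1, 1, 0),
    c(15, 0, 0, 1, 1, 0),
    c(16, 0, 0, 1, 1, 1))
  colnames(tab) <- c("X", "F1", "F2", "F3", "F6", "F7")
  as.data.frame(tab)
}
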