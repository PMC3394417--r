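# Model fitting: t-test initialization, DE estimation of the likelihood
# hyperparameters and feature coefficients, and ICM sweeps over gene states,
# alternated until the discrete assignment stops changing.

#' Fitting configuration
#'
#' @param ttest_alpha Two-sample t-test level for the state initialization
#'   (default 0.05).
#' @param de List of differential-evolution settings: `np` (population size,
#'   40), `generations` (100), `cr` (crossover rate, 0.9), `f` (differential
#'   weight, 0.8).
#' @param gamma_bounds Either length-2 bounds applied to every feature
#'   coefficient, or a 7 x 2 matrix of per-coefficient bounds (default
#'   `c(-10, 10)` for all seven).
#' @param gamma_fixed Optional named numeric vector pinning feature
#'   coefficients, e.g. `c(gamma6 = 0, gamma7 = 0)`; pinned coefficients are
#'   excluded from estimation. Restricting `gamma6`/`gamma7` weakens the
#'   equal-regulation prior on small datasets.
#' @param theta_y_bounds Optional list with elements `mu0`, `sigma`, `tau`
#'   (each length-2). Defaults: `mu0` spans the data range, `sigma` and `tau`
#'   span `[1e-3, 10]` times the overall data standard deviation.
#' @param max_cycles Cap on outer cycles (default 20).
#' @param tol Relative parameter-movement tolerance recorded in the trace
#'   (default 1e-4).
#' @param seed Master seed; all internal randomness derives from it.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(ttest_alpha = 0.05,
                       de = list(),
                       gamma_bounds = c(-10, 10),
                       gamma_fixed = NULL,
                       theta_y_bounds = NULL,
                       max_cycles = 20L,
                       tol = 1e-4,
                       seed = 0L) {
  stopifnot(ttest_alpha > 0, ttest_alpha < 1, max_cycles >= 1L, tol > 0)
  if (is.matrix(gamma_bounds)) {
    stopifnot(nrow(gamma_bounds) == 7L, ncol(gamma_bounds) == 2L,
              all(gamma_bounds[, 1] < gamma_bounds[, 2]))
  } else {
    stopifnot(length(gamma_bounds) == 2L, gamma_bounds[1] < gamma_bounds[2])
    gamma_bounds <- matrix(rep(gamma_bounds, each = 7L), ncol = 2L)
  }
  de_def <- list(np = 40L, generations = 100L, cr = 0.9, f = 0.8)
  unknown <- setdiff(names(de), names(de_def))
  if (length(unknown)) stop("unknown DE setting(s): ", paste(unknown, collapse = ", "))
  de_def[names(de)] <- de
  if (!is.null(gamma_fixed)) {
    idx <- as.integer(sub("^gamma", "", names(gamma_fixed)))
    if (any(is.na(idx)) || any(!idx %in% 1:7)) {
      stop("`gamma_fixed` must be named gamma1..gamma7")
    }
  }
  structure(list(ttest_alpha = ttest_alpha, de = de_def,
                 gamma_bounds = gamma_bounds, gamma_fixed = gamma_fixed,
                 theta_y_bounds = theta_y_bounds,
                 max_cycles = as.integer(max_cycles), tol = tol,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Initialize gene states with two-sample t-tests
#'
#' Per gene and group, a pooled-variance two-sample t-test compares control
#' against non-control samples; the gene starts DE in that group when
#' p < `alpha`. The metagene is always DE in both groups.
#'
#' @param data A [two_group_data()].
#' @param alpha Test level (default 0.05).
#' @param metagene Metagene sentinel included in the returned vectors.
#' @return List with binary named vectors `S_A` and `S_B` over the metagene
#'   plus all genes.
#' @export
init_states <- function(data, alpha = 0.05, metagene = "__g0__") {
  stopifnot(inherits(data, "two_group_data"))
  test_group <- function(grp) {
    ctrl <- data[[grp]]$control; non <- data[[grp]]$noncontrol
    if (ncol(ctrl) < 2L || ncol(non) < 2L) {
      stop(sprintf("group %s: need >= 2 control and non-control samples per gene", grp))
    }
    vapply(seq_along(data$genes), function(g) {
      ttest_pvalue(ctrl[g, ], non[g, ])
    }, numeric(1))
  }
  pA <- test_group("A"); pB <- test_group("B")
  S_A <- stats::setNames(c(1L, as.integer(pA < alpha)), c(metagene, data$genes))
  S_B <- stats::setNames(c(1L, as.integer(pB < alpha)), c(metagene, data$genes))
  list(S_A = S_A, S_B = S_B)
}

#' Per-coefficient bounds restraining the equal-regulation prior
#'
#' Feature coefficients of the equal-regulation preference can run away to
#' extreme values when few interaction nodes contradict them, after which the
#' prior overwhelms any per-gene evidence of differential regulation. For
#' adequately powered datasets the recommended remedy is to bound those two
#' coefficients while leaving the remaining five free; this helper builds the
#' corresponding 7 x 2 bound matrix for [fit_config()].
#'
#' @param cap Upper bound for the two equal-regulation coefficients (default
#'   2, of the order of the pooling advantage a few hundred null samples can
#'   produce).
#' @param range Bounds for the other five coefficients (default `c(-10, 10)`).
#' @return A 7 x 2 numeric matrix of lower/upper bounds.
#' @export
restricted_gamma_bounds <- function(cap = 2, range = c(-10, 10)) {
  stopifnot(cap > 0, length(range) == 2L, range[1] < range[2])
  b <- matrix(rep(range, each = 7L), ncol = 2L)
  b[6:7, 1] <- 0
  b[6:7, 2] <- cap
  b
}

# Pooled-variance two-sample t-test p-value with a deterministic fallback for
# degenerate (constant) data: equal means -> 1, different means -> 0.
ttest_pvalue <- function(x, y) {
  tryCatch(stats::t.test(x, y, var.equal = TRUE)$p.value,
           error = function(e) if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
}

# Model context: index structures and sufficient statistics aligned to the
# extended network's gene order (metagene first).
cmrf_context <- function(data, ext) {
  real <- ext$genes[-1L]
  if (!setequal(real, data$genes)) {
    data <- restrict_to_network(data, ext)
    if (!setequal(ext$genes[-1L], data$genes)) stop("data/network gene mismatch")
  }
  ord <- match(real, data$genes)
  reorder <- function(m) m[ord, , drop = FALSE]
  data2 <- two_group_data(reorder(data$A$control), reorder(data$A$noncontrol),
                          reorder(data$B$control), reorder(data$B$noncontrol))
  idx <- net_index(ext)
  st <- suff_stats(data2)
  wdeg <- tabulate(c(idx$emat[, "i"], idx$emat[, "j"]), idx$M)
  list(data = data2, ext = ext, idx = idx, stats = st, wdeg = wdeg)
}

# Per-gene counts of regulation values among in-/out-neighbors: 4 x M matrix.
z_counts <- function(z, nbrs) {
  vapply(nbrs, function(v) tabulate(z[v], 4L), numeric(4))
}

# Log posterior factors (likelihood x conditional prior, normalized over the
# 16 candidates) of a set of nodes under regulation vector `z`.
# Returns the summed log factor at the realized assignment, or with
# `full = TRUE` the nodes x 16 matrix of log factors.
node_log_posterior <- function(ctx, nodes, z, gamma, llz, full = FALSE) {
  emat <- ctx$idx$emat
  ii <- emat[nodes, "i"]; jj <- emat[nodes, "j"]
  ui <- unique(ii); uj <- unique(jj)
  cin <- z_counts(z, ctx$idx$in_nbrs[ui])    # 4 x |ui|
  cout <- z_counts(z, ctx$idx$out_nbrs[uj])  # 4 x |uj|
  CIN <- t(cin)[match(ii, ui), , drop = FALSE][, ROWZ, drop = FALSE]
  COUT <- t(cout)[match(jj, uj), , drop = FALSE][, COLZ, drop = FALSE]
  unary <- gamma[1] * F1_TAB + gamma[2] * F2_TAB + gamma[3] * F3_TAB +
    gamma[6] * F6_TAB + gamma[7] * F7_TAB
  W <- gamma[4] * CIN + gamma[5] * COUT +
    llz[ii, , drop = FALSE][, ROWZ, drop = FALSE] +
    llz[jj, , drop = FALSE][, COLZ, drop = FALSE]
  W <- sweep(W, 2L, unary, "+")
  logF <- W - row_log_sum_exp(W)
  if (full) return(logF)
  cur <- 4L * (z[ii] - 1L) + z[jj]
  sum(logF[cbind(seq_along(nodes), cur)])
}

# Total pseudo-log-likelihood (sum over all nodes of the log posterior factor).
pseudo_loglik <- function(ctx, z, gamma, llz) {
  node_log_posterior(ctx, seq_len(ctx$idx$n_nodes), z, gamma, llz)
}

#' Estimate the likelihood hyperparameters by differential evolution
#'
#' Maximizes the total data log-likelihood of the current interaction
#' assignment, `sum over edges of loglik_X(i, j, X_ij)`, over
#' `(mu0, sigma, tau)` within bounds.
#'
#' @param ctx Internal model context (or a [two_group_data()] together with
#'   `network` for external use).
#' @param z Integer regulation vector over the extended gene set (metagene
#'   first).
#' @param config A [fit_config()].
#' @param seed Seed for the DE run (default derived from `config$seed`).
#' @return A [likelihood_params()].
#' @keywords internal
fit_theta_y <- function(ctx, z, config, seed = NULL) {
  st <- ctx$stats
  b <- config$theta_y_bounds
  lo_mu <- if (!is.null(b$mu0)) b$mu0[1] else st$range[1]
  hi_mu <- if (!is.null(b$mu0)) b$mu0[2] else st$range[2]
  sig_b <- b$sigma %||% (c(1e-3, 10) * st$sd)
  tau_b <- b$tau %||% (c(1e-3, 10) * st$sd)
  if (hi_mu <= lo_mu) { lo_mu <- lo_mu - 1; hi_mu <- hi_mu + 1 }
  real <- 2:ctx$idx$M
  w <- ctx$wdeg[real]
  obj <- function(par) {
    llz <- llz_matrix(st, likelihood_params(par[1], par[2], par[3]))
    sum(w * llz[cbind(real, z[real])])
  }
  s <- config$de
  s$seed <- seed %||% derive_seed(config$seed, "thetaY")
  res <- de_optimize(obj, c(lo_mu, sig_b[1], tau_b[1]),
                     c(hi_mu, sig_b[2], tau_b[2]), settings = s)
  likelihood_params(res$par[1], res$par[2], res$par[3])
}

#' Estimate the feature coefficients by differential evolution
#'
#' Maximizes the summed log conditional prior of the current interaction
#' assignment over the seven feature coefficients within `gamma_bounds`,
#' honoring `gamma_fixed` overrides.
#'
#' @inheritParams fit_theta_y
#' @return Numeric vector `gamma1..gamma7`.
#' @keywords internal
fit_theta_x <- function(ctx, z, config, seed = NULL) {
  emat <- ctx$idx$emat
  ii <- emat[, "i"]; jj <- emat[, "j"]
  cin <- t(z_counts(z, ctx$idx$in_nbrs))   # M x 4
  cout <- t(z_counts(z, ctx$idx$out_nbrs))
  M4 <- cin[ii, , drop = FALSE][, ROWZ, drop = FALSE]
  M5 <- cout[jj, , drop = FALSE][, COLZ, drop = FALSE]
  cur <- 4L * (z[ii] - 1L) + z[jj]
  n <- length(cur)
  pick <- cbind(seq_len(n), cur)
  obj <- function(g) {
    unary <- g[1] * F1_TAB + g[2] * F2_TAB + g[3] * F3_TAB +
      g[6] * F6_TAB + g[7] * F7_TAB
    W <- g[4] * M4 + g[5] * M5
    W <- sweep(W, 2L, unary, "+")
    sum(W[pick]) - sum(row_log_sum_exp(W))
  }
  fixed <- NULL
  if (!is.null(config$gamma_fixed)) {
    fixed <- config$gamma_fixed
    names(fixed) <- sub("^gamma", "", names(fixed))
  }
  s <- config$de
  s$seed <- seed %||% derive_seed(config$seed, "thetaX")
  res <- de_optimize(obj, config$gamma_bounds[, 1], config$gamma_bounds[, 2],
                     settings = s, fixed = fixed)
  stats::setNames(res$par, paste0("gamma", 1:7))
}

#' One ICM sweep over the gene states
#'
#' Visits every real gene in network order and evaluates the four candidate
#' state pairs (DE/DE, DE/EE, EE/DE, EE/EE). Each candidate is scored by the
#' summed log posterior factor of every interaction node whose factor depends
#' on the gene's regulation value (the node's Markov blanket), so each update
#' is exact coordinate ascent on the pseudo-log-likelihood; ties keep the
#' current state. The metagene is never updated.
#'
#' @param z Integer regulation vector over the extended gene set.
#' @param ctx Internal model context.
#' @param gamma Feature coefficients.
#' @param llz Log-likelihood matrix from the current hyperparameters.
#' @return List with updated `z` and `flips` (number of genes changed).
#' @keywords internal
icm_sweep <- function(z, ctx, gamma, llz) {
  flips <- 0L
  for (g in seq.int(2L, ctx$idx$M)) {
    nodes <- ctx$idx$blanket[[g]]
    if (!length(nodes)) next
    cur <- z[g]
    scores <- vapply(1:4, function(cand) {
      zc <- z; zc[g] <- cand
      node_log_posterior(ctx, nodes, zc, gamma, llz)
    }, numeric(1))
    best <- which(scores > scores[cur] + 1e-12)
    if (length(best)) {
      z[g] <- best[which.max(scores[best])]
      flips <- flips + 1L
    }
  }
  list(z = z, flips = flips)
}

#' Fit the comparative MRF model
#'
#' Runs the full alternating optimization: t-test state initialization, then
#' cycles of (i) differential-evolution re-estimation of the likelihood
#' hyperparameters `(mu0, sigma, tau)`, (ii) of the feature coefficients
#' `gamma1..gamma7`, and (iii) an ICM sweep over the gene states. The loop
#' stops when a sweep changes no state (the discrete fixed point) or after
#' `max_cycles` cycles.
#'
#' @param data A [two_group_data()]; genes not in the network are dropped.
#' @param network A [gene_network()] (or an already extended network).
#' @param config A [fit_config()].
#' @param metagene Metagene sentinel used when extending the network.
#' @return An object of class `cmrf_fit`: named state vectors `S_A`, `S_B`,
#'   regulation vector `Z`, interaction assignment `X` (per extended-network
#'   edge), `params` (`theta_y`, `gamma`), per-gene log-likelihood matrix
#'   `llz`, a per-cycle `trace`, and a `converged` flag.
#' @export
cmrf_fit <- function(data, network, config = fit_config(), metagene = "__g0__") {
  stopifnot(inherits(data, "two_group_data"), inherits(network, "gene_network"))
  ext <- if (is_extended(network)) network else extend_with_metagene(network, metagene)
  keep <- data$genes %in% ext$genes[-1L]
  if (!all(keep)) data <- restrict_to_network(data, ext)
  if (!setequal(data$genes, ext$genes[-1L])) {
    # genes in the network but absent from the data are not supported
    missing <- setdiff(ext$genes[-1L], data$genes)
    stop(sprintf("%d network gene(s) have no expression data (e.g. '%s')",
                 length(missing), missing[1]))
  }
  ctx <- cmrf_context(data, ext)
  states <- init_states(ctx$data, config$ttest_alpha, metagene = ext$metagene)
  z <- encode_regulation(states$S_A, states$S_B)
  names(z) <- ext$genes

  trace <- data.frame()
  theta_y <- NULL; gamma <- NULL; llz <- NULL
  prev_par <- NULL
  converged <- FALSE
  for (cycle in seq_len(config$max_cycles)) {
    theta_y <- fit_theta_y(ctx, z, config,
                           seed = derive_seed(config$seed, paste0("thetaY", cycle)))
    llz <- llz_matrix(ctx$stats, theta_y)
    gamma <- fit_theta_x(ctx, z, config,
                         seed = derive_seed(config$seed, paste0("thetaX", cycle)))
    sw <- icm_sweep(z, ctx, gamma, llz)
    z <- sw$z
    par_now <- c(theta_y$mu0, theta_y$sigma, theta_y$tau, gamma)
    dpar <- if (is.null(prev_par)) NA_real_ else {
      max(abs(par_now - prev_par) / (1 + abs(prev_par)))
    }
    prev_par <- par_now
    trace <- rbind(trace, data.frame(
      cycle = cycle, objective = pseudo_loglik(ctx, z, gamma, llz),
      flips = sw$flips, dpar = dpar,
      mu0 = theta_y$mu0, sigma = theta_y$sigma, tau = theta_y$tau))
    if (sw$flips == 0L) { converged <- TRUE; break }
  }

  sA <- as.integer(z %in% c(1L, 2L)); sB <- as.integer(z %in% c(1L, 3L))
  x_assign <- 4L * (z[ctx$idx$emat[, "i"]] - 1L) + z[ctx$idx$emat[, "j"]]
  structure(list(genes = ext$genes[-1L], metagene = ext$metagene,
                 S_A = stats::setNames(sA, ext$genes),
                 S_B = stats::setNames(sB, ext$genes),
                 Z = z,
                 X = unname(x_assign),
                 params = list(theta_y = theta_y, gamma = gamma),
                 llz = llz, trace = trace, converged = converged,
                 config = config, ctx = ctx),
            class = "cmrf_fit")
}

#' @export
print.cmrf_fit <- function(x, ...) {
  zr <- x$Z[-1L]
  cat(sprintf("cmrf_fit: %d genes; DR: %d (A-only %d, B-only %d); cycles: %d; converged: %s\n",
              length(x$genes), sum(zr %in% c(2L, 3L)), sum(zr == 2L), sum(zr == 3L),
              nrow(x$trace), x$converged))
  cat(sprintf("theta_y: mu0 = %.4g, sigma = %.4g, tau = %.4g\n",
              x$params$theta_y$mu0, x$params$theta_y$sigma, x$params$theta_y$tau))
  cat("gamma:", paste(sprintf("%.3g", x$params$gamma), collapse = " "), "\n")
  invisible(x)
}
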