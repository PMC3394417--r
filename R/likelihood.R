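# Hierarchical Gaussian marginal likelihood.
#
# Measurements of one gene in one condition set are modeled as
# z_k ~ N(mu, sigma^2) with a gene-level latent mean mu ~ N(mu0, tau^2)
# shared across the genome.  Integrating mu out gives a multivariate normal
# with covariance sigma^2 I + tau^2 J, evaluated in closed form from the
# per-set sufficient statistics (n, sum, sum of squares).  A DE gene uses
# separate latent means for control and non-control; an EE gene pools them.

#' Likelihood hyperparameters
#'
#' @param mu0 Genome-wide mean of the latent gene means.
#' @param sigma Within-set measurement standard deviation (> 0).
#' @param tau Standard deviation of the latent gene means around `mu0`
#'   (>= 0; 0 collapses the prior to a point mass at `mu0`).
#' @return An object of class `likelihood_params`.
#' @export
likelihood_params <- function(mu0, sigma, tau) {
  stopifnot(is.finite(mu0), is.finite(sigma), is.finite(tau),
            sigma > 0, tau >= 0)
  structure(list(mu0 = mu0, sigma = sigma, tau = tau),
            class = "likelihood_params")
}

# Vectorized closed form from sufficient statistics.
mll_stats <- function(n, s, q, mu0, sigma, tau) {
  s2 <- sigma^2
  S <- q - 2 * mu0 * s + n * mu0^2      # sum (z - mu0)^2
  if (tau == 0) {
    return(-(n / 2) * log(2 * pi * s2) - S / (2 * s2))
  }
  t2 <- tau^2
  m <- s - n * mu0                      # n (zbar - mu0)
  Q <- (S - t2 * m^2 / (s2 + n * t2)) / s2
  -(n / 2) * log(2 * pi) - ((n - 1) / 2) * log(s2) -
    0.5 * log(s2 + n * t2) - Q / 2
}

#' Marginal log-likelihood of one measurement set
#'
#' Evaluates `log integral prod_k N(z_k | mu, sigma^2) N(mu | mu0, tau^2) dmu`
#' by the conjugate-Gaussian closed form, in log space.
#'
#' @param z Numeric measurement vector (length >= 1).
#' @param params A [likelihood_params()].
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(z, params) {
  stopifnot(inherits(params, "likelihood_params"))
  if (!length(z)) stop("empty measurement vector")
  if (any(!is.finite(z))) stop("measurements must be finite")
  mll_stats(length(z), sum(z), sum(z^2), params$mu0, params$sigma, params$tau)
}

#' Log-likelihood of a gene's state in one group
#'
#' DE: control and non-control sets get independent latent means, so the
#' log-likelihood is the sum of their two marginals. EE: the pooled set shares
#' one latent mean. The metagene is DE by convention: its DE log-likelihood is
#' 0 (likelihood one) and its EE log-likelihood is `-Inf` (likelihood zero).
#'
#' @param gene Gene identifier, or the metagene sentinel.
#' @param group `"A"` or `"B"`.
#' @param state `"DE"` or `"EE"`.
#' @param data A [two_group_data()].
#' @param params A [likelihood_params()].
#' @param metagene Metagene sentinel identifier (default `"__g0__"`).
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
loglik_state <- function(gene, group = c("A", "B"), state = c("DE", "EE"),
                         data, params, metagene = "__g0__") {
  group <- match.arg(group); state <- match.arg(state)
  if (identical(gene, metagene)) return(if (state == "DE") 0 else -Inf)
  if (!gene %in% data$genes) stop(sprintf("unknown gene '%s'", gene))
  g <- data[[group]]
  y <- g$control[gene, ]; yp <- g$noncontrol[gene, ]
  if (state == "DE") {
    marginal_loglik(y, params) + marginal_loglik(yp, params)
  } else {
    marginal_loglik(c(y, yp), params)
  }
}

#' Log-likelihood of a gene's regulation value
#'
#' The four regulation values factor into per-group state likelihoods:
#' Z=1 is DE/DE, Z=2 DE/EE, Z=3 EE/DE, Z=4 EE/EE (group A / group B).
#' The metagene has log-likelihood 0 at Z=1 and `-Inf` otherwise.
#'
#' @inheritParams loglik_state
#' @param z Regulation value in 1..4.
#' @return Scalar log-likelihood.
#' @export
loglik_Z <- function(gene, z, data, params, metagene = "__g0__") {
  if (!z %in% 1:4) stop("regulation value must be in 1..4")
  if (identical(gene, metagene)) return(if (z == 1) 0 else -Inf)
  stA <- if (z %in% c(1, 2)) "DE" else "EE"
  stB <- if (z %in% c(1, 3)) "DE" else "EE"
  loglik_state(gene, "A", stA, data, params, metagene) +
    loglik_state(gene, "B", stB, data, params, metagene)
}

#' Log-likelihood of an interaction value
#'
#' Factorizes over the edge's endpoint genes: with (Z_i, Z_j) decoded from
#' `x`, returns `loglik_Z(gene_i, Z_i) + loglik_Z(gene_j, Z_j)`.
#'
#' @inheritParams loglik_state
#' @param gene_i,gene_j Source and target gene of the edge (the source may be
#'   the metagene).
#' @param x Interaction value in 1..16.
#' @return Scalar log-likelihood (`-Inf` for metagene sources with Z_i != 1).
#' @export
loglik_X <- function(gene_i, gene_j, x, data, params, metagene = "__g0__") {
  zz <- decode_interaction(x)
  loglik_Z(gene_i, zz$zi, data, params, metagene) +
    loglik_Z(gene_j, zz$zj, data, params, metagene)
}

# (M+1) x 4 matrix of loglik_Z for the metagene (row 1) and every gene, from
# precomputed sufficient statistics.  Row order matches the extended network.
llz_matrix <- function(stats, params) {
  mu0 <- params$mu0; sg <- params$sigma; tu <- params$tau
  A <- stats$A; B <- stats$B
  deA <- mll_stats(A$ctrl$n, A$ctrl$s, A$ctrl$q, mu0, sg, tu) +
    mll_stats(A$non$n, A$non$s, A$non$q, mu0, sg, tu)
  eeA <- mll_stats(A$ctrl$n + A$non$n, A$ctrl$s + A$non$s,
                   A$ctrl$q + A$non$q, mu0, sg, tu)
  deB <- mll_stats(B$ctrl$n, B$ctrl$s, B$ctrl$q, mu0, sg, tu) +
    mll_stats(B$non$n, B$non$s, B$non$q, mu0, sg, tu)
  eeB <- mll_stats(B$ctrl$n + B$non$n, B$ctrl$s + B$non$s,
                   B$ctrl$q + B$non$q, mu0, sg, tu)
  rbind(c(0, -Inf, -Inf, -Inf),
        cbind(deA + deB, deA + eeB, eeA + deB, eeA + eeB))
}
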