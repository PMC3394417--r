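# Rankings and significance outputs derived from a fitted model.

ranked_list <- function(gene, score, semantics) {
  structure(data.frame(rank = seq_along(gene), gene = gene, score = score,
                       stringsAsFactors = FALSE),
            semantics = semantics, class = c("ranked_gene_list", "data.frame"))
}

ranked_genes <- function(r) {
  if (inherits(r, "ranked_gene_list") || is.data.frame(r)) as.character(r$gene)
  else as.character(r)
}

#' Posterior distribution of one interaction variable
#'
#' Normalized product of the interaction likelihood and the conditional prior
#' over the 16 candidate values, with every other variable held at its fitted
#' assignment. For metagene edges only the four values compatible with the
#' metagene being DE in both groups carry mass.
#'
#' @param fit A [cmrf_fit()] result.
#' @param gene_i,gene_j Source and target of an extended-network edge (the
#'   source may be the metagene sentinel).
#' @return Numeric vector of 16 probabilities summing to one.
#' @export
posterior_interaction <- function(fit, gene_i, gene_j) {
  stopifnot(inherits(fit, "cmrf_fit"))
  idx <- fit$ctx$idx
  gi <- match(gene_i, idx$genes); gj <- match(gene_j, idx$genes)
  if (is.na(gi) || is.na(gj)) stop("unknown gene identifier")
  node <- which(idx$emat[, "i"] == gi & idx$emat[, "j"] == gj)
  if (!length(node)) stop(sprintf("'%s' -> '%s' is not an edge of the extended network",
                                  gene_i, gene_j))
  logF <- node_log_posterior(fit$ctx, node, fit$Z, fit$params$gamma, fit$llz,
                             full = TRUE)
  p <- exp(drop(logF))
  p / sum(p)
}

#' Reverse-hypothesis log-likelihood of a differentially regulated gene
#'
#' For a gene fitted as DE in one group and EE in the other, evaluates the
#' log-likelihood of the opposite assignment (EE where it was DE and vice
#' versa). Lower values mean the reverse hypothesis fits worse, i.e. stronger
#' evidence of differential regulation.
#'
#' @param fit A [cmrf_fit()] result.
#' @param gene A gene with fitted regulation value 2 or 3.
#' @return Scalar log-likelihood.
#' @export
reverse_loglik <- function(fit, gene) {
  stopifnot(inherits(fit, "cmrf_fit"))
  g <- match(gene, fit$ctx$idx$genes)
  if (is.na(g)) stop(sprintf("unknown gene '%s'", gene))
  zg <- fit$Z[g]
  if (!zg %in% c(2L, 3L)) {
    stop(sprintf("gene '%s' is not differentially regulated (Z = %d)", gene, zg))
  }
  fit$llz[g, if (zg == 2L) 3L else 2L]
}

#' Rank candidate primarily differentially regulated genes
#'
#' Restricts to the fitted DR genes (regulation value 2 or 3) and orders them
#' either by increasing reverse-hypothesis log-likelihood (`"reverse_ll"`,
#' the default) or by decreasing likelihood of the gene's metagene interaction
#' (`"metagene_lik"`). Genes at the top are the strongest PDR candidates.
#'
#' @param fit A [cmrf_fit()] result.
#' @param method `"reverse_ll"` or `"metagene_lik"`.
#' @return A `ranked_gene_list` data frame (`rank`, `gene`, `score`) with a
#'   `semantics` attribute; empty when the fit found no DR genes.
#' @export
rank_pdr <- function(fit, method = c("reverse_ll", "metagene_lik")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "cmrf_fit"))
  real <- seq_along(fit$ctx$idx$genes)[-1L]
  dr <- real[fit$Z[real] %in% c(2L, 3L)]
  if (!length(dr)) return(ranked_list(character(0), numeric(0), method))
  if (method == "reverse_ll") {
    score <- fit$llz[cbind(dr, ifelse(fit$Z[dr] == 2L, 3L, 2L))]
    ord <- order(score)          # ascending: worse reverse fit first
  } else {
    score <- fit$llz[cbind(dr, fit$Z[dr])]
    ord <- order(-score)         # descending metagene-edge likelihood
  }
  ranked_list(fit$ctx$idx$genes[dr][ord], score[ord], method)
}

#' Rank genes of one group by two-sample t-test
#'
#' @param control,noncontrol Numeric matrices (genes x samples) sharing
#'   rownames.
#' @return A `ranked_gene_list` ordered by increasing p-value, ties broken by
#'   gene order.
#' @export
ttest_rank <- function(control, noncontrol) {
  control <- as.matrix(control); noncontrol <- as.matrix(noncontrol)
  stopifnot(identical(rownames(control), rownames(noncontrol)))
  p <- vapply(seq_len(nrow(control)), function(g) {
    ttest_pvalue(control[g, ], noncontrol[g, ])
  }, numeric(1))
  ord <- order(p)  # stable: ties keep gene order
  ranked_list(rownames(control)[ord], p[ord], "p-value")
}

#' Merge two single-group rankings into a unified DR ranking
#'
#' Scans both rankings from the top. At position k, the equally regulated set
#' is the intersection of the two top-k prefixes; each list's k-th gene is
#' appended to the unified ranking unless it lies in that intersection (or
#' was already appended), the group-A candidate first.
#'
#' @param r_a,r_b Ranked gene lists (or plain character vectors) for the two
#'   groups.
#' @return Character vector: the unified ranking.
#' @export
unified_rank <- function(r_a, r_b) {
  a <- ranked_genes(r_a); b <- ranked_genes(r_b)
  out <- character(0)
  for (k in seq_len(min(length(a), length(b)))) {
    lam <- intersect(a[seq_len(k)], b[seq_len(k)])
    if (!a[k] %in% lam && !a[k] %in% out) out <- c(out, a[k])
    if (!b[k] %in% lam && !b[k] %in% out) out <- c(out, b[k])
  }
  out
}

#' Sensitivity of a ranking at a cutoff
#'
#' @param ranking Ranked gene list or character vector.
#' @param truth Character vector of true positives (nonempty).
#' @param k Cutoff rank (>= 1).
#' @return Fraction of `truth` found in the top `k`.
#' @export
sensitivity_at_k <- function(ranking, truth, k) {
  stopifnot(k >= 1)
  truth <- unique(as.character(truth))
  if (!length(truth)) stop("empty truth set")
  top <- utils::head(ranked_genes(ranking), k)
  length(intersect(top, truth)) / length(truth)
}

#' Group-label permutation test
#'
#' Reassigns samples between the two groups (control columns shuffled with
#' control columns, non-control with non-control, preserving per-group sample
#' counts), refits the model on each permuted dataset, and records the number
#' of DR genes found. On data without a real group difference the counts are
#' expected to be zero.
#'
#' @param data A [two_group_data()].
#' @param network A [gene_network()].
#' @param config A [fit_config()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed for the permutation draws (defaults to `config$seed`).
#' @return Integer vector of DR-gene counts, one per permutation.
#' @export
permutation_test <- function(data, network, config = fit_config(),
                             n_perm = 40L, seed = NULL) {
  stopifnot(n_perm >= 1L)
  seed <- seed %||% config$seed
  vapply(seq_len(n_perm), function(p) {
    perm_data <- with_seed(derive_seed(seed, paste0("perm", p)), function() {
      shuffle <- function(mA, mB) {
        pool <- cbind(mA, mB)
        ord <- sample.int(ncol(pool))
        list(A = pool[, ord[seq_len(ncol(mA))], drop = FALSE],
             B = pool[, ord[-seq_len(ncol(mA))], drop = FALSE])
      }
      ctrl <- shuffle(data$A$control, data$B$control)
      non <- shuffle(data$A$noncontrol, data$B$noncontrol)
      two_group_data(ctrl$A, non$A, ctrl$B, non$B)
    })
    fitp <- cmrf_fit(perm_data, network, config)
    sum(fitp$Z[-1L] %in% c(2L, 3L))
  }, integer(1))
}
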