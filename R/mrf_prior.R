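# MRF prior over pairwise interaction variables.
#
# Hidden-variable hierarchy: per gene and group a binary state S (1 = DE,
# 0 = EE); the pair (S_A, S_B) encodes a regulation value Z in 1..4; for an
# edge g_i -> g_j the pair (Z_i, Z_j) encodes an interaction value
# X = 4 (Z_i - 1) + Z_j in 1..16.  Seven feature functions over X and its
# MRF neighborhood carry the prior belief: DR-due-to-perturbation frequency
# (F1, F2, F3), neighbor agreement along the network (F4, F5), and a
# preference for equal regulation (F6, F7).

#' Encode a pair of group states as a regulation value
#'
#' @param sA,sB Binary states in groups A and B (1 = DE, 0 = EE). Vectorized.
#' @return Regulation value: 1 (DE,DE), 2 (DE,EE), 3 (EE,DE), 4 (EE,EE).
#'   Values 2 and 3 are the differentially regulated cases.
#' @export
encode_regulation <- function(sA, sB) {
  if (any(!c(sA, sB) %in% c(0, 1))) stop("states must be 0 or 1")
  as.integer(4L - 2L * sA - sB)
}

#' Encode / decode an interaction value
#'
#' `encode_interaction()` maps a pair of regulation values to
#' X = 4 (Z_i - 1) + Z_j; `decode_interaction()` is its exact inverse.
#'
#' @param zi,zj Regulation values in 1..4 (vectorized).
#' @return `encode_interaction()`: integer in 1..16. `decode_interaction()`:
#'   a list with components `zi` and `zj`.
#' @export
encode_interaction <- function(zi, zj) {
  if (any(!c(zi, zj) %in% 1:4)) stop("regulation values must be in 1..4")
  as.integer(4L * (zi - 1L) + zj)
}

#' @rdname encode_interaction
#' @param x Interaction value(s) in 1..16.
#' @export
decode_interaction <- function(x) {
  if (any(!x %in% 1:16)) stop("interaction values must be in 1..16")
  list(zi = as.integer((x - 1L) %/% 4L + 1L), zj = as.integer((x - 1L) %% 4L + 1L))
}

# Fixed unary feature columns over the 16 interaction values.
ROWZ <- (0:15) %/% 4L + 1L  # Z_i component of X = 1..16
COLZ <- (0:15) %% 4L + 1L   # Z_j component
F1_TAB <- as.numeric(1:16 == 2L)
F2_TAB <- as.numeric(1:16 == 3L)
F3_TAB <- as.numeric(!(1:16 %in% c(2L, 3L)))
F6_TAB <- as.numeric(ROWZ %in% c(1L, 4L))  # g_i equally regulated
F7_TAB <- as.numeric(COLZ %in% c(1L, 4L))  # g_j equally regulated

#' Evaluate the seven MRF feature functions
#'
#' @param x Interaction value of the node, in 1..16.
#' @param left Interaction values of left (incoming-side) MRF neighbors
#'   `X_pj`; each shares the target component with `x`. May be empty.
#' @param right Interaction values of right (outgoing-side) MRF neighbors
#'   `X_ik`; each shares the source component with `x`. May be empty.
#' @param check Validate that neighbor values share the required component
#'   with `x` (the remaining table cells are unreachable by construction).
#' @return Named numeric vector `F1..F7`. `F4`/`F5` are neighbor counts and
#'   may exceed one.
#' @export
eval_features <- function(x, left = integer(), right = integer(), check = TRUE) {
  stopifnot(length(x) == 1L, x %in% 1:16)
  if (any(!c(left, right) %in% 1:16)) stop("neighbor values must be in 1..16")
  if (check) {
    if (length(left) && any(COLZ[left] != COLZ[x])) {
      stop("left neighbor with a different target regulation value is unreachable")
    }
    if (length(right) && any(ROWZ[right] != ROWZ[x])) {
      stop("right neighbor with a different source regulation value is unreachable")
    }
  }
  c(F1 = F1_TAB[x], F2 = F2_TAB[x], F3 = F3_TAB[x],
    F4 = sum(ROWZ[left] == ROWZ[x]),
    F5 = sum(COLZ[right] == COLZ[x]),
    F6 = F6_TAB[x], F7 = F7_TAB[x])
}

# gamma-weighted feature sums for all 16 candidate values of one node.
# cin4: counts of regulation values among In(g_i); cout4: among Out(g_j).
feature_weights16 <- function(gamma, cin4 = numeric(4), cout4 = numeric(4)) {
  gamma[1] * F1_TAB + gamma[2] * F2_TAB + gamma[3] * F3_TAB +
    gamma[4] * cin4[ROWZ] + gamma[5] * cout4[COLZ] +
    gamma[6] * F6_TAB + gamma[7] * F7_TAB
}

#' Conditional prior density of one interaction variable
#'
#' Computes `p(X_ij = t | neighbors, gamma)` for t = 1..16 under the
#' pseudo-likelihood factorization: feature sums are re-evaluated for every
#' candidate value with the neighbor assignment held fixed, exponentiated in
#' log space with max subtraction, and normalized over the 16 candidates.
#'
#' @param gamma Numeric vector of the seven feature coefficients.
#' @param left,right Interaction values of left/right MRF neighbors (real or
#'   virtual ones derived from the current regulation vector). May be empty.
#' @return Numeric vector of 16 probabilities summing to one.
#' @export
conditional_prior <- function(gamma, left = integer(), right = integer()) {
  stopifnot(length(gamma) == 7L, all(is.finite(gamma)))
  if (any(!c(left, right) %in% 1:16)) stop("neighbor values must be in 1..16")
  cin4 <- tabulate(ROWZ[left], 4L)
  cout4 <- tabulate(COLZ[right], 4L)
  w <- feature_weights16(gamma, cin4, cout4)
  w <- w - max(w)
  p <- exp(w)
  p / sum(p)
}

#' Build the interaction-variable graph of an extended network
#'
#' One MRF node per directed edge of the extended network (including every
#' metagene edge). Two nodes are MRF neighbors when they share the source or
#' the target component and the genes in the remaining component interact.
#' Neighbor slots whose interaction variable does not correspond to a network
#' edge are *virtual*: they are kept for completeness and their values are
#' derived from the current regulation vector when features are evaluated.
#'
#' @param ext An extended network from [extend_with_metagene()].
#' @return An object of class `interaction_graph`: `nodes` (data frame with
#'   gene identifiers `i`, `j`), `left_nbrs` / `right_nbrs` (per node, a data
#'   frame of neighbor gene pairs with the matching node index, `NA` for
#'   virtual neighbors), and the originating network.
#' @export
build_interaction_graph <- function(ext) {
  idx <- net_index(ext)
  genes <- idx$genes
  key <- paste(idx$emat[, "i"], idx$emat[, "j"])
  node_of <- stats::setNames(seq_len(idx$n_nodes), key)
  left_nbrs <- vector("list", idx$n_nodes)
  right_nbrs <- vector("list", idx$n_nodes)
  nbr_frame <- function(src, tgt) {
    if (!length(src) || !length(tgt)) {
      return(data.frame(i = character(0), j = character(0),
                        node = integer(0), stringsAsFactors = FALSE))
    }
    data.frame(i = genes[src], j = genes[tgt],
               node = unname(node_of[paste(src, tgt)]),
               stringsAsFactors = FALSE)
  }
  for (n in seq_len(idx$n_nodes)) {
    i <- idx$emat[n, "i"]; j <- idx$emat[n, "j"]
    p <- idx$in_nbrs[[i]]   # left: X_pj for p in In(g_i)
    k <- idx$out_nbrs[[j]]  # right: X_ik for k in Out(g_j)
    left_nbrs[[n]] <- nbr_frame(p, rep(j, length(p)))
    right_nbrs[[n]] <- nbr_frame(rep(i, length(k)), k)
  }
  structure(list(nodes = data.frame(i = genes[idx$emat[, "i"]],
                                    j = genes[idx$emat[, "j"]],
                                    stringsAsFactors = FALSE),
                 left_nbrs = left_nbrs, right_nbrs = right_nbrs,
                 network = ext),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d nodes over %d genes (incl. metagene)\n",
              nrow(x$nodes), length(x$network$genes)))
  invisible(x)
}

#' Dump an interaction graph as a table
#'
#' @param graph An [build_interaction_graph()] result.
#' @param z Optional named regulation vector (over the extended gene set) used
#'   to fill in current node assignments.
#' @param path Optional path; when given the table is written as TSV.
#' @return Invisibly, a data frame with node, assignment and neighbor columns.
#' @export
dump_interaction_graph <- function(graph, z = NULL, path = NULL) {
  nodes <- graph$nodes
  assign <- if (is.null(z)) NA_integer_ else {
    encode_interaction(z[nodes$i], z[nodes$j])
  }
  nbrs <- vapply(seq_len(nrow(nodes)), function(n) {
    lr <- rbind(graph$left_nbrs[[n]], graph$right_nbrs[[n]])
    paste(sprintf("%s->%s", lr$i, lr$j), collapse = ",")
  }, character(1))
  out <- data.frame(i = nodes$i, j = nodes$j, assignment = assign,
                    neighbors = nbrs, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
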