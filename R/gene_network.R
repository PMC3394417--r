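# Directed gene interaction networks and the metagene-extended network.
#
# A gene network is a directed graph over gene identifiers.  Edges carry an
# optional activation/inhibition sign; the sign is kept for the sigmoid
# perturbation simulator but is ignored by the MRF prior, whose feature
# functions depend on adjacency only.

#' Construct a directed gene interaction network
#'
#' @param from,to Character vectors of source and target gene identifiers.
#' @param sign Optional numeric vector of edge signs (+1 activation,
#'   -1 inhibition). Recycled to the number of edges; defaults to +1.
#' @param genes Optional character vector of gene identifiers. Genes appearing
#'   in edges but missing here are added. Isolated genes may be listed.
#' @param order Gene ordering: `"lexicographic"` (default, reproducible across
#'   input orders) or `"first-seen"`.
#'
#' @details Self-loops are dropped with a warning and duplicated edges are
#'   collapsed (keeping the first occurrence's sign).
#'
#' @return An object of class `gene_network` with elements `genes` (ordered
#'   identifiers) and `edges` (data frame with columns `from`, `to`, `sign`).
#' @export
gene_network <- function(from = character(), to = character(), sign = NULL,
                         genes = NULL, order = c("lexicographic", "first-seen")) {
  order <- match.arg(order)
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) stop("`from` and `to` must have equal length")
  if (is.null(sign)) sign <- rep(1, length(from))
  sign <- rep_len(as.numeric(sign), length(from))
  if (any(!sign %in% c(-1, 1)) && length(sign)) {
    stop("edge signs must be +1 or -1")
  }

  loop <- from == to
  if (any(loop)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loop)))
    from <- from[!loop]; to <- to[!loop]; sign <- sign[!loop]
  }
  key <- paste(from, to, sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(from = from[keep], to = to[keep], sign = sign[keep],
                      stringsAsFactors = FALSE)

  all_genes <- c(as.character(genes %||% character()), edges$from, edges$to)
  all_genes <- all_genes[!duplicated(all_genes)]
  if (order == "lexicographic") all_genes <- sort(all_genes, method = "radix")
  structure(list(genes = all_genes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("%s: %d genes, %d edges\n",
              if (is_extended(x)) "extended_gene_network" else "gene_network",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

is_extended <- function(net) inherits(net, "extended_gene_network")

#' Read a network edge list from a text file
#'
#' Accepts whitespace/tab-separated `source target [sign]` lines (sign in
#' `+`, `-`, `1`, `-1`) or, with `dialect = "sif"`, three-column
#' `source relation target` lines where the relation decides the sign.
#' Lines starting with `#` and blank lines are skipped.
#'
#' @param path Path to the edge-list file.
#' @param dialect `"edge"` (default) or `"sif"`.
#' @param order Gene ordering passed to [gene_network()].
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path, dialect = c("edge", "sif"),
                           order = c("lexicographic", "first-seen")) {
  dialect <- match.arg(dialect)
  order <- match.arg(order)
  if (!file.exists(path)) stop(sprintf("cannot read edge list: '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  raw_no <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; raw_no <- raw_no[keep]
  toks <- strsplit(trimws(lines), "[ \t]+")

  parse_sign <- function(s) switch(s, "+" = 1, "1" = 1, "-" = -1, "-1" = -1, NA_real_)
  fr <- character(0); to <- character(0); sg <- numeric(0)
  for (k in seq_along(toks)) {
    tk <- toks[[k]]
    need <- if (dialect == "sif") 3L else 2L
    if (length(tk) < need) {
      stop(sprintf("malformed line %d in '%s': expected at least %d columns, got %d",
                   raw_no[k], path, need, length(tk)))
    }
    if (dialect == "sif") {
      fr[k] <- tk[1]; to[k] <- tk[3]
      sg[k] <- if (grepl("^(inhibit|repress|-)", tk[2], ignore.case = TRUE)) -1 else 1
    } else {
      fr[k] <- tk[1]; to[k] <- tk[2]
      s <- if (length(tk) >= 3) parse_sign(tk[3]) else 1
      if (is.na(s)) {
        stop(sprintf("malformed line %d in '%s': sign '%s' not in {+,-,1,-1}",
                     raw_no[k], path, tk[3]))
      }
      sg[k] <- s
    }
  }
  gene_network(fr, to, sg, order = order)
}

#' Write a network as a plain edge list
#'
#' @param net A [gene_network()].
#' @param path Output path. Columns: source, target, sign.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extend a network with the perturbation metagene
#'
#' Adds a hypothetical gene representing the external perturbation, with a
#' directed edge to every gene in the network, reflecting that the
#' perturbation can directly affect any gene. The metagene is placed first in
#' the gene ordering and is never a target.
#'
#' @param net A [gene_network()].
#' @param metagene Identifier reserved for the metagene (default `"__g0__"`).
#' @return An object of class `extended_gene_network` (also a
#'   `gene_network`) with element `metagene`.
#' @export
extend_with_metagene <- function(net, metagene = "__g0__") {
  stopifnot(inherits(net, "gene_network"))
  if (is_extended(net)) stop("network is already extended with a metagene")
  if (metagene %in% net$genes) {
    stop(sprintf("gene '%s' clashes with the metagene sentinel; pass a different `metagene`",
                 metagene))
  }
  meta_edges <- data.frame(from = rep(metagene, length(net$genes)),
                           to = net$genes, sign = rep(1, length(net$genes)),
                           stringsAsFactors = FALSE)
  structure(list(genes = c(metagene, net$genes),
                 edges = rbind(meta_edges, net$edges),
                 metagene = metagene,
                 base = net),
            class = c("extended_gene_network", "gene_network"))
}

#' Incoming or outgoing neighbors of a gene
#'
#' @param net A [gene_network()] or extended network.
#' @param gene A gene identifier present in the network.
#' @param direction `"incoming"` (sources of edges into `gene`) or
#'   `"outgoing"` (targets of edges out of `gene`).
#' @return Character vector of neighbor identifiers.
#' @export
neighbors_of <- function(net, gene, direction = c("incoming", "outgoing")) {
  direction <- match.arg(direction)
  stopifnot(inherits(net, "gene_network"))
  if (!gene %in% net$genes) stop(sprintf("unknown gene '%s'", gene))
  if (direction == "incoming") unique(net$edges$from[net$edges$to == gene])
  else unique(net$edges$to[net$edges$from == gene])
}

# Integer-index view of an extended network used by the model internals.
# Index 1 is the metagene; real genes follow in network order.
net_index <- function(ext) {
  stopifnot(is_extended(ext))
  genes <- ext$genes
  M <- length(genes)
  gi <- match(ext$edges$from, genes)
  gj <- match(ext$edges$to, genes)
  emat <- cbind(i = gi, j = gj)
  in_nbrs <- vector("list", M)
  out_nbrs <- vector("list", M)
  for (g in seq_len(M)) {
    in_nbrs[[g]] <- emat[emat[, "j"] == g, "i"]
    out_nbrs[[g]] <- emat[emat[, "i"] == g, "j"]
  }
  # node -> incident node rows per gene, plus the full Markov blanket of a
  # gene's state: nodes whose posterior factor depends on that gene's Z
  # (source in {g} U Out(g) or target in {g} U In(g)).
  blanket <- vector("list", M)
  for (g in seq_len(M)) {
    src_set <- c(g, out_nbrs[[g]])
    tgt_set <- c(g, in_nbrs[[g]])
    blanket[[g]] <- which(emat[, "i"] %in% src_set | emat[, "j"] %in% tgt_set)
  }
  list(genes = genes, M = M, emat = emat, n_nodes = nrow(emat),
       in_nbrs = in_nbrs, out_nbrs = out_nbrs, blanket = blanket)
}
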