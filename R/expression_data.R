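# Two-group control / non-control expression containers and IO.

#' Assemble two-group expression data
#'
#' @param A_control,A_noncontrol,B_control,B_noncontrol Numeric matrices,
#'   genes in rows (rownames are gene identifiers), samples in columns.
#'   Control and non-control of a group may have different sample counts;
#'   all four must share the same gene set.
#' @return An object of class `two_group_data` with elements `genes`,
#'   `A` and `B` (each a list with `control` and `noncontrol` matrices).
#' @export
two_group_data <- function(A_control, A_noncontrol, B_control, B_noncontrol) {
  mats <- list(A_control = A_control, A_noncontrol = A_noncontrol,
               B_control = B_control, B_noncontrol = B_noncontrol)
  mats <- lapply(mats, as.matrix)
  genes <- rownames(mats[[1]])
  if (is.null(genes)) stop("expression matrices must have gene rownames")
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (is.null(rownames(m)) || !identical(rownames(m), genes)) {
      stop(sprintf("%s: gene rownames differ from A_control", nm))
    }
    if (!is.numeric(m)) stop(sprintf("%s: matrix is not numeric", nm))
    if (any(!is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
      stop(sprintf("%s: non-finite value at gene '%s', sample column %d",
                   nm, genes[bad[1]], bad[2]))
    }
  }
  structure(list(genes = genes,
                 A = list(control = mats$A_control, noncontrol = mats$A_noncontrol),
                 B = list(control = mats$B_control, noncontrol = mats$B_noncontrol)),
            class = "two_group_data")
}

#' @export
print.two_group_data <- function(x, ...) {
  cat(sprintf("two_group_data: %d genes; A: %d/%d samples, B: %d/%d samples (control/non-control)\n",
              length(x$genes), ncol(x$A$control), ncol(x$A$noncontrol),
              ncol(x$B$control), ncol(x$B$noncontrol)))
  invisible(x)
}

read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("'%s': need a gene column plus sample columns", path))
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("'%s': non-numeric cell at row %d (gene '%s'), sample column '%s'",
                   path, bad[1, 1], genes[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    m <- num
  }
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("'%s': missing value at row %d (gene '%s'), sample column '%s'",
                 path, bad[1], genes[bad[1]], colnames(m)[bad[2]]))
  }
  rownames(m) <- genes
  m
}

#' Read two-group expression data from four TSV matrices
#'
#' Each file holds one matrix: first column gene identifiers, header row of
#' sample identifiers, tab-separated numeric values. Genes are intersected
#' across the four files (order taken from the group-A control file); genes
#' missing from any file are dropped with a message.
#'
#' @param pathA_ctrl,pathA_non,pathB_ctrl,pathB_non File paths.
#' @return A [two_group_data()].
#' @export
read_expression <- function(pathA_ctrl, pathA_non, pathB_ctrl, pathB_non) {
  mats <- lapply(list(pathA_ctrl, pathA_non, pathB_ctrl, pathB_non),
                 read_expression_matrix)
  common <- Reduce(intersect, lapply(mats, rownames))
  if (!length(common)) stop("no genes shared across the four expression files")
  n_drop <- length(unique(unlist(lapply(mats, rownames)))) - length(common)
  if (n_drop > 0) message(sprintf("dropped %d gene(s) absent from at least one file", n_drop))
  common <- rownames(mats[[1]])[rownames(mats[[1]]) %in% common]
  mats <- lapply(mats, function(m) m[common, , drop = FALSE])
  two_group_data(mats[[1]], mats[[2]], mats[[3]], mats[[4]])
}

#' Collapse a multi-timepoint series to control / non-control
#'
#' For each gene, the non-control row is taken from the post-perturbation
#' timepoint whose mean expression deviates most (in absolute value) from the
#' gene's control mean. Ties are broken toward the earliest timepoint.
#'
#' @param control Numeric matrix (genes x samples) measured before the
#'   perturbation.
#' @param post_timepoints List of numeric matrices measured after the
#'   perturbation; all must share `control`'s rownames and have equal sample
#'   counts.
#' @return List with `control`, `noncontrol`, and `chosen` (per-gene index of
#'   the selected timepoint).
#' @export
collapse_time_series <- function(control, post_timepoints) {
  control <- as.matrix(control)
  if (!length(post_timepoints)) stop("need at least one post-perturbation timepoint")
  post_timepoints <- lapply(post_timepoints, as.matrix)
  genes <- rownames(control)
  ncols <- vapply(post_timepoints, ncol, 0L)
  if (length(unique(ncols)) != 1L) {
    stop("all post-perturbation timepoints must have the same number of samples")
  }
  for (tp in post_timepoints) {
    if (!identical(rownames(tp), genes)) stop("timepoint rownames differ from control")
  }
  ctrl_mean <- rowMeans(control)
  dev <- vapply(post_timepoints, function(tp) abs(rowMeans(tp) - ctrl_mean),
                numeric(nrow(control)))
  dev <- matrix(dev, nrow = nrow(control))
  chosen <- apply(dev, 1L, which.max)  # which.max takes the earliest on ties
  noncontrol <- matrix(NA_real_, nrow(control), ncols[1],
                       dimnames = list(genes, colnames(post_timepoints[[1]])))
  for (t in unique(chosen)) {
    rows <- chosen == t
    noncontrol[rows, ] <- post_timepoints[[t]][rows, , drop = FALSE]
  }
  list(control = control, noncontrol = noncontrol, chosen = chosen)
}

#' Restrict expression data to genes present in a network
#'
#' @param data A [two_group_data()].
#' @param net A [gene_network()].
#' @return A [two_group_data()] over the intersection, preserving `data`'s
#'   gene order.
#' @export
restrict_to_network <- function(data, net) {
  stopifnot(inherits(data, "two_group_data"), inherits(net, "gene_network"))
  keep <- data$genes %in% setdiff(net$genes, if (is_extended(net)) net$metagene)
  if (!any(keep)) stop("no expression genes found in the network")
  two_group_data(data$A$control[keep, , drop = FALSE],
                 data$A$noncontrol[keep, , drop = FALSE],
                 data$B$control[keep, , drop = FALSE],
                 data$B$noncontrol[keep, , drop = FALSE])
}

# Per-gene sufficient statistics (n, sum, sum of squares) for the four
# matrices; everything the marginal likelihood needs.
suff_stats <- function(data) {
  st <- function(m) list(n = ncol(m), s = rowSums(m), q = rowSums(m^2))
  list(A = list(ctrl = st(data$A$control), non = st(data$A$noncontrol)),
       B = list(ctrl = st(data$B$control), non = st(data$B$noncontrol)),
       range = range(unlist(lapply(list(data$A$control, data$A$noncontrol,
                                        data$B$control, data$B$noncontrol), range))),
       sd = stats::sd(c(data$A$control, data$A$noncontrol,
                        data$B$control, data$B$noncontrol)))
}
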