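# Configuration-driven pipeline: the programmatic counterpart of the
# command-line entry point (inst/scripts/cmrf). Subcommands cover model
# fitting + ranking, benchmark simulation, the significance experiment, and
# the permutation null.

run_config_defaults <- function() {
  list(subcommand = NULL,
       network = NULL, network_dialect = "edge",
       expression = NULL,   # list/paths: A_control, A_noncontrol, B_control, B_noncontrol
       out_dir = ".",
       seed = 0L,
       verbose = FALSE,
       fit = list(),        # fit_config() overrides
       generator = list(),  # simulate/significance settings
       n_perm = 40L,
       rank_method = "reverse_ll")
}

#' Load a pipeline run configuration
#'
#' YAML file with a `subcommand` (`fit`, `rank`, `simulate`, `significance`
#' or `permute`) plus the paths and parameter blocks that subcommand needs.
#' Unknown keys are rejected; omitted keys get defaults (seed 0, t-test
#' level 0.05, 20 outer cycles).
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  defs <- run_config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defs
  cfg[names(raw)] <- raw
  if (is.null(cfg$subcommand) ||
      !cfg$subcommand %in% c("fit", "rank", "simulate", "significance", "permute")) {
    stop("config must set `subcommand` to one of fit, rank, simulate, significance, permute")
  }
  if (is.null(raw$seed)) message("seed omitted; using seed = 0")
  cfg$seed <- as.integer(cfg$seed)
  stopifnot(cfg$seed >= 0L)
  if (cfg$subcommand %in% c("fit", "rank", "permute")) {
    if (is.null(cfg$network)) stop("missing required key: network")
    if (is.null(cfg$expression) || length(cfg$expression) != 4L) {
      stop("missing required key: expression (four matrix paths)")
    }
  }
  structure(cfg, class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Execute a pipeline run
#'
#' Runs the configured subcommand and writes its artifacts (TSV tables plus a
#' YAML manifest sufficient to replay the run) into `out_dir`.
#'
#' @param config A `run_config` from [load_run_config()] (or an equivalent
#'   list).
#' @return Invisibly, a character vector of written file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(cfg$out_dir, name)
  fitcfg <- do.call(fit_config, c(cfg$fit, list(seed = cfg$seed)))
  written <- character(0)
  log_msg <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))

  load_inputs <- function() {
    net <- read_edge_list(cfg$network, dialect = cfg$network_dialect)
    ex <- cfg$expression
    data <- read_expression(ex[[1]], ex[[2]], ex[[3]], ex[[4]])
    list(net = net, data = restrict_to_network(data, net))
  }

  if (cfg$subcommand %in% c("fit", "rank")) {
    inp <- load_inputs()
    fit <- cmrf_fit(inp$data, inp$net, fitcfg)
    log_msg("fit finished after %d cycle(s); %d DR gene(s)",
            nrow(fit$trace), sum(fit$Z[-1L] %in% 2:3))
    states <- data.frame(gene = fit$genes,
                         S_A = unname(fit$S_A[-1L]), S_B = unname(fit$S_B[-1L]),
                         Z = unname(fit$Z[-1L]))
    written <- c(written, write_tsv(states, out("states.tsv")),
                 write_tsv(fit$trace, out("trace.tsv")))
    params <- data.frame(
      name = c("mu0", "sigma", "tau", paste0("gamma", 1:7)),
      value = c(fit$params$theta_y$mu0, fit$params$theta_y$sigma,
                fit$params$theta_y$tau, unname(fit$params$gamma)))
    written <- c(written, write_tsv(params, out("params.tsv")))
    rk <- rank_pdr(fit, method = cfg$rank_method)
    rk_df <- as.data.frame(rk)
    rk_df$semantics <- rep(attr(rk, "semantics"), nrow(rk_df))
    written <- c(written, write_tsv(rk_df, out("ranking.tsv")))
  } else if (cfg$subcommand == "simulate") {
    g <- cfg$generator
    net <- random_scalefree_network(g$M %||% 300L, seed = derive_seed(cfg$seed, "net"))
    sizes <- g$set_sizes %||% rep(list(list(n_primary = 5L)), 3L)
    truth <- build_two_group_truth(net, sizes, q = g$q %||% 0.4,
                                   seed = derive_seed(cfg$seed, "truth"))
    N <- g$N %||% 155L
    ctrlA <- generate_control(length(net$genes), N, seed = derive_seed(cfg$seed, "cA"),
                              genes = net$genes)
    ctrlB <- generate_control(length(net$genes), N, seed = derive_seed(cfg$seed, "cB"),
                              genes = net$genes)
    data <- generate_two_group(ctrlA$mat, ctrlB$mat, truth,
                               g$d_p %||% 2, g$d_s %||% 1,
                               seed = derive_seed(cfg$seed, "gen"))
    written <- c(written, write_edge_list(net, out("network.tsv")))
    dump_mat <- function(m, name) {
      df <- data.frame(gene = rownames(m), m, check.names = FALSE)
      write_tsv(df, out(name))
    }
    written <- c(written,
                 dump_mat(data$A$control, "A_control.tsv"),
                 dump_mat(data$A$noncontrol, "A_noncontrol.tsv"),
                 dump_mat(data$B$control, "B_control.tsv"),
                 dump_mat(data$B$noncontrol, "B_noncontrol.tsv"))
    lab <- truth$labels
    lab$class <- ifelse(lab$gene %in% truth$pdr, "PDR",
                        ifelse(lab$gene %in% truth$sdr, "SDR",
                               ifelse(lab$gene %in% truth$er_affected, "ER-affected",
                                      "unaffected")))
    written <- c(written, write_tsv(lab, out("truth.tsv")))
  } else if (cfg$subcommand == "significance") {
    g <- cfg$generator
    grid <- dp_grid()
    dps <- g$d_p_values %||% grid$d_p
    res <- significance_experiment(dps, M = g$M %||% 100L, N = g$N %||% 33L,
                                   set_sizes = g$set_sizes %||% NULL,
                                   config = fitcfg, seed = cfg$seed)
    written <- c(written, write_tsv(res, out("significance.tsv")))
  } else if (cfg$subcommand == "permute") {
    inp <- load_inputs()
    counts <- permutation_test(inp$data, inp$net, fitcfg,
                               n_perm = cfg$n_perm, seed = cfg$seed)
    written <- c(written,
                 write_tsv(data.frame(perm = seq_along(counts), dr_count = counts),
                           out("permutation_counts.tsv")))
  }

  manifest <- unclass(cfg)
  manifest$package_version <- as.character(utils::packageVersion("cmrf"))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  written <- c(written, out("manifest.yaml"))
  log_msg("wrote %d artifact(s) to %s", length(written), cfg$out_dir)
  invisible(written)
}
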