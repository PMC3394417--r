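# Differential evolution (rand/1/bin) for the continuous model parameters.
# Both the likelihood hyperparameters and the feature coefficients have
# non-convex objectives, so a population-based global optimizer is used.

#' Maximize an objective by differential evolution
#'
#' Classic rand/1/bin scheme: for each population member a mutant is formed
#' from three distinct others as `x_r1 + f * (x_r2 - x_r3)`, crossed over
#' coordinate-wise with rate `cr` (one coordinate always taken from the
#' mutant), clipped to the bounds, and kept if it does not decrease the
#' objective. Fully deterministic given `seed`.
#'
#' @param objective Function mapping a parameter vector to a scalar to be
#'   maximized; may return `-Inf` for invalid regions.
#' @param lower,upper Numeric bound vectors (finite, `lower < upper`).
#' @param settings List overriding defaults `np = 40`, `generations = 100`,
#'   `cr = 0.9`, `f = 0.8`, `seed = 0`.
#' @param fixed Optional named numeric vector pinning coordinates (by integer
#'   index into the parameter vector) at given values; those coordinates are
#'   excluded from optimization.
#' @return List with `par` (best parameter vector, overrides applied),
#'   `value` (objective at `par`), and `evals`.
#' @export
de_optimize <- function(objective, lower, upper, settings = list(), fixed = NULL) {
  stopifnot(length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)), all(lower < upper))
  np <- settings$np %||% 40L
  gens <- settings$generations %||% 100L
  cr <- settings$cr %||% 0.9
  f <- settings$f %||% 0.8
  seed <- settings$seed %||% 0L

  d_all <- length(lower)
  fix_idx <- integer(0)
  fix_val <- numeric(0)
  if (!is.null(fixed) && length(fixed)) {
    fix_idx <- as.integer(names(fixed))
    if (any(is.na(fix_idx))) stop("`fixed` must be named by coordinate index")
    fix_val <- as.numeric(fixed)
  }
  free <- setdiff(seq_len(d_all), fix_idx)
  expand <- function(xf) {
    x <- numeric(d_all)
    x[free] <- xf
    x[fix_idx] <- fix_val
    x
  }
  obj_free <- function(xf) objective(expand(xf))
  d <- length(free)
  if (d == 0L) {
    v <- objective(expand(numeric(0)))
    return(list(par = expand(numeric(0)), value = v, evals = 1L))
  }
  lo <- lower[free]; up <- upper[free]

  with_seed(seed, function() {
    pop <- matrix(stats::runif(np * d, rep(lo, each = np), rep(up, each = np)),
                  nrow = np)
    fit <- apply(pop, 1L, obj_free)
    evals <- np
    if (all(!is.finite(fit))) {
      stop("objective is -Inf over the whole initial population")
    }
    for (g in seq_len(gens)) {
      for (m in seq_len(np)) {
        r <- sample(setdiff(seq_len(np), m), 3L)
        mutant <- pop[r[1], ] + f * (pop[r[2], ] - pop[r[3], ])
        jr <- sample.int(d, 1L)
        cross <- stats::runif(d) < cr
        cross[jr] <- TRUE
        trial <- ifelse(cross, mutant, pop[m, ])
        trial <- pmin(pmax(trial, lo), up)
        v <- obj_free(trial)
        evals <- evals + 1L
        if (is.finite(v) && (v >= fit[m] || !is.finite(fit[m]))) {
          pop[m, ] <- trial
          fit[m] <- v
        }
      }
    }
    best <- which.max(fit)
    list(par = expand(pop[best, ]), value = fit[best], evals = evals)
  })
}
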