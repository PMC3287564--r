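# Monte-Carlo estimation of size and power. One "cell" is a fully
# specified simulation setting (two Poisson means, replicate counts per
# condition, nominal level, run count, seed). Within a run every method
# sees the same Poisson draw (common random numbers), which sharpens
# between-method power comparisons.

#' Define one Monte-Carlo simulation setting
#'
#' A cell of the size/power study: lane counts are drawn as
#' `X_1j ~ Poisson(lambda1)` (j = 1..n1) and `X_2j ~ Poisson(lambda2)`
#' (j = 1..n2), each requested test is applied to the draw, and the
#' rejection rate at level `alpha` is estimated over `runs` repetitions.
#' Defaults follow the package's benchmark protocol: nominal level 1e-3
#' (a stringent cutoff reflecting many-gene screens) and 10,000 runs.
#'
#' @param lambda1,lambda2 Positive per-lane Poisson means of the two
#'   conditions (equal means estimate size, unequal means power).
#' @param n1,n2 Lanes (technical replicates) per condition.
#' @param alpha Nominal significance level in (0, 1); default `1e-3`.
#' @param runs Number of Monte-Carlo repetitions; default 10000.
#' @param seed Integer seed making the cell reproducible.
#' @param methods Subset of [pois_methods()] to evaluate.
#' @param fisher_lane_total Per-lane total used to build the Fisher 2x2
#'   table (the simulation generates gene counts only); the default 1e6
#'   mimics sequencing-scale lane totals, under which the Fisher test
#'   coincides with the conditional binomial test.
#' @return An object of class `"sim_design"`.
#' @seealso [simulate_cell], [run_grid]
#' @export
#' @examples
#' sim_design(5, 25, seed = 1)
sim_design <- function(lambda1, lambda2, n1 = 1L, n2 = 1L, alpha = 1e-3,
                       runs = 10000L, seed = 1L, methods = pois_methods(),
                       fisher_lane_total = 1e6) {
  stopifnot(lambda1 > 0, lambda2 > 0, n1 >= 1, n2 >= 1,
            alpha > 0, alpha < 1, runs >= 1, fisher_lane_total >= 1)
  methods <- match.arg(methods, pois_methods(), several.ok = TRUE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 alpha = alpha, runs = as.integer(runs),
                 seed = as.integer(seed),
                 methods = pois_methods()[pois_methods() %in% methods],
                 fisher_lane_total = fisher_lane_total),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "Poisson two-sample simulation cell: lambda = (%g, %g), lanes = (%d, %d)\n",
    x$lambda1, x$lambda2, x$n1, x$n2))
  cat(sprintf("alpha = %g, runs = %d, seed = %d, methods: %s\n",
              x$alpha, x$runs, x$seed, paste(x$methods, collapse = ", ")))
  invisible(x)
}

# p-values (undefined statistics mapped to p = 1) and the count of
# undefined statistics, for all methods on vectors of condition sums
method_pvalues <- function(method, S1, S2, n1, n2, fisher_lane_total) {
  kern <- switch(method,
    LRT = lrt_kernel(S1, S2, n1, n2),
    Cond = cond_kernel(S1, S2, n1, n2),
    Wald = wald_kernel(S1, S2, n1, n2),
    WaldLog = wald_log_kernel(S1, S2, n1, n2),
    VST = vst_kernel(S1, S2, n1, n2),
    Fisher = fisher_kernel(S1, S2, fisher_lane_total * n1,
                           fisher_lane_total * n2))
  list(p = kern$p.value, n_undefined = sum(is.na(kern$statistic)))
}

#' Estimate rejection rates for one simulation cell
#'
#' Draws `runs` independent datasets from the cell's design, applies every
#' requested method to each draw (all methods share the same draw), and
#' counts rejections under the strict rule `p < alpha`. Runs where a
#' method's statistic is undefined (e.g. a zero condition sum for the
#' Wald-Log test) count as non-rejections and are tallied in
#' `n_undefined`. Deterministic given the design's seed.
#'
#' @param design A [sim_design] object.
#' @return A `"power_sim"` data frame with one row per method: `lambda1`,
#'   `lambda2`, `n1`, `n2`, `method`, `rejection_rate`,
#'   `mc_stderr` (= `sqrt(r(1-r)/runs)`), `n_undefined`, `runs`, `alpha`.
#' @export
#' @examples
#' simulate_cell(sim_design(10, 10, runs = 500, seed = 7))
simulate_cell <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  runs <- design$runs
  S1 <- if (design$n1 == 1L) rpois(runs, design$lambda1) else
    colSums(matrix(rpois(runs * design$n1, design$lambda1), design$n1))
  S2 <- if (design$n2 == 1L) rpois(runs, design$lambda2) else
    colSums(matrix(rpois(runs * design$n2, design$lambda2), design$n2))
  rows <- lapply(design$methods, function(m) {
    res <- method_pvalues(m, S1, S2, design$n1, design$n2,
                          design$fisher_lane_total)
    r <- sum(res$p < design$alpha) / runs
    data.frame(lambda1 = design$lambda1, lambda2 = design$lambda2,
               n1 = design$n1, n2 = design$n2, method = m,
               rejection_rate = r,
               mc_stderr = sqrt(r * (1 - r) / runs),
               n_undefined = res$n_undefined,
               runs = runs, alpha = design$alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_sim", "data.frame")
  out
}

# Deterministic sub-seed for a grid cell: mixing the master seed with the
# cell coordinates keeps each cell's stream fixed when other cells are
# added or removed.
cell_seed <- function(seed, lambda1, lambda2, n1, n2) {
  v <- c(seed, round(lambda1 * 1000), round(lambda2 * 1000), n1, n2)
  h <- 0
  for (x in v) h <- (h * 1000003 + x + 12289) %% 2147483647
  as.integer(h)
}

#' Estimate size and power over a grid of Poisson-mean settings
#'
#' Runs [simulate_cell] for every (lambda1, lambda2) setting of a grid,
#' with one deterministic sub-seed per cell derived from the master seed
#' and the cell coordinates. Rows keep the grid order.
#'
#' @param grid Either a data frame with columns `lambda1` and `lambda2`
#'   (one row per cell, e.g. from [reference_grid]), or a numeric vector
#'   of `lambda1` values, in which case `lambda2` must be a parallel list
#'   (or single vector) of `lambda2` values to pair with each `lambda1`.
#' @param lambda2 See `grid`; ignored when `grid` is a data frame.
#' @inheritParams sim_design
#' @return A `"power_sim"` data frame, one row per cell and method.
#' @seealso [render_power_table], [plot.power_sim]
#' @export
#' @examples
#' run_grid(c(5, 10), lambda2 = list(c(5, 9), c(10, 15)),
#'          runs = 200, seed = 1, methods = c("LRT", "WaldLog"))
run_grid <- function(grid, lambda2 = NULL, n1 = 1L, n2 = 1L, alpha = 1e-3,
                     runs = 10000L, seed = 1L, methods = pois_methods(),
                     fisher_lane_total = 1e6) {
  if (is.data.frame(grid)) {
    stopifnot(all(c("lambda1", "lambda2") %in% names(grid)),
              nrow(grid) >= 1)
    cells <- grid[c("lambda1", "lambda2")]
  } else {
    stopifnot(is.numeric(grid), length(grid) >= 1, !is.null(lambda2))
    if (!is.list(lambda2)) lambda2 <- rep(list(lambda2), length(grid))
    stopifnot(length(lambda2) == length(grid))
    cells <- data.frame(
      lambda1 = rep(grid, lengths(lambda2)),
      lambda2 = unlist(lambda2))
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    l1 <- cells$lambda1[i]; l2 <- cells$lambda2[i]
    simulate_cell(sim_design(
      l1, l2, n1 = n1, n2 = n2, alpha = alpha, runs = runs,
      seed = cell_seed(seed, l1, l2, n1, n2), methods = methods,
      fisher_lane_total = fisher_lane_total))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_sim", "data.frame")
  out
}

#' Benchmark grid of Poisson-mean settings
#'
#' The package's standard size/power study evaluates each test over a grid
#' of small-to-moderate Poisson means, where the methods differ most: the
#' first condition's mean is 5, 10, 15 or 30 and the second is equal (size)
#' or larger (power). Two designs are provided: single-lane conditions
#' (`replicates = 1`, 27 settings, second means stepping further out) and
#' three lanes per condition (`replicates = 3`, 22 settings, where the
#' summed counts grow faster so smaller mean gaps suffice).
#'
#' @param replicates 1 or 3, the lanes per condition of the design.
#' @return Data frame with columns `lambda1`, `lambda2`.
#' @export
#' @examples
#' nrow(reference_grid(1))
#' reference_grid(3)[1:5, ]
reference_grid <- function(replicates = 1) {
  stopifnot(replicates %in% c(1, 3))
  cells <- if (replicates == 1) {
    list(`5` = c(5, 9, 13, 17, 21, 25),
         `10` = seq(10, 40, 5),
         `15` = seq(15, 50, 5),
         `30` = seq(30, 80, 10))
  } else {
    list(`5` = seq(5, 13, 2),
         `10` = seq(10, 20, 2),
         `15` = seq(15, 25, 2),
         `30` = seq(30, 46, 4))
  }
  data.frame(lambda1 = rep(as.numeric(names(cells)), lengths(cells)),
             lambda2 = unlist(cells, use.names = FALSE))
}

#' Render a size/power table
#'
#' Reshapes [run_grid] output to one row per (lambda1, lambda2) setting
#' and one 4-decimal column per method, in the canonical method order.
#'
#' @param results A `"power_sim"` data frame.
#' @param format `"tsv"` (default) or `"markdown"`.
#' @return A character scalar holding the rendered table.
#' @export
#' @examples
#' res <- run_grid(5, lambda2 = list(c(5, 25)), runs = 200, seed = 1,
#'                 methods = c("LRT", "WaldLog"))
#' cat(render_power_table(res))
render_power_table <- function(results, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  meths <- pois_methods()[pois_methods() %in% unique(results$method)]
  header <- c("lambda1", "lambda2", meths)
  cells <- unique(results[c("lambda1", "lambda2")])
  body <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- results$lambda1 == cells$lambda1[i] &
      results$lambda2 == cells$lambda2[i]
    rates <- setNames(results$rejection_rate[sel], results$method[sel])
    c(format(cells$lambda1[i]), format(cells$lambda2[i]),
      sprintf("%.4f", rates[meths]))
  })
  if (format == "tsv") {
    lines <- c(paste(header, collapse = "\t"),
               vapply(body, paste, "", collapse = "\t"))
  } else {
    lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(header)), collapse = "|"),
                      "|"),
               vapply(body, function(b)
                 paste0("| ", paste(b, collapse = " | "), " |"), ""))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.power_sim <- function(x, ...) {
  cat(render_power_table(x))
  invisible(x)
}

#' Plot estimated power curves
#'
#' One panel per `lambda1`: estimated rejection rate against `lambda2`,
#' one line per method.
#'
#' @param x A `"power_sim"` data frame from [run_grid].
#' @param ... Passed to [graphics::matplot].
#' @return `x`, invisibly.
#' @export
plot.power_sim <- function(x, ...) {
  l1s <- unique(x$lambda1)
  meths <- pois_methods()[pois_methods() %in% unique(x$method)]
  old <- par(mfrow = c(1, length(l1s)))
  on.exit(par(old))
  for (l1 in l1s) {
    sub <- x[x$lambda1 == l1, ]
    l2s <- sort(unique(sub$lambda2))
    mat <- sapply(meths, function(m)
      sub$rejection_rate[sub$method == m][order(sub$lambda2[sub$method == m])])
    matplot(l2s, mat, type = "b", pch = seq_along(meths), lty = 1,
            xlab = expression(lambda[2]), ylab = "rejection rate",
            main = bquote(lambda[1] == .(l1)), ylim = c(0, 1), ...)
    legend("bottomright", legend = meths, col = seq_along(meths),
           pch = seq_along(meths), lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}
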