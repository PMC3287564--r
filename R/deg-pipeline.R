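# Gene-wise differential-expression screening: every test applied to the
# condition sums of each gene, fold changes, and DEG counts at p-value
# cutoffs.

#' Test every gene of a count matrix
#'
#' Applies the requested two-sample Poisson tests to each gene's
#' condition sums (see [run_all_tests]) and reports fold changes. The
#' Fisher test's 2x2 table uses the matrix's lane totals
#' (`fisher_totals = "column_sums"` rebuilds them as column sums of the
#' current matrix; `"supplied"` uses the totals stored in `x`, e.g. read
#' from the sequencer). Genes with zero sums carry undefined statistics
#' with p = 1 rather than errors. P-values are raw: the screen uses fixed
#' cutoffs, but `adjust = TRUE` adds Benjamini-Hochberg columns.
#'
#' @param x A [gene_counts] object.
#' @param methods Subset of [pois_methods()].
#' @param fisher_totals `"column_sums"` (default) or `"supplied"`.
#' @param cond_method Two-sided rule for the exact tests.
#' @param adjust Add `padj_*` Benjamini-Hochberg columns? Default FALSE.
#' @return A `"deg_results"` data frame, one row per gene in input order:
#'   `gene_id`, `S1`, `S2`, `mean1`, `mean2`, `fold_change`
#'   (condition 1 over condition 2, `NA` when undefined), `log2_abs_fc`
#'   (`|log2 FC|`), then `stat_<m>`, `p_<m>` and `neglog10p_<m>` per
#'   method.
#' @seealso [count_degs], [write_results]
#' @export
#' @examples
#' synth <- synth_matrix(50, deg_fraction = 0.3, fold_change = 5, seed = 2)
#' res <- test_genes(synth$counts)
#' head(res[, c("gene_id", "fold_change", "p_WaldLog", "p_LRT")])
test_genes <- function(x, methods = pois_methods(),
                       fisher_totals = c("column_sums", "supplied"),
                       cond_method = c("min_likelihood", "doubled_tail"),
                       adjust = FALSE) {
  stopifnot(inherits(x, "gene_counts"), length(methods) >= 1)
  fisher_totals <- match.arg(fisher_totals)
  cond_method <- match.arg(cond_method)
  methods <- match.arg(methods, pois_methods(), several.ok = TRUE)
  methods <- pois_methods()[pois_methods() %in% methods]
  s <- cond_sums(x)
  totals <- if (fisher_totals == "column_sums") colSums(x$counts) else
    x$lane_totals
  M1 <- sum(totals[x$condition == 1L]); M2 <- sum(totals[x$condition == 2L])
  mean1 <- s$S1 / s$n1; mean2 <- s$S2 / s$n2
  fc <- ifelse(s$S2 > 0, mean1 / mean2, NA_real_)
  out <- data.frame(gene_id = x$gene_ids, S1 = s$S1, S2 = s$S2,
                    mean1 = mean1, mean2 = mean2, fold_change = fc,
                    log2_abs_fc = ifelse(s$S1 > 0 & s$S2 > 0,
                                         abs(log2(mean1 / mean2)), NA_real_),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (m in methods) {
    kern <- switch(m,
      LRT = lrt_kernel(s$S1, s$S2, s$n1, s$n2),
      Cond = cond_kernel(s$S1, s$S2, s$n1, s$n2, method = cond_method),
      Wald = wald_kernel(s$S1, s$S2, s$n1, s$n2),
      WaldLog = wald_log_kernel(s$S1, s$S2, s$n1, s$n2),
      VST = vst_kernel(s$S1, s$S2, s$n1, s$n2),
      Fisher = fisher_kernel(s$S1, s$S2, M1, M2, method = cond_method))
    out[[paste0("stat_", m)]] <- kern$statistic
    out[[paste0("p_", m)]] <- kern$p.value
    out[[paste0("neglog10p_", m)]] <- -log10(kern$p.value)
    if (adjust) out[[paste0("padj_", m)]] <- p.adjust(kern$p.value, "BH")
  }
  attr(out, "methods") <- methods
  attr(out, "n1") <- s$n1
  attr(out, "n2") <- s$n2
  class(out) <- c("deg_results", "data.frame")
  out
}

#' Count DEGs at p-value cutoffs
#'
#' For each method, the number of genes with raw p-value strictly below
#' each cutoff. Counts are necessarily non-increasing as the cutoff
#' shrinks.
#'
#' @param results A `"deg_results"` data frame from [test_genes].
#' @param cutoffs Decreasing p-value cutoffs;
#'   default `c(1e-3, 1e-4, 1e-5, 1e-6)`.
#' @return Integer matrix, methods x cutoffs.
#' @export
#' @examples
#' synth <- synth_matrix(200, deg_fraction = 0.3, fold_change = 5, seed = 3)
#' count_degs(test_genes(synth$counts))
count_degs <- function(results, cutoffs = c(1e-3, 1e-4, 1e-5, 1e-6)) {
  stopifnot(inherits(results, "deg_results"), length(cutoffs) >= 1)
  methods <- attr(results, "methods")
  out <- sapply(cutoffs, function(cut)
    vapply(methods, function(m)
      sum(results[[paste0("p_", m)]] < cut, na.rm = TRUE), 0L))
  out <- matrix(as.integer(out), nrow = length(methods),
                dimnames = list(methods, format(cutoffs, scientific = TRUE)))
  out
}

#' @export
print.deg_results <- function(x, n = 6L, ...) {
  cat(sprintf("deg_results: %d genes, methods: %s\n", nrow(x),
              paste(attr(x, "methods"), collapse = ", ")))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... %d more genes\n", nrow(x) - n))
  invisible(x)
}

#' @export
summary.deg_results <- function(object, cutoffs = c(1e-3, 1e-4, 1e-5, 1e-6),
                                ...) {
  cat(sprintf("%d genes tested (%d + %d lanes per condition)\n",
              nrow(object), attr(object, "n1"), attr(object, "n2")))
  cat("DEG counts (p < cutoff):\n")
  print(count_degs(object, cutoffs))
  invisible(count_degs(object, cutoffs))
}

#' Volcano-style plot of gene-wise results
#'
#' Plots `-log10(p)` against the signed log2 fold change for one method.
#'
#' @param x A `"deg_results"` data frame.
#' @param method One of the tested methods; default `"WaldLog"`.
#' @param alpha Cutoff drawn as a horizontal reference; default 1e-3.
#' @param ... Passed to [plot].
#' @return `x`, invisibly.
#' @export
plot.deg_results <- function(x, method = "WaldLog", alpha = 1e-3, ...) {
  stopifnot(method %in% attr(x, "methods"))
  lfc <- ifelse(is.na(x$fold_change), NA_real_, log2(x$fold_change))
  p <- x[[paste0("p_", method)]]
  graphics::plot(lfc, -log10(p), pch = 16, cex = 0.5,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ p),
                 main = method, ...)
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(x)
}

#' Write gene-wise results to a TSV file
#'
#' Serializes a `"deg_results"` data frame as tab-separated text with a
#' header row; undefined values are written as `NA`. `Inf` in the
#' `-log10(p)` columns (p = 0 underflow) round-trips as `Inf`.
#'
#' @param results A `"deg_results"` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(inherits(results, "deg_results"))
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
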