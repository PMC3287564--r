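# Gene x lane count matrices with a two-condition lane assignment.

#' Construct a gene count matrix with condition assignment
#'
#' Container for a genes x lanes matrix of non-negative integer read
#' counts, a lane-to-condition assignment (conditions 1 and 2) and
#' per-lane totals of mapped reads. Lane totals default to the column
#' sums; externally supplied totals (e.g. all mapped reads, including
#' genes not in the matrix) must be at least the column sums.
#'
#' @param counts Integer matrix, genes in rows, lanes in columns.
#' @param condition Vector of 1/2 per lane, assigning each lane (column)
#'   to a condition; both conditions need at least one lane.
#' @param gene_ids Unique gene identifiers; default rownames of `counts`.
#' @param lane_totals Per-lane non-negative totals; default
#'   `colSums(counts)`.
#' @return An object of class `"gene_counts"`.
#' @seealso [read_counts], [synth_matrix], [test_genes]
#' @export
#' @examples
#' m <- gene_counts(matrix(c(3, 0, 4, 9), 2,
#'                         dimnames = list(c("g1", "g2"), c("a", "b"))),
#'                  condition = c(1, 2))
#' m
gene_counts <- function(counts, condition, gene_ids = rownames(counts),
                        lane_totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  gene_ids <- as.character(gene_ids)
  condition <- as.integer(condition)
  if (length(condition) != ncol(counts)) {
    stop("'condition' must assign every lane (one value per column)",
         call. = FALSE)
  }
  if (!all(condition %in% c(1L, 2L)) || !all(c(1L, 2L) %in% condition)) {
    stop("'condition' must use labels 1 and 2, each on at least one lane",
         call. = FALSE)
  }
  if (length(gene_ids) != nrow(counts)) {
    stop("'gene_ids' must name every row", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be finite non-negative integers", call. = FALSE)
  }
  lane_totals <- as.numeric(lane_totals)
  if (length(lane_totals) != ncol(counts) || any(lane_totals < 0)) {
    stop("'lane_totals' must be one non-negative total per lane",
         call. = FALSE)
  }
  if (any(lane_totals < colSums(counts) - 1e-8)) {
    stop("'lane_totals' cannot be smaller than the column sums",
         call. = FALSE)
  }
  rownames(counts) <- gene_ids
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("lane", seq_len(ncol(counts)))
  }
  names(lane_totals) <- colnames(counts)
  structure(list(gene_ids = gene_ids, counts = counts,
                 condition = condition, lane_totals = lane_totals),
            class = "gene_counts")
}

#' @export
print.gene_counts <- function(x, ...) {
  cat(sprintf("gene_counts: %d genes x %d lanes (%d + %d per condition)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == 1L), sum(x$condition == 2L)))
  cat(sprintf("lane totals: %s\n",
              paste(format(x$lane_totals, big.mark = ","), collapse = " ")))
  invisible(x)
}

#' @export
dim.gene_counts <- function(x) dim(x$counts)

# subset by gene (logical or index), keeping all lanes
subset_genes <- function(x, keep) {
  gene_counts(x$counts[keep, , drop = FALSE], x$condition,
              gene_ids = x$gene_ids[keep], lane_totals = x$lane_totals)
}

#' Read a gene count matrix from a TSV file
#'
#' Expects a tab-separated file with a header row of lane names and gene
#' ids in the first column; all count cells must be non-negative
#' integers. Lanes are assigned to conditions either by the `group1` /
#' `group2` lane-name vectors or by a two-column lane/condition TSV file
#' (`condition_file`); every header lane must be assigned.
#'
#' @param path Path to the counts TSV.
#' @param group1,group2 Character vectors of lane (column) names for each
#'   condition.
#' @param condition_file Alternative to `group1`/`group2`: TSV with
#'   columns lane and condition (1 or 2), no header required.
#' @param lane_totals Optional per-lane totals (defaults to column sums).
#' @return A [gene_counts] object.
#' @export
read_counts <- function(path, group1 = NULL, group2 = NULL,
                        condition_file = NULL, lane_totals = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  if (ncol(raw) < 2L) stop("counts file needs a gene-id column and at least one lane",
                           call. = FALSE)
  ids <- raw[[1L]]
  lanes <- colnames(raw)[-1L]
  mat <- matrix(0, nrow(raw), length(lanes),
                dimnames = list(ids, lanes))
  for (j in seq_along(lanes)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf(
        "non-integer or negative count at gene '%s', lane '%s' (value '%s')",
        ids[bad[1L]], lanes[j], raw[[j + 1L]][bad[1L]]), call. = FALSE)
    }
    mat[, j] <- v
  }
  if (!is.null(condition_file)) {
    spec <- utils::read.delim(condition_file, header = FALSE,
                              colClasses = "character")
    if (tolower(spec[1L, 1L]) %in% c("lane", "sample")) spec <- spec[-1L, ]
    group1 <- spec[[1L]][spec[[2L]] == "1"]
    group2 <- spec[[1L]][spec[[2L]] == "2"]
  }
  if (is.null(group1) || is.null(group2)) {
    stop("lane assignment required: give group1/group2 or condition_file",
         call. = FALSE)
  }
  missing <- setdiff(c(group1, group2), lanes)
  if (length(missing)) {
    stop("lanes in the condition spec are absent from the file header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unassigned <- setdiff(lanes, c(group1, group2))
  if (length(unassigned)) {
    stop("lanes in the file are not assigned to a condition: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  condition <- ifelse(lanes %in% group1, 1L, 2L)
  if (is.null(lane_totals)) lane_totals <- colSums(mat)
  gene_counts(mat, condition, gene_ids = ids, lane_totals = lane_totals)
}

cond_sums <- function(x) {
  list(S1 = rowSums(x$counts[, x$condition == 1L, drop = FALSE]),
       S2 = rowSums(x$counts[, x$condition == 2L, drop = FALSE]),
       n1 = sum(x$condition == 1L), n2 = sum(x$condition == 2L))
}

#' Filter genes on a minimum total count
#'
#' Keeps genes sequenced deeply enough to test: by default a gene must
#' have at least `min_total` reads summed over the lanes of *each*
#' condition (`scope = "per_condition"`; with 5 lanes, 5 reads means an
#' average of one read per lane). `scope = "pooled"` applies the
#' threshold to the overall total instead.
#'
#' @param x A [gene_counts] object.
#' @param min_total Minimum summed count; default 5.
#' @param scope `"per_condition"` (default) or `"pooled"`.
#' @return The filtered [gene_counts] object (gene order preserved).
#' @export
filter_min_total <- function(x, min_total = 5,
                             scope = c("per_condition", "pooled")) {
  stopifnot(inherits(x, "gene_counts"))
  scope <- match.arg(scope)
  s <- cond_sums(x)
  keep <- if (scope == "per_condition") {
    s$S1 >= min_total & s$S2 >= min_total
  } else {
    s$S1 + s$S2 >= min_total
  }
  subset_genes(x, keep)
}

#' Filter to the low-expression stratum
#'
#' Keeps genes whose average count per lane lies in the closed interval
#' `[lo, hi]` within each condition — the regime where the competing
#' tests differ most and where detecting differential expression is
#' hardest.
#'
#' @param x A [gene_counts] object.
#' @param lo,hi Bounds on the per-lane average count; defaults 1 and 10.
#' @return The filtered [gene_counts] object.
#' @export
filter_low_expression <- function(x, lo = 1, hi = 10) {
  stopifnot(inherits(x, "gene_counts"))
  if (lo > hi) stop("'lo' must not exceed 'hi'", call. = FALSE)
  s <- cond_sums(x)
  m1 <- s$S1 / s$n1; m2 <- s$S2 / s$n2
  subset_genes(x, m1 >= lo & m1 <= hi & m2 >= lo & m2 <= hi)
}

#' Global scale normalization across lanes
#'
#' Rescales each lane's counts by (target total / lane total), with
#' target the mean lane total, so all lanes carry the same total after
#' normalization; results are rounded to the nearest integer so the
#' exact tests remain applicable. Off by default in the pipeline: the
#' Poisson tests operate on raw counts, and rescaling is provided only to
#' mimic upstream preprocessing of unequally loaded lanes.
#'
#' @param x A [gene_counts] object.
#' @return The rescaled [gene_counts] object (identity when all lane
#'   totals are already equal).
#' @export
global_rescale <- function(x) {
  stopifnot(inherits(x, "gene_counts"))
  if (any(x$lane_totals == 0)) stop("zero lane total", call. = FALSE)
  target <- mean(x$lane_totals)
  f <- target / x$lane_totals
  counts <- round(sweep(x$counts, 2L, f, `*`))
  gene_counts(counts, x$condition, gene_ids = x$gene_ids,
              lane_totals = pmax(round(rep(target, ncol(counts))),
                                 colSums(counts)))
}

#' Generate a synthetic RNA-seq count matrix with known DEGs
#'
#' Emulates the lane-level Poisson sampling the tests assume: gene g on a
#' lane of condition i is drawn as `Poisson(lambda_g * f_gi)`, where the
#' base mean `lambda_g` comes from `base_mean_sampler` and the factor
#' `f` is 1 everywhere except that each true DEG has `f = fold_change` in
#' one randomly chosen condition. Defaults emulate a technical-replicate
#' design of five lanes per condition with base means uniform on
#' \[1, 10\] — the low-expression regime where test choice matters.
#' Deterministic given `seed`.
#'
#' @param n_genes Number of genes.
#' @param n1,n2 Lanes per condition; default 5 each.
#' @param base_mean_sampler Function of `n` returning `n` positive base
#'   means; default `function(n) runif(n, 1, 10)`.
#' @param deg_fraction Fraction of genes that are true DEGs, in \[0, 1\].
#' @param fold_change Fold change (>= 1) applied to a DEG's elevated
#'   condition.
#' @param seed Integer seed.
#' @return A list with elements `counts` (a [gene_counts]), `is_deg`
#'   (logical ground truth) and `deg_condition` (1, 2 or NA per gene:
#'   which condition is elevated).
#' @export
#' @examples
#' synth <- synth_matrix(100, deg_fraction = 0.2, fold_change = 4, seed = 1)
#' table(synth$is_deg)
synth_matrix <- function(n_genes, n1 = 5L, n2 = 5L,
                         base_mean_sampler = function(n) runif(n, 1, 10),
                         deg_fraction = 0.1, fold_change = 3, seed = 1L) {
  stopifnot(n_genes >= 0, n1 >= 1, n2 >= 1,
            deg_fraction >= 0, deg_fraction <= 1, fold_change >= 1)
  set.seed(seed)
  lanes <- n1 + n2
  condition <- rep(c(1L, 2L), c(n1, n2))
  if (n_genes == 0L) {
    return(list(counts = gene_counts(
      matrix(integer(), 0L, lanes,
             dimnames = list(NULL, paste0("lane", seq_len(lanes)))),
      condition, gene_ids = character(), lane_totals = rep(1, lanes)),
      is_deg = logical(), deg_condition = integer()))
  }
  lambda <- base_mean_sampler(n_genes)
  stopifnot(length(lambda) == n_genes, all(lambda > 0))
  is_deg <- runif(n_genes) < deg_fraction
  deg_condition <- ifelse(is_deg, sample(c(1L, 2L), n_genes, replace = TRUE),
                          NA_integer_)
  mean1 <- lambda * ifelse(!is.na(deg_condition) & deg_condition == 1L,
                           fold_change, 1)
  mean2 <- lambda * ifelse(!is.na(deg_condition) & deg_condition == 2L,
                           fold_change, 1)
  counts <- cbind(
    matrix(rpois(n_genes * n1, mean1), n_genes, n1),
    matrix(rpois(n_genes * n2, mean2), n_genes, n2))
  colnames(counts) <- paste0("lane", seq_len(lanes))
  ids <- sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes))
  list(counts = gene_counts(counts, condition, gene_ids = ids,
                            lane_totals = pmax(colSums(counts), 1)),
       is_deg = is_deg, deg_condition = deg_condition)
}
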