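# Paired-signal distance correlation, response sorting, and the
# nonparametric group comparisons (Kruskal-Wallis / Friedman omnibus with
# Nemenyi all-pairs post-hoc tests).

#' Sample distance correlation of two signals
#'
#' Classical (biased, V-statistic) distance correlation: pairwise Euclidean
#' distance matrices are double-centered, the squared distance covariance
#' is the mean of their elementwise product, and
#' `dCor = dCov / sqrt(dVar_x * dVar_y)`. The result lies in `[0, 1]`, is 1
#' under affine dependence, and 0 (population version) iff independence.
#' If either signal is constant (`dVar = 0`) the function returns 0 with
#' the `"degenerate"` attribute set. `unbiased = TRUE` uses U-centering
#' instead (the bias-corrected statistic, which may be negative).
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @param unbiased use the U-statistic (bias-corrected) estimator.
#' @return numeric scalar; attribute `"degenerate"` is `TRUE` when either
#'   input had zero distance variance.
#' @export
distance_correlation <- function(x, y, unbiased = FALSE) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length (got ", length(x), " and ",
         length(y), ")")
  }
  n <- length(x)
  stopifnot(n >= 4, all(is.finite(x)), all(is.finite(y)))
  a <- as.matrix(stats::dist(x))
  b <- as.matrix(stats::dist(y))
  if (unbiased) {
    A <- u_center(a); B <- u_center(b)
    den <- n * (n - 3)
    dcov2 <- sum(A * B) / den
    dvx <- sum(A * A) / den
    dvy <- sum(B * B) / den
  } else {
    A <- d_center(a); B <- d_center(b)
    dcov2 <- mean(A * B)
    dvx <- mean(A * A)
    dvy <- mean(B * B)
  }
  if (dvx <= .Machine$double.eps^2 || dvy <= .Machine$double.eps^2) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r2 <- dcov2 / sqrt(dvx * dvy)
  out <- if (unbiased) sign(r2) * sqrt(abs(r2)) else sqrt(max(0, r2))
  attr(out, "degenerate") <- FALSE
  out
}

# double (V-) centering: subtract row and column means, add the grand mean
d_center <- function(m) {
  rm <- rowMeans(m); cm <- colMeans(m); gm <- mean(m)
  m - outer(rm, rep(1, ncol(m))) - outer(rep(1, nrow(m)), cm) + gm
}

# U-centering (Szekely & Rizzo 2014); diagonal set to zero
u_center <- function(m) {
  n <- nrow(m)
  rm <- rowSums(m); gm <- sum(m)
  out <- m - outer(rm, rep(1, n)) / (n - 2) -
    outer(rep(1, n), rm) / (n - 2) + gm / ((n - 1) * (n - 2))
  diag(out) <- 0
  out
}

#' Per-cell distance-correlation table for heat-map rendering
#'
#' Computes one distance correlation per cell between two matched trace
#' sets (e.g. a reporter channel vs the tracer signal). Cells with a
#' degenerate (constant) signal are flagged.
#'
#' @param traces_a,traces_b `papt_traces` data.frames (or any data.frames
#'   with `cell_label` and a signal column) sharing cell labels and a
#'   common time base.
#' @param column signal column name (default `"papt"`).
#' @param unbiased passed to [distance_correlation()].
#' @return data.frame: `cell_label`, `dcor`, `degenerate`, sorted by label.
#' @export
dc_heatmap_table <- function(traces_a, traces_b, column = "papt",
                             unbiased = FALSE) {
  labs <- intersect(unique(traces_a$cell_label), unique(traces_b$cell_label))
  if (length(labs) == 0) stop("no matched cell labels")
  out <- data.frame(cell_label = sort(labs), dcor = NA_real_,
                    degenerate = NA)
  for (i in seq_len(nrow(out))) {
    xa <- traces_a[traces_a$cell_label == out$cell_label[i], column]
    xb <- traces_b[traces_b$cell_label == out$cell_label[i], column]
    dc <- distance_correlation(xa, xb, unbiased = unbiased)
    out$dcor[i] <- as.numeric(dc)
    out$degenerate[i] <- isTRUE(attr(dc, "degenerate"))
  }
  out
}

#' Sort cells by response magnitude over a window
#'
#' Orders cells by descending mean signal over the given frame window
#' (ties broken by cell label, so the sort is stable and reproducible) and
#' returns the permutation together with the row-sorted trace matrix, the
#' layout used for response surface plots.
#'
#' @param trace_matrix numeric matrix, cells x time; rownames are cell
#'   labels (optional).
#' @param window column (frame) indices of the response window.
#' @return list with `order` (row permutation), `sorted` (the reordered
#'   matrix) and `key` (the per-cell mean response).
#' @export
sort_cells_by_response <- function(trace_matrix, window = seq_len(ncol(trace_matrix))) {
  stopifnot(is.matrix(trace_matrix), all(window >= 1),
            all(window <= ncol(trace_matrix)))
  key <- rowMeans(trace_matrix[, window, drop = FALSE])
  o <- order(-key, seq_len(nrow(trace_matrix)))
  list(order = o, sorted = trace_matrix[o, , drop = FALSE], key = key)
}

# Nemenyi all-pairs p-values from mean ranks via the studentized range
nemenyi_pvalues <- function(mean_ranks, se_mat, k) {
  q <- abs(outer(mean_ranks, mean_ranks, "-")) / se_mat
  p <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
  diag(p) <- NA_real_
  p
}

#' Kruskal-Wallis omnibus test with Nemenyi post-hoc analysis
#'
#' Rank-based one-way comparison of independent samples: the tie-corrected
#' Kruskal-Wallis H statistic (via [stats::kruskal.test()]) plus all-pairs
#' Nemenyi p-values from the studentized-range approximation on mean
#' ranks, with tie correction in the standard error.
#'
#' @param groups named list of numeric vectors, `>= 2` groups of `n >= 2`.
#' @return list of class `papt_group_test`: `method`, `statistic`,
#'   `p_value`, `pairwise_p` (symmetric matrix, `NA` diagonal),
#'   `mean_ranks`, `groups`, `n`.
#' @export
kruskal_wallis_nemenyi <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  om <- stats::kruskal.test(x, g)
  r <- rank(x)
  N <- length(x)
  mean_ranks <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_corr
  se <- sqrt(v * outer(1 / ni, 1 / ni, "+"))
  p <- nemenyi_pvalues(as.numeric(mean_ranks), se, k)
  dimnames(p) <- list(names(groups), names(groups))
  structure(list(method = "Kruskal-Wallis + Nemenyi",
                 statistic = unname(om$statistic),
                 p_value = om$p.value,
                 pairwise_p = p,
                 mean_ranks = as.numeric(mean_ranks),
                 groups = names(groups),
                 n = as.integer(ni)),
            class = "papt_group_test")
}

#' Friedman omnibus test with Nemenyi post-hoc analysis
#'
#' Within-subject rank comparison of dependent samples (complete blocks):
#' the Friedman chi-squared statistic (via [stats::friedman.test()]) plus
#' all-pairs Nemenyi p-values on condition mean ranks,
#' `SE = sqrt(k (k + 1) / (6 n))`.
#'
#' @param blocks numeric matrix, subjects x conditions, complete.
#' @return list of class `papt_group_test` (see
#'   [kruskal_wallis_nemenyi()]).
#' @export
friedman_nemenyi <- function(blocks) {
  stopifnot(is.matrix(blocks), ncol(blocks) >= 2, nrow(blocks) >= 2,
            all(is.finite(blocks)))
  if (is.null(colnames(blocks))) {
    colnames(blocks) <- paste0("c", seq_len(ncol(blocks)))
  }
  n <- nrow(blocks); k <- ncol(blocks)
  om <- stats::friedman.test(blocks)
  # complete within-subject ties leave no rank variance: statistic 0, p 1
  if (!is.finite(om$statistic)) {
    om$statistic <- 0
    om$p.value <- 1
  }
  rk <- t(apply(blocks, 1, rank))
  mean_ranks <- colMeans(rk)
  se <- matrix(sqrt(k * (k + 1) / (6 * n)), k, k)
  p <- nemenyi_pvalues(mean_ranks, se, k)
  dimnames(p) <- list(colnames(blocks), colnames(blocks))
  structure(list(method = "Friedman + Nemenyi",
                 statistic = unname(om$statistic),
                 p_value = om$p.value,
                 pairwise_p = p,
                 mean_ranks = as.numeric(mean_ranks),
                 groups = colnames(blocks),
                 n = rep(n, k)),
            class = "papt_group_test")
}

#' @export
print.papt_group_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  omnibus statistic %.4g, p = %.4g\n", x$statistic,
              x$p_value))
  cat("  pairwise Nemenyi p-values:\n")
  print(round(x$pairwise_p, 4))
  invisible(x)
}
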