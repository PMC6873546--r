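#' Covariance of a centered energy matrix
#'
#' Definitional sample covariance with divisor n - 1 of a
#' column-centered matrix; errors if the columns are not centered.
#'
#' @param cte Column-centered matrix, n >= 2 rows.
#' @return p x p symmetric positive semi-definite matrix.
#' @export
covariance_matrix <- function(cte) {
  if (nrow(cte) < 2) stop("covariance needs n >= 2 rows")
  scale <- max(abs(cte), 1e-12)
  if (max(abs(colMeans(cte))) > 1e-8 * scale)
    stop("matrix is not column-centered; call center_columns() first")
  crossprod(cte) / (nrow(cte) - 1)
}

#' Eigendecomposition of a covariance matrix
#'
#' Symmetric eigendecomposition with eigenvalues sorted non-increasing
#' and tiny negative values (numerical noise) clipped to zero.
#'
#' @param cov Symmetric matrix.
#' @return List with `values` (non-increasing, >= 0) and `vectors`
#'   (orthonormal columns, column j paired with value j).
#' @export
eigendecompose <- function(cov) {
  scale <- max(abs(cov), 1e-12)
  if (max(abs(cov - t(cov))) > 1e-8 * scale)
    stop("covariance matrix is not symmetric")
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -1e-6 * scale))
    warning("clipping substantially negative eigenvalues to zero")
  vals[vals < 0] <- 0
  list(values = vals, vectors = e$vectors)
}

#' Proportions of total variance
#'
#' Percent of total variance carried by each principal direction:
#' `100 * lambda_j / sum(lambda)`.
#'
#' @param spec An [eigendecompose()] spectrum (or numeric eigenvalues).
#' @return Numeric vector summing to 100, non-increasing.
#' @export
variance_proportions <- function(spec) {
  vals <- if (is.list(spec)) spec$values else spec
  tot <- sum(vals)
  if (tot <= 0) stop("spectrum has zero total variance")
  100 * vals / tot
}

#' Number of components for a variance threshold
#'
#' Smallest m whose leading proportions sum to at least the threshold
#' (80 percent by default).
#'
#' @param t Variance proportions (percent, summing to 100).
#' @param threshold_percent Required cumulative variance.
#' @return Integer m in `[1, length(t)]`.
#' @export
select_components <- function(t, threshold_percent = 80) {
  cs <- cumsum(t)
  m <- which(cs >= threshold_percent - 1e-9)[1]
  if (is.na(m)) m <- length(t)
  as.integer(m)
}

#' Variable contributions to principal directions
#'
#' The contribution of variable k to direction j is the squared loading
#' in percent: `100 * V_j(k)^2 / sum_k V_j(k)^2`. Columns sum to 100
#' and the value is invariant to eigenvector sign.
#'
#' @param spec An [eigendecompose()] spectrum.
#' @param m Number of leading directions.
#' @return p x m matrix of percents.
#' @export
pc_contributions <- function(spec, m) {
  stopifnot(m >= 1, m <= ncol(spec$vectors))
  v2 <- spec$vectors[, seq_len(m), drop = FALSE]^2
  sweep(v2, 2, colSums(v2), "/") * 100
}

#' Eigenvalue-weighted total contributions
#'
#' Total contribution of variable k over the m retained directions:
#' `sum_j C[k, j] * lambda_j`.
#'
#' @param C Contribution matrix from [pc_contributions()].
#' @param spec The spectrum.
#' @param m Number of retained directions (must match `ncol(C)`).
#' @return Numeric vector of length p.
#' @export
total_contributions <- function(C, spec, m = ncol(C)) {
  stopifnot(ncol(C) == m, m <= length(spec$values))
  drop(C %*% spec$values[seq_len(m)])
}

#' Uniform-contribution cutoff
#'
#' Under uniform contributions each of the p variables would
#' contribute `100 / p` percent on every direction, so the expected
#' total contribution is `tau = sum_{i=1..m} (100 / p) * lambda_i`; at
#' p = 210 the per-direction factor is 1/2.1. Algebraically tau equals
#' the mean of the eigenvalue-weighted total contributions, which is
#' asserted on every selection run.
#'
#' @param spec The spectrum.
#' @param m Retained directions.
#' @param p Number of variables.
#' @return The cutoff tau.
#' @export
uniform_threshold <- function(spec, m, p = length(spec$values)) {
  stopifnot(m >= 1)
  sum((100 / p) * spec$values[seq_len(m)])
}

#' Extract principal interactions from an energy matrix
#'
#' The full selection chain: covariance of the centered matrix,
#' eigendecomposition, variance proportions, smallest m capturing the
#' variance threshold, squared-loading contributions, eigenvalue-
#' weighted total contributions, and the uniform cutoff tau. Variables
#' whose total contribution is strictly greater than tau form the
#' principal set; the full descending ranking is also returned (used
#' for success-rate curves).
#'
#' The selection is invariant to positive rescaling of all energies,
#' row permutation or duplication, and eigenvector sign flips. It is
#' defined for any number of variables, not just the 210 pair types of
#' the full alphabet.
#'
#' @param x Energy matrix (n x p). Centered automatically unless
#'   `center = FALSE`, in which case it must already be column-centered.
#' @param threshold_percent Cumulative variance the retained components
#'   must reach (80 by default).
#' @param center Center columns before the covariance step.
#' @return Object of class `pi_selection` with fields `t` (variance
#'   proportions), `m`, `contributions`, `total_contribution`, `tau`,
#'   `principal_set`, `ranked_variables`, `spectrum`,
#'   `threshold_percent`.
#' @export
#' @examples
#' m <- generate_planted_matrix(planted_matrix_spec(
#'   n_rows = 100, p = 45, planted_indices = 1:3,
#'   planted_sd = 10, background_sd = 1, seed = 7))
#' sel <- select_principal(m)
#' sel$principal_set
select_principal <- function(x, threshold_percent = 80, center = TRUE) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  labs <- colnames(x)
  if (is.null(labs)) labs <- paste0("V", seq_len(ncol(x)))
  cte <- if (center) center_columns(x) else x
  cov <- covariance_matrix(cte)
  spec <- eigendecompose(cov)
  t <- variance_proportions(spec)
  m <- select_components(t, threshold_percent)
  C <- pc_contributions(spec, m)
  tc <- total_contributions(C, spec, m)
  p <- length(tc)
  tau <- uniform_threshold(spec, m, p)
  stopifnot(abs(mean(tc) - tau) <= 1e-8 * max(tau, 1e-12))
  ord <- order(tc, decreasing = TRUE)
  structure(list(
    t = t, m = m, contributions = C, total_contribution =
      stats::setNames(tc, labs), tau = tau,
    principal_set = labs[tc > tau],
    ranked_variables = labs[ord],
    spectrum = spec, threshold_percent = threshold_percent,
    n = nrow(x), p = p), class = "pi_selection")
}

#' @export
print.pi_selection <- function(x, ...) {
  cat(sprintf(
    "Principal-interaction selection: %d of %d variables above tau = %.4g\n",
    length(x$principal_set), x$p, x$tau))
  cat(sprintf("  m = %d components capture %.1f%% of variance (threshold %g%%)\n",
              x$m, sum(x$t[seq_len(x$m)]), x$threshold_percent))
  cat("  top of ranking:",
      paste(utils::head(x$ranked_variables, 8), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pi_selection <- function(object, ...) {
  print(object)
  sel <- names(sort(object$total_contribution[object$principal_set],
                    decreasing = TRUE))
  cat("Principal set (descending total contribution):\n")
  print(sel)
  invisible(object)
}

#' @export
plot.pi_selection <- function(x, ...) {
  tc <- sort(x$total_contribution, decreasing = TRUE)
  plot(seq_along(tc), tc, xlab = "variable rank",
       ylab = "total contribution", pch = 20,
       col = ifelse(names(tc) %in% x$principal_set, "red", "grey40"), ...)
  graphics::abline(h = x$tau, lty = 2)
  invisible(x)
}

#' Export a selection result
#'
#' TSV of per-variable totals (pair_label, total_contribution, tau,
#' selected, rank) and a JSON side file with the spectrum summary.
#'
#' @param sel A [select_principal()] result.
#' @param path TSV output path; the JSON summary goes to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  tc <- sel$total_contribution
  rank <- match(names(tc), sel$ranked_variables)
  df <- data.frame(pair_label = names(tc), total_contribution = tc,
                   tau = sel$tau, selected = names(tc) %in%
                     sel$principal_set, rank = rank)
  utils::write.table(df[order(df$rank), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    n = sel$n, p = sel$p, m = sel$m,
    threshold_percent = sel$threshold_percent, tau = sel$tau,
    variance_percent_retained = sum(sel$t[seq_len(sel$m)]),
    eigenvalues = sel$spectrum$values,
    principal_set = sel$principal_set),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Seeded row subsample of a matrix
#'
#' Convenience for running the selection on a random subset of
#' structures; no subsample is ever applied implicitly.
#'
#' @param m Matrix.
#' @param n_rows Rows to keep.
#' @param seed RNG seed.
#' @return Row-subsampled matrix.
#' @export
subsample_rows <- function(m, n_rows, seed) {
  stopifnot(n_rows <= nrow(m))
  with_seed(seed, m[sample(nrow(m), n_rows), , drop = FALSE])
}
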