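#' Native recognition (Top1)
#'
#' TRUE iff the native score is strictly the lowest; a tie with the
#' best decoy counts against recognition, with a warning.
#'
#' @param score_native Native energy.
#' @param score_decoys Decoy energies.
#' @return Logical.
#' @export
top1 <- function(score_native, score_decoys) {
  stopifnot(all(is.finite(c(score_native, score_decoys))))
  best <- min(score_decoys)
  if (score_native == best) {
    warning("native ties the best decoy; counted as not recognised")
    return(FALSE)
  }
  score_native < best
}

#' Z-score of the native energy
#'
#' `(<score_decoys> - score_native) / sd(score_decoys)` with the sample
#' standard deviation (divisor n - 1) over decoys only; positive when
#' the native scores lower (better) than the decoy mean.
#'
#' @inheritParams top1
#' @return Z-score.
#' @export
zscore_native <- function(score_native, score_decoys) {
  if (length(score_decoys) < 2) stop("need >= 2 decoys for a Z-score")
  s <- stats::sd(score_decoys)
  if (s == 0) stop("zero decoy score spread; Z-score undefined")
  (mean(score_decoys) - score_native) / s
}

#' RMSD of the minimum-energy structure
#'
#' C-alpha RMSD between the native and whichever structure (native
#' included) has the lowest energy: 0 when the native itself is the
#' minimum. Score ties among decoys resolve to the lower-RMSD decoy,
#' with a warning.
#'
#' @param ds A [decoy_set()].
#' @param score_native,score_decoys Energies.
#' @param rmsd Decoy RMSDs; defaults to [decoy_rmsds()].
#' @return RMSD in Angstrom.
#' @export
rmsd_of_minimum <- function(ds, score_native, score_decoys,
                            rmsd = decoy_rmsds(ds)) {
  if (score_native <= min(score_decoys)) return(0)
  cand <- which(score_decoys == min(score_decoys))
  if (length(cand) > 1) {
    warning("tie at the minimum decoy energy; reporting the lower-RMSD one")
    cand <- cand[which.min(rmsd[cand])]
  }
  rmsd[cand]
}

#' Pearson correlation between decoy energy and RMSD
#'
#' Standard Pearson r over decoys only (native excluded); positive when
#' worse (higher-RMSD) decoys score higher.
#'
#' @inheritParams rmsd_of_minimum
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_energy_rmsd <- function(ds, score_decoys, rmsd = decoy_rmsds(ds)) {
  ok <- is.finite(score_decoys) & is.finite(rmsd)
  if (sum(ok) < 3) stop("need >= 3 decoys with finite score and RMSD")
  if (stats::sd(score_decoys[ok]) == 0 || stats::sd(rmsd[ok]) == 0)
    stop("zero variance in scores or RMSDs; correlation undefined")
  stats::cor(score_decoys[ok], rmsd[ok])
}

#' 20 percent fraction enrichment
#'
#' Overlap between the 20 percent most accurate decoys (lowest RMSD)
#' and the 20 percent best-scoring decoys (lowest energy), relative to
#' random expectation: `|intersection| / (0.2 * 0.2 * N)` with both
#' top sets of size `max(1, floor(0.2 N))` and the native excluded
#' everywhere. Ranges from 0 (disjoint) to 5 (coincident top sets).
#'
#' @inheritParams rmsd_of_minimum
#' @return Enrichment in `[0, 5]`.
#' @export
fraction_enrichment <- function(ds, score_decoys, rmsd = decoy_rmsds(ds)) {
  n <- length(score_decoys)
  if (n < 5) stop("fraction enrichment needs >= 5 decoys, got ", n)
  k <- max(1L, floor(0.2 * n))
  by_rmsd <- order(rmsd)[seq_len(k)]
  by_score <- order(score_decoys)[seq_len(k)]
  length(intersect(by_rmsd, by_score)) / (0.04 * n)
}

#' Z-score of the best decoy
#'
#' Energy gap between the best decoy (lowest RMSD from the native,
#' identified by RMSD, never by score) and the remaining decoys:
#' `(<score_rest> - score_best) / sd(score_rest)`, the native and the
#' best decoy both excluded from the reference distribution. RMSD ties
#' for best resolve to the first, with a warning.
#'
#' @inheritParams rmsd_of_minimum
#' @return Z-score.
#' @export
zscore_best <- function(ds, score_decoys, rmsd = decoy_rmsds(ds)) {
  if (length(score_decoys) < 3) stop("need >= 3 decoys for Z-score_b")
  best <- which(rmsd == min(rmsd))
  if (length(best) > 1) {
    warning("RMSD tie for best decoy; using the first")
    best <- best[1]
  }
  rest <- score_decoys[-best]
  s <- stats::sd(rest)
  if (s == 0) stop("zero score spread among non-best decoys")
  (mean(rest) - score_decoys[best]) / s
}

#' Evaluate one decoy set under a potential
#'
#' Scores the native and all decoys (optionally masked) and computes
#' the six performance criteria plus the PI contact-fraction summary.
#'
#' @param ds A [decoy_set()].
#' @param table A [kbp()] potential.
#' @param mask Optional [interaction_mask()]; when given, energies use
#'   only masked pair types and PI is reported against it.
#' @return One-row data.frame of per-target metrics.
#' @export
evaluate_decoy_set <- function(ds, table, mask = NULL) {
  sn <- predict(table, ds$native, mask = mask)
  sd_ <- predict(table, ds$decoys, mask = mask)
  rmsd <- decoy_rmsds(ds)
  pi_vals <- if (!is.null(mask))
    vapply(c(list(ds$native), ds$decoys), pi_fraction, 0,
           table = table, mask = mask)
  data.frame(
    target = ds$target_id,
    n_decoys = length(ds$decoys),
    top1 = top1(sn, sd_),
    zscore = zscore_native(sn, sd_),
    rmsd_min = rmsd_of_minimum(ds, sn, sd_, rmsd),
    pc = pearson_energy_rmsd(ds, sd_, rmsd),
    fe = fraction_enrichment(ds, sd_, rmsd),
    zscore_b = zscore_best(ds, sd_, rmsd),
    pi_mean = if (is.null(mask)) 1 else mean(pi_vals),
    pi_sd = if (is.null(mask)) 0 else stats::sd(pi_vals),
    stringsAsFactors = FALSE)
}

#' Evaluate a collection of decoy sets
#'
#' Per-target metrics plus the aggregates reported for decoy-set
#' benchmarks: the Top1 count and means of Z-score, RMSD of the energy
#' minimum, energy-RMSD correlation, fraction enrichment, best-decoy
#' Z-score, and the PI contact fraction (mean over all structures, with
#' its standard deviation). Targets whose evaluation fails are skipped
#' with a message, not fatal.
#'
#' @param sets List of [decoy_set()].
#' @param table A [kbp()] potential.
#' @param mask Optional [interaction_mask()].
#' @return Object of class `decoy_eval` with `per_target` (data.frame)
#'   and `aggregate` (named list).
#' @export
evaluate_collection <- function(sets, table, mask = NULL) {
  stopifnot(length(sets) >= 1)
  rows <- list()
  for (ds in sets) {
    r <- tryCatch(evaluate_decoy_set(ds, table, mask),
                  error = function(e) {
                    message("skipping target '", ds$target_id, "': ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) stop("every target failed evaluation")
  pt <- do.call(rbind, rows)
  agg <- list(
    n_targets = nrow(pt),
    top1 = sum(pt$top1),
    zscore = mean(pt$zscore),
    rmsd = mean(pt$rmsd_min),
    pc = mean(pt$pc),
    fe = mean(pt$fe),
    zscore_b = mean(pt$zscore_b),
    pi_mean = mean(pt$pi_mean),
    pi_sd = mean(pt$pi_sd))
  structure(list(per_target = pt, aggregate = agg,
                 masked = !is.null(mask)),
            class = "decoy_eval")
}

#' @export
print.decoy_eval <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Decoy evaluation (%s model), %d targets:\n",
              if (x$masked) "reduced" else "full", a$n_targets))
  cat(sprintf("  Top1 %d/%d  Z-score %.2f  RMSD %.2f  PC %.2f  F.E. %.2f  Z-score_b %.2f\n",
              a$top1, a$n_targets, a$zscore, a$rmsd, a$pc, a$fe,
              a$zscore_b))
  if (x$masked)
    cat(sprintf("  PI %.2f +/- %.2f\n", a$pi_mean, a$pi_sd))
  invisible(x)
}

#' Write an evaluation report
#'
#' Per-target TSV plus an aggregate JSON side file.
#'
#' @param ev A [evaluate_collection()] result.
#' @param path TSV path; JSON goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(ev, path) {
  utils::write.table(ev$per_target, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(ev$aggregate, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Success rate versus ranked interactions
#'
#' For every k, the Top1 count over the collection when scoring with
#' only the k top-ranked pair types of `ranking` (typically the
#' descending total-contribution order of a selection). The k = p point
#' equals the full-model Top1. The curve need not be monotone.
#'
#' Energy vectors are computed once per structure; each cutoff is then
#' a masked column sum, so the whole curve costs one pass of contact
#' enumeration.
#'
#' @param sets List of [decoy_set()].
#' @param table A [kbp()] potential.
#' @param ranking Character vector: all pair labels in rank order.
#' @return data.frame with columns `k` and `top1`.
#' @export
success_curve <- function(sets, table, ranking) {
  labs <- rownames(table$energies)
  if (!setequal(ranking, labs))
    stop("ranking must cover all pair types exactly once")
  p <- length(labs)
  counts <- integer(p)
  for (ds in sets) {
    vn <- interaction_energy_vector(ds$native, table)[ranking]
    vd <- predict(table, ds$decoys, type = "vector")[, ranking,
                                                    drop = FALSE]
    cn <- cumsum(vn)
    cd <- apply(vd, 1, cumsum)           # p x n_decoys
    best <- apply(cd, 1, min)
    counts <- counts + as.integer(cn < best)
  }
  data.frame(k = seq_len(p), top1 = counts)
}
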