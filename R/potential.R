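#' Define a distance binning
#'
#' Half-open bins `[low, high)` of equal width covering
#' `[min, max)`; `max` normally equals the contact scheme's cutoff so
#' every contact falls in a bin.
#'
#' @param min,max Range in Angstrom; `(max - min) / width` must be a
#'   positive integer.
#' @param width Bin width in Angstrom.
#' @return Object of class `distance_binning` with precomputed `breaks`
#'   and bin `centers`.
#' @export
distance_binning <- function(min = 0, max = 15, width = 0.5) {
  stopifnot(max > min, min >= 0, width > 0)
  nb <- (max - min) / width
  if (abs(nb - round(nb)) > 1e-9)
    stop("(max - min) / width must be an integer number of bins")
  nb <- as.integer(round(nb))
  breaks <- min + width * (0:nb)
  structure(list(min = min, max = max, width = width, n_bins = nb,
                 breaks = breaks,
                 centers = (breaks[-1] + breaks[-(nb + 1)]) / 2),
            class = "distance_binning")
}

#' Bin index of a distance
#'
#' @param binning A [distance_binning()].
#' @param d Distances in `[min, max)` (half-open: `d == max` errors).
#' @return Integer bin indices (1-based).
#' @export
bin_of <- function(binning, d) {
  if (any(d < binning$min | d >= binning$max))
    stop("distance outside binning range [", binning$min, ", ",
         binning$max, ")")
  pmin(as.integer(floor((d - binning$min) / binning$width)) + 1L,
       binning$n_bins)
}

#' Define a reference state
#'
#' The background distance distribution observed contact frequencies
#' are compared against. `"averaged"` pools all pair types: the
#' reference of a (pair, bin) cell is the pair-type-independent distance
#' distribution scaled to that pair's total count (a row x column
#' marginal product). `"power-law"` models an ideal-gas-like density
#' growing as r^alpha with the bin-center radius, normalised per pair
#' type; it approximates DFIRE-flavoured reference states but makes no
#' claim of parameter equivalence with any published table.
#'
#' @param name `"averaged"` or `"power-law"`.
#' @param alpha Power-law exponent (> 0 required for `"power-law"`;
#'   1.61 is the conventional finite-ideal-gas value).
#' @return Object of class `reference_state`.
#' @export
reference_state <- function(name = c("averaged", "power-law"),
                            alpha = 1.61) {
  name <- match.arg(name)
  if (name == "power-law" && !(alpha > 0))
    stop("power-law reference requires alpha > 0")
  structure(list(name = name, alpha = if (name == "power-law") alpha),
            class = "reference_state")
}

#' Count contact observations over structures
#'
#' Fills the pair-type x distance-bin count table: every contact of
#' every structure increments the cell of its residue-pair type and
#' distance bin by one, then a uniform pseudocount is added to all
#' cells so downstream log-ratios stay finite.
#'
#' @param structures List of [protein_structure()].
#' @param scheme A [contact_scheme()].
#' @param binning A [distance_binning()]; its `max` must be at least the
#'   scheme cutoff.
#' @param pseudocount Added to every cell after counting.
#' @param alphabet Residue alphabet (rows are its pair types).
#' @return Matrix of pair types x bins, with attributes `pseudocount`
#'   and `raw_total` (contact count before pseudocounting).
#' @export
count_observations <- function(structures, scheme = contact_scheme(),
                               binning = distance_binning(max = scheme$cutoff),
                               pseudocount = 0.01,
                               alphabet = amino_acid_alphabet()) {
  stopifnot(length(structures) >= 1, pseudocount >= 0)
  labs <- list_pair_types(alphabet)
  counts <- matrix(0, length(labs), binning$n_bins,
                   dimnames = list(labs, NULL))
  total <- 0
  for (s in structures) {
    ct <- enumerate_contacts(s, scheme)
    if (!nrow(ct)) {
      message("structure '", s$id, "' contributed no contacts")
      next
    }
    pk <- pair_index(ct$code_i, ct$code_j, alphabet)
    bk <- bin_of(binning, ct$distance)
    tab <- table(factor(pk, levels = seq_along(labs)),
                 factor(bk, levels = seq_len(binning$n_bins)))
    counts <- counts + matrix(as.numeric(tab), nrow(counts))
    total <- total + nrow(ct)
  }
  counts <- counts + pseudocount
  attr(counts, "pseudocount") <- pseudocount
  attr(counts, "raw_total") <- total
  counts
}

#' Reference frequency table for a count table
#'
#' Both references are normalised so each pair-type row sums to that
#' pair's observed row total; count ratios then equal frequency ratios.
#'
#' @param counts Pair-type x bin count matrix (pseudocounted).
#' @param ref A [reference_state()].
#' @param binning The [distance_binning()] of `counts` (needed for the
#'   power-law radii).
#' @return Matrix of the same shape as `counts`, strictly positive.
#' @export
reference_frequencies <- function(counts, ref = reference_state(),
                                  binning = NULL) {
  g <- sum(counts)
  if (g <= 0) stop("count table has zero grand total")
  row_tot <- rowSums(counts)
  if (ref$name == "averaged") {
    col_tot <- colSums(counts)
    out <- outer(row_tot, col_tot) / g
  } else {
    if (is.null(binning))
      stop("power-law reference needs the distance binning")
    stopifnot(binning$n_bins == ncol(counts))
    w <- binning$centers^ref$alpha * binning$width
    out <- outer(row_tot, w / sum(w))
  }
  dimnames(out) <- dimnames(counts)
  out
}

#' Potential energies from observed and reference counts
#'
#' The distance-dependent knowledge-based potential: for each pair type
#' and bin, `-RT * log(observed / reference)`. Energies are in RT units
#' (RT = 1 by default); every downstream quantity -- rankings, Z-scores,
#' principal directions, contributions -- is invariant to this global
#' positive scale.
#'
#' @param counts Pair-type x bin count matrix.
#' @param ref A [reference_state()].
#' @param binning A [distance_binning()] (power-law reference only).
#' @param RT Energy scale.
#' @return Matrix of energies, same shape as `counts`.
#' @export
compute_potential <- function(counts, ref = reference_state(),
                              binning = NULL, RT = 1) {
  fr <- reference_frequencies(counts, ref, binning)
  if (any(fr <= 0)) {
    bad <- which(fr <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive reference at pair '", rownames(fr)[bad[1]],
         "', bin ", bad[2])
  }
  e <- -RT * log(counts / fr)
  # keep only the matrix structure: count-table bookkeeping attributes
  # do not belong on the energy table
  attributes(e) <- list(dim = dim(e), dimnames = dimnames(counts))
  e
}

#' Train a knowledge-based pair potential
#'
#' Fits the distance-dependent potential over all pair types from a set
#' of native structures: enumerates contacts under the scheme, bins
#' their distances, and converts observed-vs-reference frequency ratios
#' into energies. Atom pairs are typed by their residues' identities
#' only, so the atom-pair energy sum and the pair-type decomposition of
#' the total energy are exactly consistent.
#'
#' @param structures List of [protein_structure()] training natives.
#' @param scheme A [contact_scheme()].
#' @param binning A [distance_binning()] (default: width 0.5 A from 0 to
#'   the scheme cutoff).
#' @param reference A [reference_state()].
#' @param pseudocount Per-cell pseudocount.
#' @param RT Energy scale.
#' @param alphabet Residue alphabet.
#' @return Object of class `kbp`: the trained potential table plus its
#'   configuration. Use [predict.kbp()] to score structures,
#'   [pair_energy()] for single lookups, [write_kbp()] to serialise.
#' @export
#' @examples
#' ch <- generate_chain(chain_spec(length = 30, seed = 1))
#' pot <- kbp(list(ch), contact_scheme(10, 2, atom_mode = "single-center"))
#' pot
kbp <- function(structures, scheme = contact_scheme(),
                binning = distance_binning(max = scheme$cutoff),
                reference = reference_state(),
                pseudocount = 0.01, RT = 1,
                alphabet = amino_acid_alphabet()) {
  if (binning$max < scheme$cutoff)
    stop("binning must cover the scheme cutoff")
  counts <- count_observations(structures, scheme, binning, pseudocount,
                               alphabet)
  energies <- compute_potential(counts, reference, binning, RT)
  structure(list(energies = energies, counts = counts, scheme = scheme,
                 binning = binning, reference = reference,
                 pseudocount = pseudocount, RT = RT,
                 alphabet = alphabet,
                 n_structures = length(structures)),
            class = "kbp")
}

#' @export
print.kbp <- function(x, ...) {
  cat(sprintf(
    "Knowledge-based pair potential: %d pair types x %d bins (%g-%g A)\n",
    nrow(x$energies), x$binning$n_bins, x$binning$min, x$binning$max))
  cat(sprintf("  reference: %s%s; trained on %d structures, %d contacts\n",
              x$reference$name,
              if (x$reference$name == "power-law")
                sprintf(" (alpha = %g)", x$reference$alpha) else "",
              x$n_structures, attr(x$counts, "raw_total")))
  print(x$scheme)
  invisible(x)
}

#' @export
summary.kbp <- function(object, ...) {
  e <- object$energies
  cat("Energy table summary (RT units):\n")
  print(summary(as.vector(e)))
  occ <- rowSums(object$counts) - object$pseudocount * ncol(object$counts)
  cat("Pair types with zero observed contacts:", sum(occ < 0.5), "\n")
  invisible(object)
}

#' @export
coef.kbp <- function(object, ...) object$energies

#' @export
plot.kbp <- function(x, pairs = NULL, ...) {
  e <- x$energies
  if (is.null(pairs)) {
    occ <- rowSums(x$counts)
    pairs <- rownames(e)[order(occ, decreasing = TRUE)[1:min(5, nrow(e))]]
  }
  graphics::matplot(x$binning$centers, t(e[pairs, , drop = FALSE]),
                    type = "l", lty = 1, xlab = "distance (A)",
                    ylab = "energy (RT)", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = pairs, lty = 1,
                   col = seq_along(pairs), cex = 0.7, bty = "n")
  invisible(x)
}

#' Look up a pair-type energy at a distance
#'
#' Symmetric in the residue arguments; distances use the half-open bin
#' convention, so a bin's low edge returns that bin's value. Callers
#' must filter by the contact cutoff first: distances outside the
#' binning range are an error, not zero.
#'
#' @param table A [kbp()] potential.
#' @param res_a,res_b Residue codes.
#' @param d Distance(s) in Angstrom.
#' @return Energy in RT units.
#' @export
pair_energy <- function(table, res_a, res_b, d) {
  k <- pair_index(res_a, res_b, table$alphabet)
  b <- bin_of(table$binning, d)
  table$energies[cbind(k, b)]
}

#' Serialise a trained potential
#'
#' Writes a TSV (pair_label, bin_low, bin_high, energy) preceded by a
#' one-line JSON header (scheme, binning, reference, pseudocount, RT)
#' in a `#` comment, so [read_kbp()] round-trips the object.
#'
#' @param table A [kbp()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kbp <- function(table, path) {
  hdr <- jsonlite::toJSON(list(
    scheme = unclass(table$scheme),
    binning = table$binning[c("min", "max", "width")],
    reference = unclass(table$reference),
    pseudocount = table$pseudocount, RT = table$RT,
    alphabet = table$alphabet,
    n_structures = table$n_structures,
    raw_total = attr(table$counts, "raw_total")), auto_unbox = TRUE)
  b <- table$binning
  df <- data.frame(
    pair_label = rep(rownames(table$energies), b$n_bins),
    bin_low = rep(b$breaks[-(b$n_bins + 1)], each = nrow(table$energies)),
    bin_high = rep(b$breaks[-1], each = nrow(table$energies)),
    energy = sprintf("%.17g", as.vector(table$energies)),
    count = sprintf("%.17g", as.vector(table$counts)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reload a serialised potential
#'
#' @param path Path written by [write_kbp()].
#' @return A [kbp()] object reproducing the stored energies exactly.
#' @export
read_kbp <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) stop("missing JSON header in ", path)
  hdr <- jsonlite::fromJSON(sub("^#", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  binning <- distance_binning(hdr$binning$min, hdr$binning$max,
                              hdr$binning$width)
  labs <- list_pair_types(hdr$alphabet)
  energies <- matrix(df$energy, length(labs), binning$n_bins,
                     dimnames = list(labs, NULL))
  counts <- matrix(df$count, length(labs), binning$n_bins,
                   dimnames = list(labs, NULL))
  attr(counts, "pseudocount") <- hdr$pseudocount
  attr(counts, "raw_total") <- hdr$raw_total
  ref <- if (hdr$reference$name == "power-law")
    reference_state("power-law", hdr$reference$alpha)
  else reference_state("averaged")
  structure(list(
    energies = energies, counts = counts,
    scheme = contact_scheme(hdr$scheme$cutoff, hdr$scheme$min_seq_sep,
                            hdr$scheme$use_tessellation,
                            hdr$scheme$atom_mode),
    binning = binning, reference = ref,
    pseudocount = hdr$pseudocount, RT = hdr$RT,
    alphabet = hdr$alphabet, n_structures = hdr$n_structures),
    class = "kbp")
}
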