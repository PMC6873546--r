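#' Pair-type energy vector of a structure
#'
#' Decomposes a structure's total potential into its pair-type
#' components: element k is the sum of the trained potential over all
#' contacts whose residue pair has pair index k. Contacts are
#' enumerated once per unordered atom pair, so the sum of the vector is
#' the structure's total energy.
#'
#' @param s A [protein_structure()].
#' @param table A [kbp()] potential.
#' @return Named numeric vector, one element per pair type, with
#'   attribute `structure_id`.
#' @export
interaction_energy_vector <- function(s, table) {
  labs <- rownames(table$energies)
  v <- stats::setNames(numeric(length(labs)), labs)
  ct <- enumerate_contacts(s, table$scheme)
  if (nrow(ct)) {
    k <- pair_index(ct$code_i, ct$code_j, table$alphabet)
    e <- pair_energy(table, ct$code_i, ct$code_j, ct$distance)
    agg <- rowsum(e, k)
    v[as.integer(rownames(agg))] <- agg[, 1]
  }
  attr(v, "structure_id") <- s$id
  v
}

#' Total energy of a structure
#'
#' Sum of the pair-type energy vector; identical to summing the
#' potential directly over the structure's contacts (the 1/2 of the
#' double-sum form is realised by unordered contact enumeration).
#'
#' @param v An energy vector from [interaction_energy_vector()], or a
#'   structure (with `table`) to score directly.
#' @param table A [kbp()] potential, when `v` is a structure.
#' @return Energy in RT units.
#' @export
total_energy <- function(v, table = NULL) {
  if (inherits(v, "protein_structure")) {
    stopifnot(!is.null(table))
    v <- interaction_energy_vector(v, table)
  }
  sum(v)
}

#' Assemble the structures-by-pair-types energy matrix (TE)
#'
#' Row i is the pair-type energy vector of structure i; columns follow
#' the canonical pair-type order. Row sums equal total energies.
#'
#' @param structures List of [protein_structure()] with distinct ids.
#' @param table A [kbp()] potential.
#' @return Numeric matrix (n x p) with structure ids as row names and
#'   pair labels as column names; attribute `centered` is FALSE.
#' @export
build_te_matrix <- function(structures, table) {
  stopifnot(length(structures) >= 1)
  ids <- vapply(structures, function(s) s$id, "")
  if (anyDuplicated(ids))
    stop("duplicate structure ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- t(vapply(structures, interaction_energy_vector,
                numeric(nrow(table$energies)), table = table))
  rownames(m) <- ids
  attr(m, "centered") <- FALSE
  m
}

#' Center the energy matrix (TE -> CTE)
#'
#' Subtracts each column's mean so the covariance of the centered
#' matrix is well defined. A row-centering mode (subtracting each
#' structure's mean energy instead) is exposed but the selection
#' machinery expects column centering.
#'
#' @param m Energy matrix with at least 2 rows.
#' @param mode `"column"` (default) or `"row"`.
#' @return Centered matrix; attribute `centered` is TRUE for column
#'   mode. Re-centering a centered matrix is the identity.
#' @export
center_columns <- function(m, mode = c("column", "row")) {
  mode <- match.arg(mode)
  if (nrow(m) < 2)
    stop("need at least 2 rows to center (covariance undefined for n < 2)")
  if (mode == "column") {
    out <- sweep(m, 2, colMeans(m))
    attr(out, "centered") <- TRUE
  } else {
    out <- sweep(m, 1, rowMeans(m))
    attr(out, "centered") <- FALSE
  }
  out
}

#' Write / read an energy matrix as TSV
#'
#' Header row of pair labels, first column of structure ids.
#'
#' @param m Energy matrix.
#' @param path File path.
#' @return `path` / the matrix.
#' @export
write_energy_matrix <- function(m, path) {
  df <- data.frame(structure_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_energy_matrix
#' @export
read_energy_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  attr(m, "centered") <- max(abs(colMeans(m))) < 1e-8
  m
}
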