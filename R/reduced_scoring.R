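#' Interaction mask
#'
#' A designated subset of pair types; scoring with a mask ignores every
#' contact whose residue-pair type falls outside it (the reduced,
#' principal-only model).
#'
#' @param selected Character vector of pair labels.
#' @param source Provenance string (e.g. a selection run id).
#' @param alphabet Alphabet defining the admissible labels.
#' @return Object of class `interaction_mask`.
#' @export
interaction_mask <- function(selected, source = "manual",
                             alphabet = amino_acid_alphabet()) {
  labs <- list_pair_types(alphabet)
  selected <- unique(selected)
  bad <- setdiff(selected, labs)
  if (length(bad))
    stop("labels outside the canonical pair types: ",
         paste(bad, collapse = ", "))
  if (!length(selected)) stop("empty interaction mask")
  structure(list(selected = selected, source = source,
                 alphabet = alphabet),
            class = "interaction_mask")
}

#' @export
print.interaction_mask <- function(x, ...) {
  cat("Interaction mask (", x$source, "): ", length(x$selected), " of ",
      length(list_pair_types(x$alphabet)), " pair types\n", sep = "")
  invisible(x)
}

#' Read / write a mask file
#'
#' One pair label per line; `#` comments and blank lines are ignored.
#'
#' @param path File path.
#' @param mask An [interaction_mask()] (for writing).
#' @return The mask / `path`.
#' @export
read_mask <- function(path) {
  lines <- trimws(sub("#.*", "", readLines(path)))
  interaction_mask(lines[nzchar(lines)], source = path)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  writeLines(c(paste("#", mask$source), mask$selected), path)
  invisible(path)
}

#' Mask from a selection result
#'
#' @param sel A [select_principal()] result.
#' @return An [interaction_mask()] of the principal set.
#' @export
mask_from_selection <- function(sel) {
  interaction_mask(sel$principal_set,
                   source = sprintf("pi_selection (m=%d, tau=%.4g)",
                                    sel$m, sel$tau))
}

#' Reduced (masked) energy of a structure
#'
#' Sum of the pair-type energy vector over the masked types only. By
#' linearity this equals scoring with the potential restricted to the
#' mask; with the full mask it equals [total_energy()] exactly.
#'
#' @param s A [protein_structure()] or a precomputed energy vector.
#' @param table A [kbp()] potential.
#' @param mask An [interaction_mask()].
#' @return Energy in RT units.
#' @export
reduced_energy <- function(s, table, mask) {
  stopifnot(inherits(mask, "interaction_mask"))
  v <- if (inherits(s, "protein_structure"))
    interaction_energy_vector(s, table) else s
  sum(v[mask$selected])
}

#' Fraction of contacts covered by a mask (PI)
#'
#' Share of the structure's atomic contacts (under the potential's full
#' contact scheme) whose residue-pair type belongs to the mask. This is
#' a contact count ratio, not an energy ratio, and the denominator is
#' every contact passing the full scheme.
#'
#' @param s A [protein_structure()].
#' @param table A [kbp()] potential.
#' @param mask An [interaction_mask()].
#' @return Fraction in `[0, 1]`.
#' @export
pi_fraction <- function(s, table, mask) {
  ct <- enumerate_contacts(s, table$scheme)
  if (!nrow(ct))
    stop("structure '", s$id, "' has no contacts; PI undefined")
  labs <- pair_label(ct$code_i, ct$code_j, table$alphabet)
  mean(labs %in% mask$selected)
}

#' Score structures with a trained potential
#'
#' @param object A [kbp()] potential.
#' @param structures A structure or list of structures.
#' @param mask Optional [interaction_mask()] restricting the pair types.
#' @param type `"total"` for energies, `"vector"` for the n x p energy
#'   matrix.
#' @param ... Unused.
#' @return Numeric vector of energies, or an energy matrix.
#' @export
predict.kbp <- function(object, structures, mask = NULL,
                        type = c("total", "vector"), ...) {
  type <- match.arg(type)
  if (inherits(structures, "protein_structure"))
    structures <- list(structures)
  vecs <- t(vapply(structures, interaction_energy_vector,
                   numeric(nrow(object$energies)), table = object))
  rownames(vecs) <- vapply(structures, function(s) s$id, "")
  if (type == "vector") return(vecs)
  if (is.null(mask)) rowSums(vecs)
  else rowSums(vecs[, mask$selected, drop = FALSE])
}
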