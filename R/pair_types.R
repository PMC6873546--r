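#' Standard amino-acid alphabet
#'
#' The 20 standard amino acids as three-letter codes, in a fixed
#' alphabetical order. All pair-type indexing in the package is defined
#' relative to this ordering, so tabular outputs are deterministic.
#'
#' @return Character vector of 20 three-letter residue codes.
#' @export
#' @examples
#' amino_acid_alphabet()
amino_acid_alphabet <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# Nonstandard residue codes mapped onto the standard alphabet before
# typing. Anything not in the alphabet after mapping is skipped upstream.
.nonstandard_map <- c(MSE = "MET")

#' Map a residue code into the standard alphabet
#'
#' Applies the nonstandard-residue mapping (currently MSE -> MET) and
#' returns NA for codes that remain outside the alphabet.
#'
#' @param code Character vector of three-letter residue codes.
#' @return Character vector, NA where the code is not representable.
#' @export
map_residue_code <- function(code) {
  code <- toupper(code)
  mapped <- ifelse(code %in% names(.nonstandard_map),
                   unname(.nonstandard_map[code]), code)
  ifelse(mapped %in% amino_acid_alphabet(), mapped, NA_character_)
}

#' Enumerate unordered amino-acid pair types
#'
#' For the 20-letter alphabet there are 20*21/2 = 210 unordered pair
#' types (self-pairs included). Labels are `"ALA-ALA"`, `"ALA-ARG"`, ...
#' with the alphabetically earlier code first; ordering is
#' lexicographic in (first, second), so the first label is the self-pair
#' of the first alphabet entry.
#'
#' @param alphabet Character vector of residue codes; defaults to the
#'   standard 20. A reduced alphabet is accepted (k codes give
#'   k(k+1)/2 labels), which the selection machinery also supports.
#' @return Character vector of pair labels.
#' @export
#' @examples
#' length(list_pair_types())  # 210
#' list_pair_types(c("ALA", "CYS", "GLY"))
list_pair_types <- function(alphabet = amino_acid_alphabet()) {
  stopifnot(!anyDuplicated(alphabet))
  k <- length(alphabet)
  labs <- character(k * (k + 1L) / 2L)
  n <- 0L
  for (a in seq_len(k)) {
    for (b in a:k) {
      n <- n + 1L
      labs[n] <- paste0(alphabet[a], "-", alphabet[b])
    }
  }
  labs
}

#' Index of an unordered residue pair
#'
#' Symmetric 1-based index into the canonical pair-type ordering of
#' [list_pair_types()]: `pair_index(a, b) == pair_index(b, a)`, and the
#' indices of all ordered pairs cover `1..k(k+1)/2` exactly.
#'
#' @param res_a,res_b Three-letter residue codes (vectorised).
#' @param alphabet Alphabet defining the ordering.
#' @return Integer vector of indices in `[1, k(k+1)/2]`.
#' @export
#' @examples
#' pair_index("ALA", "GLY") == pair_index("GLY", "ALA")
pair_index <- function(res_a, res_b, alphabet = amino_acid_alphabet()) {
  k <- length(alphabet)
  ia <- match(res_a, alphabet)
  ib <- match(res_b, alphabet)
  bad <- unique(c(res_a[is.na(ia)], res_b[is.na(ib)]))
  if (length(bad))
    stop("residue code(s) not in alphabet: ", paste(bad, collapse = ", "))
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  # row lo starts after (lo-1) rows of lengths k, k-1, ...
  as.integer((lo - 1L) * k - (lo - 1L) * (lo - 2L) / 2L + (hi - lo + 1L))
}

#' Label of an unordered residue pair
#'
#' @inheritParams pair_index
#' @return Character vector of `"AAA-BBB"` labels, earlier code first.
#' @export
pair_label <- function(res_a, res_b, alphabet = amino_acid_alphabet()) {
  list_pair_types(alphabet)[pair_index(res_a, res_b, alphabet)]
}
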