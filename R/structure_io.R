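#' Construct a protein structure object
#'
#' Internal container used throughout the package: a single chain of
#' residues with heavy-atom coordinates. Residues are renumbered 0-based
#' and gap-free after parsing (sequence-separation filters need
#' contiguous indices); author-assigned PDB residue numbers survive only
#' as labels in `atoms$resno_label`.
#'
#' @param id Structure identifier.
#' @param chain_id Chain identifier.
#' @param atoms data.frame with columns `res_idx` (0-based residue
#'   index), `res_code` (three-letter code, already mapped into the
#'   alphabet), `atom_name`, `element`, `x`, `y`, `z`, `occupancy`.
#' @return Object of class `protein_structure`.
#' @export
protein_structure <- function(id, chain_id, atoms) {
  need <- c("res_idx", "res_code", "atom_name", "element", "x", "y", "z",
            "occupancy")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates in structure '", id, "'")
  atoms <- atoms[order(atoms$res_idx), , drop = FALSE]
  rownames(atoms) <- NULL
  res <- atoms[!duplicated(atoms$res_idx), c("res_idx", "res_code")]
  structure(
    list(id = id, chain_id = chain_id, atoms = atoms,
         res_codes = res$res_code, n_res = nrow(res)),
    class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("Protein structure '", x$id, "' chain ", x$chain_id, ": ",
      x$n_res, " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Read a single chain from a PDB file
#'
#' Parses ATOM records (plus HETATM selenomethionine, mapped to MET) of
#' the first MODEL via \pkg{bio3d}, keeping one chain. Waters and other
#' hetero records are excluded, hydrogens dropped, altloc duplicates
#' resolved to the highest-occupancy conformer, residues outside the
#' 20-letter alphabet (after nonstandard mapping) skipped with a
#' warning, and residues left without heavy atoms dropped.
#'
#' @param path PDB file path.
#' @param chain Chain identifier; default the first chain in the file.
#' @param id Structure id; defaults to the file base name.
#' @return A [protein_structure()].
#' @export
read_pdb <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" | at$resid == "MSE", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in '", path, "'")
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop("chain '", chain, "' not in '", path, "'; available: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  # hydrogens out
  elem <- toupper(trimws(at$elesy))
  elem[is.na(elem) | elem == ""] <- substr(gsub("[^A-Za-z].*", "",
                                                trimws(at$elety)), 1, 1)[
                                      is.na(elem) | elem == ""]
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  # altloc: keep highest occupancy per (residue, atom name)
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$resno, at$insert, at$elety)
  occ <- at$o
  occ[is.na(occ)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(at)), key),
                        function(i) i[which.max(occ[i])]), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  code <- map_residue_code(at$resid)
  if (anyNA(code)) {
    skipped <- unique(at$resid[is.na(code)])
    warning("skipping residues outside the standard alphabet: ",
            paste(skipped, collapse = ", "))
    at <- at[!is.na(code), , drop = FALSE]
    code <- code[!is.na(code)]
  }
  if (!nrow(at)) stop("no alphabet residues left in '", path, "'")
  rkey <- paste(at$resno, at$insert, sep = "_")
  res_idx <- as.integer(factor(rkey, levels = unique(rkey))) - 1L
  atoms <- data.frame(
    res_idx = res_idx, res_code = code,
    atom_name = trimws(at$elety), element = toupper(trimws(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    resno_label = at$resno, stringsAsFactors = FALSE)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  protein_structure(id, chain, atoms)
}

#' Write a structure as a PDB file
#'
#' Emits plain single-chain ATOM records so generated fixtures can
#' exercise the same I/O path as experimental files.
#'
#' @param s A [protein_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  name <- ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name),
                 a$atom_name)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name, "", a$res_code,
    substr(s$chain_id, 1, 1), a$res_idx + 1L, "",
    a$x, a$y, a$z, a$occupancy, 0,
    ifelse(is.na(a$element) | a$element == "",
           substr(a$atom_name, 1, 1), a$element))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Define a contact scheme
#'
#' A contact scheme fixes which atom pairs of a structure count as
#' interacting: a hard distance cutoff, a minimum sequence separation
#' (exclusive: a contact requires `|i - j| > min_seq_sep` residues), an
#' optional Delaunay-tessellation edge filter, and the per-residue atom
#' mode. Two presets mirror common potentials: `"dbni-like"` (6 A
#' cutoff, non-local only with separation > 5, tessellation on) and
#' `"dfire-like"` (15 A cutoff, no separation filter, tessellation off).
#'
#' @param cutoff Distance cutoff in Angstrom (strict: `d < cutoff`).
#' @param min_seq_sep Minimum residue separation, exclusive threshold.
#' @param use_tessellation Keep only atom pairs sharing a Delaunay edge.
#' @param atom_mode `"all-heavy"` or `"single-center"` (C-beta, C-alpha
#'   for glycine).
#' @return Object of class `contact_scheme`.
#' @export
#' @examples
#' contact_scheme_preset("dbni-like")
contact_scheme <- function(cutoff = 15, min_seq_sep = 0,
                           use_tessellation = FALSE,
                           atom_mode = c("all-heavy", "single-center")) {
  atom_mode <- match.arg(atom_mode)
  stopifnot(cutoff > 0, min_seq_sep >= 0)
  structure(list(cutoff = cutoff, min_seq_sep = as.integer(min_seq_sep),
                 use_tessellation = isTRUE(use_tessellation),
                 atom_mode = atom_mode),
            class = "contact_scheme")
}

#' @rdname contact_scheme
#' @param name Preset name.
#' @export
contact_scheme_preset <- function(name = c("dbni-like", "dfire-like")) {
  switch(match.arg(name),
    "dbni-like"  = contact_scheme(6, 5, TRUE, "all-heavy"),
    "dfire-like" = contact_scheme(15, 0, FALSE, "all-heavy"))
}

#' @export
print.contact_scheme <- function(x, ...) {
  cat(sprintf(
    "Contact scheme: d < %g A, |seq sep| > %d, tessellation %s, atoms %s\n",
    x$cutoff, x$min_seq_sep, if (x$use_tessellation) "on" else "off",
    x$atom_mode))
  invisible(x)
}

# Interaction-center atom table under the scheme's atom mode.
.scheme_atoms <- function(s, scheme) {
  a <- s$atoms
  if (scheme$atom_mode == "single-center") {
    pick <- function(i) {
      sub <- a[a$res_idx == i, , drop = FALSE]
      want <- if (sub$res_code[1] == "GLY") "CA" else "CB"
      j <- match(want, sub$atom_name)
      if (is.na(j)) j <- match("CA", sub$atom_name)
      if (is.na(j)) j <- 1L
      sub[j, , drop = FALSE]
    }
    a <- do.call(rbind, lapply(unique(a$res_idx), pick))
    rownames(a) <- NULL
  }
  a
}

#' Enumerate atomic contacts of a structure
#'
#' Lists every unordered atom pair satisfying the scheme (each pair once
#' -- this realises the 1/2 factor of the total-potential sum). When
#' the scheme's tessellation flag is set, pairs must additionally share
#' an edge of the 3-D Delaunay tessellation of the interaction centers;
#' the tessellation can only remove contacts.
#'
#' @param s A [protein_structure()].
#' @param scheme A [contact_scheme()].
#' @return data.frame with columns `res_i`, `res_j` (0-based residue
#'   indices, `res_i < res_j` or equal residue with distinct atoms),
#'   `code_i`, `code_j`, `atom_i`, `atom_j` (row indices into the
#'   center-atom table), `distance`.
#' @export
enumerate_contacts <- function(s, scheme = contact_scheme()) {
  a <- .scheme_atoms(s, scheme)
  if (s$n_res < 2) {
    message("structure '", s$id, "' has < 2 residues; no contacts")
    return(.empty_contacts())
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(a$res_idx, a$res_idx, "-"))
  ok <- upper.tri(d) & d < scheme$cutoff & sep > scheme$min_seq_sep
  if (scheme$use_tessellation) {
    edges <- delaunay_edges(xyz)
    emask <- matrix(FALSE, n, n)
    if (nrow(edges)) emask[edges] <- TRUE
    ok <- ok & (emask | t(emask))
  }
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) return(.empty_contacts())
  i <- idx[, 1]; j <- idx[, 2]
  out <- data.frame(
    res_i = a$res_idx[i], res_j = a$res_idx[j],
    code_i = a$res_code[i], code_j = a$res_code[j],
    atom_i = i, atom_j = j, distance = d[idx],
    stringsAsFactors = FALSE)
  out[order(out$res_i, out$res_j, out$atom_i, out$atom_j), , drop = FALSE]
}

.empty_contacts <- function() {
  data.frame(res_i = integer(), res_j = integer(),
             code_i = character(), code_j = character(),
             atom_i = integer(), atom_j = integer(),
             distance = numeric(), stringsAsFactors = FALSE)
}

#' C-alpha RMSD between two conformations
#'
#' Pairs residues by position (residues lacking a C-alpha in either
#' structure are excluded pairwise) and returns the root-mean-square
#' deviation, by default after optimal least-squares rigid-body
#' superposition (Kabsch). Decoys are not guaranteed pre-aligned to
#' their native, hence the superposed default; `superpose = FALSE`
#' compares coordinates as given.
#'
#' @param a,b [protein_structure()] objects with equal residue counts.
#' @param superpose Apply optimal rigid-body superposition first.
#' @return RMSD in Angstrom.
#' @export
calpha_rmsd <- function(a, b, superpose = TRUE) {
  ca <- function(s) {
    at <- s$atoms[s$atoms$atom_name == "CA", , drop = FALSE]
    m <- as.matrix(at[, c("x", "y", "z")])
    rownames(m) <- at$res_idx
    m
  }
  ma <- ca(a); mb <- ca(b)
  if (a$n_res != b$n_res)
    stop("residue count mismatch: ", a$n_res, " vs ", b$n_res)
  common <- intersect(rownames(ma), rownames(mb))
  if (length(common) < 1) stop("no paired C-alpha atoms")
  ma <- ma[common, , drop = FALSE]
  mb <- mb[common, , drop = FALSE]
  if (superpose) mb <- kabsch_fit(mb, ma)
  sqrt(mean(rowSums((ma - mb)^2)))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Rotates and translates `x` onto `target` minimising the sum of
#' squared deviations, with the SVD-based reflection guard.
#'
#' @param x,target n x 3 coordinate matrices, rows paired.
#' @return Transformed copy of `x`.
#' @export
kabsch_fit <- function(x, target) {
  stopifnot(ncol(x) == 3, dim(x) == dim(target))
  cx <- colMeans(x); ct <- colMeans(target)
  x0 <- sweep(x, 2, cx); t0 <- sweep(target, 2, ct)
  s <- svd(crossprod(x0, t0))
  dsign <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, dsign)) %*% t(s$v)
  sweep(x0 %*% rot, 2, ct, "+")
}

#' Read a decoy set from a directory
#'
#' Expects `native.pdb` plus any number of decoy PDB files in one
#' directory. An optional tab-separated `rmsd.tsv` (columns: decoy file
#' name, C-alpha RMSD) overrides internal superposition RMSDs, so
#' published decoy-set tables can be honoured exactly.
#'
#' @param dir Directory path.
#' @param chain Optional chain id passed to [read_pdb()].
#' @return A [decoy_set()].
#' @export
read_decoy_set <- function(dir, chain = NULL) {
  nat_path <- file.path(dir, "native.pdb")
  if (!file.exists(nat_path)) stop("no native.pdb in ", dir)
  native <- read_pdb(nat_path, chain = chain, id = basename(dir))
  files <- setdiff(list.files(dir, pattern = "\\.pdb$"), "native.pdb")
  if (!length(files)) stop("no decoy PDB files in ", dir)
  decoys <- lapply(file.path(dir, files), read_pdb, chain = chain)
  rmsd <- rep(NA_real_, length(files))
  rtab_path <- file.path(dir, "rmsd.tsv")
  if (file.exists(rtab_path)) {
    rtab <- utils::read.table(rtab_path, header = FALSE, sep = "\t",
                              col.names = c("file", "rmsd"),
                              stringsAsFactors = FALSE)
    rmsd <- rtab$rmsd[match(files, rtab$file)]
  }
  decoy_set(basename(dir), native, decoys, rmsd)
}

#' Assemble a decoy set
#'
#' A native structure plus alternative conformations of the same
#' sequence, optionally with externally provided C-alpha RMSDs (missing
#' entries are computed by superposition on demand).
#'
#' @param target_id Target identifier.
#' @param native Native [protein_structure()].
#' @param decoys List of decoy structures.
#' @param rmsd Optional numeric vector of provided RMSDs (NA = compute).
#' @return Object of class `decoy_set`.
#' @export
decoy_set <- function(target_id, native, decoys, rmsd = NULL) {
  stopifnot(inherits(native, "protein_structure"), length(decoys) >= 1)
  if (is.null(rmsd)) rmsd <- rep(NA_real_, length(decoys))
  stopifnot(length(rmsd) == length(decoys))
  if (any(rmsd < 0, na.rm = TRUE)) stop("negative provided RMSD")
  structure(list(target_id = target_id, native = native,
                 decoys = decoys, rmsd = rmsd),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat("Decoy set '", x$target_id, "': ", length(x$decoys),
      " decoys, native of ", x$native$n_res, " residues\n", sep = "")
  invisible(x)
}

#' Decoy RMSDs of a set
#'
#' Provided values where available, superposed C-alpha RMSD otherwise.
#'
#' @param ds A [decoy_set()].
#' @return Numeric vector, one RMSD per decoy.
#' @export
decoy_rmsds <- function(ds) {
  r <- ds$rmsd
  for (k in which(is.na(r))) r[k] <- calpha_rmsd(ds$native, ds$decoys[[k]])
  r
}
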