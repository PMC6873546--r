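#' Specification of a synthetic chain
#'
#' Parameters of the compact self-avoiding random walk used as a
#' stand-in for native single-domain chains: consecutive residues at a
#' fixed virtual bond length (3.8 A, the C-alpha - C-alpha spacing),
#' an excluded-volume radius no two non-consecutive residues may
#' violate, and confinement to a sphere whose radius grows with the
#' cube root of chain length (globular scaling), which forces the
#' non-local contacts a contact potential needs.
#'
#' @param length Residue count (>= 5).
#' @param sequence_mode `"random"` (uniform over the alphabet) or
#'   `"fixed"` (with `sequence` supplied).
#' @param sequence Optional residue-code vector for `"fixed"` mode.
#' @param bond_length Consecutive-residue spacing in Angstrom.
#' @param excluded_volume_radius Minimum non-consecutive distance.
#' @param compactness Confinement radius multiplier on
#'   `bond_length * length^(1/3)`. The default 0.8 reproduces the
#'   packing density of globular proteins (about 110 cubic Angstrom
#'   per residue).
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return Object of class `chain_spec`.
#' @export
chain_spec <- function(length, sequence_mode = c("random", "fixed"),
                       sequence = NULL, bond_length = 3.8,
                       excluded_volume_radius = 3.5,
                       compactness = 0.8, seed = 1) {
  sequence_mode <- match.arg(sequence_mode)
  stopifnot(length >= 5, bond_length > 0,
            excluded_volume_radius > 0, compactness > 0)
  if (sequence_mode == "fixed")
    stopifnot(base::length(sequence) == length,
              all(sequence %in% amino_acid_alphabet()))
  structure(list(length = as.integer(length),
                 sequence_mode = sequence_mode, sequence = sequence,
                 bond_length = bond_length,
                 excluded_volume_radius = excluded_volume_radius,
                 compactness = compactness, seed = as.integer(seed)),
            class = "chain_spec")
}

#' Generate a compact self-avoiding chain
#'
#' Single-center residues (one C-alpha pseudo-atom each) placed by a
#' confined self-avoiding walk; deterministic for a given spec.
#'
#' @param spec A [chain_spec()].
#' @param id Structure id.
#' @return A [protein_structure()].
#' @export
#' @examples
#' ch <- generate_chain(chain_spec(length = 20, seed = 42))
#' ch
generate_chain <- function(spec, id = sprintf("syn%04d", spec$seed)) {
  with_seed(spec$seed, {
    n <- spec$length
    rmax <- spec$compactness * spec$bond_length * n^(1 / 3)
    coords <- NULL
    for (attempt in 1:200) {
      coords <- .grow_chain(n, spec$bond_length,
                            spec$excluded_volume_radius, rmax)
      if (!is.null(coords)) break
    }
    if (is.null(coords))
      stop("chain placement failed after bounded retries; relax the ",
           "excluded-volume radius or compactness")
    seq_codes <- if (spec$sequence_mode == "fixed") spec$sequence
      else sample(amino_acid_alphabet(), n, replace = TRUE)
    protein_structure(id, "A", data.frame(
      res_idx = 0:(n - 1L), res_code = seq_codes,
      atom_name = "CA", element = "C",
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      occupancy = 1, stringsAsFactors = FALSE))
  })
}

# one attempt at a confined self-avoiding walk; NULL on dead end
.grow_chain <- function(n, bond, excl, rmax) {
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    placed <- FALSE
    for (try in 1:100) {
      u <- stats::rnorm(3)
      step <- u / sqrt(sum(u^2)) * bond
      cand <- xyz[i - 1, ] + step
      ctr <- colMeans(xyz[seq_len(i - 1), , drop = FALSE])
      if (sqrt(sum((cand - ctr)^2)) > rmax) next
      if (i > 2) {
        d2 <- rowSums(sweep(xyz[seq_len(i - 2), , drop = FALSE], 2,
                            cand)^2)
        if (any(d2 < excl^2)) next
      }
      xyz[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  xyz
}

#' Specification of a decoy ladder
#'
#' Controlled coordinate perturbation of a native: decoy d adds
#' isotropic Gaussian noise of standard deviation `noise_sds[d]` to
#' every coordinate, giving a ladder of decoys whose RMSDs increase
#' stochastically with the noise level (emulating decoy sets with
#' RMSDs spread evenly from near-native to very different).
#'
#' @param n_decoys Number of decoys.
#' @param noise_sds Per-decoy noise standard deviations (Angstrom),
#'   length `n_decoys`, all >= 0.
#' @param seed RNG seed.
#' @return Object of class `decoy_ladder_spec`.
#' @export
decoy_ladder_spec <- function(n_decoys,
                              noise_sds = seq(0.5, 5,
                                              length.out = n_decoys),
                              seed = 1) {
  stopifnot(length(noise_sds) == n_decoys, all(noise_sds >= 0))
  structure(list(n_decoys = as.integer(n_decoys),
                 noise_sds = noise_sds, seed = as.integer(seed)),
            class = "decoy_ladder_spec")
}

#' Generate a decoy ladder by coordinate perturbation
#'
#' @param native A [protein_structure()].
#' @param spec A [decoy_ladder_spec()].
#' @return A [decoy_set()] whose provided RMSDs are the realised
#'   superposed C-alpha RMSDs of the perturbed copies.
#' @export
generate_decoy_ladder <- function(native, spec) {
  with_seed(spec$seed, {
    decoys <- vector("list", spec$n_decoys)
    rmsd <- numeric(spec$n_decoys)
    for (d in seq_len(spec$n_decoys)) {
      a <- native$atoms
      noise <- matrix(stats::rnorm(3 * nrow(a), sd = spec$noise_sds[d]),
                      ncol = 3)
      a$x <- a$x + noise[, 1]
      a$y <- a$y + noise[, 2]
      a$z <- a$z + noise[, 3]
      dec <- protein_structure(sprintf("%s_d%03d", native$id, d),
                               native$chain_id, a)
      decoys[[d]] <- dec
      rmsd[d] <- calpha_rmsd(native, dec)
    }
    decoy_set(native$id, native, decoys, rmsd)
  })
}

#' Specification of a planted-variance matrix
#'
#' Test harness for the selection machinery: independent Gaussian
#' columns where a designated subset carries a larger standard
#' deviation, mimicking the covariance structure the selection assumes
#' (a few high-variance energy components over a noise floor).
#'
#' @param n_rows Sample count.
#' @param p Variable count (default 210).
#' @param planted_indices Indices (1-based) of the high-variance
#'   columns.
#' @param planted_sd,background_sd Column standard deviations;
#'   `planted_sd > background_sd > 0`.
#' @param seed RNG seed.
#' @return Object of class `planted_matrix_spec`.
#' @export
planted_matrix_spec <- function(n_rows, p = 210, planted_indices,
                                planted_sd, background_sd, seed = 1) {
  stopifnot(planted_sd > background_sd, background_sd > 0,
            all(planted_indices >= 1), all(planted_indices <= p))
  structure(list(n_rows = as.integer(n_rows), p = as.integer(p),
                 planted_indices = as.integer(planted_indices),
                 planted_sd = planted_sd, background_sd = background_sd,
                 seed = as.integer(seed)),
            class = "planted_matrix_spec")
}

#' Generate a planted-variance energy matrix
#'
#' @param spec A [planted_matrix_spec()].
#' @return n x p matrix with canonical pair labels as column names
#'   (the first p labels when p < 210, generic labels beyond).
#' @export
generate_planted_matrix <- function(spec) {
  with_seed(spec$seed, {
    sds <- rep(spec$background_sd, spec$p)
    sds[spec$planted_indices] <- spec$planted_sd
    m <- matrix(stats::rnorm(spec$n_rows * spec$p), spec$n_rows, spec$p)
    m <- sweep(m, 2, sds, "*")
    canon <- list_pair_types()
    colnames(m) <- if (spec$p <= length(canon)) canon[seq_len(spec$p)]
      else c(canon, sprintf("X%03d", seq_len(spec$p - length(canon))))
    rownames(m) <- sprintf("s%04d", seq_len(spec$n_rows))
    attr(m, "centered") <- FALSE
    m
  })
}

#' End-to-end synthetic benchmark
#'
#' Runs the whole method on generated data: train natives -> trained
#' potential -> energy matrix -> principal-interaction selection ->
#' full- and reduced-model evaluation on generated decoy ladders.
#' Deterministic for a given seed; every stage's sub-seed is derived
#' from `seed`.
#'
#' @param seed Master seed.
#' @param n_train Training natives.
#' @param chain_length Residues per generated chain.
#' @param n_targets Decoy-set targets (generated independently of the
#'   training natives).
#' @param n_decoys Decoys per target.
#' @param noise_sds Per-decoy perturbation ladder (Angstrom).
#' @param scheme Contact scheme; default single-center, 15 A cutoff,
#'   sequence separation > 2. The cutoff deliberately exceeds the
#'   radius of the generated chains: energies then reward native-like
#'   mid-range packing against the ideal-gas reference and penalise
#'   the expansion that coordinate noise causes.
#' @param binning Distance binning; 3 A bins keep per-pair-type counts
#'   dense enough at this training scale.
#' @param reference Reference state; the ideal-gas power law
#'   (alpha = 2, uniform density) keeps the pooled packing signal that
#'   the averaged reference would divide out.
#' @param pseudocount Per-cell pseudocount for the potential.
#' @param threshold_percent Variance threshold of the selection.
#' @param curve Also compute the success-rate-vs-ranked-interactions
#'   curve (costlier).
#' @return List with `potential`, `te`, `selection`, `mask`,
#'   `eval_full`, `eval_reduced`, and optionally `curve`.
#' @export
synthetic_benchmark <- function(seed = 1, n_train = 20,
                                chain_length = 30, n_targets = 10,
                                n_decoys = 20,
                                noise_sds = seq(0.5, 5,
                                                length.out = n_decoys),
                                scheme = contact_scheme(
                                  15, 2, atom_mode = "single-center"),
                                binning = distance_binning(
                                  0, scheme$cutoff, 3),
                                reference = reference_state(
                                  "power-law", 2),
                                pseudocount = 0.1,
                                threshold_percent = 80,
                                curve = FALSE) {
  sub <- with_seed(seed,
                   sample.int(.Machine$integer.max,
                              n_train + 2 * n_targets))
  train <- lapply(seq_len(n_train), function(i)
    generate_chain(chain_spec(chain_length, seed = sub[i]),
                   id = sprintf("train%03d", i)))
  pot <- kbp(train, scheme, binning, reference, pseudocount)
  te <- build_te_matrix(train, pot)
  sel <- select_principal(te, threshold_percent)
  mask <- mask_from_selection(sel)
  sets <- lapply(seq_len(n_targets), function(i) {
    nat <- generate_chain(chain_spec(chain_length,
                                     seed = sub[n_train + i]),
                          id = sprintf("target%03d", i))
    generate_decoy_ladder(nat, decoy_ladder_spec(
      n_decoys, noise_sds, seed = sub[n_train + n_targets + i]))
  })
  out <- list(potential = pot, te = te, selection = sel, mask = mask,
              eval_full = evaluate_collection(sets, pot),
              eval_reduced = evaluate_collection(sets, pot, mask),
              sets = sets)
  if (curve)
    out$curve <- success_curve(sets, pot, sel$ranked_variables)
  out
}
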