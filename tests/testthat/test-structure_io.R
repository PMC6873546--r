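test_that("PDB parsing keeps one chain, resolves altlocs, maps MSE", {
  p <- write_minimal_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- read_pdb(p)
  expect_s3_class(s, "protein_structure")
  expect_equal(s$n_res, 2)
  expect_identical(s$res_codes, c("ALA", "GLY"))

  p2 <- write_altloc_pdb(withr::local_tempfile(fileext = ".pdb"))
  s2 <- read_pdb(p2)
  ca <- s2$atoms[s2$atoms$res_idx == 0 & s2$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$occupancy, 0.6)

  p3 <- write_mse_pdb(withr::local_tempfile(fileext = ".pdb"))
  s3 <- read_pdb(p3)
  expect_identical(s3$res_codes, c("MET", "GLY"))

  expect_error(read_pdb(p, chain = "Z"), "available")
})

test_that("structures written as PDB re-read identically", {
  ch <- generate_chain(chain_spec(15, seed = 5))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ch, p)
  back <- read_pdb(p, id = ch$id)
  expect_identical(back$res_codes, ch$res_codes)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(ch$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("contact enumeration applies cutoff and exclusive separation", {
  two <- toy_structure(c(0, 0, 0, 4, 0, 0), c("ALA", "GLY"))
  expect_equal(nrow(enumerate_contacts(two, contact_scheme(6, 0))), 1)
  expect_equal(nrow(enumerate_contacts(two, contact_scheme(6, 5))), 0)
  expect_equal(nrow(enumerate_contacts(two, contact_scheme(4, 0))), 0)

  # 4 collinear single-atom residues spaced 3 A, cutoff 6.5:
  # 3 adjacent + 2 next-adjacent pairs
  four <- toy_structure(c(0, 0, 0, 3, 0, 0, 6, 0, 0, 9, 0, 0),
                        c("ALA", "CYS", "GLY", "SER"))
  expect_equal(nrow(enumerate_contacts(four, contact_scheme(6.5, 0))), 5)
})

test_that("contact enumeration matches the brute-force oracle", {
  for (seed in 1:5) {
    ch <- generate_chain(chain_spec(25, seed = seed))
    for (scheme in list(contact_scheme(6, 0), contact_scheme(10, 2),
                        contact_scheme(15, 5))) {
      got <- enumerate_contacts(ch, scheme)
      want <- brute_contacts(ch, scheme)
      expect_equal(got$distance, want$distance, tolerance = 1e-12)
      expect_identical(got$atom_i, want$atom_i)
      expect_identical(got$atom_j, want$atom_j)
    }
  }
})

test_that("tessellation filtering only removes contacts", {
  for (seed in c(3, 9)) {
    ch <- generate_chain(chain_spec(20, seed = seed))
    off <- enumerate_contacts(ch, contact_scheme(10, 0))
    on <- enumerate_contacts(ch, contact_scheme(10, 0,
                                                use_tessellation = TRUE))
    expect_lte(nrow(on), nrow(off))
    key <- function(x) paste(x$atom_i, x$atom_j)
    expect_true(all(key(on) %in% key(off)))
    # tessellation keeps nearest neighbours: consecutive residues
    # 3.8 A apart must stay connected
    expect_true(any(on$res_j - on$res_i == 1))
  }
})

test_that("delaunay edges of a regular tetrahedron are all six pairs", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  e <- delaunay_edges(xyz)
  expect_equal(nrow(e), 6)
  # a far-away 5th point must not steal edges between the first four
  e5 <- delaunay_edges(rbind(xyz, c(10, 10, 10)))
  expect_true(all(apply(utils::combn(4, 2), 2, function(p)
    any(e5[, 1] == p[1] & e5[, 2] == p[2]))))
})

test_that("C-alpha RMSD is superposition-invariant and symmetric", {
  ch <- generate_chain(chain_spec(12, seed = 2))
  expect_equal(calpha_rmsd(ch, ch), 0)

  # rigid rotation + translation leaves RMSD at zero
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  a2 <- ch$atoms
  m <- as.matrix(a2[, c("x", "y", "z")]) %*% rot
  a2$x <- m[, 1] + 5; a2$y <- m[, 2] - 3; a2$z <- m[, 3] + 1
  moved <- protein_structure("moved", "A", a2)
  expect_equal(calpha_rmsd(ch, moved), 0, tolerance = 1e-8)

  # two-point closed form: centroids align, residuals +/- 1
  a <- toy_structure(c(0, 0, 0, 1, 0, 0), c("ALA", "GLY"))
  b <- toy_structure(c(0, 0, 0, 3, 0, 0), c("ALA", "GLY"))
  expect_equal(calpha_rmsd(a, b), 1, tolerance = 1e-8)
  expect_equal(calpha_rmsd(a, b), calpha_rmsd(b, a))

  short <- toy_structure(c(0, 0, 0), "ALA")
  expect_error(calpha_rmsd(ch, short), "mismatch")
})

test_that("superposed RMSD agrees with the bio3d reference implementation", {
  nat <- generate_chain(chain_spec(20, seed = 7))
  ds <- generate_decoy_ladder(nat, decoy_ladder_spec(3, c(1, 2, 3),
                                                     seed = 8))
  for (d in ds$decoys) {
    xyz_a <- as.vector(t(as.matrix(nat$atoms[, c("x", "y", "z")])))
    xyz_b <- as.vector(t(as.matrix(d$atoms[, c("x", "y", "z")])))
    ref <- bio3d::rmsd(xyz_a, xyz_b, fit = TRUE)
    expect_equal(calpha_rmsd(nat, d), ref, tolerance = 1e-3)
  }
})

test_that("decoy directories round-trip with provided RMSD tables", {
  nat <- generate_chain(chain_spec(15, seed = 4), id = "native")
  ds <- generate_decoy_ladder(nat, decoy_ladder_spec(4, c(1, 2, 3, 4),
                                                     seed = 5))
  dir <- withr::local_tempdir()
  write_pdb(nat, file.path(dir, "native.pdb"))
  files <- sprintf("decoy%02d.pdb", seq_along(ds$decoys))
  for (i in seq_along(ds$decoys))
    write_pdb(ds$decoys[[i]], file.path(dir, files[i]))
  write.table(data.frame(files, round(ds$rmsd, 3)),
              file.path(dir, "rmsd.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  back <- read_decoy_set(dir)
  expect_equal(length(back$decoys), 4)
  # provided values honoured verbatim, not recomputed
  expect_equal(sort(back$rmsd), sort(round(ds$rmsd, 3)))
})
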