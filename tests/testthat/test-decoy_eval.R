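test_that("Top1 requires a strictly lowest native score", {
  expect_true(top1(-10, c(-5, -3)))
  expect_false(top1(-5, c(-10, -3)))
  expect_warning(tie <- top1(-5, c(-5, -3)), "tie")
  expect_false(tie)
})

test_that("native Z-score uses decoys-only sample statistics", {
  expect_equal(zscore_native(0, c(1, 2, 3)), 2)   # mean 2, sample sd 1
  expect_equal(zscore_native(2, c(1, 2, 3)), 0)
  # translation invariance
  expect_equal(zscore_native(0 + 7, c(1, 2, 3) + 7), 2)
  expect_error(zscore_native(0, c(1, 1)), "zero")
  expect_error(zscore_native(0, 1), "2 decoys")
})

test_that("RMSD of the minimum honours provided values and tie-breaks low", {
  ds <- fixed_rmsd_set(c(4.2, 8, 1))
  expect_equal(rmsd_of_minimum(ds, -10, c(-5, -4, -3)), 0)
  expect_equal(rmsd_of_minimum(ds, 0, c(-5, -4, -3)), 4.2)
  expect_warning(r <- rmsd_of_minimum(ds, 0, c(-5, -4, -5)), "tie")
  expect_equal(r, 1)  # the lower-RMSD of the tied decoys
})

test_that("energy-RMSD correlation is the decoys-only Pearson r", {
  ds <- fixed_rmsd_set(c(1, 2, 3))
  expect_equal(pearson_energy_rmsd(ds, c(1, 2, 3)), 1)
  expect_equal(pearson_energy_rmsd(ds, c(-1, -2, -3)), -1)
  expect_equal(pearson_energy_rmsd(ds, c(2, 4, 6)), 1)
  expect_error(pearson_energy_rmsd(ds, c(1, 1, 1)), "zero variance")
})

test_that("fraction enrichment spans [0, 5] with the floor rule", {
  # perfect overlap at N = 100 attains the maximum 5
  ds <- fixed_rmsd_set(1:100)
  expect_equal(fraction_enrichment(ds, 1:100), 5)
  # disjoint top sets give 0
  expect_equal(fraction_enrichment(ds, 100:1), 0)
  # N = 10, overlap 1: 1 / (0.04 * 10) = 2.5
  ds10 <- fixed_rmsd_set(1:10)
  sc10 <- c(1, 10, 9, 8, 7, 6, 5, 4, 3, 2)
  expect_equal(fraction_enrichment(ds10, sc10), 2.5)
  expect_error(fraction_enrichment(fixed_rmsd_set(1:4), 1:4), ">= 5")
})

test_that("best-decoy Z-score excludes the best decoy and keys on RMSD", {
  # best decoy (lowest RMSD) first; remaining scores {1,2,3}
  ds <- fixed_rmsd_set(c(0.5, 5, 6, 7))
  expect_equal(zscore_best(ds, c(0, 1, 2, 3)), 2)
  expect_equal(zscore_best(ds, c(2, 1, 2, 3)), 0)
  # identification is by RMSD even when scores disagree
  ds2 <- fixed_rmsd_set(c(5, 0.5, 6, 7))
  expect_equal(zscore_best(ds2, c(1, 0, 2, 3)), 2)
  expect_error(zscore_best(ds, c(0, 1, 1, 1)), "zero")
})

test_that("Z-scores and rank metrics are invariant to positive affine scores", {
  set.seed(17)
  rmsd <- sort(runif(12, 0.5, 10))
  ds <- fixed_rmsd_set(rmsd)
  sc <- rnorm(12)
  for (tr in list(c(1, 0), c(2.5, -3), c(0.2, 11))) {
    sc2 <- tr[1] * sc + tr[2]
    expect_equal(zscore_native(tr[1] * -2 + tr[2], sc2),
                 zscore_native(-2, sc))
    expect_equal(fraction_enrichment(ds, sc2),
                 fraction_enrichment(ds, sc))
    expect_equal(rmsd_of_minimum(ds, tr[1] * -20 + tr[2], sc2),
                 rmsd_of_minimum(ds, -20, sc))
  }
})

test_that("collection evaluation aggregates per-target reports", {
  pot <- small_potential()
  sets <- lapply(1:3, function(i) {
    nat <- generate_chain(chain_spec(20, seed = 50 + i),
                          id = paste0("t", i))
    generate_decoy_ladder(nat, decoy_ladder_spec(
      8, seq(2, 5, length.out = 8), seed = 60 + i))
  })
  ev <- evaluate_collection(sets, pot)
  expect_s3_class(ev, "decoy_eval")
  expect_equal(nrow(ev$per_target), 3)
  expect_equal(ev$aggregate$top1, sum(ev$per_target$top1))
  expect_equal(ev$aggregate$zscore, mean(ev$per_target$zscore))
  expect_equal(ev$aggregate$fe, mean(ev$per_target$fe))

  # full mask reproduces the full model exactly
  full <- interaction_mask(list_pair_types(), source = "full")
  evm <- evaluate_collection(sets, pot, full)
  expect_equal(evm$aggregate$zscore, ev$aggregate$zscore,
               tolerance = 1e-12)
  expect_equal(evm$aggregate$top1, ev$aggregate$top1)
  expect_equal(evm$aggregate$pi_mean, 1)

  p <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(ev, p)
  expect_equal(nrow(read.table(p, header = TRUE, sep = "\t")), 3)
})

test_that("the success curve ends at the full-model Top1", {
  pot <- small_potential()
  sets <- lapply(1:3, function(i) {
    nat <- generate_chain(chain_spec(20, seed = 70 + i),
                          id = paste0("c", i))
    generate_decoy_ladder(nat, decoy_ladder_spec(
      6, seq(2, 5, length.out = 6), seed = 80 + i))
  })
  ranking <- list_pair_types()[order(runif(210))]
  curve <- success_curve(sets, pot, ranking)
  expect_equal(nrow(curve), 210)
  expect_equal(curve$k, 1:210)
  ev <- evaluate_collection(sets, pot)
  expect_equal(curve$top1[210], ev$aggregate$top1)
  expect_true(all(curve$top1 >= 0 & curve$top1 <= 3))
  expect_error(success_curve(sets, pot, ranking[-1]), "cover")
})
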