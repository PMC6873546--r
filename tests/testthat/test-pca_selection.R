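test_that("covariance matches hand computation and the definitional loop", {
  # 2 samples, 2 variables, rows (-1,-1), (1,1): divisor n-1 = 1
  cte <- rbind(c(-1, -1), c(1, 1))
  expect_equal(covariance_matrix(cte), matrix(2, 2, 2))

  expect_equal(covariance_matrix(matrix(0, 4, 3)), matrix(0, 3, 3))

  # brute-force double loop on random 10 x 4 input
  set.seed(42)
  m <- center_columns(matrix(rnorm(40), 10, 4))
  got <- covariance_matrix(m)
  want <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4)
    want[a, b] <- sum(m[, a] * m[, b]) / 9
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(covariance_matrix(matrix(1:6, 3, 2)), "centered")
})

test_that("eigendecomposition sorts, clips and reconstructs", {
  e <- eigendecompose(diag(3))
  expect_equal(e$values, c(1, 1, 1))

  e2 <- eigendecompose(diag(c(4, 1)))
  expect_equal(e2$values, c(4, 1))
  expect_equal(abs(e2$vectors), diag(2), tolerance = 1e-12)

  # 2x2 closed form: [[2,2],[2,2]] -> (4, 0), first axis (1,1)/sqrt(2)
  e3 <- eigendecompose(matrix(2, 2, 2))
  expect_equal(e3$values, c(4, 0))
  expect_equal(abs(e3$vectors[, 1]), rep(1 / sqrt(2), 2))

  cov <- covariance_matrix(center_columns(matrix(rnorm(60), 12, 5)))
  es <- eigendecompose(cov)
  expect_equal(es$vectors %*% diag(es$values) %*% t(es$vectors), cov,
               tolerance = 1e-7)
  expect_equal(sum(es$values), sum(diag(cov)), tolerance = 1e-8)
  expect_equal(crossprod(es$vectors), diag(5), tolerance = 1e-8)

  expect_error(eigendecompose(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("variance proportions and component selection follow the 80% rule", {
  expect_equal(variance_proportions(list(values = c(3, 1))), c(75, 25))
  expect_equal(variance_proportions(list(values = c(1, 0, 0))),
               c(100, 0, 0))
  expect_equal(variance_proportions(list(values = c(4, 0))), c(100, 0))
  expect_error(variance_proportions(list(values = c(0, 0))), "zero")

  expect_equal(select_components(c(75, 25)), 2)
  expect_equal(select_components(c(85, 15)), 1)
  expect_equal(select_components(c(40, 40, 20)), 2)
  # minimality of m on random spectra
  set.seed(1)
  for (i in 1:20) {
    lam <- sort(rexp(15), decreasing = TRUE)
    t <- variance_proportions(list(values = lam))
    m <- select_components(t)
    expect_gte(sum(t[1:m]), 80 - 1e-9)
    if (m > 1) expect_lt(sum(t[1:(m - 1)]), 80)
  }
})

test_that("contributions are squared loadings in percent, sign-invariant", {
  spec <- list(values = c(2, 1),
               vectors = cbind(c(1, 0), c(1, 1) / sqrt(2)))
  C <- pc_contributions(spec, 2)
  expect_equal(C[, 1], c(100, 0))
  expect_equal(C[, 2], c(50, 50))
  expect_equal(colSums(C), c(100, 100))

  flipped <- spec
  flipped$vectors[, 1] <- -flipped$vectors[, 1]
  expect_equal(pc_contributions(flipped, 2), C)
})

test_that("total contributions are eigenvalue-weighted sums with tau their mean", {
  spec1 <- list(values = c(2), vectors = cbind(c(1, 0)))
  C1 <- pc_contributions(spec1, 1)
  expect_equal(total_contributions(C1, spec1, 1), c(200, 0))

  # lambda (2,1), C columns (50,50) and (100,0) -> totals (200, 100)
  C <- cbind(c(50, 50), c(100, 0))
  spec <- list(values = c(2, 1))
  expect_equal(total_contributions(C, spec, 2), c(200, 100))
  # column-sum identity
  expect_equal(sum(total_contributions(C, spec, 2)),
               100 * sum(spec$values[1:2]))

  # tau: p = 210 with retained eigenvalues summing to 2.1 -> 1.0
  spec210 <- list(values = c(1.6, 0.5, 0.1))
  expect_equal(uniform_threshold(spec210, 2, 210), 2.1 / 2.1)
  expect_equal(uniform_threshold(list(values = c(2, 1)), 1, 2), 100)

  # tau equals the mean total contribution on random spectra
  set.seed(7)
  for (i in 1:10) {
    cov <- covariance_matrix(center_columns(matrix(rnorm(12 * 6), 12, 6)))
    spec <- eigendecompose(cov)
    m <- select_components(variance_proportions(spec))
    tc <- total_contributions(pc_contributions(spec, m), spec, m)
    expect_equal(mean(tc), uniform_threshold(spec, m, 6),
                 tolerance = 1e-10)
  }
})

test_that("select_principal recovers planted high-variance columns", {
  m <- generate_planted_matrix(planted_matrix_spec(
    500, 210, planted_indices = c(4, 50, 100, 150, 208),
    planted_sd = 10, background_sd = 1, seed = 33))
  sel <- select_principal(m)
  expect_setequal(sel$principal_set,
                  colnames(m)[c(4, 50, 100, 150, 208)])
  expect_s3_class(sel, "pi_selection")
  # internal identities
  expect_equal(sum(sel$t), 100, tolerance = 1e-8)
  expect_equal(unname(colSums(sel$contributions)),
               rep(100, sel$m), tolerance = 1e-8)
  expect_equal(mean(sel$total_contribution), sel$tau, tolerance = 1e-8)
  # ranking covers everything, descending
  expect_setequal(sel$ranked_variables, colnames(m))
  expect_true(all(diff(sel$total_contribution[sel$ranked_variables])
                  <= 1e-12))
})

test_that("selection is invariant to scaling, row permutation and duplication", {
  m <- generate_planted_matrix(planted_matrix_spec(
    80, 28, planted_indices = 1:3, planted_sd = 8, background_sd = 1,
    seed = 12))
  base <- select_principal(m)
  expect_identical(select_principal(m * 3.7)$principal_set,
                   base$principal_set)
  set.seed(5)
  expect_identical(select_principal(m[sample(nrow(m)), ])$principal_set,
                   base$principal_set)
  dup <- select_principal(rbind(m, m))
  expect_identical(dup$principal_set, base$principal_set)
})

test_that("exchangeable equal-variance columns never exceed tau beyond noise", {
  # exactly centered, exactly orthogonal, equal-norm columns: the
  # empirical covariance is a scalar matrix, contributions are uniform
  # and equal tau, so under the strict > tau rule nothing stands out
  # beyond floating-point noise
  m <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  colnames(m) <- paste0("V", 1:3)
  sel <- select_principal(m, center = FALSE)
  expect_equal(unname(sel$total_contribution), rep(sel$tau, 3),
               tolerance = 1e-10)
  expect_true(all(sel$total_contribution <= sel$tau * (1 + 1e-9)))
  expect_equal(sel$m, 3)
})

test_that("selection results serialise to TSV and JSON", {
  m <- generate_planted_matrix(planted_matrix_spec(
    60, 21, 1:2, 6, 1, seed = 3))
  sel <- select_principal(m)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_selection(sel, p)
  tab <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 21)
  expect_equal(sum(tab$selected), length(sel$principal_set))
  js <- jsonlite::fromJSON(paste0(p, ".json"))
  expect_equal(js$m, sel$m)
  expect_equal(js$tau, sel$tau, tolerance = 1e-12)
})

test_that("seeded row subsampling is deterministic", {
  m <- matrix(rnorm(100), 20, 5)
  s1 <- subsample_rows(m, 8, seed = 9)
  s2 <- subsample_rows(m, 8, seed = 9)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(8, 5))
})
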