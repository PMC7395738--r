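# helper: study with means differing only in gene 1
two_gene_study <- function() {
  X <- rbind(G1 = c(10, 10.1, 9.9, 10, 8, 8.1, 7.9, 8),
             G2 = c(5, 5.2, 4.8, 5, 5.1, 4.9, 5.2, 4.8))
  colnames(X) <- c(paste0("c", 1:4), paste0("n", 1:4))
  expression_study("toy2", X, paste0("c", 1:4), paste0("n", 1:4))
}

test_that("near-identity shrinkage recovers the mean-difference axis", {
  st <- two_gene_study()
  cd <- characteristic_direction(st, gamma = 1e-12, n_components = "full")
  expect_gt(cd$coefficients[["G1"]], 0.99)   # cases higher in G1 => positive
  expect_lt(abs(cd$coefficients[["G2"]]), 0.15)
})

test_that("PCA-subspace computation matches the direct full-space solve", {
  for (seed in 1:8) {
    n_genes <- sample(4:15, 1)
    st <- random_study(n_genes, n_genes + 4, n_genes + 5, seed = 100 + seed,
                       shift_genes = sprintf("G%03d", 1:2), shift = 1.5)
    for (gamma in c(0.2, 0.5, 1)) {
      cd <- characteristic_direction(st, gamma = gamma, n_components = "full")
      expect_equal(cd$coefficients, oracle_cd(st, gamma), tolerance = 1e-8)
    }
  }
})

test_that("CD directions are unit norm and scale invariant", {
  for (seed in 1:6) {
    st <- random_study(50, 5, 6, seed = 200 + seed,
                       shift_genes = sprintf("G%03d", 1:5), shift = 2)
    cd <- characteristic_direction(st)
    expect_equal(sqrt(sum(cd$coefficients^2)), 1, tolerance = 1e-9)
    st_scaled <- st
    st_scaled$values <- st$values * 7
    class(st_scaled) <- "ExpressionStudy"
    cd2 <- characteristic_direction(st_scaled)
    expect_equal(cd2$coefficients, cd$coefficients, tolerance = 1e-8)
  }
})

test_that("degenerate inputs are rejected", {
  st <- random_study(10, 4, 4, seed = 33)
  # identical case and control values: no discriminating direction
  st$values[, st$control_samples] <- st$values[, st$case_samples]
  class(st) <- "ExpressionStudy"
  expect_error(characteristic_direction(st), "degenerate")

  # a class with fewer than 2 samples
  X <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("G", 1:4), paste0("s", 1:3)))
  st1 <- expression_study("tiny", X, "s1", c("s2", "s3"))
  expect_error(characteristic_direction(st1), "at least 2 samples")

  # zero variance everywhere
  Z <- matrix(5, 4, 8, dimnames = list(paste0("G", 1:4), paste0("s", 1:8)))
  stz <- expression_study("flat", Z, paste0("s", 1:4), paste0("s", 5:8))
  expect_error(characteristic_direction(stz), "degenerate")

  expect_error(characteristic_direction(random_study(5, 3, 3, 1), gamma = 0),
               "gamma")
})

test_that("signatures rank by |coefficient| with lexicographic ties", {
  cd <- structure(list(study_id = "s", gamma = 0.5, n_components = 2,
                       category = "cancer_vs_normal",
                       coefficients = c(A = 0.9, B = -0.8, C = 0.1, D = -0.05)),
                  class = "CDResult")
  sig <- signature_from_cd(cd, cutoff = 2)
  expect_equal(sig$up_genes, "A")
  expect_equal(sig$down_genes, "B")

  cd_tie <- cd
  cd_tie$coefficients <- c(B = 0.5, A = -0.5)
  sig_tie <- signature_from_cd(cd_tie, cutoff = 1)
  expect_equal(sig_tie$down_genes, "A")   # |A| == |B|, A wins lexicographically
  expect_length(sig_tie$up_genes, 0)
})

test_that("cutoff beyond the gene count keeps all nonzero genes, with warning", {
  set.seed(9)
  coefs <- setNames(rnorm(300), sprintf("G%03d", 1:300))
  coefs <- coefs / sqrt(sum(coefs^2))
  cd <- structure(list(study_id = "s", gamma = 0.5, n_components = 5,
                       category = "cancer_vs_normal", coefficients = coefs),
                  class = "CDResult")
  expect_warning(sig <- signature_from_cd(cd, cutoff = 500), "cutoff")
  expect_equal(length(sig$up_genes) + length(sig$down_genes), 300)
  expect_true(all(sig$scores[sig$up_genes] > 0))
  expect_true(all(sig$scores[sig$down_genes] < 0))
  expect_length(intersect(sig$up_genes, sig$down_genes), 0)

  sig_pd <- suppressWarnings(signature_from_cd(cd, cutoff = 500,
                                               per_direction = TRUE))
  expect_equal(sort(c(sig_pd$up_genes, sig_pd$down_genes)),
               sort(c(sig$up_genes, sig$down_genes)))
})

test_that("planted signal lands at the top of the signature", {
  planted <- sprintf("G%03d", 1:20)
  st <- random_study(400, 10, 10, seed = 77, shift_genes = planted, shift = 2)
  cd <- characteristic_direction(st)
  sig <- signature_from_cd(cd, cutoff = 100)
  expect_gte(length(intersect(sig$up_genes, planted)), 19)  # >= 95% recovered
})
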