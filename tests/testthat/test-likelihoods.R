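test_that("per-base emission matches the uniform-miscall model", {
  expect_equal(base_given_allele("A", "A", 0.01), 0.99)
  expect_equal(base_given_allele("A", "C", 0.03), 0.01)
  ## normalization over observable bases for several error rates
  for (e in c(0, 0.2, 1)) {
    for (a in c("A", "C", "G", "T")) {
      expect_equal(sum(sapply(c("A", "C", "G", "T"), base_given_allele,
                              a = a, e = e)), 1)
    }
  }
  expect_error(base_given_allele("N", "A", 0.1), "allele")
  expect_error(base_given_allele("A", "A", 1.5), "\\[0, 1\\]")
})

test_that("genotype log-likelihood follows the 50/50 allele mixture", {
  p1 <- pileup("A", 0.01)
  expect_equal(genotype_log_likelihood(p1, "AA"), log(0.99))
  expect_equal(genotype_log_likelihood(p1, "AC"),
               log(0.5 * 0.99 + 0.5 * 0.01 / 3))
  ## empty pileup: all genotypes log-likelihood 0
  expect_equal(genotype_log_likelihood(pileup(), "GT"), 0)
  expect_equal(unname(unclass(compute_all_likelihoods(pileup()))),
               rep(0, 10))
  ## per-base enumeration oracle at heterogeneous error rates
  set.seed(1)
  bases <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
  errs <- runif(12, 0.001, 0.2)
  pu <- pileup(bases, errs)
  for (g in sample(genotype_names(), 4)) {
    a <- strsplit(g, "")[[1]]
    manual <- sum(log(0.5 * base_given_allele(bases, a[1], errs) +
                        0.5 * base_given_allele(bases, a[2], errs)))
    expect_equal(genotype_log_likelihood(pu, g), manual)
    expect_equal(unname(compute_all_likelihoods(pu)[g]), manual)
  }
})

test_that("likelihoods are additive over bases and permutation invariant", {
  set.seed(2)
  b1 <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
  b2 <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
  gl1 <- compute_all_likelihoods(pileup(b1, 0.02))
  gl2 <- compute_all_likelihoods(pileup(b2, 0.02))
  gl12 <- compute_all_likelihoods(pileup(c(b1, b2), 0.02))
  expect_equal(unclass(gl12), unclass(gl1) + unclass(gl2))
  perm <- sample(13)
  glp <- compute_all_likelihoods(pileup(c(b1, b2)[perm],
                                        rep(0.02, 13)[perm]))
  expect_equal(unclass(glp), unclass(gl12))
})

test_that("error clamping keeps likelihoods finite and e->0 is monotone", {
  ## Q-infinity input (e = 0) is clamped, not -Inf
  gl <- compute_all_likelihoods(pileup(rep("A", 5), 0))
  expect_true(all(is.finite(unclass(gl))))
  expect_equal(unname(gl["AA"]), 5 * log(1 - 1e-10))
  ## with all-A pileups, GL(AA) -> 0 and non-A genotypes fall monotonically
  es <- c(0.1, 0.01, 0.001)
  lls <- sapply(es, function(e) {
    unclass(compute_all_likelihoods(pileup(rep("A", 10), e)))
  })
  expect_true(all(diff(lls["CC", ]) < 0))
  expect_true(all(diff(lls["GT", ]) < 0))
  expect_true(all(lls["AA", ] == cummax(lls["AA", ])))
})

test_that("phred_scale normalizes to the maximum and rounds", {
  expect_equal(unname(phred_scale(c(0, 0, 0))), c(0, 0, 0))
  expect_equal(unname(phred_scale(log(c(1, 0.1)))), c(0, 10))
  gl <- compute_all_likelihoods(pileup("A", 0.01))
  pl <- phred_scale(gl)
  expect_equal(unname(pl["AA"]), 0L)
  expect_equal(unname(pl["CC"]), 25L)
  ## invariance under scaling all likelihoods by a constant
  expect_equal(phred_scale(gl + 12.3), pl)
})
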