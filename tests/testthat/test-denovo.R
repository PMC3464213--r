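test_that("Mendelian consistency classification", {
  expect_false(mendelian_consistent(1, 0, 0))  # het child, hom-ref parents
  expect_true(mendelian_consistent(0, 1, 0))
  expect_false(mendelian_consistent(0, 2, 0))  # hom-alt parent forces het
  expect_true(mendelian_consistent("RefRef", "RefAlt", "RefRef"))
  expect_false(mendelian_consistent("RefRef", "AltAlt", "RefRef"))
  expect_equal(mendelian_consistent(c(0, 1, 2), c(0, 0, 0), c(0, 0, 1)),
               c(TRUE, FALSE, FALSE))
  ## exhaustive agreement with positive-transmission-probability rule
  for (c_ in 0:2) for (f_ in 0:2) for (m_ in 0:2) {
    tp <- famcall:::transmission_cube(c(1L, 2L), NULL)[c_ + 1, f_ + 1,
                                                      m_ + 1]
    expect_equal(mendelian_consistent(c_, f_, m_), tp > 0)
  }
})

test_that("denovo LR is 1 for uninformative or mu ~ 0 models", {
  trio <- pedigree_trio()
  mdl <- mutation_model()
  ## flat GLs: both likelihoods are 1 up to the O(mu) probability mass
  ## that the biallelic restriction lets leak to the other two alleles
  r <- denovo_score(trio, list(), c("A", "C"), 0.3, mdl)
  expect_equal(r$lr, 1, tolerance = 1e-7)
  ## numerically null mutation rate
  gls <- rand_gls_for(trio)
  r2 <- denovo_score(trio, gls, c("A", "C"), 0.3,
                     mutation_model(mu = 1e-30))
  expect_equal(r2$lr, 1, tolerance = 1e-6)
  ## mu = 0 warns and forces lr = 1
  expect_warning(r3 <- denovo_score(trio, gls, c("A", "C"), 0.3,
                                    mutation_model(mu = 0)), "degenerate")
  expect_equal(r3$lr, 1)
})

test_that("denovo LR matches brute-force enumeration on a clear trio DNM", {
  trio <- pedigree_trio()
  mdl <- mutation_model()
  set.seed(50)
  gls <- list(fa = unclass(gl_from_bases(rep("A", 30))),
              mo = unclass(gl_from_bases(rep("A", 30))),
              ch = unclass(gl_from_bases(rep(c("A", "G"), 15))))
  freq <- 1e-6
  r <- denovo_score(trio, gls, c("A", "G"), freq, mdl)
  l_dn <- brute_force_log_likelihood(trio, gls, freq, c("A", "G"), mdl)
  l_me <- brute_force_log_likelihood(trio, gls, freq, c("A", "G"), NULL)
  expect_equal(r$log_l_denovo, l_dn, tolerance = 1e-10)
  expect_equal(r$log_l_mendel, l_me, tolerance = 1e-10)
  expect_equal(r$lr, exp(l_dn - l_me), tolerance = 1e-8)
  expect_gt(r$lr, 10)
  expect_gt(r$posterior, 0.99)
  expect_equal(r$candidate_triplets$child, "ch")
})

test_that("LR is symmetric in the parents", {
  trio <- pedigree_trio()
  mdl <- mutation_model()
  glA <- unclass(gl_from_bases(rep("A", 25)))
  glC <- unclass(gl_from_bases(c(rep("A", 12), rep("C", 13))))
  r1 <- denovo_score(trio, list(fa = glA, mo = glC,
                                ch = rand_gl() * 0), c("A", "C"), 0.1, mdl)
  r2 <- denovo_score(trio, list(fa = glC, mo = glA,
                                ch = rand_gl() * 0), c("A", "C"), 0.1, mdl)
  expect_equal(r1$lr, r2$lr, tolerance = 1e-9)
})

test_that("call_denovo applies the LR x inconsistency conjunction", {
  px <- dnm_power_experiment(n_sites = 60, coverage = 30, seed = 52,
                             lr_threshold = 10)
  cand <- px$candidates
  expect_true(all(cand$lr >= 10))
  ## every candidate triplet is genuinely inconsistent
  expect_true(all(!mendelian_consistent(cand$child_g, cand$father_g,
                                        cand$mother_g)))
  ## strict filter is a subset
  strict <- call_denovo(px$calls, lr_threshold = 10,
                        require_hom_parents_het_child = TRUE)
  expect_lte(nrow(strict), nrow(cand))
  expect_true(all(strict$father_g == 0 & strict$mother_g == 0 &
                    strict$child_g == 1))
})

test_that("Mendelian data rarely exceeds the LR threshold", {
  ## polymorphic sites without DNMs, called with the mutation model
  sim <- tiny_sim(n_ped = 4, n_sites = 400, coverage = 20, seed = 53,
                  type = "trio")
  ## no stochastic DNMs landed (rate 1.4e-8 x 2400 transmissions)
  expect_equal(sum(vapply(sim$families, function(f) nrow(f$registry),
                          numeric(1))), 0)
  calls <- call_sites(sim, model = mutation_model())
  lrs <- exp(unlist(lapply(calls$geno, `[[`, "log_lr")))
  lrs <- lrs[is.finite(lrs)]
  expect_gt(length(lrs), 50)
  expect_lt(abs(log(stats::median(lrs))), 0.2)  # median lr ~ 1
  cand <- call_denovo(calls, lr_threshold = 10)
  n_site_trans <- sum(calls$sites$emitted) * 4  # 4 triplets scanned
  expect_lt(nrow(cand) / max(n_site_trans, 1), 0.01)
})
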