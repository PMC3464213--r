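test_that("coalescent variant prior", {
  expect_equal(variant_prior(1, 0.001), 0.001)
  expect_equal(variant_prior(2, 0.001), 0.001 * (1 + 1 / 2 + 1 / 3))
  expect_equal(variant_prior(17, 0), 0)
  expect_error(variant_prior(0), "founder")
})

test_that("allele frequency MLE recovers empirical frequencies", {
  ## 10 unrelated hom-ref individuals -> boundary MLE ~ 0
  singles <- lapply(1:10, function(k) {
    pedigree(paste0("s", k), id = paste0("i", k), father = NA, mother = NA)
  })
  gls <- stats::setNames(lapply(1:10, function(k) certain_gl("AA")),
                         paste0("i", 1:10))
  fe <- estimate_allele_frequency(singles, gls, c("A", "C"))
  expect_lte(fe$alt_freq, 1e-4)
  ## RefRef + RefAlt unrelated pair -> MLE 1/4 (allele count / 2n)
  two <- singles[1:2]
  gl2 <- list(i1 = certain_gl("AA"), i2 = certain_gl("AC"))
  fe2 <- estimate_allele_frequency(two, gl2, c("A", "C"))
  expect_equal(fe2$alt_freq, 0.25, tolerance = 1e-4)
  ## grid-search oracle on a sibship with unsequenced parents
  ped <- pedigree_nuclear("n", 2)
  gls3 <- list(ch1 = certain_gl("AC"), ch2 = certain_gl("AC"))
  fe3 <- estimate_allele_frequency(ped, gls3, c("A", "C"))
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  ll <- vapply(grid, function(p) {
    family_log_likelihood(ped, gls3, p, c("A", "C"))
  }, numeric(1))
  expect_equal(fe3$alt_freq, grid[which.max(ll)], tolerance = 2e-4)
  expect_equal(fe3$max_loglik, max(ll), tolerance = 1e-6)
  ## flat input warns and returns 0.5
  expect_warning(
    fe0 <- estimate_allele_frequency(two, list(), c("A", "C")),
    "no informative")
  expect_equal(fe0$alt_freq, 0.5)
})

test_that("site discovery picks the dominant configuration", {
  trio <- pedigree_trio()
  ## deep reference-matching pileups: monomorphic, variant posterior ~ 0
  gls_ref <- list(fa = unclass(gl_from_bases(rep("A", 40), 0.001)),
                  mo = unclass(gl_from_bases(rep("A", 40), 0.001)),
                  ch = unclass(gl_from_bases(rep("A", 40), 0.001)))
  d0 <- discover_site(trio, gls_ref, "A")
  expect_false(d0$emitted)
  ## the profile likelihood of a variant configuration approaches the
  ## monomorphic likelihood as freq -> 0, so the variant posterior floors
  ## at roughly the prior mass rather than at 0
  expect_lt(d0$post_variant, 2 * variant_prior(2))
  expect_lt(d0$site_quality, 0.05)
  ## all members near-certain het ref/transition -> (ref, transition)
  gls_het <- list(fa = certain_gl("AG"), mo = certain_gl("AG"),
                  ch = certain_gl("AG"))
  d1 <- discover_site(trio, gls_het, "A")
  expect_true(d1$emitted)
  expect_equal(d1$a1, "A")
  expect_equal(d1$a2, "G")
  expect_gt(d1$site_quality, 50)
})

test_that("configuration posteriors agree with direct enumeration", {
  ## one individual, moderate data; enumerate the 7 configurations with
  ## profile likelihoods from a fine frequency grid
  solo <- pedigree("s", id = "x", father = NA, mother = NA)
  gl <- unclass(gl_from_bases(c("A", "A", "C", "C", "G"), 0.05))
  gls <- list(x = gl)
  prior <- site_prior()
  d <- discover_site(solo, gls, "A", prior = prior)
  p_var <- variant_prior(1, prior$theta)
  grid <- seq(1e-8, 1 - 1e-8, length.out = 2001)
  prof <- function(a1, a2) {
    idx <- c(famcall:::gt10_index(a1, a1), famcall:::gt10_index(a1, a2),
             famcall:::gt10_index(a2, a2))
    max(vapply(grid, function(p) {
      w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      log(sum(w * exp(gl[idx] - max(gl))))
    }, numeric(1))) + max(gl)
  }
  ## A=1 C=2 G=3 T=4; ref A: transition G, transversions C, T
  cfg_ll <- c(mono = unname(gl[1]),
              ts = prof(1, 3), tv1 = prof(1, 2), tv2 = prof(1, 4),
              d1 = prof(2, 3), d2 = prof(2, 4), d3 = prof(3, 4))
  lp <- log(c(1 - p_var, p_var * 2 / 3, p_var / 6, p_var / 6,
              rep(p_var * prior$p_double_factor / 3, 3)))
  post <- exp(cfg_ll + lp - max(cfg_ll + lp))
  post <- post / sum(post)
  expect_equal(sum(post), 1, tolerance = 1e-9)
  expect_equal(d$post_variant, 1 - post[["mono"]], tolerance = 1e-4)
  expect_equal(d$site_quality, -10 * log10(post[["mono"]]),
               tolerance = 0.02)
})

test_that("genotype calls: HWE defaults, dosage identity, tie-breaks", {
  solo <- pedigree("s", id = "x", father = NA, mother = NA)
  gc <- call_genotypes(solo, list(), c("A", "C"), 0.5)
  expect_equal(gc$genotype, "ref_alt")
  expect_equal(gc$dosage, 1)
  expect_equal(unlist(gc[c("p_ref_ref", "p_ref_alt", "p_alt_alt")]),
               c(p_ref_ref = 0.25, p_ref_alt = 0.5, p_alt_alt = 0.25))
  ## dosage identity on random cases
  set.seed(30)
  for (rep in 1:100) {
    ped <- rand_small_pedigree()
    gc <- call_genotypes(ped, rand_gls_for(ped), c("A", "C"),
                         runif(1, 0.05, 0.95))
    expect_equal(gc$dosage, gc$p_ref_alt + 2 * gc$p_alt_alt,
                 tolerance = 1e-9)
    expect_true(all(gc$dosage >= 0 & gc$dosage <= 2))
    expect_true(all(gc$gq <= 99))
  }
  ## trio child with flat GL, parents RefRef x RefAlt -> dosage 0.5
  gls <- list(fa = certain_gl("AA"), mo = certain_gl("AC"))
  gct <- call_genotypes(pedigree_trio(), gls, c("A", "C"), 0.3)
  expect_equal(gct$dosage[gct$id == "ch"], 0.5, tolerance = 1e-5)
})

test_that("call_sites: family and unrelated modes coincide for singletons", {
  sim <- tiny_sim(n_ped = 1, n_sites = 120, coverage = 8, seed = 41,
                  type = "trio")
  ## family-aware calling over singleton pedigrees (via the GL-table
  ## path) must equal unrelated mode over the trio: every individual is
  ## then a founder in both, so priors and likelihoods coincide
  glf <- tempfile(fileext = ".tsv")
  write_gl_table(sim, glf)
  gl <- read_gl_table(glf)
  singles <- lapply(gl$ids, function(id) {
    pedigree(paste0("u-", id), id = id, father = NA, mother = NA)
  })
  c_fam_singles <- call_sites(gl, peds = singles, mode = "family")
  c_unrel_gl <- call_sites(gl, peds = list(sim$families[[1]]$ped),
                           mode = "unrelated")
  expect_equal(c_fam_singles$sites$emitted, c_unrel_gl$sites$emitted)
  expect_equal(c_fam_singles$sites$qual, c_unrel_gl$sites$qual,
               tolerance = 1e-9)
  gt1 <- do.call(cbind, lapply(c_fam_singles$geno, `[[`, "gt"))
  gt2 <- c_unrel_gl$geno[[1]]$gt[, colnames(gt1), drop = FALSE]
  expect_equal(unname(gt1), unname(gt2))
  c_unrel <- call_sites(sim, mode = "unrelated")
  expect_equal(c_unrel$params$n_founders, 3)
  ## identical input, identical seeds: deterministic
  c_unrel2 <- call_sites(sim, mode = "unrelated")
  expect_identical(c_unrel$sites, c_unrel2$sites)
  expect_identical(c_unrel$geno[[1]]$gt, c_unrel2$geno[[1]]$gt)
})

test_that("monomorphic deep data yields no emitted variants", {
  ## all-reference simulation: fixed frequency list with freq ~ 0 is not
  ## possible (SFS needs freq > 0), so build counts directly
  ped <- pedigree_trio()
  S <- 200
  hap <- matrix(1L, 3, S)  # everyone AA
  counts <- famcall:::simulate_counts(hap, hap, rep(30, 3), 0.001)
  sim <- structure(list(
    sites = data.frame(chrom = "c", pos = 1:S, ref = "A", alt = "G",
                       freq_true = 0, stringsAsFactors = FALSE),
    families = list(f = list(ped = ped, ids = ped$members$id,
                             hap1 = hap, hap2 = hap, counts = counts,
                             registry = NULL)),
    base_error = 0.001), class = "famcall_sim")
  set.seed(5)
  calls <- call_sites(sim)
  expect_equal(sum(calls$sites$emitted), 0)
})

test_that("pedigree members absent from the GL input act as unsequenced", {
  sim <- tiny_sim(n_ped = 1, n_sites = 60, coverage = 10, seed = 42,
                  type = "trio")
  glf <- tempfile(fileext = ".tsv")
  write_gl_table(sim, glf)
  gl <- read_gl_table(glf)
  m <- sim$families[[1]]$ped$members
  ## an extra never-sequenced sibling integrates in with flat likelihoods
  ped2 <- pedigree(sim$families[[1]]$ped$fam,
                   id = c(m$id, "f001-ch2"),
                   father = c(m$father, "f001-fa"),
                   mother = c(m$mother, "f001-mo"),
                   sequenced = c(m$sequenced, FALSE))
  calls <- call_sites(gl, peds = list(ped2))
  expect_equal(ncol(calls$geno[[1]]$gt), 4)
  emitted <- which(calls$sites$emitted)
  expect_true(all(!is.na(calls$geno[[1]]$gt[emitted, 4])))
  ## a supposedly sequenced member with no data column is an error
  ped3 <- pedigree(sim$families[[1]]$ped$fam,
                   id = c(m$id, "ghost"),
                   father = c(m$father, "f001-fa"),
                   mother = c(m$mother, "f001-mo"))
  expect_error(call_sites(gl, peds = list(ped3)), "ghost")
})
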