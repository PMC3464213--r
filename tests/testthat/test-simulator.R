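test_that("founder haplotype generator: SFS shape and fixed frequencies", {
  set.seed(60)
  ## n_sites = 0 -> empty
  fh0 <- simulate_founder_haplotypes(8, 0)
  expect_equal(dim(fh0$haps), c(8, 0))
  ## fixed-frequency list [0.5]: empirical frequency 0.5 within 3 SE
  cfg <- sim_config(sfs = 0.5)
  n <- 1e5
  fh <- simulate_founder_haplotypes(2, n, cfg)
  emp <- mean(fh$haps)
  se <- sqrt(0.25 / (2 * n))
  expect_lt(abs(emp - 0.5), 3 * se)
  ## neutral SFS: the singleton class is the largest frequency class
  fh2 <- simulate_founder_haplotypes(20, 2e4)
  tab <- table(factor(round(fh2$freq * 20), levels = 1:19))
  expect_equal(names(which.max(tab)), "1")
  ## transition fraction of alt alleles ~ 2/3
  ts <- mean(is_transition(famcall:::ALLELES[fh2$ref],
                           famcall:::ALLELES[fh2$alt]))
  expect_lt(abs(ts - 2 / 3), 3 * sqrt(2 / 9 / 2e4) + 0.02)
})

test_that("gene dropping conserves parental alleles and recombination rate", {
  set.seed(61)
  ped <- pedigree_3gen()
  S <- 500
  fh <- matrix(sample(1:2, 8 * S, replace = TRUE), 8, S)
  pos <- sort(sample.int(1e6, S))
  ## zero recombination: transmitted haplotypes are unmodified parental ones
  dr0 <- gene_drop(ped, fh, pos, recomb_rate = 0, region_length = 1e6)
  m <- ped$members
  fa <- match(m$father, m$id)
  for (i in which(!m$founder)) {
    h <- dr0$hap1[i, ]
    expect_true(identical(h, dr0$hap1[fa[i], ]) ||
                  identical(h, dr0$hap2[fa[i], ]))
  }
  ## Mendelian conservation at every site under any recombination
  dr <- gene_drop(ped, fh, pos, recomb_rate = 1.5e-8, region_length = 1e6)
  mo <- match(m$mother, m$id)
  for (i in which(!m$founder)) {
    expect_true(all(dr$hap1[i, ] == dr$hap1[fa[i], ] |
                      dr$hap1[i, ] == dr$hap2[fa[i], ]))
    expect_true(all(dr$hap2[i, ] == dr$hap1[mo[i], ] |
                      dr$hap2[i, ] == dr$hap2[mo[i], ]))
  }
  ## crossover count: mean over meioses = rate x length within 3 SE
  n_mei <- 1e4
  k <- stats::rpois(n_mei, 1.5e-8 * 1e6)  # the exact sampler used
  lam <- 1.5e-8 * 1e6
  expect_lt(abs(mean(k) - lam), 3 * sqrt(lam / n_mei))
})

test_that("de novo injection: forced registry and rate moments", {
  set.seed(62)
  ped <- pedigree_trio()
  S <- 1000
  hap <- matrix(1L, 3, S)
  ## rate 0 -> empty registry
  inj0 <- inject_denovo(list(hap1 = hap, hap2 = hap), ped, dnm_rate = 0)
  expect_equal(nrow(inj0$registry), 0)
  ## forced mode plants exactly the listed events
  forced <- data.frame(site = 1:S, individual = "ch")
  injf <- inject_denovo(list(hap1 = hap, hap2 = hap), ped,
                        model = mutation_model(), forced = forced)
  expect_equal(nrow(injf$registry), S)
  expect_true(all(injf$registry$to != injf$registry$from))
  ## every forced child genotype is het for a non-ref allele
  expect_true(all((injf$hap1[3, ] != 1L) | (injf$hap2[3, ] != 1L)))
  ## stochastic mode: count ~ Binomial(2 * S, rate) within 3 SE
  rate <- 5e-3
  counts <- replicate(30, {
    nrow(inject_denovo(list(hap1 = hap, hap2 = hap), ped,
                       dnm_rate = rate)$registry)
  })
  expected <- 2 * S * rate
  expect_lt(abs(mean(counts) - expected),
            3 * sqrt(expected / 30))
})

test_that("pileup simulation moments", {
  set.seed(63)
  ## coverage 0 -> empty pileup; e = 0 -> no miscalls
  expect_length(simulate_pileup("AA", 0, 0.01)$base, 0)
  pu <- simulate_pileup("AA", 200, 0)
  expect_true(all(pu$base == 1L))
  ## empirical mismatch fraction ~ e
  e <- 0.01
  n_bases <- 0
  n_err <- 0
  for (r in 1:50) {
    pu <- simulate_pileup("CC", 2000, e)
    n_bases <- n_bases + length(pu$base)
    n_err <- n_err + sum(pu$base != 2L)
  }
  expect_lt(abs(n_err / n_bases - e), 3 * sqrt(e / n_bases))
  ## count-based sampler agrees with per-base simulation in distribution:
  ## depth and per-base composition for a het genotype
  hap1 <- matrix(1L, 1, 4000)
  hap2 <- matrix(2L, 1, 4000)
  cnt <- famcall:::simulate_counts(hap1, hap2, 10, e)
  depth <- rowSums(cnt[, 1, ])
  expect_lt(abs(mean(depth) - 10), 3 * sqrt(10 / 4000))
  pA <- sum(cnt[, 1, 1]) / sum(depth)
  exp_pA <- 0.5 * (1 - e) + 0.5 * e / 3
  expect_lt(abs(pA - exp_pA), 3 * sqrt(exp_pA / sum(depth)))
})

test_that("simulate_dataset is deterministic given the seed", {
  s1 <- tiny_sim(n_ped = 2, n_sites = 100, seed = 64)
  s2 <- tiny_sim(n_ped = 2, n_sites = 100, seed = 64)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$families[[2]]$counts, s2$families[[2]]$counts)
  s3 <- tiny_sim(n_ped = 2, n_sites = 100, seed = 65)
  expect_false(identical(s1$families[[1]]$counts, s3$families[[1]]$counts))
  ## byte-identical GL tables
  f1 <- tempfile()
  f2 <- tempfile()
  write_gl_table(s1, f1)
  write_gl_table(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## truth is Mendelian-consistent without DNMs
  for (f in s1$families) {
    expect_equal(nrow(f$registry), 0)
  }
})

test_that("per-individual coverage allocation is honored", {
  cfg <- sim_config(n_sites = 400, region_length = 4000,
                    coverage = c(founder = 30, nonfounder = 5), seed = 66)
  sim <- simulate_dataset(cfg, make_pedigrees("3gen", 1))
  f <- sim$families[[1]]
  depth <- apply(f$counts, 2, sum) / 400
  founder <- f$ped$members$founder
  expect_lt(max(abs(depth[founder] - 30)), 3 * sqrt(30 / 400))
  expect_lt(max(abs(depth[!founder] - 5)), 3 * sqrt(5 / 400))
})
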