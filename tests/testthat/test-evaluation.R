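# hand-built toy call/truth structures for the counting metrics
toy_world <- function() {
  ped <- pedigree_trio("f")
  S <- 10
  ## truth: father and child het at sites 1-5 (allele C), rest hom-ref A
  hap1 <- matrix(1L, 3, S)
  hap2 <- matrix(1L, 3, S)
  hap2[1, 1:5] <- 2L
  hap2[3, 1:5] <- 2L
  sim <- structure(list(
    sites = data.frame(chrom = "c", pos = 1:S, ref = "A", alt = "C",
                       freq_true = 0.2, stringsAsFactors = FALSE),
    families = list(f = list(ped = ped, ids = ped$members$id,
                             hap1 = hap1, hap2 = hap2,
                             registry = data.frame()))),
    class = "famcall_sim")
  ## calls: sites 1-3 emitted with father+child het (correct), site 4
  ## emitted but both called hom-ref, site 5 and 6-10 unemitted
  gt <- matrix(NA_integer_, S, 3)
  gt[1:4, ] <- 0L
  gt[1:3, 1] <- 1L
  gt[1:3, 3] <- 1L
  sites <- data.frame(chrom = "c", pos = 1:S, ref = "A", a1 = "A",
                      alt = "C", qual = 30, af = 0.2, post_variant = 1,
                      emitted = c(rep(TRUE, 4), rep(FALSE, 6)),
                      stringsAsFactors = FALSE)
  calls <- structure(list(
    sites = sites,
    geno = list(f = list(fam = "f", ids = ped$members$id, gt = gt,
                         gq = gt * 0 + 99, ds = gt)),
    peds = list(ped), mode = "family", params = list()),
    class = "famcall_calls")
  list(sim = sim, calls = calls)
}

test_that("false negative rate counts missed non-reference genotypes", {
  w <- toy_world()
  fnr <- false_negative_rate(w$calls, w$sim)
  ## father and child: 5 true non-ref each, 3 recovered -> 40%; the mother
  ## has no non-reference genotypes and is excluded from the average
  expect_equal(unname(fnr$per_individual["f:ch"]), 40)
  expect_equal(unname(fnr$per_individual["f:fa"]), 40)
  expect_true(is.na(fnr$per_individual["f:mo"]))
  expect_equal(fnr$fnr, 40)
})

test_that("mismatch rates partition by true genotype category", {
  w <- toy_world()
  mm <- mismatch_rates(w$calls, w$sim)
  ## variant sites in truth: 1-5; Het cells: father + child at 5 sites,
  ## 2 wrong each (site 4 called hom-ref, site 5 unemitted)
  expect_equal(unname(mm$overall["Het"]), 40)
  expect_equal(unname(mm$overall["HomRef"]), 0)
  expect_equal(unname(mm$counts["Het"]), 10)
  expect_equal(unname(mm$counts["HomRef"]), 5)
  expect_equal(unname(mm$counts["All"]),
               unname(mm$counts["HomRef"] + mm$counts["Het"] +
                        mm$counts["HomAlt"]))
  expect_equal(unname(mm$overall["All"]), 100 * 4 / 15)
  ## frequency stratification: all cells fall in the freq = 0.2 bin
  expect_equal(nrow(mm$by_freq), 10)
  expect_equal(mm$by_freq$All[2], unname(mm$overall["All"]))
  expect_true(all(mm$by_freq$All[-2] == 0))
})

test_that("Mendelian inconsistency counting and pooling", {
  w <- toy_world()
  ## make site 2 inconsistent: child hom-alt with a hom-ref mother
  w$calls$geno$f$gt[2, 3] <- 2L
  mi <- mendelian_inconsistency_rate(w$calls, w$sim)
  expect_equal(mi$n_triplets, 1)
  expect_equal(mi$n_sites, 5)  # truth-variant sites only
  expect_equal(mi$n_inconsistent, 1)
  expect_equal(mi$rate, 1 / 5)
  ## without truth: denominator is all sites in the call set
  mi2 <- mendelian_inconsistency_rate(w$calls)
  expect_equal(mi2$rate, 1 / 10)
  ## fully consistent calls -> 0
  w2 <- toy_world()
  expect_equal(mendelian_inconsistency_rate(w2$calls, w2$sim)$rate, 0)
})

test_that("dnm power/fpr sweep is monotone in the threshold", {
  cand <- data.frame(pos = c(1, 2, 3), child = "ch",
                     lr = c(5, 50, 500))
  reg <- data.frame(pos = 1:4, individual = "ch")
  nullc <- data.frame(pos = 8:9, child = "ch", lr = c(20, 3))
  tab <- dnm_power_fpr(cand, reg, lr_grid = c(1, 10, 100, 1000),
                       null_candidates = nullc, n_transmissions = 1000)
  expect_equal(tab$power, c(75, 50, 25, 0))
  expect_equal(tab$fpr, c(2, 1, 0, 0) / 1000)
  expect_true(all(diff(tab$power) <= 0))
  expect_true(all(diff(tab$fpr) <= 0))
  ## empty candidates -> power 0
  tab0 <- dnm_power_fpr(cand[0, ], reg, lr_grid = 10)
  expect_equal(tab0$power, 0)
})

test_that("Ts/Tv ratio", {
  df <- data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "C"))
  expect_equal(ts_tv_ratio(df), 2)
  expect_warning(r <- ts_tv_ratio(data.frame(ref = "A", alt = "G")),
                 "transversion")
  expect_true(is.nan(r))
  ## random substitutions: 2 of 6 pair classes are transitions -> 0.5
  set.seed(70)
  n <- 1e5
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  r <- ts_tv_ratio(data.frame(ref = ref, alt = alt))
  expect_lt(abs(r - 0.5), 0.02)
})
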