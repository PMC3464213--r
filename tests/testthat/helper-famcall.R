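# shared fixtures: random genotype likelihoods and small random pedigrees
# for oracle comparisons

rand_gl <- function() {
  stats::setNames(stats::rnorm(10, sd = 2), genotype_names())
}

# near-certain 10-genotype log-likelihood vector for a genotype string
certain_gl <- function(g, logodds = 50) {
  ll <- rep(-logodds, 10)
  names(ll) <- genotype_names()
  ll[g] <- 0
  ll
}

gl_from_bases <- function(bases, e = 0.01) {
  compute_all_likelihoods(pileup(bases, e))
}

# random small pedigree (<= 6 members) for brute-force comparisons
rand_small_pedigree <- function() {
  type <- sample(c("trio", "quartet", "threegen6", "sibs", "two_fam"), 1)
  switch(type,
    trio = pedigree_trio("r"),
    quartet = pedigree("r", id = c("fa", "mo", "c1", "c2"),
                       father = c(NA, NA, "fa", "fa"),
                       mother = c(NA, NA, "mo", "mo")),
    threegen6 = pedigree("r", id = c("a", "b", "c", "d", "e", "f"),
                         father = c(NA, NA, "a", "a", NA, "c"),
                         mother = c(NA, NA, "b", "b", NA, "e")),
    sibs = pedigree("r", id = c("fa", "mo", "c1", "c2", "c3"),
                    father = c(NA, NA, "fa", "fa", "fa"),
                    mother = c(NA, NA, "mo", "mo", "mo")),
    two_fam = pedigree("r", id = c("fa", "mo", "c1", "sp", "g1", "g2"),
                       father = c(NA, NA, "fa", NA, "c1", "c1"),
                       mother = c(NA, NA, "mo", NA, "sp", "sp")))
}

rand_gls_for <- function(ped) {
  stats::setNames(lapply(ped$members$id, function(i) rand_gl()),
                  ped$members$id)
}

# tiny simulated dataset for pipeline tests
tiny_sim <- function(n_ped = 2, n_sites = 300, coverage = 10, seed = 99,
                     type = "3gen", base_error = 0.01) {
  simulate_dataset(
    sim_config(n_sites = n_sites, region_length = 10 * n_sites,
               coverage = coverage, base_error = base_error, seed = seed),
    make_pedigrees(type, n_ped))
}
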