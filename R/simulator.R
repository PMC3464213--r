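## Pedigree sequencing simulator with known truth.
##
## World being emulated: independent biallelic SNV sites whose alternative
## allele frequency follows the neutral site frequency spectrum
## P(freq = i/n) proportional to 1/i; founder haplotypes drawn independently
## at that frequency; gene dropping through the pedigrees with crossovers at
## a constant per-bp recombination rate (1.5e-8 per meiosis); per-site
## per-individual read depth Poisson with mean c; each base drawn 50/50
## from the two alleles and miscalled uniformly to one of the three other
## bases with probability e; optional germline de novo mutations at
## 1.4e-8 per transmitted allele per generation.  Sites are independent (no
## linkage disequilibrium); all randomness flows from `config$seed`.

#' Simulation configuration
#'
#' @param n_sites Number of candidate variant sites.
#' @param region_length Region length in bp (site positions are sampled
#'   uniformly without replacement).
#' @param sfs `"neutral"` for the 1/i site frequency spectrum, or a numeric
#'   vector of fixed alternative allele frequencies sampled uniformly.
#' @param coverage Mean sequencing depth: a scalar, or a named vector
#'   `c(founder = , nonfounder = )` for differential allocation, or a
#'   vector with one entry per pedigree member.
#' @param base_error Per-base miscall probability e (Q20 = 0.01,
#'   Q30 = 0.001).
#' @param recomb_rate Per-bp per-meiosis recombination rate.
#' @param dnm_rate De novo mutation rate per site per transmitted allele
#'   per generation.
#' @param seed Integer seed; the full dataset is deterministic given it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_sites = 20000L, region_length = 1e6,
                       sfs = "neutral", coverage = 5, base_error = 0.01,
                       recomb_rate = 1.5e-8, dnm_rate = 1.4e-8,
                       seed = 1L) {
  stopifnot(n_sites >= 0, region_length >= n_sites, all(coverage >= 0),
            base_error >= 0, base_error <= 1, recomb_rate >= 0,
            dnm_rate >= 0)
  structure(list(n_sites = as.integer(n_sites),
                 region_length = region_length, sfs = sfs,
                 coverage = coverage, base_error = base_error,
                 recomb_rate = recomb_rate, dnm_rate = dnm_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate founder haplotypes under a neutral SFS
#'
#' Per site, an alternative allele frequency is drawn from the neutral
#' spectrum `P(freq = i/n) proportional to 1/i` (`n = n_haplotypes`) or
#' from the configured fixed-frequency list; haplotype alleles are then
#' sampled independently at that frequency.  Each site gets a uniform
#' reference allele and an alternative that is the transition with
#' probability 2/3, otherwise one of the two transversions.
#'
#' @param n_haplotypes Even number of haplotypes (2 per diploid founder).
#' @param n_sites Number of sites.
#' @param config A [sim_config()] (only `sfs` is used here).
#' @return List: `haps` (0/1 matrix `n_haplotypes x n_sites`, 1 = alt),
#'   `freq` (drawn frequencies), `ref`, `alt` (allele indices 1..4).
#' @export
simulate_founder_haplotypes <- function(n_haplotypes, n_sites,
                                        config = sim_config()) {
  stopifnot(n_haplotypes >= 2, n_haplotypes %% 2 == 0)
  n_sites <- as.integer(n_sites)
  if (identical(config$sfs, "neutral")) {
    i <- sample.int(n_haplotypes - 1L, n_sites, replace = TRUE,
                    prob = 1 / seq_len(n_haplotypes - 1L))
    freq <- i / n_haplotypes
  } else {
    freq <- sample(as.numeric(config$sfs), n_sites, replace = TRUE)
  }
  haps <- matrix(stats::rbinom(n_haplotypes * n_sites, 1L,
                               rep(freq, each = n_haplotypes)),
                 nrow = n_haplotypes)
  ref <- sample.int(4L, n_sites, replace = TRUE)
  transition_of <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T
  is_ts <- stats::runif(n_sites) < 2 / 3
  alt <- integer(n_sites)
  alt[is_ts] <- transition_of[ref[is_ts]]
  if (any(!is_ts)) {
    tv <- which(!is_ts)
    for (s in tv) {
      others <- setdiff(1:4, c(ref[s], transition_of[ref[s]]))
      alt[s] <- others[sample.int(2L, 1L)]
    }
  }
  list(haps = haps, freq = freq, ref = ref, alt = alt)
}

## one meiosis: recombine the parent's two allele haplotypes (vectors over
## sites at `positions`) and return the transmitted haplotype
meiosis <- function(h1, h2, positions, recomb_rate, region_length) {
  k <- stats::rpois(1L, recomb_rate * region_length)
  start <- sample.int(2L, 1L)
  if (k == 0L) {
    return(if (start == 1L) h1 else h2)
  }
  cross <- sort(stats::runif(k, 0, region_length))
  strand <- (start - 1L + findInterval(positions, cross)) %% 2L
  ifelse(strand == 0L, h1, h2)
}

#' Drop founder haplotypes through a pedigree
#'
#' Founders take consecutive haplotype pairs from `founder_haps`;
#' every non-founder receives one recombinant haplotype per parent
#' (crossovers Poisson with mean `recomb_rate * region_length`, positions
#' uniform, random start strand).
#'
#' @param ped A [pedigree()].
#' @param founder_haps Matrix of allele indices (rows = haplotypes, columns
#'   = sites), at least 2 rows per founder.
#' @param positions Site positions in bp.
#' @param recomb_rate Per-bp per-meiosis recombination rate.
#' @param region_length Region length in bp.
#' @return List `hap1`, `hap2`: allele-index matrices
#'   `n_members x n_sites` (hap1 = paternal for non-founders).
#' @export
gene_drop <- function(ped, founder_haps, positions, recomb_rate = 1.5e-8,
                      region_length = max(positions)) {
  m <- ped$members
  n <- nrow(m)
  S <- ncol(founder_haps)
  founders <- which(m$founder)
  if (nrow(founder_haps) < 2 * length(founders)) {
    stop("not enough founder haplotypes: need ", 2 * length(founders))
  }
  hap1 <- matrix(0L, n, S)
  hap2 <- matrix(0L, n, S)
  for (k in seq_along(founders)) {
    hap1[founders[k], ] <- founder_haps[2L * k - 1L, ]
    hap2[founders[k], ] <- founder_haps[2L * k, ]
  }
  fa <- match(m$father, m$id)
  mo <- match(m$mother, m$id)
  done <- m$founder
  while (!all(done)) {
    ready <- which(!done & done[ifelse(is.na(fa), 1L, fa)] &
                     done[ifelse(is.na(mo), 1L, mo)])
    if (!length(ready)) stop("unresolvable pedigree order")
    for (i in ready) {
      hap1[i, ] <- meiosis(hap1[fa[i], ], hap2[fa[i], ], positions,
                           recomb_rate, region_length)
      hap2[i, ] <- meiosis(hap1[mo[i], ], hap2[mo[i], ], positions,
                           recomb_rate, region_length)
      done[i] <- TRUE
    }
  }
  list(hap1 = hap1, hap2 = hap2)
}

#' Inject germline de novo mutations
#'
#' In stochastic mode every transmitted allele (2 per non-founder per site)
#' mutates with total probability `dnm_rate`, the target allele drawn from
#' the normalized off-diagonal of the mutation matrix row.  In forced mode
#' (`forced` data frame with columns `site`, `individual`) exactly one
#' transmitted allele of each listed child mutates at the listed site.
#'
#' @param drop Result of [gene_drop()].
#' @param ped The [pedigree()].
#' @param dnm_rate Per-allele per-generation mutation probability.
#' @param model A [mutation_model()] providing the target-allele
#'   distribution.
#' @param forced Optional data frame `site` (index), `individual` (id).
#' @return List `hap1`, `hap2`, `registry` (data frame: `site`,
#'   `individual`, `from`, `to` allele indices).
#' @export
inject_denovo <- function(drop, ped, dnm_rate = 1.4e-8,
                          model = mutation_model(), forced = NULL) {
  m <- ped$members
  S <- ncol(drop$hap1)
  registry <- data.frame(site = integer(), individual = character(),
                         from = integer(), to = integer(),
                         stringsAsFactors = FALSE)
  M <- model$matrix
  mutate_one <- function(from) {
    w <- M[from, ]
    w[from] <- 0
    if (sum(w) <= 0) return(from)
    sample.int(4L, 1L, prob = w)
  }
  kids <- which(!m$founder)
  if (!is.null(forced)) {
    for (r in seq_len(nrow(forced))) {
      i <- match(forced$individual[r], m$id)
      s <- forced$site[r]
      side <- sample.int(2L, 1L)
      h <- if (side == 1L) "hap1" else "hap2"
      from <- drop[[h]][i, s]
      to <- mutate_one(from)
      drop[[h]][i, s] <- to
      registry <- rbind(registry, data.frame(
        site = s, individual = m$id[i], from = from, to = to,
        stringsAsFactors = FALSE))
    }
  } else if (dnm_rate > 0 && length(kids)) {
    n_trans <- 2L * length(kids) * S
    n_mut <- stats::rbinom(1L, n_trans, dnm_rate)
    if (n_mut > 0) {
      picks <- sample.int(n_trans, n_mut)
      for (p in picks) {
        side <- ((p - 1L) %% 2L) + 1L
        rest <- (p - 1L) %/% 2L
        ki <- kids[(rest %% length(kids)) + 1L]
        s <- (rest %/% length(kids)) + 1L
        h <- if (side == 1L) "hap1" else "hap2"
        from <- drop[[h]][ki, s]
        to <- mutate_one(from)
        drop[[h]][ki, s] <- to
        registry <- rbind(registry, data.frame(
          site = s, individual = m$id[ki], from = from, to = to,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(hap1 = drop$hap1, hap2 = drop$hap2, registry = registry)
}

#' Simulate a base pileup for one genotype
#'
#' Depth is Poisson with mean `coverage`; each base originates from either
#' allele with probability 1/2 and is miscalled uniformly to one of the
#' three other bases with probability `base_error`.
#'
#' @param genotype Two allele symbols (e.g. `c("A", "C")` or `"AC"`).
#' @param coverage Mean depth.
#' @param base_error Miscall probability.
#' @return A [pileup()] with constant error `base_error`.
#' @export
simulate_pileup <- function(genotype, coverage, base_error) {
  al <- if (length(genotype) == 1L) strsplit(genotype, "")[[1]] else genotype
  a <- allele_index(al)
  stopifnot(length(a) == 2L, coverage >= 0)
  d <- stats::rpois(1L, coverage)
  if (d == 0L) return(pileup())
  tmpl <- a[sample.int(2L, d, replace = TRUE)]
  err <- stats::runif(d) < base_error
  obs <- tmpl
  if (any(err)) {
    obs[err] <- vapply(tmpl[err], function(x) {
      setdiff(1:4, x)[sample.int(3L, 1L)]
    }, integer(1))
  }
  pileup(ALLELES[obs], rep(max(base_error, 1e-10), d))
}

## base-count sampling equivalent to per-base simulation: counts | depth
## are multinomial with the genotype's emission probabilities, drawn as a
## chain of binomials (vectorized over all site x member cells)
simulate_counts <- function(hap1, hap2, coverage_by_member, base_error) {
  n <- nrow(hap1)
  S <- ncol(hap1)
  d <- matrix(stats::rpois(n * S, rep(coverage_by_member, times = S)),
              n, S)
  e <- base_error
  counts <- array(0L, c(S, n, 4L))
  rem <- d
  acc <- matrix(0, n, S)  # cumulative probability already consumed
  for (b in 1:4) {
    pb <- e / 3 + (1 - 4 * e / 3) * ((hap1 == b) + (hap2 == b)) / 2
    if (b < 4L) {
      cond <- pb / pmax(1 - acc, 1e-15)
      cond[cond > 1] <- 1
      nb <- matrix(stats::rbinom(n * S, as.vector(rem), as.vector(cond)),
                   n, S)
      rem <- rem - nb
      acc <- acc + pb
    } else {
      nb <- rem
    }
    counts[, , b] <- t(nb)
  }
  counts
}

## per-member mean coverage from a config coverage spec
resolve_coverage <- function(coverage, ped) {
  n <- nrow(ped$members)
  if (length(coverage) == 1L && is.null(names(coverage))) {
    return(rep(as.numeric(coverage), n))
  }
  if (!is.null(names(coverage)) &&
      all(c("founder", "nonfounder") %in% names(coverage))) {
    return(ifelse(ped$members$founder, coverage[["founder"]],
                  coverage[["nonfounder"]]))
  }
  if (length(coverage) == n) return(as.numeric(coverage))
  stop("coverage must be a scalar, c(founder=, nonfounder=), or one value ",
       "per member")
}

#' Simulate a full pedigree sequencing dataset
#'
#' Runs the whole pipeline -- founder haplotypes from the neutral SFS,
#' gene dropping with recombination, stochastic de novo mutation
#' injection, Poisson-depth base counts with uniform miscalls -- for a list
#' of pedigrees sharing one set of polymorphic sites.  Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param peds List of [pedigree()]s (pedigree ids must be unique; member
#'   ids may repeat across families).
#' @param model [mutation_model()] used for de novo target alleles.
#' @return Object of class `"famcall_sim"`: `sites` (data frame `chrom`,
#'   `pos`, `ref`, `alt`, `freq_true`), `families` (per pedigree: `ped`,
#'   `ids`, `hap1`, `hap2`, `counts`, `registry`), `base_error`, `config`.
#' @export
simulate_dataset <- function(config, peds, model = mutation_model()) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(peds, "pedigree")) peds <- list(peds)
  set.seed(config$seed)
  S <- config$n_sites
  n_founders <- vapply(peds, function(p) sum(p$members$founder), numeric(1))
  fh <- simulate_founder_haplotypes(2L * sum(n_founders), S, config)
  positions <- sort(sample.int(config$region_length, S))
  ## allele-coded haplotypes
  hap_alleles <- matrix(fh$ref[col(fh$haps)], nrow(fh$haps))
  hap_alleles[fh$haps == 1L] <- fh$alt[col(fh$haps)][fh$haps == 1L]
  offset <- 0L
  families <- vector("list", length(peds))
  for (k in seq_along(peds)) {
    ped <- peds[[k]]
    nf <- n_founders[k]
    rows <- offset + seq_len(2L * nf)
    offset <- offset + 2L * nf
    drop <- gene_drop(ped, hap_alleles[rows, , drop = FALSE], positions,
                      config$recomb_rate, config$region_length)
    inj <- inject_denovo(drop, ped, config$dnm_rate, model)
    cov <- resolve_coverage(config$coverage, ped)
    counts <- simulate_counts(inj$hap1, inj$hap2, cov, config$base_error)
    families[[k]] <- list(ped = ped, ids = ped$members$id,
                          hap1 = inj$hap1, hap2 = inj$hap2,
                          counts = counts, registry = inj$registry)
  }
  names(families) <- vapply(peds, `[[`, character(1), "fam")
  if (anyDuplicated(names(families))) {
    stop("pedigree family ids must be unique")
  }
  sites <- data.frame(chrom = "sim1", pos = positions,
                      ref = ALLELES[fh$ref], alt = ALLELES[fh$alt],
                      freq_true = fh$freq, stringsAsFactors = FALSE)
  structure(list(sites = sites, families = families,
                 base_error = max(config$base_error, 1e-10),
                 config = config),
            class = "famcall_sim")
}

#' @export
print.famcall_sim <- function(x, ...) {
  cat("<famcall simulated dataset>", nrow(x$sites), "sites,",
      length(x$families), "families,",
      sum(vapply(x$families, function(f) length(f$ids), numeric(1))),
      "individuals, base error", x$base_error, "\n")
  invisible(x)
}

#' Simulate forced de novo mutation trio sites
#'
#' Power-study generator mirroring the benchmark cohort of 300 sequenced
#' individuals: `n_trios` trios are sequenced at every site; at each of
#' `n_sites` independent sites the parents of the first trio are truly
#' homozygous reference and its child carries one germline de novo allele
#' (heterozygous, mutant base drawn from the mutation matrix, so
#' transition-biased); all remaining trios are homozygous reference.  The
#' cohort matters: the founder allele frequency is profiled jointly across
#' families per site, and the background trios pin it near 0 at a true de
#' novo site, exactly as a rate-based injection into a sequenced cohort
#' would.  Estimating power at the genome-wide mutation rate directly
#' would need ~1e10 site-transmissions, so power is estimated conditional
#' on a mutation having occurred.
#'
#' @param n_sites Number of independent sites.
#' @param coverage Mean depth (scalar or per-member length 3).
#' @param base_error Miscall probability.
#' @param model [mutation_model()] for the mutant target allele.
#' @param seed Integer seed.
#' @param n_trios Total sequenced trios per site (default 100, i.e. 300
#'   individuals).
#' @return A `famcall_sim` object; the carrier family is `t001` and its
#'   registry lists one de novo event per site.
#' @export
simulate_dnm_trios <- function(n_sites = 1000L, coverage = 30,
                               base_error = 0.01,
                               model = mutation_model(), seed = 1L,
                               n_trios = 100L) {
  set.seed(seed)
  S <- as.integer(n_sites)
  ref <- sample.int(4L, S, replace = TRUE)
  empty_reg <- data.frame(site = integer(), individual = character(),
                          from = integer(), to = integer(),
                          stringsAsFactors = FALSE)
  families <- vector("list", n_trios)
  for (k in seq_len(n_trios)) {
    ped <- pedigree_trio(sprintf("t%03d", k))
    hap1 <- matrix(rep(ref, each = 3L), 3L, S)
    hap2 <- hap1
    if (k == 1L) {
      forced <- data.frame(site = seq_len(S), individual = "ch",
                           stringsAsFactors = FALSE)
      inj <- inject_denovo(list(hap1 = hap1, hap2 = hap2), ped,
                           model = model, forced = forced)
    } else {
      inj <- list(hap1 = hap1, hap2 = hap2, registry = empty_reg)
    }
    cov <- resolve_coverage(coverage, ped)
    counts <- simulate_counts(inj$hap1, inj$hap2, cov, base_error)
    families[[k]] <- list(ped = ped, ids = ped$members$id,
                          hap1 = inj$hap1, hap2 = inj$hap2,
                          counts = counts, registry = inj$registry)
  }
  names(families) <- vapply(families, function(f) f$ped$fam, character(1))
  carrier <- families[[1L]]
  sites <- data.frame(chrom = "sim1", pos = seq_len(S),
                      ref = ALLELES[ref],
                      alt = ALLELES[ifelse(carrier$hap1[3L, ] != ref,
                                           carrier$hap1[3L, ],
                                           carrier$hap2[3L, ])],
                      freq_true = 0, stringsAsFactors = FALSE)
  structure(list(sites = sites, families = families,
                 base_error = max(base_error, 1e-10),
                 config = sim_config(n_sites = S, region_length = S,
                                     coverage = coverage,
                                     base_error = base_error, seed = seed)),
            class = "famcall_sim")
}
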