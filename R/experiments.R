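## Ready-made simulation experiments: simulate a set of pedigrees, call the
## same dataset family-aware and/or unrelated, and evaluate against truth.
## These drive the acceptance checks and give users one-call
## reproductions of the benchmark scenarios.

#' Build replicate pedigrees of a standard structure
#'
#' @param type `"trio"`, `"nuclear2"` (2 parents + 2 sibs), `"nuclear3"`,
#'   `"sibs4"`, `"3gen"` (10-person 3-generation), or `"cousin"`
#'   (10-person first-cousin marriage).
#' @param n Number of replicate pedigrees (family ids `f001`, ...).
#' @return List of [pedigree()]s.
#' @export
make_pedigrees <- function(type = "3gen", n = 1L) {
  builder <- switch(type,
    trio = pedigree_trio,
    nuclear2 = function(id) pedigree_nuclear(id, 2L),
    nuclear3 = function(id) pedigree_nuclear(id, 3L),
    sibs4 = function(id) pedigree_nuclear(id, 4L, parents = 0L),
    "3gen" = pedigree_3gen,
    cousin = pedigree_first_cousin,
    stop("unknown pedigree type: ", type))
  ## member ids are family-qualified so flat per-individual formats
  ## (GL table, VCF sample columns) stay unambiguous across replicates
  lapply(seq_len(n), function(k) {
    fam <- sprintf("f%03d", k)
    prefix_member_ids(builder(fam), paste0(fam, "-"))
  })
}

## rename all members (and parent references) with a prefix
prefix_member_ids <- function(ped, prefix) {
  m <- ped$members
  m$id <- paste0(prefix, m$id)
  m$father <- ifelse(is.na(m$father), NA, paste0(prefix, m$father))
  m$mother <- ifelse(is.na(m$mother), NA, paste0(prefix, m$mother))
  m$gl_source <- paste0(prefix, m$gl_source)
  ped$members <- m
  ped
}

#' Simulate, call and evaluate one benchmark scenario
#'
#' Simulates `n_pedigrees` replicates of a pedigree structure over shared
#' polymorphic sites, calls the dataset in the requested modes and
#' evaluates each call set against the truth.
#'
#' @param n_pedigrees Number of replicate pedigrees.
#' @param pedigree_type See [make_pedigrees()].
#' @param n_sites Number of simulated sites.
#' @param coverage Mean depth (scalar or `c(founder=, nonfounder=)`).
#' @param base_error Per-base miscall probability.
#' @param seed Integer seed.
#' @param modes Character subset of `c("family", "unrelated")`.
#' @param theta Site prior scale.
#' @param model Optional [mutation_model()] for mutation-aware calling.
#' @param region_length Region length in bp.
#' @return List: `sim`, plus per mode `calls_<mode>` and
#'   `metrics_<mode>`.
#' @export
run_family_experiment <- function(n_pedigrees = 30L,
                                  pedigree_type = "3gen",
                                  n_sites = 20000L, coverage = 5,
                                  base_error = 0.01, seed = 1L,
                                  modes = c("family", "unrelated"),
                                  theta = 0.001, model = NULL,
                                  region_length = 1e6) {
  peds <- make_pedigrees(pedigree_type, n_pedigrees)
  cfg <- sim_config(n_sites = n_sites, region_length = region_length,
                    coverage = coverage, base_error = base_error,
                    seed = seed)
  sim <- simulate_dataset(cfg, peds)
  out <- list(sim = sim)
  for (mode in modes) {
    calls <- call_sites(sim, mode = mode, theta = theta, model = model)
    out[[paste0("calls_", mode)]] <- calls
    out[[paste0("metrics_", mode)]] <- evaluate_calls(calls, sim)
  }
  out
}

#' De novo mutation power experiment on forced-mutation trios
#'
#' Simulates independent trio sites that each carry one planted germline
#' mutation ([simulate_dnm_trios()]), calls them with the mutation-aware
#' model and claims candidates by the likelihood-ratio +
#' Mendelian-inconsistency rule.
#'
#' @param n_sites Number of trio sites.
#' @param coverage Mean depth.
#' @param base_error Miscall probability.
#' @param seed Integer seed.
#' @param model [mutation_model()] used both to plant and to score.
#' @param lr_threshold Claim threshold on the likelihood ratio.
#' @return List: `power` (percent of planted events claimed), `candidates`,
#'   `sim`, `calls`.
#' @export
dnm_power_experiment <- function(n_sites = 1000L, coverage = 30,
                                 base_error = 0.01, seed = 1L,
                                 model = mutation_model(),
                                 lr_threshold = 10) {
  sim <- simulate_dnm_trios(n_sites, coverage, base_error, model, seed)
  calls <- call_sites(sim, mode = "family", model = model)
  cand <- call_denovo(calls, lr_threshold = lr_threshold)
  carrier <- names(sim$families)[1L]
  reg <- sim$families[[1L]]$registry
  reg$pos <- sim$sites$pos[reg$site]
  detected <- paste(reg$pos, carrier, reg$individual) %in%
    paste(cand$pos, cand$fam, cand$child)
  list(power = 100 * mean(detected), candidates = cand, registry = reg,
       sim = sim, calls = calls)
}
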