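## Variant site discovery, founder allele-frequency estimation and genotype
## calling.
##
## At each site the caller scores seven allele configurations -- the
## monomorphic reference, the transition from the reference, the two
## transversions, and the three allele pairs excluding the reference --
## each by (coalescent prior) x (pedigree likelihood profiled over the
## founder alt allele frequency).  The maximum-posterior configuration
## defines the called alleles; the site quality is the Phred-scaled
## posterior probability that the site is monomorphic reference.

#' Coalescent prior probability that a site is variant
#'
#' In a sample of `n` diploid founders under the neutral coalescent the
#' prior probability that a site carries non-reference alleles is
#' `theta * sum_{i=1}^{2n-1} 1/i`, capped below 1.
#'
#' @param n_diploid_founders Number of diploid founders across all families
#'   (>= 1).
#' @param theta Population-scaled mutation rate per site (default `1/1000`).
#' @return Probability.
#' @export
#' @examples
#' variant_prior(1, 0.001)  # 0.001
#' variant_prior(2, 0.001)  # 0.001 * (1 + 1/2 + 1/3)
variant_prior <- function(n_diploid_founders, theta = 0.001) {
  if (n_diploid_founders < 1) stop("need at least one founder")
  if (theta < 0) stop("theta must be >= 0")
  min(theta * sum(1 / seq_len(2 * n_diploid_founders - 1)), 0.99)
}

#' Variant site prior configuration
#'
#' @param theta Population-scaled mutation rate per site.
#' @param p_transition Prior that a variant site is the transition of the
#'   reference.
#' @param p_transversion_each Prior for each of the two transversions.
#' @param p_double_factor Fraction of the variant mass assigned (split
#'   evenly) to the three allele pairs that exclude the reference.
#' @return List of class `"site_prior"`.
#' @export
site_prior <- function(theta = 0.001, p_transition = 2 / 3,
                       p_transversion_each = 1 / 6,
                       p_double_factor = 1e-3) {
  stopifnot(theta >= 0,
            p_transition + 2 * p_transversion_each <= 1 + 1e-12)
  structure(list(theta = theta, p_transition = p_transition,
                 p_transversion_each = p_transversion_each,
                 p_double_factor = p_double_factor),
            class = "site_prior")
}

## plans for a list of pedigrees; id_cols is a list (one entry per data
## block) of named vectors mapping individual id -> data column.
## mode "family": one unit per pedigree (loops broken automatically);
## mode "unrelated": one singleton unit per member.
build_plans <- function(peds, id_cols, data_fam_of_ped,
                        mode = c("family", "unrelated")) {
  mode <- match.arg(mode)
  plans <- list()
  for (k in seq_along(peds)) {
    ped <- peds[[k]]
    dfam <- data_fam_of_ped[k]
    ids <- ped$members$id
    cols <- id_cols[[dfam]][ids]
    ## members without a data column are fine if flagged unsequenced
    ## (column 0 = flat likelihoods); otherwise name the offenders
    miss <- is.na(cols)
    if (any(miss & ped$members$sequenced)) {
      stop("no genotype data column for sequenced individual(s): ",
           paste(ids[miss & ped$members$sequenced], collapse = ", "))
    }
    cols[miss | !ped$members$sequenced] <- 0L
    if (mode == "family") {
      broken <- detect_and_break_loops(ped)
      plan <- peeling_plan(broken$pedigree, data_fam = dfam)
      plan$glrow <- as.integer(cols[plan$glrow])
      plan$fam <- ped$fam
      plan$ids <- ids
      plans[[length(plans) + 1L]] <- plan
    } else {
      for (i in seq_along(ids)) {
        plans[[length(plans) + 1L]] <- list(
          data_fam = as.integer(dfam), n = 1L,
          glrow = as.integer(cols[i]), out_col = 1L,
          founder = 1L, sched = list(), singles = 1L,
          fam = ped$fam, ids = ids[i])
      }
    }
  }
  plans
}

## named list of GL vectors -> data block of dim (1, n, 10) + plans, used by
## the single-site entry points
single_site_input <- function(peds, gls) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  ids <- unlist(lapply(peds, function(p) p$members$id))
  if (anyDuplicated(ids)) {
    stop("individual ids must be unique across families")
  }
  block <- array(0, c(1L, length(ids), 10L))
  for (i in seq_along(ids)) {
    g <- gls[[ids[i]]]
    if (!is.null(g)) block[1L, i, ] <- as.numeric(g)
  }
  list(peds = peds, ids = ids, block = block,
       id_col = stats::setNames(seq_along(ids), ids))
}

#' Maximum-likelihood founder allele frequency
#'
#' Maximizes the summed family log-likelihoods over the alternative allele
#' frequency by a coarse scan followed by Brent search on
#' `[1e-8, 1 - 1e-8]` (absolute tolerance `1e-8`).
#'
#' @param peds A [pedigree()] or list of pedigrees.
#' @param gls Named list: individual id -> numeric 10-vector of natural-log
#'   genotype likelihoods.
#' @param alleles Length-2 character vector `(A1, A2)`.
#' @param model Optional [mutation_model()].
#' @return List with `alt_freq` (the MLE) and `max_loglik`.
#' @export
estimate_allele_frequency <- function(peds, gls, alleles, model = NULL) {
  inp <- single_site_input(peds, gls)
  if (all(vapply(inp$peds, function(p) {
    all(vapply(p$members$id, function(i) is.null(gls[[i]]) ||
                 diff(range(gls[[i]])) == 0, logical(1)))
  }, logical(1)))) {
    warning("no informative genotype likelihoods; returning freq = 0.5")
    return(list(alt_freq = 0.5, max_loglik = 0))
  }
  plans <- build_plans(inp$peds, list(inp$id_col),
                       rep(1L, length(inp$peds)), "family")
  a <- allele_index(alleles)
  cube <- as.numeric(transmission_cube(a, model))
  lls <- lapply(plans, function(pl) {
    idx <- c(gt10_index(a[1], a[1]), gt10_index(a[1], a[2]),
             gt10_index(a[2], a[2]))
    ll <- matrix(0, 3L, pl$n)
    for (i in seq_len(pl$n)) {
      if (pl$glrow[i] > 0L) ll[, i] <- inp$block[1L, pl$glrow[i], idx]
    }
    ll
  })
  ## plans reference columns of a shared block; peel wants member matrices
  plans0 <- lapply(plans, function(pl) {
    pl$glrow <- seq_len(pl$n)
    pl
  })
  cpp_estimate_freq(lls, plans0, cube, 1e-8)
}

#' Discover the variant configuration at one site
#'
#' Scores the seven candidate allele configurations at a single site from
#' per-individual 10-genotype likelihoods and returns the maximum-posterior
#' pair, the Phred-scaled site quality and the frequency estimate.
#'
#' @inheritParams estimate_allele_frequency
#' @param ref Reference allele symbol.
#' @param prior A [site_prior()].
#' @param model Optional [mutation_model()]; when supplied, transmissions
#'   are mutation-aware throughout.
#' @param emit_threshold Minimum posterior probability that the site is
#'   variant for `emitted` to be `TRUE`.
#' @return List with `a1`, `a2` (best pair, characters), `emitted`,
#'   `site_quality`, `post_variant`, `alt_freq`, `max_loglik` and the full
#'   per-family genotype matrices (`gt`, `gq`, `ds`, `log_lr`).
#' @export
discover_site <- function(peds, gls, ref, prior = site_prior(),
                          model = NULL, emit_threshold = 0.5) {
  inp <- single_site_input(peds, gls)
  plans <- build_plans(inp$peds, list(inp$id_col),
                       rep(1L, length(inp$peds)), "family")
  n_founders <- sum(vapply(inp$peds, function(p) sum(p$members$founder),
                           numeric(1)))
  res <- cpp_call_dataset(
    data = list(inp$block), is_gl = TRUE, eps = 0.01,
    ref = allele_index(ref), plans = plans,
    n_founders = as.integer(n_founders), theta = prior$theta,
    mutmat = if (is.null(model)) NULL else model$matrix,
    emit_threshold = emit_threshold,
    p_double_factor = prior$p_double_factor,
    compute_denovo = !is.null(model), keep_pl = FALSE, freq_tol = 1e-8)
  list(a1 = ALLELES[res$a1], a2 = ALLELES[res$a2],
       emitted = res$emitted[1L], site_quality = res$qual[1L],
       post_variant = res$post_variant[1L], alt_freq = res$alt_freq[1L],
       gt = res$gt, gq = res$gq, ds = res$ds, log_lr = res$log_lr,
       family_ids = lapply(plans, `[[`, "ids"))
}

#' Call genotypes for one family at a discovered site
#'
#' Computes per-member posteriors by conditioning on all family reads, then
#' records the modal genotype (ties broken toward fewer alternative
#' alleles), the Phred-scaled genotype quality `-10 log10(1 - max
#' posterior)` capped at 99, and the dosage `P(het) + 2 P(hom alt)`.
#'
#' @inheritParams family_log_likelihood
#' @return Data frame with one row per member: `id`, `genotype`
#'   (`"ref_ref"`, `"ref_alt"`, `"alt_alt"`), `alt_count`, `gq`, `dosage`
#'   and the three posterior columns.
#' @export
call_genotypes <- function(ped, gls, alleles, freq, model = NULL) {
  post <- genotype_posteriors(ped, gls, freq, alleles, model)
  modal <- max.col(post, ties.method = "first") # first = fewer alt alleles
  pmax_ <- post[cbind(seq_len(nrow(post)), modal)]
  gq <- pmin(-10 * log10(pmax(1 - pmax_, 1.26e-10)), 99)
  data.frame(id = rownames(post),
             genotype = colnames(post)[modal],
             alt_count = modal - 1L,
             gq = gq,
             dosage = post[, 2L] + 2 * post[, 3L],
             p_ref_ref = post[, 1L], p_ref_alt = post[, 2L],
             p_alt_alt = post[, 3L],
             row.names = NULL)
}

#' Call variants across a whole dataset
#'
#' Runs the per-site discovery/genotyping pipeline over every site of a
#' dataset (a simulated dataset from [simulate_dataset()] or a GL table
#' loaded with [read_gl_table()]), either modeling the pedigrees
#' (`mode = "family"`) or treating every individual as a singleton founder
#' family (`mode = "unrelated"`).  Founder allele frequencies are profiled
#' per site jointly across all families.  Pedigrees with consanguinity
#' loops are loop-broken automatically.
#'
#' @param dataset A `famcall_sim` or `famcall_gl` object.
#' @param peds List of [pedigree()]s; defaults to the pedigrees stored in a
#'   simulated dataset.
#' @param mode `"family"` or `"unrelated"`.
#' @param theta Population-scaled mutation rate for the site prior.
#' @param model Optional [mutation_model()]; enables mutation-aware
#'   transmission and per-family de novo likelihood ratios.
#' @param emit_threshold Variant posterior required to emit a site
#'   (default 0.5).
#' @param p_double_factor See [site_prior()].
#' @param keep_pl Keep per-genotype Phred PLs (needed for VCF output).
#' @return Object of class `"famcall_calls"`.
#' @export
call_sites <- function(dataset, peds = NULL,
                       mode = c("family", "unrelated"),
                       theta = 0.001, model = NULL, emit_threshold = 0.5,
                       p_double_factor = 1e-3, keep_pl = FALSE) {
  mode <- match.arg(mode)
  if (is.null(peds)) {
    if (is.null(dataset$families)) stop("`peds` is required for GL input")
    peds <- lapply(dataset$families, `[[`, "ped")
  }
  if (inherits(peds, "pedigree")) peds <- list(peds)
  is_gl <- inherits(dataset, "famcall_gl")
  if (is_gl) {
    blocks <- list(dataset$gl)
    id_cols <- list(stats::setNames(seq_along(dataset$ids), dataset$ids))
    data_fam_of_ped <- rep(1L, length(peds))
    eps <- 0.01
  } else {
    ## count blocks are stored per simulated family: pedigrees must match
    ## them one-to-one (regrouping is supported for GL-table input only)
    if (length(peds) != length(dataset$families)) {
      stop("`peds` must match the dataset families one-to-one for ",
           "count-based datasets")
    }
    blocks <- lapply(dataset$families, `[[`, "counts")
    data_fam_of_ped <- seq_along(peds)
    id_cols <- lapply(dataset$families, function(f) {
      stats::setNames(seq_along(f$ids), f$ids)
    })
    eps <- dataset$base_error
  }
  plans <- build_plans(peds, id_cols, data_fam_of_ped, mode)
  n_founders <- if (mode == "family") {
    sum(vapply(peds, function(p) sum(p$members$founder), numeric(1)))
  } else {
    sum(vapply(peds, function(p) nrow(p$members), numeric(1)))
  }
  ref_idx <- allele_index(dataset$sites$ref)
  res <- cpp_call_dataset(
    data = blocks, is_gl = is_gl, eps = eps, ref = ref_idx, plans = plans,
    n_founders = as.integer(n_founders), theta = theta,
    mutmat = if (is.null(model)) NULL else model$matrix,
    emit_threshold = emit_threshold, p_double_factor = p_double_factor,
    compute_denovo = !is.null(model), keep_pl = keep_pl, freq_tol = 1e-8)

  sites <- data.frame(chrom = dataset$sites$chrom,
                      pos = dataset$sites$pos,
                      ref = dataset$sites$ref,
                      alt = ALLELES[res$a2],
                      a1 = ALLELES[res$a1],
                      qual = res$qual,
                      af = res$alt_freq,
                      post_variant = res$post_variant,
                      emitted = res$emitted,
                      stringsAsFactors = FALSE)
  ## reassemble per-pedigree genotype matrices (units are individuals in
  ## unrelated mode)
  geno <- vector("list", length(peds))
  unit_fam <- vapply(plans, `[[`, character(1), "fam")
  fams <- vapply(peds, `[[`, character(1), "fam")
  for (k in seq_along(peds)) {
    units <- which(unit_fam == fams[k])
    ids <- unlist(lapply(plans[units], `[[`, "ids"))
    bindm <- function(el) do.call(cbind, el[units])
    g <- list(fam = fams[k], ids = ids,
              gt = bindm(res$gt), gq = bindm(res$gq), ds = bindm(res$ds))
    if (!is_gl) g$dp <- bindm(res$dp)
    if (keep_pl) {
      pl <- array(NA_integer_, c(nrow(sites), length(ids), 3L))
      off <- 0L
      for (u in res$pl[units]) {
        nu <- dim(u)[2L]
        pl[, off + seq_len(nu), ] <- u
        off <- off + nu
      }
      g$pl <- pl
    }
    if (!is.null(model) && mode == "family") g$log_lr <- res$log_lr[[units]]
    colnames(g$gt) <- ids
    geno[[k]] <- g
  }
  names(geno) <- fams
  structure(list(sites = sites, geno = geno, peds = peds, mode = mode,
                 params = list(theta = theta, emit_threshold = emit_threshold,
                               model = model,
                               p_double_factor = p_double_factor,
                               n_founders = n_founders)),
            class = "famcall_calls")
}

#' @export
print.famcall_calls <- function(x, ...) {
  cat("<famcall calls>", nrow(x$sites), "sites,",
      sum(x$sites$emitted), "emitted variants,",
      length(x$geno), "families, mode =", x$mode, "\n")
  invisible(x)
}
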