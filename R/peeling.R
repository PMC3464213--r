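## Pedigree likelihood by Elston-Stewart peeling, a brute-force enumeration
## oracle, and conditional genotype posteriors.
##
## The likelihood of the read data R for one family at a biallelic site with
## alleles (A1, A2) and founder alt frequency p is
##   L = sum over genotype vectors G of
##         prod_i GL_i(G_i) * prod_founders HWE(G_f; p)
##         * prod_triplets P(G_child | G_father, G_mother)
## Peeling evaluates this sum in time linear in pedigree size for loop-free
## pedigrees and matches the exhaustive nested sum exactly.

## build the 3 x n_members biallelic log-likelihood matrix for a plan.
## gls: named list, individual id -> numeric 10-vector of natural-log GLs
## (missing / NULL entries and unsequenced members give flat likelihoods)
member_ll_matrix <- function(ped, gls, alleles) {
  a <- if (is.character(alleles)) allele_index(alleles) else as.integer(alleles)
  stopifnot(length(a) == 2L)
  idx <- c(gt10_index(a[1L], a[1L]), gt10_index(a[1L], a[2L]),
           gt10_index(a[2L], a[2L]))
  m <- ped$members
  ll <- matrix(0, 3L, nrow(m))
  for (i in seq_len(nrow(m))) {
    g <- gls[[m$gl_source[i]]]
    if (!is.null(g) && isTRUE(m$sequenced[i])) {
      if (length(g) != 10L) stop("GL vector for ", m$gl_source[i],
                                 " must have length 10")
      ll[, i] <- as.numeric(g)[idx]
    }
  }
  ll
}

#' Family log-likelihood by Elston-Stewart peeling
#'
#' Computes the log-likelihood of all read data in one family at a biallelic
#' site, summing over every genotype configuration: founder genotypes follow
#' Hardy-Weinberg at the alternative allele frequency `freq`, offspring
#' genotypes follow Mendelian transmission (or mutation-aware transmission
#' when a [mutation_model()] is supplied), and each member contributes its
#' genotype likelihood.  Time is linear in pedigree size; the result equals
#' [brute_force_log_likelihood()] on loop-free pedigrees.
#'
#' @param ped A [pedigree()] (loop-free; run [detect_and_break_loops()]
#'   first for consanguineous pedigrees).
#' @param gls Named list: individual id -> numeric 10-vector of natural-log
#'   genotype likelihoods in canonical order.  Missing members carry flat
#'   likelihoods.
#' @param freq Alternative (A2) allele frequency in founders, in `[0, 1]`.
#' @param alleles Length-2 character vector `(A1, A2)`, e.g. `c("A", "C")`.
#' @param model Optional [mutation_model()].
#' @return Log-likelihood (natural log).
#' @export
family_log_likelihood <- function(ped, gls, freq, alleles, model = NULL) {
  stopifnot(inherits(ped, "pedigree"), freq >= 0, freq <= 1)
  plan <- peeling_plan(ped)
  ll <- member_ll_matrix(ped, gls, alleles)
  cube <- transmission_cube(allele_index(alleles), model)
  cpp_peel_loglik(ll, plan, freq, as.numeric(cube))
}

#' Exhaustive pedigree likelihood (test oracle)
#'
#' Evaluates the same nested sum as [family_log_likelihood()] by explicit
#' enumeration of all `3^n` biallelic genotype configurations.  Reference
#' implementation for validating the peeling engine; refuses pedigrees with
#' more than 8 members.
#'
#' @inheritParams family_log_likelihood
#' @return Log-likelihood (natural log).
#' @export
brute_force_log_likelihood <- function(ped, gls, freq, alleles,
                                       model = NULL) {
  post <- brute_force_engine(ped, gls, freq, alleles, model)
  post$loglik
}

## shared enumeration: returns total loglik and per-member conditional
## posteriors
brute_force_engine <- function(ped, gls, freq, alleles, model = NULL) {
  m <- ped$members
  n <- nrow(m)
  if (n > 8L) stop("brute force enumeration refuses pedigrees with > 8 members")
  ll <- member_ll_matrix(ped, gls, alleles)
  cube <- transmission_cube(allele_index(alleles), model)
  prior <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  fa <- match(m$father, m$id)
  mo <- match(m$mother, m$id)
  configs <- as.matrix(expand.grid(rep(list(1:3), n)))
  logw <- apply(configs, 1L, function(g) {
    v <- sum(ll[cbind(g, seq_len(n))])
    for (i in seq_len(n)) {
      if (m$founder[i]) {
        v <- v + log(prior[g[i]])
      } else {
        v <- v + log(cube[g[i], g[fa[i]], g[mo[i]]])
      }
    }
    v
  })
  mx <- max(logw)
  if (!is.finite(mx)) {
    return(list(loglik = -Inf,
                posteriors = matrix(1 / 3, n, 3,
                                    dimnames = list(m$id, NULL))))
  }
  w <- exp(logw - mx)
  total <- sum(w)
  post <- matrix(0, n, 3, dimnames = list(m$id, c("ref_ref", "ref_alt",
                                                  "alt_alt")))
  for (i in seq_len(n)) {
    for (g in 1:3) post[i, g] <- sum(w[configs[, i] == g]) / total
  }
  list(loglik = mx + log(total), posteriors = post)
}

#' Per-member genotype posteriors given all family reads
#'
#' For each family member, the posterior over `{RefRef, RefAlt, AltAlt}`
#' conditioning on the sequence data of the whole family, obtained by
#' clamped peeling.  Loop-breaking clones (ids suffixed `_dup`) are included
#' as separate rows; callers normally use the original member's row.
#'
#' @inheritParams family_log_likelihood
#' @return Numeric matrix `n_members x 3` with rownames the member ids and
#'   columns `ref_ref`, `ref_alt`, `alt_alt`; rows sum to 1.
#' @export
genotype_posteriors <- function(ped, gls, freq, alleles, model = NULL) {
  plan <- peeling_plan(ped)
  ll <- member_ll_matrix(ped, gls, alleles)
  cube <- transmission_cube(allele_index(alleles), model)
  post <- cpp_peel_posteriors(ll, plan, freq, as.numeric(cube))
  out <- t(post)
  dimnames(out) <- list(ped$members$id, c("ref_ref", "ref_alt", "alt_alt"))
  out
}
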