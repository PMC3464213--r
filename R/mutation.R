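## De novo mutation model: a 4x4 allele transition matrix applied
## independently to each transmitted allele in a meiosis.  Transitions
## (A<->G, C<->T) mutate at rate alpha per generation, each transversion at
## rate beta; the diagonal makes rows sum to 1.  The total per-allele
## mutation probability is therefore alpha + 2 * beta.

#' Germline mutation model
#'
#' Builds the per-generation 4x4 allele transition matrix used to make
#' parent-to-offspring transmission mutation-aware.  Either supply `alpha`
#' (transition rate) and `beta` (rate of each transversion) directly, supply
#' a total rate `mu` split between transition and transversions with
#' `alpha = 2 * beta` (transition twice as likely as each transversion, so
#' `alpha = mu/2`, `beta = mu/4`), or supply an arbitrary 4x4 `matrix` whose
#' rows sum to 1.
#'
#' @param mu Total per-allele per-generation mutation rate
#'   (`alpha + 2 beta`).  Default `1.5e-8` per site per generation.
#' @param alpha,beta Transition / per-transversion rates, overriding `mu`.
#' @param matrix Optional user 4x4 allele transition matrix (rows A,C,G,T
#'   summing to 1); overrides everything else.
#' @return Object of class `"mutation_model"`: list with `alpha`, `beta`,
#'   `mu` (total per-allele rate) and `matrix`.
#' @export
#' @examples
#' m <- mutation_model(mu = 1.5e-8)
#' rowSums(m$matrix)  # all 1
mutation_model <- function(mu = 1.5e-8, alpha = NULL, beta = NULL,
                           matrix = NULL) {
  if (!is.null(matrix)) {
    M <- unname(as.matrix(matrix))
    if (!all(dim(M) == c(4L, 4L)) || any(M < 0)) {
      stop("`matrix` must be a non-negative 4x4 matrix")
    }
    if (any(abs(rowSums(M) - 1) > 1e-12)) {
      stop("rows of `matrix` must sum to 1")
    }
    dimnames(M) <- list(ALLELES, ALLELES)
    ## summarise: average transition / transversion entries
    ts <- mean(M[cbind(c(1, 3, 2, 4), c(3, 1, 4, 2))])
    tv <- mean(M[upper.tri(M) | lower.tri(M)][-1]) # rough summary only
    return(structure(list(alpha = ts, beta = NA_real_,
                          mu = mean(1 - diag(M)), matrix = M),
                     class = "mutation_model"))
  }
  if (is.null(alpha) != is.null(beta)) {
    stop("supply both `alpha` and `beta`, or neither")
  }
  if (is.null(alpha)) {
    if (mu < 0) stop("`mu` must be >= 0")
    alpha <- mu / 2
    beta <- mu / 4
  }
  if (alpha < 0 || beta < 0) stop("rates must be >= 0")
  if (alpha + 2 * beta > 1) stop("total per-allele rate exceeds 1")
  M <- base::matrix(beta, 4L, 4L, dimnames = list(ALLELES, ALLELES))
  M[cbind(c(1, 3, 2, 4), c(3, 1, 4, 2))] <- alpha  # A<->G, C<->T
  diag(M) <- 1 - (alpha + 2 * beta)
  structure(list(alpha = alpha, beta = beta, mu = alpha + 2 * beta,
                 matrix = M),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("<mutation model> per-allele rate", format(x$mu, digits = 4),
      "(alpha =", format(x$alpha, digits = 4),
      ", beta =", format(x$beta, digits = 4), ")\n")
  invisible(x)
}

## per-parent-genotype allele transmission probabilities over an allele set.
## alleles: integer indices (length 2 for the biallelic space, or 1:4).
## Returns matrix [parent genotype over `alleles` pairs x transmitted allele]
## -- internal helper for transmission_cube.
allele_transmission <- function(parent_pair, target_allele, model) {
  M <- if (is.null(model)) diag(4) else model$matrix
  (M[parent_pair[1L], target_allele] + M[parent_pair[2L], target_allele]) / 2
}

#' Parent-to-offspring genotype transmission probability
#'
#' Under Mendelian transmission each parent passes one of its two alleles
#' with probability 1/2.  With a [mutation_model()] every transmitted allele
#' additionally passes through the 4x4 allele transition matrix, so an
#' offspring may carry alleles absent from both parents.  Probabilities sum
#' to 1 over the 10 possible child genotypes for fixed parents.
#'
#' @param child_g,father_g,mother_g Genotypes as 2-character strings (e.g.
#'   `"AC"`), unordered.
#' @param model A [mutation_model()], or `NULL` for strict Mendelian
#'   transmission.
#' @return Numeric probability.
#' @export
#' @examples
#' transmission_prob("AC", "AC", "AC")          # 0.5
#' transmission_prob("AA", "AA", "AA")          # 1
transmission_prob <- function(child_g, father_g, mother_g, model = NULL) {
  cg <- allele_index(strsplit(child_g, "")[[1]])
  fg <- allele_index(strsplit(father_g, "")[[1]])
  mg <- allele_index(strsplit(mother_g, "")[[1]])
  if (length(cg) != 2L || length(fg) != 2L || length(mg) != 2L) {
    stop("genotypes must consist of exactly 2 alleles")
  }
  ## P(father transmits x) * P(mother transmits y), summed over ordered
  ## (x, y) consistent with the unordered child genotype
  pf <- function(x) allele_transmission(fg, x, model)
  pm <- function(y) allele_transmission(mg, y, model)
  if (cg[1L] == cg[2L]) {
    pf(cg[1L]) * pm(cg[1L])
  } else {
    pf(cg[1L]) * pm(cg[2L]) + pf(cg[2L]) * pm(cg[1L])
  }
}

## 3x3x3 transmission table over the biallelic genotype space of an allele
## pair (a1, a2): T[child+1, father+1, mother+1] with genotypes coded by alt
## (a2) allele count 0/1/2.  With a mutation model, entries are the
## restriction of the full 4-allele transmission to {a1, a2}; rows then sum
## to slightly less than 1, the missing ~mu mass having leaked to the other
## two alleles (biallelic approximation).
transmission_cube <- function(alleles, model = NULL) {
  a <- as.integer(alleles)
  stopifnot(length(a) == 2L)
  M <- if (is.null(model)) diag(4) else model$matrix
  ## t[g+1, j]: P(parent with alt-count g transmits allele a_j)
  t <- rbind(c(M[a[1L], a[1L]], M[a[1L], a[2L]]),
             (c(M[a[1L], a[1L]], M[a[1L], a[2L]]) +
              c(M[a[2L], a[1L]], M[a[2L], a[2L]])) / 2,
             c(M[a[2L], a[1L]], M[a[2L], a[2L]]))
  cube <- array(0, c(3L, 3L, 3L))
  for (f in 1:3) for (m in 1:3) {
    cube[1L, f, m] <- t[f, 1L] * t[m, 1L]
    cube[2L, f, m] <- t[f, 1L] * t[m, 2L] + t[f, 2L] * t[m, 1L]
    cube[3L, f, m] <- t[f, 2L] * t[m, 2L]
  }
  cube
}
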