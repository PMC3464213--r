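## Genotype likelihoods from base pileups.
##
## Model: at one site for one individual, each aligned base b_j comes with an
## error probability e_j (Phred-convertible).  Conditional on a true diploid
## genotype the base originates from either allele with probability 1/2, is
## read correctly with probability 1 - e_j and is miscalled uniformly as one
## of the three alternative bases otherwise.  Base errors are independent, so
## the log-likelihood of the pileup is the sum of per-base log emissions.
## All computations are in natural-log space; Phred conversion happens only
## at I/O boundaries.

## floor for per-base error rates; Q-infinity inputs would otherwise give
## -Inf logs
ERR_FLOOR <- 1e-10

#' Base pileup at one site for one individual
#'
#' @param bases Character vector of observed bases (`"A"/"C"/"G"/"T"`); may
#'   be empty (missing data).
#' @param errors Numeric vector of per-base error probabilities in `[0, 1]`,
#'   recycled if length 1.  Errors below `1e-10` are clamped to `1e-10`.
#' @return An object of class `"pileup"`: list with integer `base` indices
#'   and clamped `error` probabilities.
#' @export
#' @examples
#' p <- pileup(c("A", "A", "C"), 0.01)
#' compute_all_likelihoods(p)
pileup <- function(bases = character(), errors = numeric()) {
  b <- if (length(bases)) allele_index(bases) else integer()
  if (length(errors) == 1L) errors <- rep(errors, length(b))
  if (length(errors) != length(b)) {
    stop("`bases` and `errors` lengths differ")
  }
  if (length(errors) && (any(errors < 0) || any(errors > 1))) {
    stop("error probabilities must lie in [0, 1]")
  }
  structure(list(base = b, error = pmax(errors, ERR_FLOOR)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("<pileup> depth", length(x$base), "\n")
  if (length(x$base)) {
    cat(" bases:", paste0(ALLELES[x$base], collapse = ""), "\n")
    cat(" mean error:", format(mean(x$error), digits = 4), "\n")
  }
  invisible(x)
}

#' Per-base emission probability
#'
#' Probability of observing base `b` given that the true template allele is
#' `a` and the call is wrong with probability `e`: `1 - e` on a match, `e/3`
#' on each of the three possible miscalls.
#'
#' @param b Observed base symbol.
#' @param a True allele symbol.
#' @param e Error probability in `[0, 1]`.
#' @return Numeric probability (vectorised over its arguments).
#' @export
#' @examples
#' base_given_allele("A", "A", 0.01)  # 0.99
#' base_given_allele("A", "C", 0.03)  # 0.01
base_given_allele <- function(b, a, e) {
  bi <- allele_index(b)
  ai <- allele_index(a)
  if (any(e < 0 | e > 1)) stop("error probability must lie in [0, 1]")
  ifelse(bi == ai, 1 - e, e / 3)
}

#' Log-likelihood of a pileup for one genotype
#'
#' Sum over bases of `log(0.5 P(b | a1, e) + 0.5 P(b | a2, e))`; for
#' homozygous genotypes the mixture collapses to a single emission term.  An
#' empty pileup has log-likelihood 0 for every genotype.
#'
#' @param pu A [pileup()].
#' @param g Genotype as a 2-character string (e.g. `"AC"`) or a length-2
#'   vector of allele symbols.  Unordered.
#' @return Natural-log likelihood (scalar).
#' @export
genotype_log_likelihood <- function(pu, g) {
  stopifnot(inherits(pu, "pileup"))
  al <- if (length(g) == 1L) strsplit(g, "")[[1]] else as.character(g)
  if (length(al) != 2L) stop("genotype must consist of exactly 2 alleles")
  a <- allele_index(al)
  if (!length(pu$base)) return(0)
  e <- pu$error
  p1 <- ifelse(pu$base == a[1L], 1 - e, e / 3)
  p2 <- ifelse(pu$base == a[2L], 1 - e, e / 3)
  sum(log(0.5 * p1 + 0.5 * p2))
}

#' All 10 genotype log-likelihoods for a pileup
#'
#' @param pu A [pileup()].
#' @return Named numeric vector of length 10 in canonical genotype order
#'   (class `"genotype_likelihoods"`), natural-log scale.
#' @export
compute_all_likelihoods <- function(pu) {
  stopifnot(inherits(pu, "pileup"))
  counts <- tabulate(pu$base, 4L)
  if (!length(pu$base)) {
    ll <- numeric(10L)
  } else if (length(unique(pu$error)) == 1L) {
    ## constant error rate: likelihood depends on base counts only
    ll <- as.numeric(counts %*% log_emission_matrix(pu$error[1L]))
  } else {
    ll <- vapply(seq_len(10L), function(k) {
      a <- GT10_PAIRS[, k]
      e <- pu$error
      p1 <- ifelse(pu$base == a[1L], 1 - e, e / 3)
      p2 <- ifelse(pu$base == a[2L], 1 - e, e / 3)
      sum(log(0.5 * p1 + 0.5 * p2))
    }, numeric(1))
  }
  structure(stats::setNames(ll, GT10_NAMES), class = "genotype_likelihoods")
}

#' @export
print.genotype_likelihoods <- function(x, ...) {
  cat("<genotype log-likelihoods>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

## 4 x 10 matrix: log P(observed base b | genotype g) at constant error e
log_emission_matrix <- function(e) {
  e <- max(e, ERR_FLOOR)
  m <- matrix(0, 4L, 10L, dimnames = list(ALLELES, GT10_NAMES))
  for (k in seq_len(10L)) {
    a <- GT10_PAIRS[, k]
    for (b in 1:4) {
      p1 <- if (b == a[1L]) 1 - e else e / 3
      p2 <- if (b == a[2L]) 1 - e else e / 3
      m[b, k] <- log(0.5 * p1 + 0.5 * p2)
    }
  }
  m
}

#' Phred-scaled PL vector from genotype likelihoods
#'
#' `PL_i = round(-10 log10(L_i / max_k L_k))`; the most likely genotype gets
#' 0.  Order follows the canonical 10-genotype ordering (or the order of the
#' input vector for biallelic 3-vectors).
#'
#' @param gls Numeric vector of natural-log likelihoods (any length).
#' @return Integer vector of the same length.
#' @export
phred_scale <- function(gls) {
  ll <- as.numeric(gls)
  if (!length(ll)) return(integer())
  if (any(!is.finite(ll))) stop("log-likelihoods must be finite")
  pl <- as.integer(round(-10 * (ll - max(ll)) / log(10)))
  stats::setNames(pl, names(gls))
}
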