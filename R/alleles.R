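## Allele and genotype bookkeeping shared by every module.
##
## Alleles are indexed 1..4 = A, C, G, T.  The canonical 10-genotype order is
## AA, AC, AG, AT, CC, CG, CT, GG, GT, TT (unordered pairs, lexicographic);
## every 10-vector in the package (genotype likelihoods, Phred PLs, the
## tabular GL format) follows it.

#' @keywords internal
ALLELES <- c("A", "C", "G", "T")

## 2 x 10 matrix of allele indices per canonical genotype
GT10_PAIRS <- local({
  p <- matrix(0L, 2L, 10L)
  k <- 0L
  for (i in 1:4) for (j in i:4) {
    k <- k + 1L
    p[, k] <- c(i, j)
  }
  p
})

GT10_NAMES <- apply(GT10_PAIRS, 2L, function(p) paste0(ALLELES[p], collapse = ""))

#' Canonical genotype names
#'
#' The fixed 10-genotype ordering (`AA, AC, AG, AT, CC, CG, CT, GG, GT, TT`)
#' used for all genotype-likelihood vectors and the tabular GL format.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' genotype_names()
genotype_names <- function() GT10_NAMES

allele_index <- function(a) {
  i <- match(toupper(a), ALLELES)
  if (anyNA(i)) {
    stop("invalid allele symbol(s): ",
         paste(unique(a[is.na(i)]), collapse = ", "))
  }
  i
}

## index into the canonical 10-vector for an unordered allele pair (indices)
gt10_index <- function(a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  ## offset of pairs starting at allele lo: pairs (1,*),(2,*),... counts 4,3,2,1
  c(0L, 4L, 7L, 9L)[lo] + (hi - lo + 1L)
}

#' Is an allele substitution a transition?
#'
#' Transitions are A<->G and C<->T; the four other unordered substitutions
#' are transversions.
#'
#' @param a,b Allele symbols (`"A"`, `"C"`, `"G"`, `"T"`) or indices 1..4.
#' @return Logical.
#' @export
is_transition <- function(a, b) {
  ai <- if (is.character(a)) allele_index(a) else as.integer(a)
  bi <- if (is.character(b)) allele_index(b) else as.integer(b)
  purine <- c(TRUE, FALSE, TRUE, FALSE)  # A, G purines
  ai != bi & purine[ai] == purine[bi]
}

#' Phred scale conversions
#'
#' `phred_to_prob()` converts a Phred quality to an error probability
#' (`10^(-Q/10)`); `prob_to_phred()` is the inverse.
#'
#' @param q,p Numeric vectors.
#' @return Numeric vector.
#' @export
phred_to_prob <- function(q) 10^(-q / 10)

#' @rdname phred_to_prob
#' @export
prob_to_phred <- function(p) -10 * log10(p)
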