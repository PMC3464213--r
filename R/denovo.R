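## De novo mutation scoring: the ratio of the mutation-aware pedigree
## likelihood L_denovo to the strictly Mendelian likelihood L_mendel,
## evaluated at the same plugged-in allele frequency, summarizes the
## evidence that a germline mutation occurred in the family at the site.
## A candidate call additionally requires a Mendelian-inconsistent called
## genotype triplet (father, mother, offspring).

## 3x3x3 lookup: is (child, father, mother) alt-count triple Mendelian
## consistent?  A genotype triple is consistent iff its Mendelian
## transmission probability is positive.
MENDEL_OK <- local({
  t <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1)) # parent alt count -> allele
  cube <- array(0, c(3L, 3L, 3L))
  for (f in 1:3) for (m in 1:3) {
    cube[1L, f, m] <- t[f, 1L] * t[m, 1L]
    cube[2L, f, m] <- t[f, 1L] * t[m, 2L] + t[f, 2L] * t[m, 1L]
    cube[3L, f, m] <- t[f, 2L] * t[m, 2L]
  }
  cube > 0
})

#' Mendelian consistency of a genotype triplet
#'
#' `TRUE` iff the child genotype can be formed by taking one allele from
#' each parent.  Genotypes are biallelic alt-allele counts (0, 1, 2) or the
#' labels `"RefRef"/"RefAlt"/"AltAlt"` (case and separator insensitive).
#'
#' @param child_g,father_g,mother_g Genotypes (vectorized).
#' @return Logical vector.
#' @export
#' @examples
#' mendelian_consistent(1, 0, 0)  # FALSE: het child of two hom-ref parents
#' mendelian_consistent(0, 1, 0)  # TRUE
mendelian_consistent <- function(child_g, father_g, mother_g) {
  code <- function(g) {
    if (is.numeric(g)) return(as.integer(g))
    key <- gsub("[^a-z]", "", tolower(as.character(g)))
    out <- c(refref = 0L, refalt = 1L, altref = 1L, altalt = 2L,
             het = 1L, homref = 0L, homalt = 2L)[key]
    if (anyNA(out)) stop("unrecognized genotype label")
    unname(out)
  }
  c_ <- code(child_g)
  f_ <- code(father_g)
  m_ <- code(mother_g)
  if (any(c(c_, f_, m_) < 0L | c(c_, f_, m_) > 2L)) {
    stop("genotype codes must be 0, 1 or 2")
  }
  MENDEL_OK[cbind(c_ + 1L, f_ + 1L, m_ + 1L)]
}

#' Score de novo mutation evidence in one family at one site
#'
#' Computes the family log-likelihood twice with the same peeling engine --
#' once with mutation-aware transmission (`log_l_denovo`) and once with
#' strict Mendelian transmission (`log_l_mendel`) -- at the same plugged-in
#' allele frequency, and reports the likelihood ratio
#' `lr = exp(log_l_denovo - log_l_mendel)`.  The posterior probability of a
#' de novo event is `1 - exp(log_l_nomut - log_l_denovo)`, where
#' `log_l_nomut` is the mass of the mutation-aware likelihood restricted to
#' transmissions without any mutation event (a third peeling pass with the
#' off-diagonal of the mutation matrix zeroed).
#'
#' @inheritParams family_log_likelihood
#' @param model A [mutation_model()] with positive total rate.
#' @return List of class `"denovo_result"`: `log_l_denovo`, `log_l_mendel`,
#'   `lr`, `posterior`, `candidate_triplets` (data frame of
#'   Mendelian-inconsistent called triplets: child, father, mother and
#'   their modal alt counts).
#' @export
denovo_score <- function(ped, gls, alleles, freq, model) {
  if (is.null(model) || model$mu <= 0) {
    warning("mutation model with mu = 0 is degenerate; lr forced to 1")
    ll <- family_log_likelihood(ped, gls, freq, alleles, NULL)
    return(structure(list(log_l_denovo = ll, log_l_mendel = ll, lr = 1,
                          posterior = 0,
                          candidate_triplets = empty_triplets()),
                     class = "denovo_result"))
  }
  plan <- peeling_plan(ped)
  ll <- member_ll_matrix(ped, gls, alleles)
  a <- allele_index(alleles)
  cube_dn <- as.numeric(transmission_cube(a, model))
  cube_me <- as.numeric(transmission_cube(a, NULL))
  nomut <- model
  nomut$matrix <- diag(diag(model$matrix))
  cube_nm <- as.numeric(transmission_cube(a, nomut))
  l_dn <- cpp_peel_loglik(ll, plan, freq, cube_dn)
  l_me <- cpp_peel_loglik(ll, plan, freq, cube_me)
  l_nm <- cpp_peel_loglik(ll, plan, freq, cube_nm)
  post <- genotype_posteriors(ped, gls, freq, alleles, model)
  modal <- max.col(post, ties.method = "first") - 1L
  names(modal) <- rownames(post)
  m <- ped$members
  kids <- which(!m$founder)
  trip <- data.frame(child = m$id[kids], father = m$father[kids],
                     mother = m$mother[kids], stringsAsFactors = FALSE)
  trip$child_g <- modal[trip$child]
  trip$father_g <- modal[trip$father]
  trip$mother_g <- modal[trip$mother]
  cons <- if (nrow(trip)) {
    mendelian_consistent(trip$child_g, trip$father_g, trip$mother_g)
  } else {
    logical()
  }
  structure(list(log_l_denovo = l_dn, log_l_mendel = l_me,
                 lr = exp(l_dn - l_me),
                 posterior = max(0, min(1, 1 - exp(l_nm - l_dn))),
                 candidate_triplets = trip[!cons, , drop = FALSE]),
            class = "denovo_result")
}

empty_triplets <- function() {
  data.frame(child = character(), father = character(),
             mother = character(), child_g = integer(),
             father_g = integer(), mother_g = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.denovo_result <- function(x, ...) {
  cat("<denovo score> lr =", format(x$lr, digits = 4),
      " posterior =", format(x$posterior, digits = 4),
      " inconsistent triplets:", nrow(x$candidate_triplets), "\n")
  invisible(x)
}

#' Candidate de novo mutations from a call set
#'
#' A site/family is a candidate iff the de novo likelihood ratio meets the
#' threshold AND at least one (father, mother, offspring) triplet of called
#' genotypes violates Mendelian consistency.  Optionally the stricter
#' filter requiring both parents called homozygous reference and the
#' offspring heterozygous is applied.
#'
#' @param calls A [call_sites()] result produced with a mutation model.
#' @param lr_threshold Minimum likelihood ratio (default 10).
#' @param require_hom_parents_het_child Apply the strict RefRef x RefRef ->
#'   RefAlt filter.
#' @return Data frame: `chrom`, `pos`, `fam`, `child`, `lr`,
#'   `child_g`, `father_g`, `mother_g` (modal alt counts).
#' @export
call_denovo <- function(calls, lr_threshold = 10,
                        require_hom_parents_het_child = FALSE) {
  stopifnot(inherits(calls, "famcall_calls"))
  out <- list()
  emitted <- which(calls$sites$emitted)
  for (g in calls$geno) {
    if (is.null(g$log_lr)) next
    ped <- calls$peds[[match(g$fam, vapply(calls$peds, `[[`, "",
                                           "fam"))]]
    m <- ped$members
    kids <- which(!m$founder)
    if (!length(kids)) next
    ci <- match(m$id[kids], g$ids)
    fi <- match(m$father[kids], g$ids)
    mi <- match(m$mother[kids], g$ids)
    for (s in emitted) {
      lr <- exp(g$log_lr[s])
      if (!is.finite(lr) || lr < lr_threshold) next
      cg <- g$gt[s, ci]
      fg <- g$gt[s, fi]
      mg <- g$gt[s, mi]
      ok <- !is.na(cg) & !is.na(fg) & !is.na(mg)
      if (!any(ok)) next
      cg2 <- ifelse(ok, cg, 0L)
      fg2 <- ifelse(ok, fg, 0L)
      mg2 <- ifelse(ok, mg, 0L)
      incons <- ok & !mendelian_consistent(cg2, fg2, mg2)
      if (require_hom_parents_het_child) {
        incons <- incons & cg == 1L & fg == 0L & mg == 0L
      }
      if (!any(incons, na.rm = TRUE)) next
      k <- which(incons)
      out[[length(out) + 1L]] <- data.frame(
        chrom = calls$sites$chrom[s], pos = calls$sites$pos[s],
        fam = g$fam, child = m$id[kids][k], lr = lr,
        child_g = cg[k], father_g = fg[k], mother_g = mg[k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      fam = character(), child = character(),
                      lr = numeric(), child_g = integer(),
                      father_g = integer(), mother_g = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
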