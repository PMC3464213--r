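## Metrics comparing call sets with simulated truth: per-individual false
## negative rate, genotype mismatch rates by category and allele frequency,
## Mendelian inconsistency per triplet, de novo detection power/FPR, and
## the Ts/Tv ratio.
##
## Conventions: a genotype is compared as an unordered allele pair; at
## sites that were not emitted every individual counts as called
## homozygous reference.  Denominators are restricted to sites that are
## polymorphic in the simulated sample (the "true variant sites").

## per-family truth and called allele-pair matrices, both S x n with
## alleles sorted within pair; called defaults to (ref, ref)
pair_matrices <- function(calls, sim, fam) {
  g <- calls$geno[[fam]]
  f <- sim$families[[fam]]
  S <- nrow(calls$sites)
  refi <- allele_index(calls$sites$ref)
  a1i <- allele_index(calls$sites$a1)
  a2i <- allele_index(calls$sites$alt)
  ## score sequenced members only (unsequenced ones carry prior-based
  ## calls and are not part of the benchmark denominators)
  seq_ids <- f$ped$members$id[f$ped$members$sequenced]
  g <- list(ids = g$ids[g$ids %in% seq_ids],
            gt = g$gt[, g$ids %in% seq_ids, drop = FALSE])
  th1 <- t(f$hap1)[, match(g$ids, f$ids), drop = FALSE]
  th2 <- t(f$hap2)[, match(g$ids, f$ids), drop = FALSE]
  t_lo <- pmin(th1, th2)
  t_hi <- pmax(th1, th2)
  code <- g$gt
  code[is.na(code)] <- -1L
  c1 <- matrix(refi, S, ncol(code))
  c2 <- c1
  c1[code == 0L] <- a1i[row(code)][code == 0L]
  c2[code == 0L] <- a1i[row(code)][code == 0L]
  c1[code == 1L] <- a1i[row(code)][code == 1L]
  c2[code == 1L] <- a2i[row(code)][code == 1L]
  c1[code == 2L] <- a2i[row(code)][code == 2L]
  c2[code == 2L] <- a2i[row(code)][code == 2L]
  list(t_lo = t_lo, t_hi = t_hi, c_lo = pmin(c1, c2), c_hi = pmax(c1, c2),
       refi = refi, ids = g$ids)
}

## logical vector: site polymorphic in the simulated sample (truth)
variant_site_mask <- function(sim) {
  refi <- allele_index(sim$sites$ref)
  mask <- rep(FALSE, nrow(sim$sites))
  for (f in sim$families) {
    mask <- mask | colSums(f$hap1 != rep(refi, each = nrow(f$hap1))) > 0 |
      colSums(f$hap2 != rep(refi, each = nrow(f$hap2))) > 0
  }
  mask
}

#' Per-individual false negative rate
#'
#' Percentage of true non-reference genotypes not recovered as
#' non-reference (site unemitted, or modal called genotype homozygous
#' reference), averaged over individuals.
#'
#' @param calls A [call_sites()] result.
#' @param sim The matching [simulate_dataset()] object.
#' @return List: `fnr` (percent, mean over individuals), `per_individual`
#'   (named vector of percentages).
#' @export
false_negative_rate <- function(calls, sim) {
  check_calls_truth(calls, sim)
  rates <- c()
  for (fam in names(calls$geno)) {
    p <- pair_matrices(calls, sim, fam)
    t_nonref <- p$t_lo != p$refi | p$t_hi != p$refi
    c_nonref <- p$c_lo != p$refi | p$c_hi != p$refi
    denom <- colSums(t_nonref)
    num <- colSums(t_nonref & !c_nonref)
    r <- ifelse(denom > 0, 100 * num / denom, NA_real_)
    names(r) <- paste(fam, p$ids, sep = ":")
    rates <- c(rates, r)
  }
  list(fnr = mean(rates, na.rm = TRUE), per_individual = rates)
}

#' Genotype mismatch rates by category and allele frequency
#'
#' Fraction (%) of called genotypes differing from truth among all
#' genotypes (`All`) and within the three true-genotype categories
#' `HomRef`, `Het`, `HomAlt`, at sites polymorphic in the simulated
#' sample.  Unemitted sites count as homozygous-reference calls.  Also
#' stratified per individual and by true alternative allele frequency.
#'
#' @inheritParams false_negative_rate
#' @param n_freq_bins Number of equal-width bins on the true alt frequency.
#' @return List: `overall` (named vector All/HomRef/Het/HomAlt, percent),
#'   `per_individual` (data frame), `by_freq` (data frame), `counts`
#'   (denominators).
#' @export
mismatch_rates <- function(calls, sim, n_freq_bins = 10L) {
  check_calls_truth(calls, sim)
  vmask <- variant_site_mask(sim)
  freq <- sim$sites$freq_true
  bins <- pmin(pmax(ceiling(freq * n_freq_bins), 1L), n_freq_bins)
  cat_tot <- cat_mis <- c(All = 0, HomRef = 0, Het = 0, HomAlt = 0)
  per_ind <- list()
  bin_tot <- bin_mis <- matrix(0, n_freq_bins, 4L,
                               dimnames = list(NULL, names(cat_tot)))
  for (fam in names(calls$geno)) {
    p <- pair_matrices(calls, sim, fam)
    keep <- vmask
    mis <- (p$t_lo != p$c_lo | p$t_hi != p$c_hi)[keep, , drop = FALSE]
    t_lo <- p$t_lo[keep, , drop = FALSE]
    t_hi <- p$t_hi[keep, , drop = FALSE]
    refi <- p$refi[keep]
    cat_ <- matrix("Het", nrow(t_lo), ncol(t_lo))
    hom <- t_lo == t_hi
    cat_[hom & t_lo == refi] <- "HomRef"
    cat_[hom & t_lo != refi] <- "HomAlt"
    b <- bins[keep]
    for (cc in c("HomRef", "Het", "HomAlt")) {
      sel <- cat_ == cc
      cat_tot[cc] <- cat_tot[cc] + sum(sel)
      cat_mis[cc] <- cat_mis[cc] + sum(mis[sel])
      bin_tot[, cc] <- bin_tot[, cc] +
        tabulate(b[row(sel)[sel]], n_freq_bins)
      bin_mis[, cc] <- bin_mis[, cc] +
        tabulate(b[row(sel)[sel & mis]], n_freq_bins)
    }
    per_ind[[fam]] <- data.frame(
      fam = fam, id = p$ids,
      mismatch = 100 * colMeans(mis),
      het_mismatch = 100 * vapply(seq_len(ncol(mis)), function(j) {
        h <- cat_[, j] == "Het"
        if (any(h)) mean(mis[h, j]) else NA_real_
      }, numeric(1)),
      stringsAsFactors = FALSE)
  }
  cat_tot["All"] <- sum(cat_tot[-1L])
  cat_mis["All"] <- sum(cat_mis[-1L])
  bin_tot[, "All"] <- rowSums(bin_tot[, -1L, drop = FALSE])
  bin_mis[, "All"] <- rowSums(bin_mis[, -1L, drop = FALSE])
  by_freq <- data.frame(
    bin_low = (seq_len(n_freq_bins) - 1L) / n_freq_bins,
    bin_high = seq_len(n_freq_bins) / n_freq_bins,
    100 * bin_mis / pmax(bin_tot, 1))
  names(by_freq)[3:6] <- names(cat_tot)
  list(overall = 100 * cat_mis / pmax(cat_tot, 1),
       per_individual = do.call(rbind, per_ind),
       by_freq = by_freq,
       counts = cat_tot)
}

#' Mendelian inconsistency rate per triplet per site
#'
#' Number of (site, father-mother-offspring triplet) pairs whose called
#' genotypes are Mendelian inconsistent, divided by `n_sites x n_triplets`.
#' Unemitted sites count as homozygous-reference calls (always
#' consistent); the site denominator is the number of sites polymorphic in
#' the simulated sample when `sim` is given, otherwise all sites in the
#' call set.
#'
#' @inheritParams false_negative_rate
#' @param sim Optional truth object (restricts the denominator to true
#'   variant sites).
#' @return List: `rate`, `n_inconsistent`, `n_triplets`, `n_sites`.
#' @export
mendelian_inconsistency_rate <- function(calls, sim = NULL) {
  n_sites <- if (is.null(sim)) nrow(calls$sites) else
    sum(variant_site_mask(sim))
  n_trip <- 0L
  n_bad <- 0L
  for (g in calls$geno) {
    ped <- calls$peds[[match(g$fam, vapply(calls$peds, `[[`, "", "fam"))]]
    m <- ped$members
    kids <- which(!m$founder)
    if (!length(kids)) next
    ci <- match(m$id[kids], g$ids)
    fi <- match(m$father[kids], g$ids)
    mi <- match(m$mother[kids], g$ids)
    n_trip <- n_trip + length(kids)
    gt <- g$gt
    gt[is.na(gt)] <- 0L
    for (k in seq_along(kids)) {
      bad <- !mendelian_consistent(gt[, ci[k]], gt[, fi[k]], gt[, mi[k]])
      n_bad <- n_bad + sum(bad)
    }
  }
  list(rate = n_bad / (as.numeric(n_sites) * max(n_trip, 1L)),
       n_inconsistent = n_bad, n_triplets = n_trip, n_sites = n_sites)
}

#' De novo detection power and false positive rate over thresholds
#'
#' @param candidates Candidate data frame from [call_denovo()] (run at
#'   threshold 0 or 1 to keep all scored sites), with columns `pos`,
#'   `child`, `lr`.
#' @param truth_registry Data frame of planted events with columns `pos`,
#'   `individual`.
#' @param lr_grid Thresholds to sweep.
#' @param null_candidates Optional candidates obtained on data simulated
#'   without de novo mutations (for the false positive rate).
#' @param n_transmissions Number of site-transmissions scanned in the null
#'   data.
#' @return Data frame: `threshold`, `power` (%), `fpr` (per
#'   site-transmission; `NA` without null data).
#' @export
dnm_power_fpr <- function(candidates, truth_registry,
                          lr_grid = c(1, 2, 5, 10, 20, 50, 100, 1000),
                          null_candidates = NULL, n_transmissions = NA) {
  key_t <- paste(truth_registry$pos, truth_registry$individual)
  key_c <- paste(candidates$pos, candidates$child)
  lr_of <- rep(-Inf, length(key_t))
  hit <- match(key_t, key_c)
  lr_of[!is.na(hit)] <- candidates$lr[hit[!is.na(hit)]]
  out <- data.frame(threshold = lr_grid)
  out$power <- vapply(lr_grid, function(th) {
    if (!length(key_t)) return(NA_real_)
    100 * mean(lr_of >= th)
  }, numeric(1))
  out$fpr <- vapply(lr_grid, function(th) {
    if (is.null(null_candidates)) return(NA_real_)
    sum(null_candidates$lr >= th) / n_transmissions
  }, numeric(1))
  out
}

#' Transition/transversion ratio of a call set
#'
#' @param calls A [call_sites()] result or a data frame with columns
#'   `ref` and `alt` (emitted biallelic SNVs).
#' @return Ratio (count of transitions over transversions); `NaN` with a
#'   warning when there are no transversions.
#' @export
ts_tv_ratio <- function(calls) {
  df <- if (inherits(calls, "famcall_calls")) {
    calls$sites[calls$sites$emitted, c("a1", "alt")]
  } else {
    data.frame(a1 = calls$ref, alt = calls$alt)
  }
  if (!nrow(df)) {
    warning("no variant calls; Ts/Tv undefined")
    return(NaN)
  }
  ts <- sum(is_transition(df$a1, df$alt))
  tv <- nrow(df) - ts
  if (tv == 0L) {
    warning("no transversions; Ts/Tv undefined")
    return(NaN)
  }
  ts / tv
}

#' Full metrics report for a call set against simulated truth
#'
#' @inheritParams false_negative_rate
#' @return List of class `"famcall_metrics"` combining
#'   [false_negative_rate()], [mismatch_rates()],
#'   [mendelian_inconsistency_rate()] and [ts_tv_ratio()].
#' @export
evaluate_calls <- function(calls, sim) {
  fnr <- false_negative_rate(calls, sim)
  mm <- mismatch_rates(calls, sim)
  mi <- mendelian_inconsistency_rate(calls, sim)
  structure(list(fnr = fnr$fnr, fnr_per_individual = fnr$per_individual,
                 mismatch = mm$overall, mismatch_counts = mm$counts,
                 mismatch_by_freq = mm$by_freq,
                 mismatch_per_individual = mm$per_individual,
                 mendelian_rate = mi$rate, mendelian = mi,
                 tstv = suppressWarnings(ts_tv_ratio(calls)),
                 n_variant_sites = sum(variant_site_mask(sim))),
            class = "famcall_metrics")
}

#' @export
print.famcall_metrics <- function(x, ...) {
  cat("<famcall metrics>\n")
  cat("  FNR per individual (%):", format(x$fnr, digits = 4), "\n")
  cat("  mismatch (%):",
      paste(names(x$mismatch), format(x$mismatch, digits = 3),
            sep = "=", collapse = "  "), "\n")
  cat("  Mendelian inconsistency rate:",
      format(x$mendelian_rate, digits = 3), "\n")
  cat("  Ts/Tv:", format(x$tstv, digits = 4), "\n")
  invisible(x)
}

check_calls_truth <- function(calls, sim) {
  if (nrow(calls$sites) != nrow(sim$sites) ||
      any(calls$sites$pos != sim$sites$pos)) {
    stop("call set and truth cover different sites")
  }
  missing <- setdiff(names(calls$geno), names(sim$families))
  if (length(missing)) {
    stop("no truth for families: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
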