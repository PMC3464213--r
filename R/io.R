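## Readers and writers: tabular GL format, truth TSV, VCF 4.2.
##
## Tabular GL format (replaces the obsolete binary GLF): one row per
## individual-site, tab-separated with a '#'-prefixed header:
##   chrom  pos  id  ref  GL_AA ... GL_TT  depth
## The 10 genotype log-likelihoods are natural logs in the canonical order.
## Coordinates are 1-based everywhere.

#' Write a simulated dataset as a tabular GL file
#'
#' @param sim A [simulate_dataset()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gl_table <- function(sim, path) {
  logE <- log_emission_matrix(sim$base_error)
  parts <- list()
  for (f in sim$families) {
    n <- length(f$ids)
    S <- nrow(sim$sites)
    cmat <- matrix(as.numeric(f$counts), S * n, 4L) # (site, ind) x base
    gl <- cmat %*% logE
    depth <- as.integer(rowSums(cmat))
    dt <- data.table::data.table(
      chrom = rep(sim$sites$chrom, times = n),
      pos = rep(sim$sites$pos, times = n),
      id = rep(f$ids, each = S),
      ref = rep(sim$sites$ref, times = n))
    for (k in 1:10) dt[[paste0("GL_", GT10_NAMES[k])]] <- round(gl[, k], 6)
    dt$depth <- depth
    parts[[length(parts) + 1L]] <- dt
  }
  out <- data.table::rbindlist(parts)
  data.table::setorder(out, pos, id)
  header <- paste0("#", paste(names(out), collapse = "\t"))
  writeLines(header, path)
  data.table::fwrite(out, path, sep = "\t", append = TRUE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a tabular GL file
#'
#' @param path Path to a file written by [write_gl_table()] (or compatible).
#' @return Object of class `"famcall_gl"`: `sites` (data frame `chrom`,
#'   `pos`, `ref`), `ids`, and `gl`, a numeric array
#'   `(n_sites, n_individuals, 10)` of natural-log likelihoods (flat rows
#'   for individuals missing at a site), plus `depth` (matrix).
#' @export
read_gl_table <- function(path) {
  first <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", first), "\t")[[1]]
  dt <- data.table::fread(path, skip = 1L, header = FALSE, sep = "\t")
  data.table::setnames(dt, cols)
  key <- paste(dt$chrom, dt$pos)
  usite <- !duplicated(key)
  sites <- data.frame(chrom = dt$chrom[usite], pos = dt$pos[usite],
                      ref = dt$ref[usite], stringsAsFactors = FALSE)
  o <- order(sites$pos)
  sites <- sites[o, , drop = FALSE]
  site_of <- match(key, paste(sites$chrom, sites$pos))
  ids <- sort(unique(dt$id))
  ind_of <- match(dt$id, ids)
  S <- nrow(sites)
  n <- length(ids)
  gl <- array(0, c(S, n, 10L))
  depth <- matrix(NA_integer_, S, n)
  glcols <- paste0("GL_", GT10_NAMES)
  glm <- as.matrix(dt[, glcols, with = FALSE])
  for (k in 1:10) gl[cbind(site_of, ind_of, k)] <- glm[, k]
  depth[cbind(site_of, ind_of)] <- dt$depth
  structure(list(sites = sites, ids = ids, gl = gl, depth = depth),
            class = "famcall_gl")
}

#' Write / read the simulation truth TSV
#'
#' Long format, tab-separated with a '#'-prefixed header: `chrom`, `pos`,
#' `fam`, `id`, `genotype` (two allele symbols, e.g. `AC`), `dnm`
#' (0/1: individual carries a de novo allele at the site).
#'
#' @param sim A [simulate_dataset()] object.
#' @param path File path.
#' @return `path` (write) or a data frame (read).
#' @export
write_truth <- function(sim, path) {
  parts <- list()
  for (fam in names(sim$families)) {
    f <- sim$families[[fam]]
    S <- nrow(sim$sites)
    n <- length(f$ids)
    g1 <- ALLELES[pmin(t(f$hap1), t(f$hap2))]
    g2 <- ALLELES[pmax(t(f$hap1), t(f$hap2))]
    dnm <- matrix(0L, S, n)
    if (nrow(f$registry)) {
      dnm[cbind(f$registry$site, match(f$registry$individual, f$ids))] <- 1L
    }
    parts[[length(parts) + 1L]] <- data.table::data.table(
      chrom = rep(sim$sites$chrom, times = n),
      pos = rep(sim$sites$pos, times = n),
      fam = fam,
      id = rep(f$ids, each = S),
      genotype = paste0(g1, g2),
      dnm = as.integer(dnm))
  }
  out <- data.table::rbindlist(parts)
  writeLines(paste0("#", paste(names(out), collapse = "\t")), path)
  data.table::fwrite(out, path, sep = "\t", append = TRUE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  first <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", first), "\t")[[1]]
  dt <- data.table::fread(path, skip = 1L, header = FALSE, sep = "\t")
  data.table::setnames(dt, cols)
  as.data.frame(dt)
}

## ---- VCF ---------------------------------------------------------------

#' Write a call set as VCF 4.2
#'
#' Emitted sites only, sorted by position.  `QUAL` is the Phred-scaled
#' variant quality; INFO carries `AF` (estimated founder alt frequency,
#' 4 decimals), `NS`, and -- for calls made with a mutation model --
#' `DNLR` (log10 de novo likelihood ratio, maximum over families) and
#' `DNCHILD`.  FORMAT is `GT:GQ:DP:PL:DS` (PL requires
#' `call_sites(keep_pl = TRUE)`; missing fields are written as `.`).
#' Sample columns are named `fam:id`.
#'
#' @param calls A [call_sites()] result.
#' @param path Output path.
#' @param source_version String recorded in the header (fixed for
#'   byte-deterministic output).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, source_version = "famcall-0.1.0") {
  st <- calls$sites
  if (is.unsorted(st$pos)) stop("call set must be sorted by position")
  keep <- which(st$emitted)
  samples <- unlist(lapply(calls$geno, function(g) paste(g$fam, g$ids,
                                                         sep = ":")))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source_version),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Estimated founder alternative allele frequency\">",
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of samples\">",
    "##INFO=<ID=DNLR,Number=1,Type=Float,Description=\"log10 likelihood ratio of de novo vs Mendelian transmission (max over families)\">",
    "##INFO=<ID=DNCHILD,Number=1,Type=String,Description=\"Offspring implicated by the de novo likelihood ratio\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Phred genotype quality (-10log10(1-max posterior), capped 99)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternative allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  lines <- character(length(keep))
  dn_cand <- NULL
  for (ii in seq_along(keep)) {
    s <- keep[ii]
    ref <- st$ref[s]
    a1 <- st$a1[s]
    a2 <- st$alt[s]
    if (a1 == ref) {
      alt_field <- a2
      gt_str <- c("0/0", "0/1", "1/1")
    } else { # both called alleles differ from the reference
      alt_field <- paste(a1, a2, sep = ",")
      gt_str <- c("1/1", "1/2", "2/2")
    }
    info <- sprintf("AF=%.4f;NS=%d", st$af[s],
                    sum(vapply(calls$geno, function(g) length(g$ids),
                               numeric(1))))
    lrs <- vapply(calls$geno, function(g) {
      if (is.null(g$log_lr)) NA_real_ else g$log_lr[s]
    }, numeric(1))
    if (any(is.finite(lrs))) {
      b <- which.max(lrs)
      info <- paste0(info, sprintf(";DNLR=%.4f", lrs[b] / log(10)))
    }
    fields <- character()
    for (g in calls$geno) {
      for (j in seq_along(g$ids)) {
        code <- g$gt[s, j]
        if (is.na(code)) {
          fields <- c(fields, "./.")
          next
        }
        dp <- if (!is.null(g$dp)) g$dp[s, j] else NA_integer_
        pl <- if (!is.null(g$pl)) {
          paste(g$pl[s, j, ], collapse = ",")
        } else "."
        fields <- c(fields, paste(
          gt_str[code + 1L],
          as.integer(round(g$gq[s, j])),
          ifelse(is.na(dp), ".", dp),
          pl,
          sprintf("%.4f", g$ds[s, j]), sep = ":"))
      }
    }
    lines[ii] <- paste(c(st$chrom[s], st$pos[s], ".", ref, alt_field,
                         sprintf("%.2f", min(st$qual[s], 9999)), "PASS",
                         info, "GT:GQ:DP:PL:DS", fields), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a famcall VCF back into site and genotype tables
#'
#' Light parser for VCFs written by [write_vcf()] (plain-text, biallelic
#' or double-non-reference sites).  Used for round-tripping and by the
#' `evaluate`/`denovo` CLI subcommands.
#'
#' @param path VCF path.
#' @return List: `sites` (chrom, pos, ref, a1, alt, qual, af, dnlr),
#'   `samples`, `gt` (alt-count codes, `NA` for `./.`), `gq`, `ds`
#'   matrices.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1L], "\t")[[1]]
  samples <- hdr[-(1:9)]
  body <- body[-1L]
  n <- length(body)
  sites <- data.frame(chrom = character(n), pos = integer(n),
                      ref = character(n), a1 = character(n),
                      alt = character(n), qual = numeric(n),
                      af = numeric(n), dnlr = rep(NA_real_, n),
                      stringsAsFactors = FALSE)
  gt <- matrix(NA_integer_, n, length(samples),
               dimnames = list(NULL, samples))
  gq <- matrix(NA_integer_, n, length(samples))
  ds <- matrix(NA_real_, n, length(samples))
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t")[[1]]
    alts <- strsplit(f[5L], ",")[[1]]
    sites$chrom[i] <- f[1L]
    sites$pos[i] <- as.integer(f[2L])
    sites$ref[i] <- f[4L]
    if (length(alts) == 1L) {
      sites$a1[i] <- f[4L]
      sites$alt[i] <- alts[1L]
    } else {
      sites$a1[i] <- alts[1L]
      sites$alt[i] <- alts[2L]
    }
    sites$qual[i] <- as.numeric(f[6L])
    info <- strsplit(f[8L], ";")[[1]]
    kv <- strsplit(info, "=")
    for (p in kv) {
      if (p[1L] == "AF") sites$af[i] <- as.numeric(p[2L])
      if (p[1L] == "DNLR") sites$dnlr[i] <- as.numeric(p[2L])
    }
    fmt <- strsplit(f[9L], ":")[[1]]
    for (j in seq_along(samples)) {
      sub <- strsplit(f[9L + j], ":")[[1]]
      gtf <- sub[match("GT", fmt)]
      if (gtf %in% c("./.", ".")) next
      al <- as.integer(strsplit(gtf, "[/|]")[[1]])
      gt[i, j] <- if (length(alts) == 1L) sum(al) else sum(al) - 2L
      gqf <- sub[match("GQ", fmt)]
      if (!is.na(gqf) && gqf != ".") gq[i, j] <- as.integer(gqf)
      dsf <- sub[match("DS", fmt)]
      if (!is.na(dsf) && dsf != ".") ds[i, j] <- as.numeric(dsf)
    }
  }
  list(sites = sites, samples = samples, gt = gt, gq = gq, ds = ds)
}

#' Read biallelic genotype likelihoods from VCF PL/GL fields
#'
#' Imports externally computed genotype likelihoods (for example GATK indel
#' likelihoods) for family-aware genotype refinement.  Each biallelic
#' record's `PL` (Phred-scaled) or `GL` (log10) FORMAT field is converted
#' to natural-log likelihoods over (ref/ref, ref/alt, alt/alt); samples
#' missing the field at a site get flat likelihoods; records without any
#' `PL`/`GL` are skipped with a warning.
#'
#' @param path VCF path (plain text).
#' @return List of class `"famcall_vcf_gl"`: `sites` (chrom, pos, ref,
#'   alt as strings -- indel alleles allowed), `ids`, `ll`
#'   (`n_sites x n_samples x 3` natural-log array).
#' @export
read_vcf_gl <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1L], "\t")[[1]]
  ids <- hdr[-(1:9)]
  body <- body[-1L]
  keep <- list()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    if (grepl(",", f[5L], fixed = TRUE)) next # multi-allelic: skip
    fmt <- strsplit(f[9L], ":")[[1]]
    ipl <- match("PL", fmt)
    igl <- match("GL", fmt)
    if (is.na(ipl) && is.na(igl)) {
      warning("site ", f[1L], ":", f[2L], " has no PL/GL field; skipped")
      next
    }
    ll <- matrix(0, length(ids), 3L)
    for (j in seq_along(ids)) {
      sub <- strsplit(f[9L + j], ":")[[1]]
      v <- if (!is.na(ipl)) sub[ipl] else sub[igl]
      if (is.na(v) || v == "." || v == "") next
      x <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
      if (length(x) != 3L || anyNA(x)) next
      ll[j, ] <- if (!is.na(ipl)) -x / 10 * log(10) else x * log(10)
      ll[j, ] <- ll[j, ] - max(ll[j, ])
    }
    keep[[length(keep) + 1L]] <- list(
      site = data.frame(chrom = f[1L], pos = as.integer(f[2L]),
                        ref = f[4L], alt = f[5L],
                        stringsAsFactors = FALSE),
      ll = ll)
  }
  S <- length(keep)
  ll <- array(0, c(S, length(ids), 3L))
  for (i in seq_len(S)) ll[i, , ] <- keep[[i]]$ll
  sites <- do.call(rbind, lapply(keep, `[[`, "site"))
  structure(list(sites = sites, ids = ids, ll = ll),
            class = "famcall_vcf_gl")
}

#' Family-aware genotype refinement from external likelihoods
#'
#' Re-genotypes the records of a VCF (any polymorphism type whose
#' likelihoods are biallelic, including indels) using family information:
#' per site the founder alt frequency is estimated by maximum likelihood
#' and per-member posteriors are computed by peeling.
#'
#' @param vcfgl A [read_vcf_gl()] object.
#' @param peds List of [pedigree()]s covering the VCF samples.
#' @param model Optional [mutation_model()] (SNV records only; ignored
#'   with a message for non-SNV alleles).
#' @return Data frame: one row per site x member with `chrom`, `pos`,
#'   `fam`, `id`, `genotype`, `gq`, `dosage`, `alt_freq`.
#' @export
refine_genotypes <- function(vcfgl, peds, model = NULL) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  id_col <- stats::setNames(seq_along(vcfgl$ids), vcfgl$ids)
  plans <- build_plans(peds, list(id_col), rep(1L, length(peds)), "family")
  plans0 <- lapply(plans, function(pl) {
    pl2 <- pl
    pl2$cols <- pl$glrow
    pl2$glrow <- seq_len(pl$n)
    pl2
  })
  out <- list()
  for (s in seq_len(nrow(vcfgl$sites))) {
    snv <- all(c(vcfgl$sites$ref[s], vcfgl$sites$alt[s]) %in% ALLELES)
    mod <- if (snv) model else NULL
    cube <- if (snv) {
      transmission_cube(allele_index(c(vcfgl$sites$ref[s],
                                       vcfgl$sites$alt[s])), mod)
    } else {
      transmission_cube(c(1L, 2L), NULL)
    }
    lls <- lapply(plans0, function(pl) {
      m <- matrix(0, 3L, pl$n)
      for (i in seq_len(pl$n)) {
        if (pl$cols[i] > 0L) m[, i] <- vcfgl$ll[s, pl$cols[i], ]
      }
      m
    })
    fe <- cpp_estimate_freq(lls, plans0, as.numeric(cube), 1e-8)
    for (k in seq_along(plans0)) {
      pl <- plans0[[k]]
      post <- cpp_peel_posteriors(lls[[k]], pl, fe$alt_freq,
                                  as.numeric(cube))
      orig <- which(pl$out_col > 0L)
      modal <- apply(post[, orig, drop = FALSE], 2L, which.max)
      pmax_ <- post[cbind(modal, orig)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = vcfgl$sites$chrom[s], pos = vcfgl$sites$pos[s],
        fam = pl$fam, id = pl$ids[pl$out_col[orig]],
        genotype = c("ref_ref", "ref_alt", "alt_alt")[modal],
        gq = pmin(-10 * log10(pmax(1 - pmax_, 1.26e-10)), 99),
        dosage = post[2L, orig] + 2 * post[3L, orig],
        alt_freq = fe$alt_freq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
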