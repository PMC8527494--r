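#' Marker quality-control thresholds
#'
#' Mirrors standard SNP-array preprocessing: markers are REMOVED when call
#' rate is strictly below \code{min_call_rate}, MAF strictly below
#' \code{min_maf}, or the exact HWE p-value strictly below
#' \code{min_hwe_p}; markers exactly at a threshold are kept. Non-autosomal
#' markers (chromosomes outside "1"--"26", e.g. X/Y/MT) are removed first
#' when \code{autosomes_only}.
#'
#' @param min_call_rate minimum marker call rate kept (default 0.95).
#' @param min_maf minimum minor allele frequency kept (default 0.01).
#' @param min_hwe_p minimum exact HWE p-value kept (default 1e-6).
#' @param autosomes_only drop non-autosomal markers first (default TRUE).
#' @return a list of class \code{QCThresholds}.
#' @export
qcThresholds <- function(min_call_rate = 0.95, min_maf = 0.01,
                         min_hwe_p = 1e-6, autosomes_only = TRUE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            min_hwe_p >= 0, min_hwe_p <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p,
                 autosomes_only = isTRUE(autosomes_only)),
            class = "QCThresholds")
}

#' Marker call rate
#'
#' @param dosage_column numeric vector of dosages with NA = missing.
#' @return fraction of non-missing entries.
#' @export
markerCallRate <- function(dosage_column) {
  stopifnot(length(dosage_column) > 0L)
  mean(!is.na(dosage_column))
}

#' Marker minor allele frequency
#'
#' p is the counted-allele frequency mean(dosage)/2 over non-missing
#' entries; the MAF is min(p, 1 - p).
#'
#' @param dosage_column numeric vector of dosages with NA = missing.
#' @return the minor allele frequency.
#' @export
markerMAF <- function(dosage_column) {
  x <- dosage_column[!is.na(dosage_column)]
  if (!length(x)) stop("all-missing marker")
  p <- mean(x) / 2
  min(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test with probability ordering: conditional on the
#' observed allele counts, the p-value is the sum of hypergeometric-null
#' probabilities of all heterozygote counts whose probability does not
#' exceed that of the observed count. Computed in log space over the full
#' enumeration, so it is exact for any sample size.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (homozygous counted, heterozygous,
#'   homozygous other).
#' @return the exact two-sided p-value.
#' @export
hweExactPvalue <- function(n_AA, n_Aa, n_aa) {
  if (n_AA < 0 || n_Aa < 0 || n_aa < 0) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop("no genotyped individuals")
  nA <- 2L * n_AA + n_Aa            # counted-allele copies
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  # heterozygote count shares the parity of the rare-allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(n_Aa = h | nA, na) = const + lchoose terms; normalize over hets
  logp <- vapply(hets, function(h) {
    hAA <- (nA - h) %/% 2L
    haa <- (na - h) %/% 2L
    lfactorial(n) - lfactorial(hAA) - lfactorial(h) - lfactorial(haa) +
      h * log(2)
  }, 0)
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[match(n_Aa, hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  # 1e-12 relative slack keeps ties (equal probabilities) inside the sum
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Apply marker quality control
#'
#' Filters are applied sequentially — non-autosomal, call rate, MAF, HWE —
#' so the report attributes each removed marker to the first filter that
#' rejects it. Removal is strict-inequality ("below threshold"); markers
#' exactly at a threshold are kept. MAF and HWE are computed from the
#' non-missing genotypes of markers surviving the call-rate filter.
#' Surviving markers keep their original order.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param thresholds a \code{\link{qcThresholds}}.
#' @return list with \code{genotypes} (filtered \linkS4class{GenotypeData})
#'   and \code{report} (a \linkS4class{QCReport}).
#' @export
applyQC <- function(gm, thresholds = qcThresholds()) {
  stopifnot(inherits(thresholds, "QCThresholds"))
  d <- dosages(gm)
  mk <- markerInfo(gm)
  m0 <- ncol(d)
  keep <- rep(TRUE, m0)
  autosomes <- as.character(1:26)
  rm_auto <- 0L
  if (thresholds$autosomes_only) {
    bad <- !(mk$chrom %in% autosomes)
    rm_auto <- sum(bad)
    keep[bad] <- FALSE
  }
  cr <- colMeans(!is.na(d))
  bad <- keep & cr < thresholds$min_call_rate
  rm_cr <- sum(bad)
  keep[bad] <- FALSE
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0           # all-missing column: MAF undefined -> 0
  bad <- keep & maf < thresholds$min_maf
  rm_maf <- sum(bad)
  keep[bad] <- FALSE
  rm_hwe <- 0L
  if (thresholds$min_hwe_p > 0) {
    for (j in which(keep)) {
      x <- d[, j]
      x <- x[!is.na(x)]
      # HWE is defined on hard genotype calls; fractional (imputed)
      # dosages are rounded to the nearest genotype
      x <- round(x)
      pv <- hweExactPvalue(sum(x == 2), sum(x == 1), sum(x == 0))
      if (pv < thresholds$min_hwe_p) {
        keep[j] <- FALSE
        rm_hwe <- rm_hwe + 1L
      }
    }
  }
  rep_ <- new("QCReport", nMarkersIn = m0,
              removedNonAutosomal = as.integer(rm_auto),
              removedCallRate = as.integer(rm_cr),
              removedMaf = as.integer(rm_maf),
              removedHwe = as.integer(rm_hwe),
              nMarkersOut = as.integer(sum(keep)),
              nImputedCells = 0L)
  list(genotypes = gm[, which(keep)], report = rep_)
}

#' Impute sporadic missing genotypes from allele frequencies
#'
#' Fills each missing cell of marker j using the observed counted-allele
#' frequency p_j: \code{expected_dosage} mode fills the (possibly
#' fractional) mean dosage 2*p_j; \code{sampled} mode draws from
#' Binomial(2, p_j). Non-missing cells are never changed.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param mode "expected_dosage" (default) or "sampled".
#' @param seed integer seed used in sampled mode.
#' @return list with \code{genotypes} (complete \linkS4class{GenotypeData})
#'   and \code{n_imputed}, the number of cells filled.
#' @export
imputeSporadic <- function(gm, mode = c("expected_dosage", "sampled"),
                           seed = 1L) {
  mode <- match.arg(mode)
  d <- dosages(gm)
  nmiss_col <- colSums(is.na(d))
  nobs_col <- nrow(d) - nmiss_col
  if (any(nobs_col == 0L)) stop("all-missing marker cannot be imputed")
  total <- sum(nmiss_col)
  if (total > 0L) {
    if (mode == "sampled") set.seed(seed)
    p <- colMeans(d, na.rm = TRUE) / 2
    for (j in which(nmiss_col > 0L)) {
      idx <- is.na(d[, j])
      d[idx, j] <- if (mode == "expected_dosage") 2 * p[j]
                   else rbinom(sum(idx), 2L, p[j])
    }
  }
  list(genotypes = GenotypeData(d, markerInfo(gm)),
       n_imputed = as.integer(total))
}
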