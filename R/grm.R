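#' Counted-allele frequencies
#'
#' p_f = mean(dosage_f)/2 per marker, computed from the analyzed sample.
#' Frequencies are of the counted allele (not folded to the minor allele):
#' the GRM denominator p(1-p) is fold-invariant, while the column centering
#' 2p must use the counted allele's frequency for the centered columns to
#' sum to zero.
#'
#' @param gm a \linkS4class{GenotypeData} with a complete (imputed) dosage
#'   matrix.
#' @return named numeric vector of per-marker frequencies.
#' @export
alleleFreqs <- function(gm) {
  d <- dosages(gm)
  if (!length(d)) stop("empty genotype matrix")
  if (anyNA(d)) stop("missing dosages: impute before computing frequencies")
  colMeans(d) / 2
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' G = W W' / (2 * sum_f p_f (1 - p_f)) where W is the dosage matrix with
#' each column centered by twice its allele frequency. Monomorphic markers
#' (p in \{0, 1\}) contribute nothing to W but would deflate the
#' denominator; they are excluded from the denominator sum when
#' \code{drop_monomorphic}, otherwise their presence is an error.
#'
#' @param gm a complete \linkS4class{GenotypeData}.
#' @param freqs optional per-marker frequencies (defaults to
#'   \code{\link{alleleFreqs}} of the sample).
#' @param drop_monomorphic drop p(1-p) = 0 markers from the denominator
#'   (default TRUE).
#' @return a \linkS4class{GRMatrix}.
#' @export
vanRadenGRM <- function(gm, freqs = NULL, drop_monomorphic = TRUE) {
  d <- dosages(gm)
  if (anyNA(d)) stop("missing dosages: impute before building the GRM")
  if (is.null(freqs)) freqs <- alleleFreqs(gm)
  stopifnot(length(freqs) == ncol(d), all(freqs >= 0), all(freqs <= 1))
  pq <- freqs * (1 - freqs)
  mono <- pq == 0
  if (any(mono) && !drop_monomorphic)
    stop(sum(mono), " monomorphic markers present; drop them or impute")
  denom <- 2 * sum(pq[!mono])
  if (denom <= 0) stop("all markers monomorphic: zero denominator")
  W <- sweep(d[, !mono, drop = FALSE], 2L, 2 * freqs[!mono])
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(d), rownames(d))
  new("GRMatrix", mat = G, denominator = denom)
}

#' Add a diagonal ridge to a GRM
#'
#' A small diagonal inflation stabilizes inversion- and
#' eigendecomposition-based operations downstream when G is numerically
#' singular (e.g. more individuals than effective markers).
#'
#' @param grm a \linkS4class{GRMatrix}.
#' @param ridge value added to the diagonal (default 1e-6).
#' @return the inflated \linkS4class{GRMatrix}.
#' @export
grmRidge <- function(grm, ridge = 1e-6) {
  m <- grmMatrix(grm)
  diag(m) <- diag(m) + ridge
  new("GRMatrix", mat = m, denominator = grm@denominator)
}

#' Write / read a GRM as TSV
#'
#' Full-matrix TSV with individual IDs as the header and first column.
#'
#' @param grm a \linkS4class{GRMatrix}.
#' @param path output path.
#' @export
writeGRM <- function(grm, path) {
  m <- grmMatrix(grm)
  tab <- data.frame(id = rownames(m), m, check.names = FALSE)
  attr_line <- sprintf("# denominator\t%.10g", grm@denominator)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGRM
#' @export
readGRM <- function(path) {
  first <- readLines(path, n = 1L)
  denom <- as.numeric(strsplit(first, "\t")[[1L]][2L])
  tab <- read.table(path, header = TRUE, sep = "\t", skip = 1L,
                    check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  new("GRMatrix", mat = (m + t(m)) / 2, denominator = denom)
}
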