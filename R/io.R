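#' Read genotypes from PLINK text files (PED/MAP)
#'
#' Dosages are counts of the counted allele per marker. By default the
#' counted allele is the first non-missing allele encountered in file order
#' for that marker (PED carries no reference allele; every downstream
#' quantity here is invariant to the choice). '0 0' allele pairs become
#' missing dosages.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param counted_alleles optional named character vector
#'   (marker id -> allele) overriding the counted-allele convention.
#' @return a \linkS4class{GenotypeData}; row/marker order equals file order.
#' @export
readPlinkText <- function(ped_path, map_path, counted_alleles = NULL) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- read.table(map_path, header = FALSE, sep = "",
                    colClasses = "character")
  if (ncol(map) < 4L) stop("MAP file must have 4 columns")
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  if (anyDuplicated(map$id)) stop("duplicate marker IDs in MAP")
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  if (length(unique(nf)) > 1L) stop("ragged PED rows")
  if (nf[1L] != 6L + 2L * m)
    stop("PED row length ", nf[1L], " does not match MAP (",
         6L + 2L * m, " fields expected)")
  n <- length(toks)
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  ids <- tok[, 2L]
  if (anyDuplicated(ids)) stop("duplicate individual IDs in PED")
  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  ok <- c("A", "C", "G", "T", "0", "1", "2", "B")
  bad <- !(a1 %in% ok & a2 %in% ok)
  if (any(bad)) stop("unrecognized allele symbol: ",
                     paste(unique(c(a1[bad], a2[bad])), collapse = ", "))
  # '0 0' = missing; a half-missing pair is malformed
  miss <- a1 == "0" | a2 == "0"
  if (any(miss & !(a1 == "0" & a2 == "0")))
    stop("half-missing allele pair in PED")
  dos <- matrix(NA_real_, n, m, dimnames = list(ids, map$id))
  counted <- character(m)
  other <- character(m)
  for (j in seq_len(m)) {
    obs1 <- a1[!miss[, j], j]
    obs2 <- a2[!miss[, j], j]
    seen <- unique(c(rbind(obs1, obs2)))
    if (length(seen) > 2L)
      stop("marker ", map$id[j], " has >2 alleles: ",
           paste(seen, collapse = ","))
    cj <- if (!is.null(counted_alleles) && map$id[j] %in% names(counted_alleles))
      counted_alleles[[map$id[j]]] else if (length(seen)) seen[1L] else "0"
    counted[j] <- cj
    other[j] <- if (length(seen) >= 2L) setdiff(seen, cj)[1L]
                else if (length(seen) == 1L && seen[1L] != cj) seen[1L]
                else "0"
    dj <- (obs1 == cj) + (obs2 == cj)
    dos[!miss[, j], j] <- dj
  }
  markers <- data.frame(id = map$id, chrom = map$chrom,
                        pos = as.integer(map$pos),
                        allele1 = counted, allele2 = other,
                        low_panel = TRUE, stringsAsFactors = FALSE)
  GenotypeData(dos, markers)
}

#' Write genotypes to PLINK text files (PED/MAP)
#'
#' Inverse of \code{\link{readPlinkText}} on non-missing data: dosage 2 is
#' written as a homozygous counted-allele pair, 0 as homozygous other
#' allele, 1 as heterozygous (counted allele first), missing as '0 0'.
#' Fractional (imputed) dosages cannot be represented and raise an error.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param ped_path,map_path output paths.
#' @export
writePlinkText <- function(gm, ped_path, map_path) {
  d <- dosages(gm)
  mk <- markerInfo(gm)
  v <- d[!is.na(d)]
  if (length(v) && any(v != round(v)))
    stop("fractional dosages cannot be written as allele pairs")
  write.table(data.frame(mk$chrom, mk$id, 0L, mk$pos),
              map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nrow(d); m <- ncol(d)
  a1 <- matrix(mk$allele1[col(d)], n, m)
  a2 <- matrix(mk$allele2[col(d)], n, m)
  first <- ifelse(is.na(d), "0", ifelse(d >= 1, a1, a2))
  second <- ifelse(is.na(d), "0", ifelse(d == 2, a1, a2))
  geno <- matrix("", n, 2L * m)
  geno[, 2L * seq_len(m) - 1L] <- first
  geno[, 2L * seq_len(m)] <- second
  ids <- rownames(d)
  out <- cbind(ids, ids, "0", "0", "0", "-9", geno)
  writeLines(apply(out, 1L, paste, collapse = " "), ped_path)
  invisible(c(ped_path, map_path))
}

#' Read a dosage matrix from TSV
#'
#' Expects a header row of marker IDs with the first column holding
#' individual IDs; cells must be 0, 1, 2 or NA (blank).
#'
#' @param path TSV path.
#' @return a \linkS4class{GenotypeData} with stub marker metadata.
#' @export
readMatrixTSV <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) stop("duplicate individual IDs")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(as.numeric(vals))
  if (any(!is.na(vals) & is.na(num))) stop("non-numeric dosage cell")
  bad <- !is.na(num) & !(num %in% c(0, 1, 2))
  if (any(bad)) stop("dosage outside {0,1,2,NA}: ",
                     paste(unique(num[bad]), collapse = ", "))
  d <- matrix(num, nrow = nrow(tab),
              dimnames = list(ids, colnames(tab)[-1L]))
  GenotypeData(d)
}

#' Read a phenotype table
#'
#' Expects a TSV with header columns id, herd, sex and at least one trait
#' column; trait cells parse as numeric with blank/NA meaning missing
#' (e.g. a prediction candidate).
#'
#' @param path TSV path.
#' @return data.frame with character id/herd/sex and numeric trait columns,
#'   in file order.
#' @export
readPhenotypes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", na.strings = c("NA", ""))
  need <- c("id", "herd", "sex")
  if (!all(need %in% names(tab)) || ncol(tab) < 4L)
    stop("phenotype file needs columns id, herd, sex and >=1 trait")
  if (anyDuplicated(tab$id)) stop("duplicate individual IDs")
  traits <- setdiff(names(tab), need)
  for (tr in traits) {
    num <- suppressWarnings(as.numeric(tab[[tr]]))
    if (any(!is.na(tab[[tr]]) & is.na(num)))
      stop("non-numeric value in trait column ", tr)
    tab[[tr]] <- num
  }
  if (anyNA(tab$herd) || anyNA(tab$sex))
    stop("herd and sex must be non-missing")
  tab
}
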