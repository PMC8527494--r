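#' @useDynLib wgrBayes, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats var cor sd rnorm rbinom rbeta runif rexp rt rchisq
#'   quantile complete.cases dbinom setNames
#' @importFrom utils read.table write.table
NULL

#' Genotype dosages with marker metadata
#'
#' An individuals-by-markers matrix of counted-allele dosages in
#' \{0, 1, 2\} (or \code{NA} for a missing call; fractional values are
#' permitted after expected-dosage imputation), together with a per-marker
#' metadata table. Row names of \code{dosages} are individual IDs, column
#' names are marker IDs.
#'
#' @slot dosages numeric matrix, individuals x markers.
#' @slot markers data.frame with one row per marker: \code{id},
#'   \code{chrom} (character; sheep autosomes are "1"--"26"), \code{pos}
#'   (1-based bp), \code{allele1} (the counted allele), \code{allele2},
#'   and logical \code{low_panel} flagging membership in the nested
#'   low-density panel.
#'
#' @export
setClass("GenotypeData",
  representation(dosages = "matrix", markers = "data.frame"),
  validity = function(object) {
    d <- object@dosages
    mk <- object@markers
    msg <- character()
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
      msg <- c(msg, "individual IDs (rownames) must be present and unique")
    if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
      msg <- c(msg, "marker IDs (colnames) must be present and unique")
    need <- c("id", "chrom", "pos", "allele1", "allele2")
    if (!all(need %in% names(mk)))
      msg <- c(msg, paste("markers must have columns:",
                          paste(need, collapse = ", ")))
    else if (nrow(mk) != ncol(d) || !identical(as.character(mk$id), colnames(d)))
      msg <- c(msg, "markers$id must match dosage column names in order")
    v <- d[!is.na(d)]
    if (length(v) && (min(v) < 0 || max(v) > 2))
      msg <- c(msg, "dosages must lie in [0, 2]")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a GenotypeData object
#'
#' @param dosages individuals x markers numeric matrix with rownames
#'   (individual IDs) and colnames (marker IDs); entries in \{0,1,2\} or
#'   fractional in [0,2] after imputation, \code{NA} = missing.
#' @param markers per-marker data.frame (see \linkS4class{GenotypeData});
#'   if \code{NULL} a stub with chromosome "1" and consecutive positions
#'   is built.
#' @return a \linkS4class{GenotypeData}.
#' @export
GenotypeData <- function(dosages, markers = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(markers)) {
    markers <- data.frame(
      id = colnames(dosages), chrom = "1", pos = seq_len(ncol(dosages)),
      allele1 = "A", allele2 = "B", low_panel = TRUE,
      stringsAsFactors = FALSE)
  }
  if (is.null(markers$low_panel)) markers$low_panel <- TRUE
  rownames(markers) <- NULL
  new("GenotypeData", dosages = dosages, markers = markers)
}

#' @describeIn GenotypeData-class dosage matrix accessor
#' @param x,object a \code{GenotypeData}
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-class
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @describeIn GenotypeData-class individual ID accessor
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname GenotypeData-class
#' @export
setMethod("individualIds", "GenotypeData", function(x) rownames(x@dosages))

#' @describeIn GenotypeData-class marker metadata accessor
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname GenotypeData-class
#' @export
setMethod("markerInfo", "GenotypeData", function(x) x@markers)

#' @rdname GenotypeData-class
#' @param i,j,drop row (individual) and column (marker) indices
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  GenotypeData(x@dosages[i, j, drop = FALSE], x@markers[j, , drop = FALSE])
})

setMethod("show", "GenotypeData", function(object) {
  d <- object@dosages
  nmiss <- sum(is.na(d))
  cat("GenotypeData:", nrow(d), "individuals x", ncol(d), "markers\n")
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(d)))
  cat("  low-density panel markers:", sum(object@markers$low_panel), "\n")
})

#' Genomic relationship matrix (VanRaden method 1)
#'
#' @slot mat n x n symmetric relationship matrix with individual IDs as
#'   dimnames.
#' @slot denominator the scalar 2 * sum(p_f (1 - p_f)) used to scale
#'   \code{W W'}.
#' @export
setClass("GRMatrix",
  representation(mat = "matrix", denominator = "numeric"),
  validity = function(object) {
    m <- object@mat
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
      msg <- c(msg, "matrix must be symmetric")
    if (is.null(rownames(m))) msg <- c(msg, "individual IDs required")
    if (object@denominator <= 0) msg <- c(msg, "denominator must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn GRMatrix-class relationship matrix accessor
#' @param x,object a \code{GRMatrix}
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname GRMatrix-class
#' @export
setMethod("grmMatrix", "GRMatrix", function(x) x@mat)

#' @rdname GRMatrix-class
#' @export
setMethod("individualIds", "GRMatrix", function(x) rownames(x@mat))

setMethod("show", "GRMatrix", function(object) {
  cat("GRMatrix:", nrow(object@mat), "individuals\n")
  cat(sprintf("  denominator 2*sum(p(1-p)) = %.4f\n", object@denominator))
  cat(sprintf("  mean diagonal = %.4f\n", mean(diag(object@mat))))
})

#' Marker quality-control report
#'
#' Counts of markers removed by each sequentially applied filter
#' (non-autosomal, call rate, MAF, HWE, in that order) plus the number of
#' imputed cells if imputation was run.
#'
#' @slot nMarkersIn,nMarkersOut marker counts before/after filtering.
#' @slot removedNonAutosomal,removedCallRate,removedMaf,removedHwe
#'   markers removed by each filter, attributed in application order.
#' @slot nImputedCells missing cells filled by \code{\link{imputeSporadic}}.
#' @export
setClass("QCReport",
  representation(nMarkersIn = "integer", removedNonAutosomal = "integer",
                 removedCallRate = "integer", removedMaf = "integer",
                 removedHwe = "integer", nMarkersOut = "integer",
                 nImputedCells = "integer"),
  validity = function(object) {
    tot <- object@removedNonAutosomal + object@removedCallRate +
      object@removedMaf + object@removedHwe
    if (object@nMarkersOut != object@nMarkersIn - tot)
      "removal counts do not reconcile with marker counts" else TRUE
  }
)

setMethod("show", "QCReport", function(object) {
  cat("QCReport:\n")
  cat("  markers in:          ", object@nMarkersIn, "\n")
  cat("  removed non-autosomal:", object@removedNonAutosomal, "\n")
  cat("  removed call rate:   ", object@removedCallRate, "\n")
  cat("  removed MAF:         ", object@removedMaf, "\n")
  cat("  removed HWE:         ", object@removedHwe, "\n")
  cat("  markers out:         ", object@nMarkersOut, "\n")
  cat("  imputed cells:       ", object@nImputedCells, "\n")
})

#' Posterior fit of a whole-genome regression model
#'
#' Holds stored MCMC draws of the scalar parameters (residual variance,
#' genetic variance, pi, lambda^2, fixed effects), posterior means and SDs
#' of marker effects (marker models) or breeding values (GBLUP), and the
#' posterior-mean genetic value per individual.
#'
#' @slot model one of "bayesA", "bayesB", "bayesCpi", "blasso", "gblup",
#'   "ridge".
#' @slot scalarDraws matrix of stored draws (rows) for named scalar
#'   parameters; always contains \code{varE} and \code{varG} (per-draw
#'   additive variance: variance of genetic values for marker models,
#'   sigma^2_a for GBLUP).
#' @slot bDraws stored fixed-effect draws (draws x p).
#' @slot effects data.frame with posterior \code{mean} and \code{sd} per
#'   marker effect (marker models) or per breeding value (GBLUP).
#' @slot effectDraws optional matrix of per-marker effect draws (only when
#'   requested; empty otherwise).
#' @slot gMean posterior-mean genetic value for every individual in the fit.
#' @slot settings list echoing resolved hyperparameters, MCMC settings,
#'   training allele frequencies, design column names, diagnostics.
#' @export
setClass("WgrFit",
  representation(model = "character", scalarDraws = "matrix",
                 bDraws = "matrix", effects = "data.frame",
                 effectDraws = "matrix", gMean = "numeric",
                 settings = "list"),
  validity = function(object) {
    msg <- character()
    sd_ <- object@scalarDraws
    if (!all(c("varE", "varG") %in% colnames(sd_)))
      msg <- c(msg, "scalarDraws must contain varE and varG")
    if (any(sd_[, "varE"] <= 0)) msg <- c(msg, "varE draws must be > 0")
    if ("pi" %in% colnames(sd_)) {
      p <- sd_[, "pi"]
      if (any(p < 0 | p > 1)) msg <- c(msg, "pi draws must lie in [0,1]")
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "WgrFit", function(object) {
  s <- object@scalarDraws
  cat("WgrFit:", object@model, "-", nrow(s), "stored draws\n")
  cat(sprintf("  varE: %.4g (sd %.3g)   varG: %.4g (sd %.3g)\n",
              mean(s[, "varE"]), sd(s[, "varE"]),
              mean(s[, "varG"]), sd(s[, "varG"])))
  h <- heritability(object)
  cat(sprintf("  h2:   %.3f (sd %.3f)\n", h[["estimate"]], h[["sd"]]))
})

#' @describeIn WgrFit-class stored scalar parameter draws
#' @param x,object a \code{WgrFit}
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' @rdname WgrFit-class
#' @export
setMethod("posteriorDraws", "WgrFit", function(x)
  cbind(x@scalarDraws,
        if (ncol(x@bDraws)) x@bDraws else NULL))

#' @describeIn WgrFit-class posterior mean/sd of marker effects or
#'   breeding values
#' @export
setGeneric("posteriorEffects", function(x) standardGeneric("posteriorEffects"))

#' @rdname WgrFit-class
#' @export
setMethod("posteriorEffects", "WgrFit", function(x) x@effects)

#' Cross-validation result
#'
#' Per (replicate, fold) prediction accuracies for each model, with the
#' overall mean and standard error recomputable from the stored values.
#'
#' @slot folds data.frame with columns \code{replicate}, \code{fold},
#'   \code{model}, \code{trait}, \code{accuracy}, \code{n_validation}.
#' @slot meta list of seeds and settings used.
#' @export
setClass("CVResult",
  representation(folds = "data.frame", meta = "list"),
  validity = function(object) {
    need <- c("replicate", "fold", "model", "accuracy")
    if (!all(need %in% names(object@folds)))
      paste("folds must have columns:", paste(need, collapse = ", "))
    else TRUE
  }
)

#' @describeIn CVResult-class per fold-replicate accuracy table
#' @param x,object a \code{CVResult}
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))

#' @rdname CVResult-class
#' @export
setMethod("cvFolds", "CVResult", function(x) x@folds)

#' @describeIn CVResult-class mean accuracy and SE per model (and trait)
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))

#' @rdname CVResult-class
#' @export
setMethod("cvSummary", "CVResult", function(x) {
  f <- x@folds
  sp <- split(f$accuracy, list(model = f$model, trait = f$trait), drop = TRUE)
  keys <- strsplit(names(sp), "\\.")
  data.frame(
    model = vapply(keys, `[`, "", 1L),
    trait = vapply(keys, `[`, "", 2L),
    mean = vapply(sp, mean, 0),
    se = vapply(sp, function(a) sd(a) / sqrt(length(a)), 0),
    n = vapply(sp, length, 0L),
    row.names = NULL)
})

setMethod("show", "CVResult", function(object) {
  cat("CVResult:", nrow(object@folds), "fold-replicate accuracies\n")
  print(cvSummary(object), digits = 3)
})
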