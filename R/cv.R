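#' Random k-fold assignment
#'
#' Uniformly random permutation split into k blocks whose sizes differ by
#' at most one (the first \code{n mod k} folds get the extra individual).
#'
#' @param ids individual IDs.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold indices (1..k) named by \code{ids}.
#' @export
kfoldAssign <- function(ids, k = 5L, seed = 1L) {
  n <- length(ids)
  stopifnot(k >= 2, k <= n)
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  setNames(fold, ids)
}

#' Corrected phenotype
#'
#' y* = y - X b_hat: the phenotype with the fixed-effect estimates (from
#' the TRAINING fit) removed, the quantity GEBVs are correlated with when
#' scoring prediction accuracy.
#'
#' @param y phenotypes of the individuals to correct.
#' @param X their fixed-effect design rows (columns matching
#'   \code{b_hat}).
#' @param b_hat posterior-mean fixed effects from the training fit.
#' @return numeric vector y*.
#' @export
correctedPhenotype <- function(y, X, b_hat) {
  X <- as.matrix(X)
  if (ncol(X) != length(b_hat))
    stop("design columns do not match length(b_hat)")
  drop(y - X %*% b_hat)
}

#' Prediction accuracy
#'
#' Pearson correlation between GEBVs and corrected phenotypes.
#'
#' @param gebv predicted breeding values.
#' @param y_star corrected phenotypes, same length (>= 3).
#' @return the correlation, in [-1, 1].
#' @export
predictionAccuracy <- function(gebv, y_star) {
  stopifnot(length(gebv) == length(y_star), length(gebv) >= 3)
  if (sd(gebv) == 0 || sd(y_star) == 0)
    stop("zero variance: accuracy undefined")
  cor(gebv, y_star)
}

#' K-fold cross-validated genomic prediction accuracy
#'
#' For each replicate a fresh random fold assignment is drawn (replicate
#' seeds are master_seed + replicate). For each fold, the fold's
#' phenotypes are masked and the model refit on the full design with the
#' candidates carried inside the sampler as missing y; their GEBVs are
#' extracted and correlated with their training-corrected phenotypes
#' y* = y - X b_hat. For marker models the dosage matrix is re-centered
#' per fold with training-individual allele frequencies. The final
#' accuracy per model is the mean over all k x n_replicates values.
#'
#' @param genotypes complete \linkS4class{GenotypeData} (marker models and
#'   GRM construction).
#' @param phenotypes data.frame with id, herd, sex and the trait column;
#'   row order must match \code{genotypes}.
#' @param trait trait column name (default first non-id/herd/sex column).
#' @param models character vector of prior families to evaluate.
#' @param k folds (default 5).
#' @param n_replicates fold-assignment replicates (default 3).
#' @param seed master seed.
#' @param mcmc a \code{\link{mcmcSettings}} template; its seed is
#'   overridden per fit for auditability.
#' @param priors optional named list of \code{\link{priorSpec}} objects
#'   per model (default \code{priorSpec(family)}).
#' @param grm optional precomputed \linkS4class{GRMatrix} for gblup
#'   (default: VanRaden from \code{genotypes}).
#' @return a \linkS4class{CVResult}.
#' @export
crossValidate <- function(genotypes, phenotypes, trait = NULL,
                          models = c("bayesA", "bayesB", "bayesCpi",
                                     "blasso", "gblup"),
                          k = 5L, n_replicates = 3L, seed = 1L,
                          mcmc = mcmcSettings(), priors = NULL,
                          grm = NULL) {
  Z <- dosages(genotypes)
  if (anyNA(Z)) stop("missing dosages: impute before cross-validation")
  stopifnot(nrow(phenotypes) == nrow(Z),
            all(phenotypes$id == rownames(Z)))
  if (is.null(trait))
    trait <- setdiff(names(phenotypes), c("id", "herd", "sex"))[1L]
  y_all <- phenotypes[[trait]]
  design <- buildDesign(phenotypes)
  X <- design$X
  obs <- which(!is.na(y_all))
  if ("gblup" %in% models && is.null(grm))
    grm <- vanRadenGRM(genotypes)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    fold <- kfoldAssign(phenotypes$id, k, seed = seed + r)
    for (f in seq_len(k)) {
      val <- intersect(which(fold == f), obs)
      y <- y_all
      y[fold == f] <- NA           # candidates carried as missing
      tf <- colMeans(Z[which(!is.na(y)), , drop = FALSE]) / 2
      for (mod in models) {
        pr <- if (!is.null(priors) && mod %in% names(priors))
          priors[[mod]] else priorSpec(mod)
        mc <- mcmcSettings(mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                           seed = seed + 1000L * r + 10L * f,
                           n_chains = mcmc$n_chains)
        fit <- if (mod == "gblup")
          wgrFit(y, design, grm = grm, prior = pr, mcmc = mc)
        else
          wgrFit(y, design, genotypes = Z, prior = pr, mcmc = mc,
                 train_freqs = tf)
        g_val <- gebv(fit)[val]
        b_hat <- if (ncol(fit@bDraws)) colMeans(fit@bDraws) else numeric(0)
        y_star <- if (length(b_hat))
          correctedPhenotype(y_all[val], X[val, , drop = FALSE], b_hat)
        else y_all[val]
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, fold = f, model = mod, trait = trait,
          accuracy = predictionAccuracy(g_val, y_star),
          n_validation = length(val), stringsAsFactors = FALSE)
      }
    }
  }
  new("CVResult", folds = do.call(rbind, rows),
      meta = list(seed = seed, k = k, n_replicates = n_replicates,
                  mcmc = mcmc, models = models, trait = trait))
}
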