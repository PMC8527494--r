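#' Prior specification for a whole-genome regression model
#'
#' Each family matches a marker-effect distribution: normal
#' (GBLUP / ridge), scaled-t (bayesA), point-mass + t (bayesB), point-mass
#' + common-variance normal whose variance carries a scaled-inv-chi-square
#' prior, hence marginally a point-t mixture (bayesCpi), and
#' double-exponential via the Park-Casella scale-mixture hierarchy
#' (blasso). Unset scales are resolved at fit time by the R2 heuristic:
#' the prior mode of the genetic variance is set to \code{R2 * Var(y)},
#' spread over markers through the sum of marker variances for marker
#' models.
#'
#' @param family one of "bayesA", "bayesB", "bayesCpi", "blasso", "gblup",
#'   "ridge" ("ridge" is bayesCpi with pi fixed at 0).
#' @param df degrees of freedom of the scaled-inv-chi-square variance
#'   priors (default 5; must exceed 2 for a finite prior variance).
#' @param scale scale S of the marker-variance (or sigma2_a) prior;
#'   \code{NULL} = resolve from \code{R2}.
#' @param scale_estimate for bayesA/bayesB, sample S under a Gamma
#'   hyperprior (mode at the resolved scale) so per-marker variances pool
#'   information across markers; without this the t prior is
#'   prior-dominated when markers far outnumber individuals. Default TRUE
#'   for bayesA/bayesB when \code{scale} is auto-resolved, FALSE
#'   otherwise.
#' @param dfE,scaleE residual-variance prior df and scale (scale
#'   \code{NULL} = resolve from \code{R2}).
#' @param pi prior probability a marker effect is exactly zero. Defaults:
#'   0.95 fixed for bayesB, 0.5 (starting value, estimated) for bayesCpi,
#'   0 for the others.
#' @param pi_estimate sample pi with a Beta(1,1) prior (default TRUE for
#'   bayesCpi, FALSE otherwise).
#' @param lambda2 squared double-exponential rate for blasso; \code{NULL}
#'   = resolve from \code{R2}. Sampled under a Gamma hyperprior unless
#'   \code{lambda_fixed}.
#' @param lambda_fixed keep lambda2 fixed (default FALSE).
#' @param lambda_shape shape of the Gamma hyperprior on lambda2
#'   (default 1.1); its rate is set so the prior mean equals the resolved
#'   lambda2.
#' @param R2 assumed model R-squared used to auto-set scales
#'   (default 0.5).
#' @param fix_varE optional fixed residual variance (diagnostics only);
#'   \code{NULL} = sample it.
#' @return a list of class \code{PriorSpec}.
#' @export
priorSpec <- function(family = c("bayesA", "bayesB", "bayesCpi", "blasso",
                                 "gblup", "ridge"),
                      df = 5, scale = NULL, scale_estimate = NULL,
                      dfE = 5, scaleE = NULL,
                      pi = NULL, pi_estimate = NULL, lambda2 = NULL,
                      lambda_fixed = FALSE, lambda_shape = 1.1, R2 = 0.5,
                      fix_varE = NULL) {
  family <- match.arg(family)
  stopifnot(df > 2, dfE > 0, R2 > 0, R2 < 1)
  if (is.null(pi))
    pi <- switch(family, bayesB = 0.95, bayesCpi = 0.5, 0)
  stopifnot(pi >= 0, pi <= 1)
  if (is.null(pi_estimate)) pi_estimate <- family == "bayesCpi"
  if (is.null(scale_estimate))
    scale_estimate <- is.null(scale) && family %in% c("bayesA", "bayesB")
  structure(list(family = family, df = df, scale = scale,
                 scale_estimate = scale_estimate, dfE = dfE,
                 scaleE = scaleE, pi = pi, pi_estimate = pi_estimate,
                 lambda2 = lambda2, lambda_fixed = lambda_fixed,
                 lambda_shape = lambda_shape, R2 = R2,
                 fix_varE = fix_varE), class = "PriorSpec")
}

#' MCMC settings
#'
#' @param n_iter total Gibbs iterations (default 15000).
#' @param burn_in discarded iterations (default 5000).
#' @param thin store every thin-th post-burn-in iteration (default 5);
#'   (n_iter - burn_in) must be a multiple of thin.
#' @param seed integer seed.
#' @param n_chains independent chains run with seeds seed, seed+1, ...;
#'   stored draws are concatenated (default 1).
#' @return a list of class \code{McmcSettings}.
#' @export
mcmcSettings <- function(n_iter = 15000L, burn_in = 5000L, thin = 5L,
                         seed = 1L, n_chains = 1L) {
  stopifnot(burn_in >= 0, burn_in < n_iter, thin >= 1,
            (n_iter - burn_in) %% thin == 0, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 n_chains = as.integer(n_chains)), class = "McmcSettings")
}

#' Build the fixed-effect design matrix
#'
#' Intercept plus reference-level dummy coding for the requested factors
#' (typically herd and sex). A factor with a single observed level
#' collapses into the intercept with a message. Sex labels must be
#' M/F (or male/female, any case).
#'
#' @param phenos phenotype data.frame with columns id and the factors.
#' @param factors factor column names (default c("herd", "sex")); pass
#'   \code{character(0)} for an intercept-only design.
#' @return list of class \code{FixedDesign}: \code{X} (n x p full-rank
#'   matrix), \code{coef_names}, \code{ids} (row-to-individual mapping),
#'   \code{levels} (reference and other observed levels per factor).
#' @export
buildDesign <- function(phenos, factors = c("herd", "sex")) {
  stopifnot("id" %in% names(phenos))
  miss <- setdiff(factors, names(phenos))
  if (length(miss)) stop("missing factor columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(phenos)
  X <- matrix(1, n, 1, dimnames = list(phenos$id, "intercept"))
  lev <- list()
  for (f in factors) {
    v <- as.character(phenos[[f]])
    if (anyNA(v)) stop("factor ", f, " has missing values")
    if (f == "sex") {
      vu <- toupper(v)
      vu[vu %in% c("MALE", "M")] <- "M"
      vu[vu %in% c("FEMALE", "F")] <- "F"
      if (!all(vu %in% c("M", "F")))
        stop("unknown sex label: ",
             paste(unique(v[!vu %in% c("M", "F")]), collapse = ", "))
      v <- vu
    }
    lv <- unique(v)
    lev[[f]] <- lv
    if (length(lv) < 2L) {
      message("factor '", f, "' has a single level; collapsed to intercept")
      next
    }
    for (l in lv[-1L]) {
      X <- cbind(X, as.numeric(v == l))
      colnames(X)[ncol(X)] <- paste0(f, l)
    }
  }
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    drop <- qd$pivot[(qd$rank + 1L):ncol(X)]
    message("dropping collinear design columns: ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  structure(list(X = X, coef_names = colnames(X), ids = phenos$id,
                 levels = lev), class = "FixedDesign")
}

# Resolve prior scales from the R2 heuristic against the observed y.
resolveHyper <- function(prior, y_obs, MSx = NULL, meanDiagG = NULL) {
  Vy <- var(y_obs)
  if (!is.finite(Vy) || Vy <= 0) Vy <- 1
  nu <- prior$df
  family <- prior$family
  S <- prior$scale
  if (is.null(S)) {
    S <- if (family == "gblup") {
      prior$R2 * Vy * (nu + 2) / nu / max(meanDiagG, 1e-8)
    } else {
      base <- prior$R2 * Vy * (nu + 2) / (nu * max(MSx, 1e-8))
      keep <- if (family %in% c("bayesB", "bayesCpi")) 1 - prior$pi else 1
      base / max(keep, 0.01)
    }
  }
  SE <- prior$scaleE
  if (is.null(SE)) SE <- (1 - prior$R2) * Vy * (prior$dfE + 2) / prior$dfE
  lambda2 <- prior$lambda2
  if (is.null(lambda2))
    lambda2 <- 2 * max(MSx, 1e-8) * (1 - prior$R2) / prior$R2
  SShape <- 1.1
  list(nu = nu, S = S, nuE = prior$dfE, SE = SE, pi = prior$pi,
       SEstimate = isTRUE(prior$scale_estimate), SShape = SShape,
       SRate = (SShape - 1) / S,
       piEstimate = isTRUE(prior$pi_estimate), lambda2 = lambda2,
       lambdaFixed = isTRUE(prior$lambda_fixed),
       lambdaShape = prior$lambda_shape,
       lambdaRate = prior$lambda_shape / lambda2,
       fixVarE = !is.null(prior$fix_varE),
       varEFixed = if (is.null(prior$fix_varE)) 0 else prior$fix_varE)
}

#' Fit a whole-genome regression model by Gibbs sampling
#'
#' Single-site Gibbs sampler with residual updating for the marker models
#' (bayesA, bayesB, bayesCpi/ridge, blasso) on y = Xb + W alpha + e, and
#' an eigendecomposition-based sampler for GBLUP on y = Xb + u + e with
#' Var(u) = G sigma2_a. Individuals with missing y (prediction candidates)
#' stay in the model; their phenotypes are redrawn from the model each
#' iteration (data augmentation), so their genetic values are sampled
#' jointly with everything else.
#'
#' @param y numeric response; \code{NA} marks candidates.
#' @param design a \code{\link{buildDesign}} result, or \code{NULL} for no
#'   fixed effects at all (not even an intercept).
#' @param genotypes for marker models: a complete
#'   \linkS4class{GenotypeData} or a bare dosage matrix (individuals in the
#'   same order as y). Columns are centered internally by
#'   \code{2 * train_freqs}. Markers with zero dosage variance are
#'   unidentifiable and keep a zero effect.
#' @param grm for gblup: a \linkS4class{GRMatrix} covering the individuals
#'   of y, in order.
#' @param prior a \code{\link{priorSpec}}.
#' @param mcmc a \code{\link{mcmcSettings}}.
#' @param train_freqs allele frequencies used to center W; default:
#'   computed from the individuals with observed y, so candidate rows are
#'   centered with training frequencies.
#' @param save_effects store full per-marker effect (or breeding value)
#'   draws; memory-heavy, default FALSE.
#' @param debug recompute the residual from scratch at every stored
#'   iteration and record the maximum deviation from the maintained
#'   residual (reported in \code{settings$resid_dev}).
#' @return a \linkS4class{WgrFit}.
#' @export
wgrFit <- function(y, design = NULL, genotypes = NULL, grm = NULL,
                   prior = priorSpec(), mcmc = mcmcSettings(),
                   train_freqs = NULL, save_effects = FALSE,
                   debug = FALSE) {
  stopifnot(inherits(prior, "PriorSpec"), inherits(mcmc, "McmcSettings"))
  n <- length(y)
  yMiss <- is.na(y)
  if (all(yMiss) && is.null(prior$scale))
    stop("all y missing: prior scales cannot be resolved from data; ",
         "supply scale and scaleE explicitly")
  y0 <- ifelse(yMiss, 0, y)
  if (!all(yMiss) && var(y[!yMiss]) == 0 && is.null(prior$scale))
    stop("zero-variance response")
  X <- if (is.null(design)) matrix(0, n, 0) else design$X
  if (nrow(X) != n) stop("design rows do not match length(y)")
  family <- prior$family
  model_code <- match(family,
                      c("bayesA", "bayesB", "bayesCpi", "blasso")) - 1L
  if (family == "ridge") model_code <- 2L

  run_chain <- function(fun, ..., seed) {
    set.seed(seed)
    fun(...)
  }

  if (family == "gblup") {
    stopifnot(!is.null(grm))
    G <- grmMatrix(grm)
    if (nrow(G) != n) stop("GRM does not cover the individuals of y")
    eg <- eigen(G, symmetric = TRUE)
    tol <- 1e-8 * max(eg$values, 1)
    nClamped <- sum(eg$values < tol)
    d <- pmax(eg$values, tol)
    hy <- resolveHyper(prior, y[!yMiss], meanDiagG = mean(diag(G)))
    res <- NULL
    for (ch in seq_len(mcmc$n_chains)) {
      r <- run_chain(.gblup_mcmc, y0, yMiss, X, eg$vectors, d, hy,
                     mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                     save_effects, debug, seed = mcmc$seed + ch - 1L)
      res <- if (is.null(res)) r else {
        r$scalar <- rbind(res$scalar, r$scalar)
        r$b <- rbind(res$b, r$b)
        r$uDraws <- rbind(res$uDraws, r$uDraws)
        r$uMean <- (res$uMean + r$uMean) / 2
        r$uSD <- (res$uSD + r$uSD) / 2
        r$residDev <- max(res$residDev, r$residDev)
        r
      }
    }
    sc <- res$scalar
    colnames(sc) <- c("varE", "varG")
    bD <- res$b
    colnames(bD) <- if (ncol(X)) colnames(X) else character(0)
    ids <- rownames(G)
    return(new("WgrFit", model = "gblup", scalarDraws = sc, bDraws = bD,
               effects = data.frame(id = ids, mean = res$uMean,
                                    sd = res$uSD,
                                    stringsAsFactors = FALSE),
               effectDraws = res$uDraws, gMean = setNames(res$uMean, ids),
               settings = list(prior = prior, hyper = hy, mcmc = mcmc,
                               individual_ids = ids,
                               design_cols = colnames(X),
                               n_clamped_eigen = nClamped,
                               resid_dev = res$residDev)))
  }

  # marker models
  stopifnot(!is.null(genotypes))
  Z <- if (is(genotypes, "GenotypeData")) dosages(genotypes)
       else as.matrix(genotypes)
  if (nrow(Z) != n) stop("genotype rows do not match length(y)")
  if (anyNA(Z)) stop("missing dosages: impute before fitting")
  if (is.null(train_freqs)) {
    rows <- if (any(!yMiss)) which(!yMiss) else seq_len(n)
    train_freqs <- colMeans(Z[rows, , drop = FALSE]) / 2
  }
  W <- sweep(Z, 2L, 2 * train_freqs)
  MSx <- sum(apply(W, 2L, var))
  hy <- resolveHyper(prior, y[!yMiss], MSx = MSx)
  res <- NULL
  for (ch in seq_len(mcmc$n_chains)) {
    r <- run_chain(.wgr_mcmc, y0, yMiss, X, W, model_code, hy,
                   mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                   save_effects, debug, seed = mcmc$seed + ch - 1L)
    res <- if (is.null(res)) r else {
      r$scalar <- rbind(res$scalar, r$scalar)
      r$b <- rbind(res$b, r$b)
      r$alphaDraws <- rbind(res$alphaDraws, r$alphaDraws)
      r$alphaMean <- (res$alphaMean + r$alphaMean) / 2
      r$alphaSD <- (res$alphaSD + r$alphaSD) / 2
      r$gMean <- (res$gMean + r$gMean) / 2
      r$residDev <- max(res$residDev, r$residDev)
      r
    }
  }
  sc <- res$scalar
  keep_cols <- c("varE", "varG",
                 if (family %in% c("bayesB", "bayesCpi", "ridge")) "pi",
                 if (family == "blasso") "lambda2")
  sc <- sc[, keep_cols, drop = FALSE]
  bD <- res$b
  colnames(bD) <- if (ncol(X)) colnames(X) else character(0)
  mids <- colnames(Z)
  ids <- rownames(Z)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  new("WgrFit", model = family, scalarDraws = sc, bDraws = bD,
      effects = data.frame(id = if (is.null(mids))
                             as.character(seq_len(ncol(Z))) else mids,
                           mean = res$alphaMean, sd = res$alphaSD,
                           stringsAsFactors = FALSE),
      effectDraws = res$alphaDraws, gMean = setNames(res$gMean, ids),
      settings = list(prior = prior, hyper = hy, mcmc = mcmc,
                      train_freqs = train_freqs,
                      individual_ids = ids, marker_ids = mids,
                      design_cols = colnames(X),
                      resid_dev = res$residDev))
}

#' Genomic estimated breeding values
#'
#' For marker models, multiplies new dosages (centered with the TRAINING
#' allele frequencies stored in the fit) by the posterior-mean marker
#' effects. For GBLUP, returns the posterior mean of the sampled breeding
#' values of individuals present in the fitted G.
#'
#' @param fit a \linkS4class{WgrFit}.
#' @param genotypes marker models: \linkS4class{GenotypeData} or dosage
#'   matrix with the fit's markers (matched by name when named).
#' @param ids gblup: individual IDs to extract (default: all).
#' @param ... unused.
#' @return named numeric vector of GEBVs.
#' @export
setGeneric("gebv", function(fit, ...) standardGeneric("gebv"))

#' @rdname gebv
#' @export
setMethod("gebv", "WgrFit", function(fit, genotypes = NULL, ids = NULL,
                                     ...) {
  if (fit@model == "gblup") {
    u <- fit@gMean
    if (is.null(ids)) return(u)
    if (!all(ids %in% names(u)))
      stop("individuals not in the fitted GRM: ",
           paste(setdiff(ids, names(u)), collapse = ", "))
    return(u[ids])
  }
  if (is.null(genotypes)) return(fit@gMean)
  Z <- if (is(genotypes, "GenotypeData")) dosages(genotypes)
       else as.matrix(genotypes)
  mids <- fit@settings$marker_ids
  if (!is.null(mids) && !is.null(colnames(Z))) {
    if (!all(mids %in% colnames(Z)))
      stop("marker mismatch: fit markers absent from new genotypes")
    Z <- Z[, mids, drop = FALSE]
  } else if (ncol(Z) != nrow(fit@effects)) {
    stop("marker mismatch: ", ncol(Z), " columns vs ",
         nrow(fit@effects), " fitted markers")
  }
  W <- sweep(Z, 2L, 2 * fit@settings$train_freqs)
  drop(W %*% fit@effects$mean)
})

#' Posterior heritability
#'
#' h2 = sigma2_a / (sigma2_a + sigma2_e) computed per stored draw and then
#' summarized. For marker models sigma2_a at a draw is the variance of the
#' genetic values W alpha across individuals at that draw; for GBLUP it is
#' the sampled sigma2_a.
#'
#' @param fit a \linkS4class{WgrFit}.
#' @param ... unused.
#' @return named vector: \code{estimate} (posterior mean) and \code{sd}
#'   (posterior SD).
#' @export
setGeneric("heritability", function(fit, ...) standardGeneric("heritability"))

#' @rdname heritability
#' @export
setMethod("heritability", "WgrFit", function(fit, ...) {
  s <- fit@scalarDraws
  h <- s[, "varG"] / (s[, "varG"] + s[, "varE"])
  c(estimate = mean(h), sd = if (nrow(s) > 1) sd(h) else 0)
})
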