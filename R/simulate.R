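#' Simulation configuration for a two-density genotype/phenotype study
#'
#' Defines the study conditions the generator emulates: a sheep-scale
#' population genotyped on a high-density panel with a nested low-density
#' subset, herd and sex fixed effects, and an additive architecture matched
#' to one of the whole-genome regression prior families. Defaults reflect a
#' flock of 821 animals across 7 herds; the marker panels are scaled-down
#' stand-ins for commercial HD/50K arrays keeping their ~13:1 density ratio.
#'
#' @param n_individuals number of animals (default 821).
#' @param n_markers_high markers on the high-density panel (default 13000).
#' @param n_markers_low markers on the nested low-density panel
#'   (default 1000); every k-th high-panel marker is flagged,
#'   k = round(high/low).
#' @param freq_beta_a,freq_beta_b shape parameters of the Beta distribution
#'   allele frequencies are drawn from, truncated to [0.01, 0.99]
#'   (default 1, 1: array-like flat spectrum).
#' @param ld_rho correlation in [0, 1) between adjacent-marker alleles on a
#'   haplotype (first-order Markov LD; default 0.3).
#' @param missing_rate proportion of dosage cells set missing, in
#'   [0, 0.05] (default 0.01).
#' @param architecture marker-effect distribution: one of "normal", "t",
#'   "point_t", "point_normal", "laplace" — each matching one prior family.
#' @param prop_qtl proportion of markers with nonzero effect in point-mass
#'   architectures (default 0.01).
#' @param h2_target narrow-sense heritability the phenotype is calibrated
#'   to, in (0, 1) (default 0.5, the middle of typical wool-trait values).
#' @param n_herds number of herds, assigned balanced (default 7).
#' @param herd_sd SD of herd effects, in phenotypic-SD units (default 0.3).
#' @param sex_effect additive male-vs-female shift, in phenotypic-SD units
#'   (default 0.2).
#' @param df_t degrees of freedom for t-family architectures (default 5).
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(n_individuals = 821L, n_markers_high = 13000L,
                      n_markers_low = 1000L, freq_beta_a = 1, freq_beta_b = 1,
                      ld_rho = 0.3, missing_rate = 0.01,
                      architecture = c("normal", "t", "point_t",
                                       "point_normal", "laplace"),
                      prop_qtl = 0.01, h2_target = 0.5, n_herds = 7L,
                      herd_sd = 0.3, sex_effect = 0.2, df_t = 5,
                      seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(n_individuals >= 2, n_markers_high >= 1,
            n_markers_low <= n_markers_high, n_markers_low >= 1,
            freq_beta_a > 0, freq_beta_b > 0,
            ld_rho >= 0, ld_rho < 1,
            missing_rate >= 0, missing_rate <= 0.05,
            prop_qtl > 0, prop_qtl <= 1,
            h2_target > 0, h2_target < 1,
            n_herds >= 1, herd_sd >= 0, df_t > 2)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_markers_high = as.integer(n_markers_high),
    n_markers_low = as.integer(n_markers_low),
    freq_beta_a = freq_beta_a, freq_beta_b = freq_beta_b,
    ld_rho = ld_rho, missing_rate = missing_rate,
    architecture = architecture, prop_qtl = prop_qtl,
    h2_target = h2_target, n_herds = as.integer(n_herds),
    herd_sd = herd_sd, sex_effect = sex_effect, df_t = df_t,
    seed = as.integer(seed)), class = "SimConfig")
}

#' Simulate biallelic genotype dosages
#'
#' Draws per-marker allele frequencies from a truncated Beta distribution,
#' builds two haplotypes per individual by a first-order Markov chain with
#' adjacent-allele correlation \code{ld_rho}, sums them to 0/1/2 dosages,
#' and sprinkles missing calls uniformly at \code{missing_rate}. Markers
#' are spread over sheep autosomes 1--26 with a nested low-density panel
#' flag on every k-th marker.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \linkS4class{GenotypeData}; dosages contain \code{NA} where
#'   calls are missing.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_markers_high
  p <- rbeta(m, config$freq_beta_a, config$freq_beta_b)
  p <- pmin(pmax(p, 0.01), 0.99)
  rho <- config$ld_rho
  # two haplotypes per individual, Markov across markers:
  # P(a_j = 1 | a_{j-1}) = p_j + rho * sqrt(pq_j / pq_{j-1}) * (a_{j-1} - p_{j-1})
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  H[, 1L] <- rbinom(2L * n, 1L, p[1L])
  if (m > 1L) {
    q <- sqrt(p * (1 - p))
    for (j in 2L:m) {
      cond <- p[j] + rho * (q[j] / q[j - 1L]) * (H[, j - 1L] - p[j - 1L])
      cond <- pmin(pmax(cond, 0), 1)
      H[, j] <- rbinom(2L * n, 1L, cond)
    }
  }
  dos <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  storage.mode(dos) <- "double"
  if (config$missing_rate > 0) {
    miss <- runif(length(dos)) < config$missing_rate
    dos[miss] <- NA_real_
  }
  rownames(dos) <- sprintf("ind_%04d", seq_len(n))
  colnames(dos) <- sprintf("snp_%06d", seq_len(m))
  chrom <- as.character(rep_len(rep(1:26, each = ceiling(m / 26)), m))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- seq_len(length(idx)) * 1000L
  }
  # nested low panel: evenly spaced (every k-th) markers of the high panel
  idx <- unique(round(seq(1L, m, length.out = config$n_markers_low)))
  if (length(idx) < config$n_markers_low)
    idx <- c(idx, setdiff(seq_len(m), idx)[
      seq_len(config$n_markers_low - length(idx))])
  low <- logical(m)
  low[idx] <- TRUE
  markers <- data.frame(id = colnames(dos), chrom = chrom, pos = pos,
                        allele1 = "A", allele2 = "G", low_panel = low,
                        stringsAsFactors = FALSE)
  GenotypeData(dos, markers)
}

#' Simulate additive marker effects under a prior-family architecture
#'
#' Effect distributions mirror the model priors: "normal" (GBLUP/ridge),
#' "t" (BayesA), "point_t" (BayesB/BayesCpi: exact zeros with probability
#' 1 - prop_qtl, t-distributed otherwise), "point_normal", and "laplace"
#' (Bayesian LASSO, double-exponential).
#'
#' @param n_markers number of markers.
#' @param architecture one of "normal", "t", "point_t", "point_normal",
#'   "laplace".
#' @param prop_qtl proportion of nonzero effects for point-mass families;
#'   exactly \code{round(prop_qtl * n_markers)} markers get nonzero effects.
#' @param df_t degrees of freedom for t families (default 5).
#' @param seed integer seed.
#' @return numeric vector of per-marker effects.
#' @export
simulateEffects <- function(n_markers, architecture, prop_qtl = 0.01,
                            df_t = 5, seed = 1L) {
  stopifnot(n_markers >= 1)
  set.seed(seed)
  rlaplace <- function(k) rexp(k) - rexp(k)  # difference of exponentials
  draw <- switch(architecture,
    normal = rnorm(n_markers),
    t = rt(n_markers, df = df_t),
    laplace = rlaplace(n_markers),
    point_t = , point_normal = {
      nqtl <- round(prop_qtl * n_markers)
      eff <- numeric(n_markers)
      qtl <- sample.int(n_markers, nqtl)
      eff[qtl] <- if (architecture == "point_t") rt(nqtl, df = df_t)
                  else rnorm(nqtl)
      eff
    },
    stop("unknown architecture: ", architecture))
  draw
}

#' Simulate phenotypes from genotypes and marker effects
#'
#' Builds y = mu + herd + sex + BV + e. Breeding values are the centered
#' dosage matrix times the effects (missing dosages treated as the marker
#' mean). The residual variance is calibrated to the REALIZED variance of
#' the breeding values so that Var(BV)/(Var(BV)+sigma2_e) equals
#' \code{h2_target} exactly for the generated dataset. Herd assignment is
#' balanced; sex is Bernoulli(0.5). Herd and sex effect sizes are expressed
#' in phenotypic-SD units, sigma_P = sqrt(Var(BV)/h2_target).
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param effects per-marker effect vector (length = number of markers).
#' @param config a \code{\link{simConfig}} (uses h2_target, n_herds,
#'   herd_sd, sex_effect, seed).
#' @return list with \code{phenotypes} (data.frame: id, herd, sex, trait1)
#'   and \code{truth} (list: true_effects, true_bv, realized_h2, varE).
#' @export
simulatePhenotypes <- function(genotypes, effects, config) {
  stopifnot(inherits(config, "SimConfig"))
  Z <- dosages(genotypes)
  if (ncol(Z) != length(effects))
    stop("dimension mismatch: ", ncol(Z), " markers vs ",
         length(effects), " effects")
  cm <- colMeans(Z, na.rm = TRUE)
  for (j in which(colSums(is.na(Z)) > 0L)) Z[is.na(Z[, j]), j] <- cm[j]
  W <- sweep(Z, 2L, cm)
  bv <- drop(W %*% effects)
  n <- nrow(Z)
  varBV <- if (n > 1) var(bv) else 0
  if (varBV > 0) {
    varE <- varBV * (1 - config$h2_target) / config$h2_target
    h2 <- varBV / (varBV + varE)
  } else {
    varE <- 1
    h2 <- 0
  }
  sigmaP <- sqrt(if (varBV > 0) varBV / config$h2_target else 1)
  set.seed(config$seed + 1L)
  herd <- rep_len(seq_len(config$n_herds), n)[sample.int(n)]
  herd_eff <- rnorm(config$n_herds, 0, config$herd_sd * sigmaP)
  sex <- ifelse(rbinom(n, 1L, 0.5) == 1L, "M", "F")
  e <- rnorm(n, 0, sqrt(varE))
  y <- herd_eff[herd] + ifelse(sex == "M", config$sex_effect * sigmaP, 0) +
    bv + e
  phen <- data.frame(id = individualIds(genotypes),
                     herd = paste0("herd", herd), sex = sex, trait1 = y,
                     stringsAsFactors = FALSE)
  list(phenotypes = phen,
       truth = list(true_effects = effects, true_bv = bv,
                    realized_h2 = h2, varE = varE))
}

#' Generate and write a complete synthetic dataset
#'
#' Simulates genotypes, effects and phenotypes from one \code{SimConfig}
#' and writes the high-density panel as PED/MAP, the low-panel marker list
#' (one ID per line), the phenotype TSV (id, herd, sex, trait1) and the
#' ground-truth TSV (id, true_bv). Files round-trip through the package
#' readers.
#'
#' @param config a \code{\link{simConfig}}.
#' @param out_dir writable output directory (created if absent).
#' @return invisibly, a list: \code{paths} (the written files),
#'   \code{genotypes} (\linkS4class{GenotypeData}), \code{phenotypes},
#'   \code{truth}.
#' @export
makeDataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- simulateGenotypes(config)
  eff <- simulateEffects(config$n_markers_high, config$architecture,
                         config$prop_qtl, config$df_t,
                         seed = config$seed + 2L)
  sim <- simulatePhenotypes(gm, eff, config)
  paths <- list(ped = file.path(out_dir, "geno.ped"),
                map = file.path(out_dir, "geno.map"),
                low_panel = file.path(out_dir, "low_panel.txt"),
                phenotypes = file.path(out_dir, "phenotypes.tsv"),
                truth = file.path(out_dir, "truth.tsv"))
  writePlinkText(gm, paths$ped, paths$map)
  writeLines(markerInfo(gm)$id[markerInfo(gm)$low_panel], paths$low_panel)
  write.table(sim$phenotypes, paths$phenotypes, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = individualIds(gm),
                         true_bv = sim$truth$true_bv),
              paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, genotypes = gm,
                 phenotypes = sim$phenotypes, truth = sim$truth))
}
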