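#' Pipeline run configuration
#'
#' Bundles every stage's settings: input paths (or a \code{SimConfig} for
#' a fully simulated run), QC thresholds, per-model priors, MCMC and CV
#' settings, and a master seed. The resolved configuration is echoed
#' verbatim as JSON into the output directory so a rerun from the echo is
#' bit-reproducible.
#'
#' @param out_dir output directory.
#' @param sim a \code{\link{simConfig}} for a simulated run, or NULL.
#' @param ped,map,phenotypes,low_panel input file paths (ignored when
#'   \code{sim} is given).
#' @param trait trait column to analyze (default: first trait).
#' @param qc a \code{\link{qcThresholds}}.
#' @param models prior families to fit and cross-validate.
#' @param mcmc a \code{\link{mcmcSettings}}.
#' @param k,n_replicates CV folds and replicates.
#' @param density "high", "low" or "both": which marker panel(s) to run.
#' @param seed master seed; stage seeds derive from it.
#' @param overwrite rerun stages whose artifacts already exist.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(out_dir, sim = NULL, ped = NULL, map = NULL,
                      phenotypes = NULL, low_panel = NULL, trait = NULL,
                      qc = qcThresholds(),
                      models = c("bayesA", "bayesB", "bayesCpi", "blasso",
                                 "gblup"),
                      mcmc = mcmcSettings(), k = 5L, n_replicates = 3L,
                      density = c("low", "high", "both"), seed = 1L,
                      overwrite = FALSE) {
  density <- match.arg(density)
  if (is.null(sim) && (is.null(ped) || is.null(map) ||
                       is.null(phenotypes)))
    stop("either a SimConfig or ped/map/phenotype paths are required")
  structure(list(out_dir = out_dir, sim = sim, ped = ped, map = map,
                 phenotypes = phenotypes, low_panel = low_panel,
                 trait = trait, qc = qc, models = models, mcmc = mcmc,
                 k = as.integer(k), n_replicates = as.integer(n_replicates),
                 density = density, seed = as.integer(seed),
                 overwrite = isTRUE(overwrite)), class = "RunConfig")
}

#' Run the genomic-prediction pipeline
#'
#' Stages, in order: load or simulate genotypes/phenotypes; marker QC and
#' imputation (qc_report.tsv); GRM construction (grm.tsv); full-data model
#' fits with posterior summaries and heritability (fits/<density>_<model>
#' _summary.tsv, heritability.tsv); k-fold cross-validation (cv_long.tsv,
#' cv_summary.tsv). Every table carries the master seed and a config hash;
#' config.json echoes the resolved configuration. Stages whose artifacts
#' exist are skipped unless \code{overwrite}.
#'
#' @param config a \code{\link{runConfig}}.
#' @param verbose log stage progress to stderr (default TRUE).
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(...) if (verbose) message("[wgrBayes] ", ...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_(sprintf("%s done in %.1fs", name,
                 as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  cfg_path <- file.path(out, "config.json")
  cfg_echo <- config
  cfg_echo$qc <- unclass(cfg_echo$qc)
  cfg_echo$mcmc <- unclass(cfg_echo$mcmc)
  if (!is.null(cfg_echo$sim)) cfg_echo$sim <- unclass(cfg_echo$sim)
  jsonlite::write_json(unclass(cfg_echo), cfg_path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  # hash the analysis-relevant settings only, so reruns into a different
  # directory stamp the same fingerprint
  hash_tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg_echo)[setdiff(names(cfg_echo),
                                                 c("out_dir", "overwrite"))],
                       hash_tmp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  cfg_hash <- unname(tools::md5sum(hash_tmp))
  unlink(hash_tmp)
  stamp <- function(tab) {
    tab$master_seed <- config$seed
    tab$config_hash <- cfg_hash
    tab
  }

  # --- stage: data
  dat <- stage("data", {
    if (!is.null(config$sim)) {
      makeDataset(config$sim, file.path(out, "data"))
    } else {
      gm <- readPlinkText(config$ped, config$map)
      if (!is.null(config$low_panel)) {
        lp <- readLines(config$low_panel)
        mk <- markerInfo(gm)
        mk$low_panel <- mk$id %in% lp
        gm <- GenotypeData(dosages(gm), mk)
      }
      list(genotypes = gm, phenotypes = readPhenotypes(config$phenotypes))
    }
  })
  gm <- dat$genotypes
  phen <- dat$phenotypes
  phen <- phen[match(individualIds(gm), phen$id), , drop = FALSE]
  if (anyNA(phen$id)) stop("phenotypes missing for some genotyped IDs")
  trait <- if (is.null(config$trait))
    setdiff(names(phen), c("id", "herd", "sex"))[1L] else config$trait

  # --- stage: qc + imputation
  qc_path <- file.path(out, "qc_report.tsv")
  qcres <- stage("qc", applyQC(gm, config$qc))
  imp <- stage("impute", imputeSporadic(qcres$genotypes, seed = config$seed))
  rp <- qcres$report
  write.table(stamp(data.frame(
    n_markers_in = rp@nMarkersIn,
    removed_non_autosomal = rp@removedNonAutosomal,
    removed_call_rate = rp@removedCallRate,
    removed_maf = rp@removedMaf, removed_hwe = rp@removedHwe,
    n_markers_out = rp@nMarkersOut, n_imputed_cells = imp$n_imputed)),
    qc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  clean <- imp$genotypes

  panels <- switch(config$density, low = "low", high = "high",
                   both = c("low", "high"))
  sel <- function(panel) {
    if (panel == "high") clean
    else clean[, which(markerInfo(clean)$low_panel)]
  }

  herit_rows <- list()
  cv_rows <- list()
  for (panel in panels) {
    gp <- sel(panel)
    # --- stage: grm
    grm_path <- file.path(out, paste0("grm_", panel, ".tsv"))
    grm <- stage(paste0("grm_", panel), {
      g <- vanRadenGRM(gp)
      if (config$overwrite || !file.exists(grm_path)) writeGRM(g, grm_path)
      g
    })
    # --- stage: fits
    fit_dir <- file.path(out, "fits")
    dir.create(fit_dir, showWarnings = FALSE)
    y <- phen[[trait]]
    design <- buildDesign(phen)
    for (mod in config$models) {
      fit <- stage(paste("fit", panel, mod), {
        mc <- mcmcSettings(config$mcmc$n_iter, config$mcmc$burn_in,
                           config$mcmc$thin, seed = config$seed)
        if (mod == "gblup")
          wgrFit(y, design, grm = grm, prior = priorSpec(mod), mcmc = mc)
        else
          wgrFit(y, design, genotypes = gp, prior = priorSpec(mod),
                 mcmc = mc)
      })
      s <- fit@scalarDraws
      summ <- data.frame(parameter = colnames(s),
                         mean = colMeans(s),
                         sd = apply(s, 2L, sd))
      write.table(stamp(summ),
                  file.path(fit_dir,
                            paste0(panel, "_", mod, "_summary.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      h <- heritability(fit)
      herit_rows[[length(herit_rows) + 1L]] <- data.frame(
        density = panel, model = mod, trait = trait,
        h2 = h[["estimate"]], h2_sd = h[["sd"]])
    }
    # --- stage: cv
    cvres <- stage(paste("cv", panel), crossValidate(
      gp, phen, trait = trait, models = config$models, k = config$k,
      n_replicates = config$n_replicates, seed = config$seed,
      mcmc = config$mcmc, grm = grm))
    fl <- cvFolds(cvres)
    fl$density <- panel
    cv_rows[[length(cv_rows) + 1L]] <- fl
  }
  write.table(stamp(do.call(rbind, herit_rows)),
              file.path(out, "heritability.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cv_long <- do.call(rbind, cv_rows)
  write.table(stamp(cv_long), file.path(out, "cv_long.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sp <- split(cv_long$accuracy,
              list(model = cv_long$model, density = cv_long$density),
              drop = TRUE)
  keys <- strsplit(names(sp), "\\.")
  cv_sum <- data.frame(model = vapply(keys, `[`, "", 1L),
                       density = vapply(keys, `[`, "", 2L),
                       trait = trait,
                       mean = vapply(sp, mean, 0),
                       se = vapply(sp, function(a)
                         sd(a) / sqrt(length(a)), 0), row.names = NULL)
  write.table(stamp(cv_sum), file.path(out, "cv_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_("pipeline complete: ", out)
  invisible(out)
}
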