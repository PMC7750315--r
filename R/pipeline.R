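#' Build and validate a pipeline configuration
#'
#' Configuration for the end-to-end analysis, either from a named list or a
#' JSON file. Defaults run the bundled synthetic two-clade scenario; to
#' analyse real data supply `spectra` (long CSV), `tree` (Newick) and
#' `metadata` (CSV with species, mode, zone) paths. All file paths are
#' validated before any stage runs, and every output records the seed.
#'
#' @param config named list or path to a JSON config file.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(
    simulate = TRUE, n_species = 11, spectra = NULL, tree = NULL,
    metadata = NULL, span = 0.25, n_bins = 10, trim = c(300, 700),
    illuminant_hawkmoth = "sunset", illuminant_fly = "D65",
    weber = 0.1, n_boot = 1000, n_perm = 1000,
    mcmc_generations = 10000, mcmc_burn_in = 2000, mcmc_thin = 10,
    n_maps = 100, seed = 1)
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null,
                                                    logical(1))])
  if (!cfg$simulate) {
    for (f in c("spectra", "tree", "metadata")) {
      if (is.null(cfg[[f]]))
        stop("config error: '", f, "' path required when simulate = FALSE")
      if (!file.exists(cfg[[f]]))
        stop("config error: ", f, " file not found: ", cfg[[f]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

write_stage <- function(df, out_dir, name, seed) {
  path <- file.path(out_dir, name)
  con <- file(path, "w")
  writeLines(sprintf("# pollicolor stage output; seed = %d", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  name
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: ingest -> preprocess (trim, smooth, average
#' by individual) -> binned PCA + phylomorphospace -> visual models (hawkmoth
#' Maxwell triangle + RNL contrasts; blowfly and hoverfly categorical loci) ->
#' colour statistics (bootstrap + permutation by pollination mode) ->
#' continuous-trait fits of PC1 -> discrete-mode fits, ancestral states and
#' stochastic maps -> threshold MCMC on zones -> colour vectors + PGLS. One
#' tidy CSV per stage plus a JSON manifest (config, seed, output hashes) is
#' written to `out_dir`. A stage failure aborts with the stage name and leaves
#' a FAILED marker; outputs are pure functions of (inputs, config, seed).
#'
#' @param config a [pipeline_config()] (or list / JSON path coerced to one).
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste("FAILED at stage", name, ":", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    outputs <<- c(outputs, res)
    res
  }

  # -- ingest ----------------------------------------------------------------
  env <- new.env()
  stage("ingest", function() {
    if (cfg$simulate) {
      scn <- simulate_scenario(cfg$n_species, seed = cfg$seed)
      env$spectra <- scn$spectra
      env$leaves <- scn$leaves
      env$tree <- scn$tree
      env$meta <- scn$metadata
      write_newick(env$tree, file.path(out_dir, "tree.nwk"))
    } else {
      coll <- read_spectra(cfg$spectra, layout = "long")
      tis <- vapply(coll$spectra, function(s) s$tissue, character(1))
      env$spectra <- spectrum_collection(unname(coll$spectra[tis ==
                                                               "corolla"]))
      env$leaves <- spectrum_collection(unname(coll$spectra[tis == "leaf"]))
      env$tree <- read_newick(cfg$tree)
      env$meta <- utils::read.csv(cfg$metadata)
      file.copy(cfg$tree, file.path(out_dir, "tree.nwk"), overwrite = TRUE)
    }
    write_stage(as.data.frame(env$spectra), out_dir, "01_spectra_raw.csv",
                cfg$seed)
  })

  stage("preprocess", function() {
    proc <- trim_spectrum(env$spectra, cfg$trim[1], cfg$trim[2])
    proc <- smooth_spectrum(proc, span = cfg$span)
    env$proc <- aggregate_spectra(proc, "individual")
    leaves <- smooth_spectrum(trim_spectrum(env$leaves, cfg$trim[1],
                                            cfg$trim[2]), span = cfg$span)
    grid <- leaves$grid
    env$leaf_mean <- reflectance_spectrum(
      grid, rowMeans(vapply(leaves$spectra, function(s) s$reflectance,
                            numeric(length(grid)))),
      species = "background", individual = "mean", tissue = "leaf")
    write_stage(as.data.frame(env$proc), out_dir, "02_spectra_processed.csv",
                cfg$seed)
  })

  stage("pca", function() {
    bm <- binned_matrix(env$proc, cfg$n_bins)
    env$pca <- standardized_pca(bm)
    env$spp_scores <- species_scores(env$pca)
    env$pms <- phylomorphospace(env$tree, env$spp_scores)
    df <- data.frame(sample = rownames(env$pca$scores),
                     species = env$pca$species,
                     PC1 = env$pca$scores[, 1], PC2 = env$pca$scores[, 2],
                     var1 = env$pca$var_explained[1],
                     var2 = env$pca$var_explained[2])
    write_stage(df, out_dir, "03_pca_scores.csv", cfg$seed)
  })

  stage("phylomorphospace", function() {
    co <- rbind(env$pms$tip_coords, env$pms$node_coords)
    write_stage(data.frame(label = rownames(co), PC1 = co[, 1],
                           PC2 = co[, 2]),
                out_dir, "04_phylomorphospace.csv", cfg$seed)
  })

  stage("vismodel", function() {
    grid <- env$proc$grid
    illum_h <- load_illuminant(cfg$illuminant_hawkmoth, grid)
    illum_f <- load_illuminant(cfg$illuminant_fly, grid)
    env$recs_h <- default_receptor_set("hawkmoth", grid)
    env$tab_h <- locus_table(env$proc, env$recs_h, illum_h, env$leaf_mean)
    env$tab_bf <- locus_table(env$proc, default_receptor_set("blowfly", grid),
                              illum_f, env$leaf_mean)
    tab_hf <- locus_table(env$proc, default_receptor_set("hoverfly", grid),
                          illum_f, env$leaf_mean)
    write_stage(rbind(cbind(viewer2 = "blowfly", env$tab_bf),
                      cbind(viewer2 = "hoverfly", tab_hf)),
                out_dir, "05b_loci_fly.csv", cfg$seed)
    write_stage(env$tab_h, out_dir, "05_loci_hawkmoth.csv", cfg$seed)
  })

  stage("colstats", function() {
    env$noise <- noise_model(env$recs_h, weber = cfg$weber)
    mode_of <- stats::setNames(env$meta$mode, env$meta$species)
    loci_h <- attr(env$tab_h, "loci")
    groups_h <- unname(mode_of[vapply(loci_h, function(l) l$species,
                                      character(1))])
    rnl <- color_discrimination(loci_h, groups_h, "rnl", env$noise,
                                n_boot = cfg$n_boot, n_perm = cfg$n_perm,
                                seed = cfg$seed)
    loci_f <- attr(env$tab_bf, "loci")
    groups_f <- unname(mode_of[vapply(loci_f, function(l) l$species,
                                      character(1))])
    fly <- color_discrimination(loci_f, groups_f, "fly_euclid",
                                n_boot = cfg$n_boot, n_perm = cfg$n_perm,
                                seed = cfg$seed)
    write_stage(rbind(rnl, fly), out_dir, "06_color_stats.csv", cfg$seed)
  })

  stage("continuous_fits", function() {
    pc1 <- env$spp_scores[, 1]
    cmp <- compare_continuous(env$tree, pc1[env$tree$tip.label])
    env$fit_bm <- attr(cmp, "fits")[[1]]
    write_stage(cmp, out_dir, "07_continuous_fits.csv", cfg$seed)
  })

  stage("ancestral", function() {
    modes <- stats::setNames(env$meta$mode, env$meta$species)
    cmp <- compare_mk(env$tree, modes)
    fit <- attr(cmp, "fits")[[attr(cmp, "chosen")]]
    env$simmap <- stochastic_map(env$tree, modes, fit, n_maps = cfg$n_maps,
                                 seed = cfg$seed)
    anc <- anc_ml(env$tree, env$spp_scores[env$tree$tip.label, 1])
    post <- env$simmap$node_posterior
    write_stage(data.frame(node = rownames(post), anc_pc1 = anc,
                           post, check.names = FALSE),
                out_dir, "08_ancestral.csv", cfg$seed)
  })

  stage("threshold", function() {
    zones <- stats::setNames(env$meta$zone, env$meta$species)
    env$thr <- threshold_mcmc(env$tree, zones,
                              generations = cfg$mcmc_generations,
                              burn_in = cfg$mcmc_burn_in,
                              thin = cfg$mcmc_thin, seed = cfg$seed)
    write_stage(data.frame(label = names(env$thr$liability_mean),
                           liability = env$thr$liability_mean),
                out_dir, "09_threshold.csv", cfg$seed)
  })

  stage("pgls", function() {
    loci_h <- attr(env$tab_h, "loci")
    sp <- vapply(loci_h, function(l) l$species, character(1))
    agg_h <- lapply(split(seq_along(sp), sp), function(i) {
      l <- loci_h[[i[1]]]
      l$q <- rowMeans(vapply(loci_h[i], function(x) x$q, numeric(3)))
      l$r <- l$q / sum(l$q)
      l
    })
    cv_h <- color_vector(agg_h, "hawkmoth")
    liab <- env$thr$liability_mean[env$tree$tip.label]
    fits <- lapply(c("BM", "OU"), function(m)
      pgls_corr(env$tree, liab, cv_h[env$tree$tip.label], m))
    df <- data.frame(model = c("BM", "OU"),
                     r = vapply(fits, function(f) f$r, numeric(1)),
                     slope = vapply(fits, function(f) f$slope, numeric(1)),
                     logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                     AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                     p = vapply(fits, function(f) f$p_value, numeric(1)))
    write_stage(df, out_dir, "10_pgls.csv", cfg$seed)
  })

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE)
  manifest <- list(
    package = "pollicolor",
    version = as.character(utils::packageVersion("pollicolor")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = outputs,
    output_md5 = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
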