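#' Configuration for an end-to-end run
#'
#' Bundles the cohort specification with preprocessing, feature, model
#' and explanation parameters. A run is reproducible from its persisted
#' configuration: every stochastic stage derives its seed from `seed`.
#'
#' @param out_dir output directory for all artifacts.
#' @param n_subjects cohort size (default 206, the study population).
#' @param grid `"small"` or `"mni3mm"` (see [cohort_spec()]).
#' @param seed master seed.
#' @param bin_width radiomics discretization width.
#' @param use_truth_masks use the generator's painted masks (default);
#'   otherwise run [segment_threshold()].
#' @param with_cae train the autoencoder feature set (mini scale).
#' @param cae_epochs,cae_train_max autoencoder training epochs and the
#'   maximum number of training volumes used.
#' @param folds cross-validation folds for the SVM grid search.
#' @param shap_subjects number of test subjects explained by Kernel
#'   SHAP.
#' @param shap_samples coalitions per explanation.
#' @param test_fraction,val_fraction cohort split fractions.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir, n_subjects = 206, grid = "small", seed = 1,
                       bin_width = 0.25, use_truth_masks = TRUE,
                       with_cae = TRUE, cae_epochs = 20, cae_train_max = 40,
                       folds = 5, shap_subjects = 8, shap_samples = 512,
                       test_fraction = 0.2, val_fraction = 0) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param path YAML or JSON file with `run_config` fields.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full feature-set comparison end-to-end
#'
#' Generate, normalize, (re-)segment, extract the FIV / radiomics /
#' latent feature sets, grid-search one SVM per feature set, evaluate on
#' the held-out test set, compare AUCs pairwise against the best by
#' DeLong's test, and rank the radiomics features by Kernel SHAP. All
#' intermediates are written under `cfg$out_dir` together with a
#' manifest; any stage failure aborts with the stage name.
#'
#' @param cfg a [run_config()].
#' @param verbose log stage timings to stderr.
#' @return A `model_report` list: `metrics` (one row per feature set),
#'   `delong`, `shap`, `paths`.
#' @export
run_all <- function(cfg, verbose = TRUE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_name <- "init"
  log_stage <- function(name) {
    stage_name <<- name
    if (verbose)
      message(sprintf("[%6.1fs] stage: %s",
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      name))
  }
  tryCatch({
    log_stage("generate")
    spec <- cohort_spec(n_subjects = cfg$n_subjects, grid = cfg$grid,
                        seed = cfg$seed, test_fraction = cfg$test_fraction,
                        val_fraction = cfg$val_fraction)
    cohort <- generate_cohort(spec)
    tab <- cohort$table
    write.csv(tab, file.path(cfg$out_dir, "cohort.csv"), row.names = FALSE)

    log_stage("preprocess")
    norm <- lapply(cohort$subjects, function(s) white_stripe_normalize(s$volume))
    names(norm) <- tab$id

    log_stage("masks")
    masks <- if (cfg$use_truth_masks) lapply(cohort$subjects, `[[`, "mask")
             else lapply(norm, segment_threshold)
    names(masks) <- tab$id

    log_stage("features")
    fiv <- data.frame(id = tab$id,
                      fiv_ml = vapply(masks, mask_volume_ml, 0))
    rad <- extract_feature_table(norm, masks, cfg$bin_width)
    write.csv(fiv, file.path(cfg$out_dir, "features_fiv.csv"), row.names = FALSE)
    write.csv(rad, file.path(cfg$out_dir, "features_radiomics.csv"),
              row.names = FALSE)

    feature_sets <- list(fiv = fiv, radiomics = rad)

    if (cfg$with_cae) {
      log_stage("cae")
      ccfg <- cae_config("mini", epochs = cfg$cae_epochs,
                         seed = derive_seed(cfg$seed, 31))
      padded <- lapply(norm, function(v) cae_prepare(v, ccfg$input_shape))
      # when compute limits training to a subset, take the subjects with
      # the largest (observed) lesions: lesion reconstruction is the
      # signal the latent code must carry, and large lesions provide the
      # most voxels of it per gradient step
      train_ids <- tab$id[tab$split == "train"]
      vol_ml <- vapply(masks[train_ids], mask_volume_ml, 0)
      use <- train_ids[order(-vol_ml)][seq_len(min(cfg$cae_train_max,
                                                   length(train_ids)))]
      model <- build_cae(ccfg)
      model <- train_cae(model, padded[use], verbose = FALSE)
      lat <- t(vapply(padded, function(v) encode(model, v),
                      numeric(ccfg$latent_dim)))
      cae_tab <- cbind(data.frame(id = tab$id), as.data.frame(lat))
      write.csv(cae_tab, file.path(cfg$out_dir, "features_cae.csv"),
                row.names = FALSE)
      feature_sets$cae <- cae_tab
      saveRDS(list(model = model, history = model$history),
              file.path(cfg$out_dir, "cae_model.rds"))
    }

    log_stage("classify")
    is_test <- tab$split == "test"
    models <- list(); metrics <- list(); scores <- list()
    for (fs in names(feature_sets)) {
      ft <- feature_sets[[fs]]
      xm <- as.matrix(ft[, setdiff(names(ft), "id"), drop = FALSE])
      sc <- robust_scale_fit_transform(xm[!is_test, , drop = FALSE],
                                       xm[is_test, , drop = FALSE])
      mod <- grid_search_svm(sc$train, tab$outcome[!is_test],
                             folds = cfg$folds,
                             seed = derive_seed(cfg$seed, 41))
      ev <- evaluate_svm(mod, sc$train, tab$outcome[!is_test],
                         sc$other, tab$outcome[is_test])
      models[[fs]] <- list(model = mod, scaler = sc$params)
      metrics[[fs]] <- ev
      scores[[fs]] <- ev$scores
    }

    log_stage("delong")
    aucs <- vapply(metrics, `[[`, 0, "auc")
    ref <- names(which.max(aucs))
    others <- setdiff(names(metrics), ref)
    delong <- lapply(others, function(fs)
      delong_test(scores[[ref]], scores[[fs]], tab$outcome[is_test]))
    names(delong) <- others

    log_stage("shap")
    rad_x <- as.matrix(rad[, -1])
    sc <- robust_scale_fit_transform(rad_x[!is_test, , drop = FALSE],
                                     rad_x[is_test, , drop = FALSE])
    bg <- medoid_background(sc$train, 25, seed = derive_seed(cfg$seed, 51))
    fit <- models$radiomics$model$fit
    model_fn <- function(m) svm_scores(fit, m)
    expl_idx <- with_seed(derive_seed(cfg$seed, 52),
                          sample(seq_len(sum(is_test)),
                                 min(cfg$shap_subjects, sum(is_test))))
    shaps <- lapply(expl_idx, function(i)
      kernel_shap(model_fn, sc$other[i, ], bg,
                  n_samples = cfg$shap_samples,
                  seed = derive_seed(cfg$seed, 100 + i)))
    shap_rank <- importance_report(shaps, colnames(rad_x), k = 15)
    write.csv(shap_rank, file.path(cfg$out_dir, "shap_ranking.csv"),
              row.names = FALSE)

    log_stage("report")
    table1 <- do.call(rbind, lapply(names(metrics), function(fs) {
      m <- metrics[[fs]]
      data.frame(feature_set = fs, train_accuracy = m$train_accuracy,
                 test_accuracy = m$test_accuracy, auc = m$auc,
                 precision = m$precision, recall = m$recall,
                 kernel = m$kernel, C = m$C, gamma = m$gamma,
                 delong_p_vs_best = if (fs %in% names(delong))
                   delong[[fs]]$p_two_sided else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    write.csv(table1, file.path(cfg$out_dir, "table1.csv"), row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("strokefeat")),
      config = cfg[setdiff(names(cfg), "out_dir")],
      checksums = as.list(tools::md5sum(list.files(cfg$out_dir,
                                                   pattern = "[.]csv$",
                                                   full.names = TRUE))))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    report <- list(metrics = table1, delong = delong, shap = shap_rank,
                   models = models, paths = cfg$out_dir)
    jsonlite::write_json(
      list(metrics = table1,
           delong = lapply(delong, function(d) d[c("auc_a", "auc_b", "z",
                                                   "p_two_sided")]),
           shap_top = shap_rank),
      file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    class(report) <- "model_report"
    report
  }, error = function(e) {
    stop(sprintf("pipeline failed in stage '%s': %s", stage_name,
                 conditionMessage(e)), call. = FALSE)
  })
}
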