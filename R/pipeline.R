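# Orchestration: run the simulate -> featurize -> associate -> train ->
# validate -> importance -> impact workflow from a single configuration,
# writing plain-text artefacts and a provenance manifest.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param stages Stages to run, in dependency order.
#' @param n_train,n_test Cohort sizes (defaults 200 / 75).
#' @param n_iter Random-search iterations per seed.
#' @param seeds Cross-validation seeds of the ensemble.
#' @param models "all" (the nested six) or "integrated" (clinical-only plus
#'   fully integrated).
#' @return Configuration list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            stages = c("simulate", "featurize", "associate",
                                       "train", "validate", "impact",
                                       "report"),
                            n_train = 200, n_test = 75, n_iter = 100,
                            seeds = 1:5, models = c("all", "integrated")) {
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 n_train = n_train, n_test = n_test, n_iter = n_iter,
                 seeds = seeds, models = match.arg(models)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the end-to-end workflow
#'
#' Executes the requested stages in dependency order. Later stages reload
#' the plain-text artefacts of earlier ones from `out_dir`, so any stage can
#' be re-run in isolation. Every run writes a provenance manifest
#' (seed, package version, artefact checksums).
#'
#' @param config A `run_config` (see [pipeline_config()]).
#' @return Invisibly, the artefact directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  stages <- config$stages
  need <- function(f, stage) {
    if (!file.exists(f)) {
      stop("stage '", stage, "': missing upstream artefact ", f)
    }
    f
  }

  if ("simulate" %in% stages) {
    tr <- simulate_cohort(simulation_config(n_patients = config$n_train,
                                            seed = config$seed))
    te <- simulate_cohort(simulation_config(n_patients = config$n_test,
                                            seed = substream_seed(
                                              config$seed, 777)))
    write_cohort(tr, file.path(od, "cohort_train"))
    write_cohort(te, file.path(od, "cohort_test"))
  }

  if ("featurize" %in% stages) {
    for (split in c("train", "test")) {
      cdir <- need(file.path(od, paste0("cohort_", split)), "featurize")
      co <- read_cohort(cdir)
      fm <- suppressWarnings(build_feature_matrix(co))
      fm <- clean_training_data(fm, co$clinical,
                                mode = if (split == "train") "training"
                                       else "validation")
      write_tsv(data.frame(patient = rownames(fm$X), fm$X,
                           pcr = fm$pcr, rcb = fm$rcb,
                           check.names = FALSE),
                file.path(od, paste0("features_", split, ".tsv")))
    }
  }

  read_features <- function(split) {
    f <- need(file.path(od, paste0("features_", split, ".tsv")), "features")
    d <- utils::read.delim(f, check.names = FALSE)
    defs <- feature_definitions()
    feature_matrix(`rownames<-`(as.matrix(d[, defs$name]), d$patient),
                   stats::setNames(defs$modality, defs$name),
                   pcr = d$pcr, rcb = d$rcb)
  }

  if ("associate" %in% stages) {
    fm <- read_features("train")
    assoc <- associate_features(fm$X, fm$pcr)
    trend <- do.call(rbind, lapply(colnames(fm$X), function(nm) {
      r <- tryCatch(ordinal_trend(fm$X[, nm], fm$rcb),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      cbind(data.frame(feature = nm), r)
    }))
    write_tsv(assoc, file.path(od, "associations_logistic.tsv"))
    write_tsv(trend, file.path(od, "associations_ordinal.tsv"))
  }

  if ("train" %in% stages) {
    fm <- read_features("train")
    models <- if (config$models == "all") {
      run_nested_models(fm, seeds = config$seeds, n_iter = config$n_iter)
    } else {
      tags <- fm$modality
      list(
        clinical = train_model(
          fm$X[, tags == "clinical", drop = FALSE], fm$pcr,
          seeds = config$seeds, n_iter = config$n_iter),
        fully_integrated = train_model(fm$X, fm$pcr, seeds = config$seeds,
                                       n_iter = config$n_iter)
      )
    }
    saveRDS(models, file.path(od, "models.rds"))
    manifest <- lapply(models, function(m) {
      list(features = m$features, cv_auc = m$cv_auc,
           hyperparameters = lapply(m$predictors, function(p) p$hp),
           kbest = lapply(m$predictors, function(p) p$keep_kbest))
    })
    jsonlite::write_json(manifest, file.path(od, "models_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  if ("validate" %in% stages) {
    models <- readRDS(need(file.path(od, "models.rds"), "validate"))
    fm <- read_features("test")
    rows <- lapply(names(models), function(nm) {
      ev <- evaluate(models[[nm]], fm$X, fm$pcr)
      data.frame(model = nm, auc = ev$auc,
                 auc_bootstrap_sd = ev$auc_bootstrap_sd,
                 auc_ci_low = ev$auc_delong_ci[["low"]],
                 auc_ci_high = ev$auc_delong_ci[["high"]],
                 average_precision = ev$average_precision)
    })
    write_tsv(do.call(rbind, rows), file.path(od, "validation_auc.tsv"))
  }

  if ("importance" %in% stages) {
    models <- readRDS(need(file.path(od, "models.rds"), "importance"))
    fm <- read_features("train")
    m <- models[[length(models)]]
    imp <- feature_importance(m$predictors[[1]],
                              fm$X[, m$features, drop = FALSE], fm$pcr)
    write_tsv(imp, file.path(od, "importance.tsv"))
  }

  if ("impact" %in% stages) {
    models <- readRDS(need(file.path(od, "models.rds"), "impact"))
    fm <- read_features("test")
    rows <- lapply(names(models), function(nm) {
      s <- predict(models[[nm]], fm$X)
      do.call(rbind, lapply(c(0, 2), function(b) {
        ci <- clinical_impact(s, fm$pcr, fn_budget = b)
        data.frame(model = nm, fn_budget = b,
                   identified_non_responders =
                     ci$projected[["identified_non_responders"]],
                   false_negatives = ci$projected[["false_negatives"]])
      }))
    })
    write_tsv(do.call(rbind, rows), file.path(od, "clinical_impact.tsv"))
  }

  if ("report" %in% stages) {
    arts <- setdiff(list.files(od, recursive = TRUE), "manifest.json")
    manifest <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("neopredict")),
      r_version = R.version.string,
      stages = stages,
      artefacts = as.list(tools::md5sum(file.path(od, arts)))
    )
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(od)
}
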