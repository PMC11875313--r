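#' Pipeline run configuration
#'
#' Assembles every knob of the end-to-end run: the seed (default 3, the
#' pipeline's reproducibility default), synthetic-data sizes, the model
#' panel, fold counts, reduction and PBPK settings. The configuration is
#' serialized (with a content hash) into the output directory alongside
#' every artifact for provenance.
#'
#' @param seed Integer seed used for every stage.
#' @param n_invitro Synthetic in vitro sample count.
#' @param models Character subset of `names(default_specs())`.
#' @param k_outer,k_inner Nested cross-validation fold counts.
#' @param test_fraction Held-out internal test fraction.
#' @param reduction_epsilon,reduction_patience Plateau rule for
#'   [iterative_reduction()].
#' @param run_invivo Run the PBPK to in vivo bridge stage.
#' @param n_studies Synthetic in vivo study count.
#' @param grids Optional named list of hyperparameter grids per model.
#' @return List of class `nanotox_config`.
#' @export
pipeline_config <- function(seed = 3, n_invitro = 2000,
                            models = c("gbt_depthwise", "random_forest",
                                       "extra_trees"),
                            k_outer = 10, k_inner = 5, test_fraction = 0.2,
                            reduction_epsilon = 0.005, reduction_patience = 2,
                            run_invivo = TRUE, n_studies = 20, grids = NULL) {
  structure(list(seed = seed, n_invitro = n_invitro, models = models,
                 k_outer = k_outer, k_inner = k_inner,
                 test_fraction = test_fraction,
                 reduction_epsilon = reduction_epsilon,
                 reduction_patience = reduction_patience,
                 run_invivo = run_invivo, n_studies = n_studies,
                 grids = grids),
            class = "nanotox_config")
}

write_report <- function(x, dir, name, config_hash, seed) {
  x$provenance <- list(config_hash = config_hash, seed = seed)
  jsonlite::write_json(x, file.path(dir, name), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in order -- generate, harmonize/encode/split, nested
#' cross-validation per model, stacking, attribution and ranking, iterative
#' feature reduction, PBPK calibration and the in vivo bridge -- writing a
#' JSON report per stage into `out_dir`. Stages whose report already exists
#' are skipped when `resume = TRUE`, so a deleted intermediate reruns only
#' its own stage and everything downstream of a changed seed is
#' reproducible byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param resume Skip stages whose report file already exists.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "nanotox_run",
                         resume = FALSE, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- unclass(config)
  hash <- substr(paste(
    as.hexmode(utf8ToInt(substr(jsonlite::toJSON(cfg_plain), 1, 1e6)) %% 256),
    collapse = ""), 1, 16)
  yaml::write_yaml(cfg_plain, file.path(out_dir, "config.yaml"))
  say <- function(...) if (!quiet) message("[nanotox] ", ...)
  stage <- function(name, fun) {
    path <- file.path(out_dir, paste0(name, ".json"))
    if (resume && file.exists(path)) { say(name, ": cached"); return(NULL) }
    t0 <- Sys.time()
    res <- fun()
    say(name, ": done in ",
        format(round(difftime(Sys.time(), t0, units = "secs"), 1)))
    res
  }
  results <- list()
  seed <- config$seed

  # synthetic data + harmonization
  synth <- stage("synth", function() {
    ds <- gen_invitro(synth_config(n = config$n_invitro, seed = seed))
    write_report(list(n = nrow(ds$records),
                      prevalence = mean(ds$records$label),
                      bayes_pr_auc = ds$bayes_pr_auc),
                 out_dir, "synth.json", hash, seed)
    ds
  })
  if (is.null(synth)) synth <- gen_invitro(synth_config(n = config$n_invitro,
                                                        seed = seed))
  cur <- harmonize(synth$records)
  mat <- encode(cur)
  parts <- split_dataset(mat, config$test_fraction, seed)

  # per-model nested CV + final fit
  specs <- default_specs()[config$models]
  models <- list()
  for (nm in names(specs)) {
    models[[nm]] <- stage(paste0("train_", nm), function() {
      fit <- nanotox_train(parts$train, specs[[nm]],
                           grid = config$grids[[nm]],
                           k_outer = config$k_outer, k_inner = config$k_inner,
                           seed = seed)
      test_scores <- predict(fit, parts$test)
      write_report(list(model = nm, params = fit$params,
                        outer_pr_auc = mean(fit$ncv$outer_pr_auc),
                        internal_test = unclass(
                          metric_report(parts$test$y, test_scores,
                                        fit$threshold))),
                   out_dir, paste0("train_", nm, ".json"), hash, seed)
      fit
    })
    if (is.null(models[[nm]]))
      models[[nm]] <- nanotox_train(parts$train, specs[[nm]],
                                    grid = config$grids[[nm]],
                                    k_outer = config$k_outer,
                                    k_inner = config$k_inner, seed = seed)
  }
  results$models <- models

  # stacking ensemble over the panel
  stack <- stage("stack", function() {
    st <- fit_stack(parts$train, unname(specs),
                    base_params = lapply(models, `[[`, "params"), seed = seed)
    sc <- predict(st, parts$test)
    write_report(list(bases = names(specs), coefficients = as.list(coef(st)),
                      internal_test = unclass(
                        metric_report(parts$test$y, sc, st$threshold))),
                 out_dir, "stack.json", hash, seed)
    st
  })
  results$stack <- stack

  # attribution, ranking, PDP fits, reduction
  explain <- stage("explain", function() {
    ref <- models[[1]]
    n_att <- min(200L, nrow(parts$train$x))   # attribution sample
    att <- attribute(ref, mat_rows(parts$train, seq_len(n_att)),
                     n_background = 32, seed = seed)
    grouped <- group_and_rank(att)
    conc_pdp <- pdp(ref, parts$train, "conc_ug_per_ml")
    size_pdp <- pdp(ref, parts$train, "size_nm")
    sig <- fit_sigmoid(conc_pdp, log10_x = TRUE)
    pl <- fit_powerlaw(size_pdp)
    red <- iterative_reduction(grouped$ranking, parts$train, specs[[1]],
                               params = models[[1]]$params,
                               epsilon = config$reduction_epsilon,
                               patience = config$reduction_patience,
                               seed = seed)
    write_report(list(ranking = grouped$ranking,
                      importance = as.list(grouped$importance),
                      sigmoid = as.list(sig$params),
                      powerlaw = as.list(pl$params),
                      plateau_size = red$plateau_size,
                      reduction_trace = red$trace),
                 out_dir, "explain.json", hash, seed)
    list(attribution = grouped, sigmoid = sig, powerlaw = pl, reduction = red)
  })
  results$explain <- explain

  # PBPK calibration and in vivo bridge
  if (config$run_invivo) {
    results$invivo <- stage("invivo", function() {
      panel <- gen_invivo_studies(n_studies = config$n_studies, seed = seed)
      fits <- lapply(panel$studies$study_id, function(sid) {
        pbpk_fit(panel$biodist[[sid]], panel$physiology,
                 pbpk_doses("IV",
                            panel$studies$dose_ug[panel$studies$study_id == sid]),
                 n_starts = 5, seed = child_seed(seed, match(sid, panel$studies$study_id)))
      })
      names(fits) <- panel$studies$study_id
      accepted <- vapply(fits, accept_fit, logical(1))
      ivmat <- build_invivo_features(
        gen_invivo_tox(add_chat(panel, fits), seed = seed), fits)
      ncv <- nested_cv(ivmat, specs[[1]], k_outer = min(config$k_outer, 5),
                       k_inner = 3, seed = seed)
      write_report(list(n_studies = config$n_studies,
                        n_accepted = sum(accepted),
                        prevalence = mean(ivmat$y),
                        outer_pr_auc = mean(ncv$outer_pr_auc)),
                   out_dir, "invivo.json", hash, seed)
      list(fits = fits, matrix = ivmat, ncv = ncv)
    })
  }
  invisible(results)
}

# Internal: attach the exposure metric of each accepted study/organ/time to
# the record table (used by the pipeline and the acceptance script).
add_chat <- function(panel, fits) {
  rec <- panel$records
  rec$c_hat <- NA_real_
  for (i in seq_len(nrow(rec))) {
    f <- fits[[rec$study_id[i]]]
    if (!is.null(f) && accept_fit(f))
      rec$c_hat[i] <- exposure(f, rec$organ[i], rec$time_h[i])$c_hat
  }
  rec[!is.na(rec$c_hat), , drop = FALSE]
}
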