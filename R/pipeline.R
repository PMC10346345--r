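# End-to-end pipeline: simulate -> preprocess -> segment -> features ->
# select -> evaluate, driven by a single nested configuration with a global
# seed, with per-stage logging of parameters and counts.

#' Pipeline configuration
#'
#' Nested configuration covering every stage. Unknown keys in any section
#' are rejected. The configuration round-trips losslessly through JSON
#' ([pipeline_config_to_json()] / [pipeline_config_from_json()]).
#'
#' @param simulate generator section: `n_subjects`, `trial_duration` (s)
#'   and any other [session_config()] argument.
#' @param preprocess `hp`, `lp`, `stop` (Hz), `ica` (logical),
#'   `ica_threshold`, `ica_components`, `ica_max_samples`.
#' @param segment `side`, `n` (normalized samples), `bounds`, `grf_threshold`
#'   (N), `reconcile_tol` (s).
#' @param features `levels`, `eps_k`, `p`.
#' @param select `k`, `corr_threshold`, `per_fold` (re-select inside each CV
#'   training fold instead of once per run).
#' @param models character vector of model kinds to evaluate plus an
#'   optional `hyperparameters` list keyed by kind.
#' @param evaluate `k` folds, `labelings`, `group_by_subject`.
#' @param seed global integer seed.
#' @param out_dir optional output directory for reports and intermediates.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), preprocess = list(),
                            segment = list(), features = list(),
                            select = list(), models = list(),
                            evaluate = list(), seed = 1L, out_dir = NULL) {
  defaults <- list(
    simulate = list(n_subjects = 4L, trial_duration = 120,
                    sampling_rate_eeg = 1000, sampling_rate_mocap = 100,
                    n_channels = 64L),
    preprocess = list(hp = 1, lp = 70, stop = c(55, 65), ica = TRUE,
                      ica_threshold = 0.90, ica_components = 32L,
                      ica_max_samples = 10000L),
    segment = list(side = "right", n = 100L, bounds = c(0.4, 2.5),
                   grf_threshold = 20, reconcile_tol = 0.05),
    features = list(levels = 8L, eps_k = 0.2, p = 1.5),
    select = list(k = 40L, corr_threshold = 0.8, per_fold = FALSE),
    models = list(kinds = c("svm", "random_forest", "xgboost", "rnn_lstm",
                            "chrononet"),
                  hyperparameters = list()),
    evaluate = list(k = 5L,
                    labelings = c("four_class", "three_class", "two_class"),
                    group_by_subject = FALSE))
  merge_checked <- function(def, user, section) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown)) {
      stop("unknown key(s) in ", section, " config: ",
           paste(unknown, collapse = ", "))
    }
    modifyList(def, user)
  }
  # the simulate section accepts any session_config argument
  sim_allowed <- union(names(defaults$simulate),
                       setdiff(names(formals(session_config)), "seed"))
  unknown_sim <- setdiff(names(simulate), sim_allowed)
  if (length(unknown_sim)) {
    stop("unknown key(s) in simulate config: ",
         paste(unknown_sim, collapse = ", "))
  }
  cfg <- list(
    simulate = modifyList(defaults$simulate, simulate),
    preprocess = merge_checked(defaults$preprocess, preprocess, "preprocess"),
    segment = merge_checked(defaults$segment, segment, "segment"),
    features = merge_checked(defaults$features, features, "features"),
    select = merge_checked(defaults$select, select, "select"),
    models = merge_checked(defaults$models, models, "models"),
    evaluate = merge_checked(defaults$evaluate, evaluate, "evaluate"),
    seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Demonstration configuration (small, minutes on one CPU)
#'
#' Two subjects, 60-second trials, random-forest evaluation of all three
#' labelings.
#'
#' @param seed global seed.
#' @param out_dir optional output directory.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(seed = 1L, out_dir = NULL) {
  pipeline_config(
    simulate = list(n_subjects = 2L, trial_duration = 60),
    models = list(kinds = "random_forest"),
    seed = seed, out_dir = out_dir)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> %d subjects x 4 conditions x %g s, models: %s, seed %d\n",
    x$simulate$n_subjects, x$simulate$trial_duration,
    paste(x$models$kinds, collapse = ", "), x$seed))
  invisible(x)
}

#' Serialize / deserialize a pipeline configuration
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `pipeline_config_from_json()` returns a validated
#'   [pipeline_config()].
#' @export
pipeline_config_to_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname pipeline_config_to_json
#' @export
pipeline_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("simulate", "preprocess", "segment", "features", "select",
             "models", "evaluate", "seed", "out_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "))
  }
  pipeline_config(
    simulate = as.list(raw$simulate), preprocess = as.list(raw$preprocess),
    segment = as.list(raw$segment), features = as.list(raw$features),
    select = as.list(raw$select), models = as.list(raw$models),
    evaluate = as.list(raw$evaluate), seed = raw$seed %||% 1L,
    out_dir = raw$out_dir)
}

#' Preprocess one session's EEG
#'
#' Band-pass/band-stop filtering followed (optionally) by ICA decomposition,
#' rule-based component scoring and artifact removal at the configured
#' probability threshold.
#'
#' @param eeg an [eeg_recording()].
#' @param cfg the `preprocess` section of a [pipeline_config()].
#' @param seed seed for the ICA start.
#' @return A cleaned [eeg_recording()]; the number of removed components is
#'   attached as `removed_components` when ICA ran.
#' @export
preprocess_eeg <- function(eeg, cfg = pipeline_config()$preprocess,
                           seed = 1L) {
  rec <- bandpass_bandstop(eeg, hp = cfg$hp, lp = cfg$lp, stop = cfg$stop)
  if (isTRUE(cfg$ica)) {
    dec <- decompose_ica(rec, n_components = cfg$ica_components,
                         seed = seed, max_samples = cfg$ica_max_samples)
    dec <- score_components(dec)
    rec <- remove_artifacts(dec, threshold = cfg$ica_threshold)
  }
  rec
}

#' Detect, reconcile and segment one session into cycles
#'
#' Heel strikes are detected from the configured side's heel marker,
#' confirmed against the forceplate, and used to cut the (preprocessed) EEG
#' into 0-100% normalized cycles.
#'
#' @param session a `gait_session`.
#' @param rec the preprocessed [eeg_recording()] of that session.
#' @param cfg the `segment` section of a [pipeline_config()].
#' @return A [cycle_set()] carrying the session's subject and condition.
#' @export
segment_session <- function(session, rec,
                            cfg = pipeline_config()$segment) {
  heel <- if (cfg$side == "right") session$heel_z_right else
    session$heel_z_left
  grf <- if (cfg$side == "right") session$grf_right else session$grf_left
  ev_m <- detect_events_marker(heel)
  ev_f <- detect_events_grf(grf, threshold = cfg$grf_threshold)
  ev <- reconcile_events(ev_m, ev_f, tol = cfg$reconcile_tol)
  cycles <- segment_and_normalize(rec, ev, n = cfg$n, bounds = cfg$bounds)
  cycles$subject <- session$subject_id
  cycles$condition <- session$condition
  cycles
}

# stack the normalized arrays of several cycle_sets into one tensor + metadata
stack_cycles <- function(cycle_sets) {
  n_tot <- sum(vapply(cycle_sets, length, integer(1)))
  d <- dim(cycle_sets[[1]]$normalized)
  tensor <- array(NA_real_, c(d[1], d[2], n_tot))
  subject <- integer(n_tot)
  condition <- character(n_tot)
  off <- 0L
  for (cs in cycle_sets) {
    nk <- length(cs)
    if (nk == 0L) next
    tensor[, , off + seq_len(nk)] <- cs$normalized
    subject[off + seq_len(nk)] <- cs$subject
    condition[off + seq_len(nk)] <- cs$condition
    off <- off + nk
  }
  list(tensor = tensor, subject = subject, condition = condition)
}

#' Run the full pipeline
#'
#' Generates (or reuses) synthetic sessions for every subject x condition,
#' preprocesses, segments, extracts features, and evaluates the configured
#' models under all configured labelings with stratified cross-validation.
#' Feature models are evaluated on the Wilcoxon/correlation-selected feature
#' subset; sequence models on the normalized cycle tensors. Every stage logs
#' its parameters and counts. Deterministic: the same configuration and seed
#' reproduce every report byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return A list of class `pipeline_result` with `reports` (one
#'   `evaluation_report` per labeling x model), `feature_table`,
#'   `selection` (per labeling), `log` (stage counts), and `config`. When
#'   `config$out_dir` is set, reports are additionally written as
#'   `report_<labeling>.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  sim <- config$simulate
  sim$seed <- config$seed
  cfg_gen <- do.call(session_config, sim)

  log <- list()
  cycle_sets <- list()
  feature_tabs <- list()
  say("simulate+preprocess+segment: %d subjects x %d conditions, %g s trials",
      cfg_gen$n_subjects, length(CONDITIONS), cfg_gen$trial_duration)
  for (sj in seq_len(cfg_gen$n_subjects)) {
    for (cond in CONDITIONS) {
      ses <- generate_session(cfg_gen, cond, sj)
      rec <- preprocess_eeg(ses$eeg, config$preprocess,
                            seed = trial_seed(config$seed, sj, cond) + 7L)
      cyc <- segment_session(ses, rec, config$segment)
      key <- sprintf("s%02d_%s", sj, cond)
      log[[key]] <- list(
        cycles = length(cyc), discarded = cyc$n_discarded,
        components_removed = length(rec$removed_components %||% integer(0)))
      say("  subject %d %s: %d cycles (%d discarded, %d ICA components removed)",
          sj, cond, length(cyc), cyc$n_discarded,
          length(rec$removed_components %||% integer(0)))
      cycle_sets[[key]] <- cyc
      feature_tabs[[key]] <- build_feature_table(
        cyc, levels = config$features$levels,
        eps_k = config$features$eps_k, p = config$features$p)
    }
  }
  feature_table <- do.call(rbind, c(feature_tabs, make.row.names = FALSE))
  stacked <- stack_cycles(cycle_sets)
  say("feature extraction: %d cycles x %d features", nrow(feature_table),
      length(feature_columns(feature_table)))

  reports <- list()
  selection <- list()
  for (lab in config$evaluate$labelings) {
    labels <- make_labels(feature_table$condition, lab)
    keep <- !is.na(labels)
    groups <- if (isTRUE(config$evaluate$group_by_subject)) {
      feature_table$subject
    } else NULL
    sel <- NULL
    if (!config$select$per_fold) {
      sel <- select_features(feature_table[keep, , drop = FALSE],
                             labels[keep], k = config$select$k,
                             corr_threshold = config$select$corr_threshold)
      say("selection (%s): %d features", lab, length(sel$selected))
      selection[[lab]] <- sel
    }
    for (kind in config$models$kinds) {
      spec <- model_spec(kind, n_classes = length(unique(labels[keep])),
                         hyperparameters =
                           config$models$hyperparameters[[kind]] %||% list(),
                         seed = config$seed)
      if (is_deep(kind)) {
        rep <- crossvalidate(stacked$tensor, labels, spec,
                             k = config$evaluate$k, seed = config$seed,
                             groups = groups, labeling = lab)
      } else {
        Xf <- if (is.null(sel)) feature_table else
          feature_table[, c("subject", "condition", "cycle_index",
                            sel$selected), drop = FALSE]
        rep <- crossvalidate(Xf, labels, spec, k = config$evaluate$k,
                             seed = config$seed, groups = groups,
                             per_fold_select = config$select$per_fold,
                             select_k = config$select$k,
                             corr_threshold = config$select$corr_threshold,
                             labeling = lab)
      }
      say("  %s %s: accuracy %.4f, MCC %.4f", lab, kind,
          rep$metrics$accuracy, rep$metrics$mcc)
      reports[[paste(lab, kind, sep = "_")]] <- rep
    }
  }
  say("total wall time %.1f min",
      as.numeric(difftime(Sys.time(), t0, units = "mins")))

  result <- structure(
    list(reports = reports, feature_table = feature_table,
         selection = selection, log = log, config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_reports(result, config$out_dir)
  result
}

report_to_list <- function(rep) {
  m <- rep$metrics
  list(labeling = rep$labeling, model = rep$model, n = rep$n, k = rep$k,
       seed = rep$seed, classes = rep$classes,
       metrics = list(accuracy = m$accuracy, precision = m$precision,
                      recall = m$recall, f_score = m$f_score, mcc = m$mcc,
                      roc_area = m$roc_area, auc = m$auc),
       fold_accuracy = rep$fold_accuracy,
       confusion = as.vector(m$confusion),
       roc_curves = lapply(m$roc_curves, function(rc) {
         list(fpr = rc$fpr, tpr = rc$tpr)
       }))
}

#' Write pipeline reports to JSON
#'
#' One `report_<labeling>.json` per labeling, each holding every model's
#' metric panel, pooled confusion matrix and ROC curves. Output depends only
#' on configuration and seed, so repeated runs are byte-identical.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_reports <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (lab in unique(vapply(result$reports, `[[`, "", "labeling"))) {
    reps <- Filter(function(r) r$labeling == lab, result$reports)
    out <- list(labeling = lab, seed = result$config$seed,
                models = lapply(unname(reps), report_to_list))
    p <- file.path(dir, paste0("report_", lab, ".json"))
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (r in x$reports) {
    cat(sprintf("  %-12s %-14s accuracy %.4f\n", r$labeling, r$model,
                r$metrics$accuracy))
  }
  invisible(x)
}
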