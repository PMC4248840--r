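# End-to-end reproducible runs from a single configuration: simulate a
# study, extract features, train per-session networks, run the requested
# evaluation protocols and the noise sweep, and write delimited result
# tables plus run metadata (seed, config hash, versions) to an output
# directory.  A single master seed fans out deterministically to every
# stochastic stage.

PIPELINE_KEYS <- list(
  top = c("seed", "output_dir", "schedule", "model", "drift", "epoching",
          "net", "protocol", "ensemble", "protocols"),
  schedule = c("n_subjects", "days", "sessions_per_day",
               "session_length_s", "block_plan", "sampling_rate_hz",
               "channel_labels", "session_spacing_s", "day_spacing_s"),
  model = c("background_exponent", "background_rms_uV", "band_components",
            "blink_rate_hz", "blink_amp_uV"),
  drift = c("session_drift_sd", "day_drift_sd", "within_session_slope"),
  epoching = c("window_s", "step_s", "fft_len", "bands_hz"),
  net = c("hidden_layers", "max_iters", "early_stop_patience",
          "train_fraction", "n_restarts"),
  protocol = c("train_epochs_per_class", "test_window_epochs",
               "test_window_step_epochs", "rms_levels", "n_chance_runs"),
  ensemble = c("n_members"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0) {
    abort_invalid("unknown configuration key(s) in %s: %s", where,
                  paste(bad, collapse = ", "))
  }
}

build_arg_list <- function(section, defaults_fn, transform = identity) {
  if (is.null(section)) return(defaults_fn())
  do.call(defaults_fn, transform(section))
}

#' Resolve a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, validates it against the
#' configuration schema (unknown keys are rejected), and instantiates
#' all component configuration objects before any computation runs.
#'
#' @param config YAML path or list.
#' @return list of resolved configuration objects.
#' @export
resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, PIPELINE_KEYS$top, "top level")
  for (sec in c("schedule", "model", "drift", "epoching", "net",
                "protocol", "ensemble")) {
    if (!is.null(config[[sec]])) {
      check_keys(config[[sec]], PIPELINE_KEYS[[sec]], sec)
    }
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  sched_args <- config$schedule
  if (!is.null(sched_args$block_plan)) {
    sched_args$block_plan <- do.call(rbind, lapply(
      sched_args$block_plan,
      function(b) data.frame(state = b$state, duration_s = b$duration_s)))
  }
  schedule <- build_arg_list(sched_args, study_schedule)

  model_args <- config$model
  if (!is.null(model_args$band_components)) {
    model_args$band_components <- do.call(rbind, lapply(
      model_args$band_components, as.data.frame))
  }
  model <- build_arg_list(model_args, signal_model_params)

  drift <- build_arg_list(config$drift, drift_params)
  epo_args <- config$epoching
  if (!is.null(epo_args$bands_hz)) {
    epo_args$bands_hz <- lapply(epo_args$bands_hz, unlist)
  }
  epoching <- build_arg_list(
    c(epo_args, list(rate_hz = schedule$sampling_rate_hz)),
    epoching_config)
  net_cfg <- build_arg_list(
    c(config$net, list(seed = derive_seed(seed, 101))), net_config)
  protocol <- build_arg_list(config$protocol, protocol_config)
  protocol$chance_seed <- derive_seed(seed, 103)
  ensemble <- build_arg_list(config$ensemble, ensemble_config)
  protocols_run <- if (is.null(config$protocols)) {
    c("same_session", "cross_session", "loocv", "chance", "noise_sweep")
  } else config$protocols

  list(seed = seed, output_dir = config$output_dir, schedule = schedule,
       model = model, drift = drift, epoching = epoching,
       net_cfg = net_cfg, protocol = protocol, ensemble = ensemble,
       protocols_run = protocols_run)
}

write_result_table <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", meta$seed), con)
  writeLines(sprintf("# config_hash: %s", meta$config_hash), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline from one configuration
#'
#' Stages: simulate the study, extract features, train the per-session
#' networks, evaluate the requested protocols (same-session,
#' cross-session at every feasible scale, leave-one-out, chance-level
#' resampling) and a test-time noise sweep over the configured RMS
#' levels, then write one delimited table per stage plus `summary.json`
#' and `run_meta.json` (seed, config hash, versions) into the output
#' directory.  Identical configuration + seed produce byte-identical
#' tables.
#'
#' @param config YAML path or configuration list (see
#'   [resolve_config()]).
#' @param output_dir overrides the configured output directory.
#' @return invisibly, a list with the in-memory results and the output
#'   directory.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- resolve_config(config)
  out_dir <- if (!is.null(output_dir)) output_dir else cfg$output_dir
  if (is.null(out_dir)) abort_invalid("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  resolved_path <- file.path(out_dir, "resolved_config.yaml")
  dump_cfg <- cfg
  dump_cfg$schedule$block_plan <- apply(
    cfg$schedule$block_plan, 1, as.list, simplify = FALSE)
  yaml::write_yaml(lapply(dump_cfg[c("seed", "schedule", "model", "drift",
                                     "epoching", "net_cfg", "protocol",
                                     "ensemble", "protocols_run")],
                          unclass),
                   resolved_path)
  config_hash <- unname(tools::md5sum(resolved_path))
  meta <- list(seed = cfg$seed, config_hash = config_hash,
               r_version = R.version.string,
               package_version = as.character(
                 utils::packageVersion("workloadbci")))
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  message("stage: simulate (", cfg$schedule$n_subjects, " subjects)")
  study <- generate_study(cfg$model, cfg$schedule, cfg$drift,
                          seed = derive_seed(cfg$seed, 1))
  message("stage: features (", length(study), " sessions)")
  feats <- study_features(study, cfg$epoching)
  meta_df <- session_meta(study)
  results <- list(output_dir = out_dir, meta = meta)
  summary <- list(seed = cfg$seed, config_hash = config_hash,
                  n_sessions = length(study))

  nets <- vector("list", length(study))
  if ("same_session" %in% cfg$protocols_run) {
    message("stage: same-session protocol")
    rows <- list()
    for (i in seq_along(study)) {
      ss <- same_session_protocol(features = feats[[i]],
                                  epoching = cfg$epoching,
                                  protocol = cfg$protocol,
                                  net_cfg = cfg$net_cfg)
      nets[[i]] <- ss$net
      rows[[i]] <- cbind(meta_df[rep(i, nrow(ss$windows)),
                                 c("subject", "day", "session")],
                         ss$windows)
    }
    same_tab <- do.call(rbind, rows)
    rownames(same_tab) <- NULL
    write_result_table(same_tab, file.path(out_dir, "same_session.tsv"),
                       meta)
    results$same_session <- same_tab
    # Average per session, then per subject, then across subjects.
    per_sess <- stats::aggregate(accuracy ~ subject + day + session, same_tab,
                          mean)
    per_subj <- stats::aggregate(accuracy ~ subject, per_sess, mean)
    summary$same_session_acc <- mean(per_subj$accuracy)
  }

  if ("cross_session" %in% cfg$protocols_run) {
    rows <- list()
    for (scale in c("minutes", "hours", "days")) {
      feasible <- tryCatch({
        cross_session_pairs(meta_df, scale); TRUE
      }, workloadbci_invalid = function(e) FALSE)
      if (!feasible) next
      message("stage: cross-session protocol (", scale, ")")
      cs <- cross_session_protocol(study, scale, cfg$epoching,
                                   cfg$protocol, cfg$net_cfg,
                                   features_list = feats, nets = nets)
      nets <- attr(cs, "nets")
      rows[[scale]] <- cbind(scale = scale, as.data.frame(cs))
      per_subj <- stats::aggregate(accuracy ~ subject, cs, mean)
      summary[[paste0("cross_session_", scale, "_acc")]] <-
        mean(per_subj$accuracy)
    }
    if (length(rows) > 0) {
      cross_tab <- do.call(rbind, rows)
      rownames(cross_tab) <- NULL
      write_result_table(cross_tab,
                         file.path(out_dir, "cross_session.tsv"), meta)
      results$cross_session <- cross_tab
    }
  }

  if ("loocv" %in% cfg$protocols_run) {
    message("stage: leave-one-out protocol")
    lo <- loocv_protocol(study, cfg$epoching, cfg$net_cfg,
                         features_list = feats)
    write_result_table(lo$folds, file.path(out_dir, "loocv.tsv"), meta)
    results$loocv <- lo
    summary$loocv_acc <- lo$overall
  }

  if ("chance" %in% cfg$protocols_run) {
    message("stage: chance-level resampling")
    structure_labels <- lapply(feats, `[[`, "labels")
    ch <- chance_resample(structure_labels, cfg$protocol$n_chance_runs,
                          seed = cfg$protocol$chance_seed)
    summary$chance_mean_acc <- ch$mean_acc
    summary$chance_max_acc <- ch$max_acc
    results$chance <- ch
  }

  if ("noise_sweep" %in% cfg$protocols_run) {
    message("stage: noise sweep (",
            paste(cfg$protocol$rms_levels, collapse = ", "), " uVrms)")
    pairs <- cross_session_pairs(meta_df, "minutes")
    rows <- list()
    for (rms in cfg$protocol$rms_levels) {
      for (i in seq_len(nrow(pairs))) {
        tr <- pairs$train_index[i]; te <- pairs$test_index[i]
        if (is.null(nets[[tr]])) {
          nets[[tr]] <- train_session_net(feats[[tr]], cfg$protocol,
                                          cfg$net_cfg)
        }
        preds <- if (rms == 0) {
          predict(nets[[tr]], feats[[te]])
        } else {
          ensemble_predict(
            nets[[tr]], study[[te]]$recording, study[[te]]$labels,
            cfg$epoching,
            noise_config(rms, seed = derive_seed(cfg$seed, 2, i,
                                                 round(rms * 10))),
            cfg$ensemble)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          rms_uV = rms, subject = pairs$subject[i],
          train_index = tr, test_index = te,
          accuracy = accuracy(preds, feats[[te]]$labels))
      }
    }
    sweep_tab <- do.call(rbind, rows)
    write_result_table(sweep_tab, file.path(out_dir, "noise_sweep.tsv"),
                       meta)
    results$noise_sweep <- sweep_tab
    agg <- stats::aggregate(accuracy ~ rms_uV, sweep_tab, mean)
    for (i in seq_len(nrow(agg))) {
      summary[[sprintf("noise_sweep_acc_rms%g", agg$rms_uV[i])]] <-
        agg$accuracy[i]
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$summary <- summary
  invisible(results)
}
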