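#' Pipeline configuration
#'
#' Bundles the tunable parameters of the end-to-end workflow. Defaults are
#' the study conventions: correlation cutoff 0.4, exhaustive enumeration up
#' to four descriptors, residual outlier threshold 0.4 pIC50 units,
#' Tanimoto cutoff 0.35, at most one Lipinski violation, and the as-printed
#' sign convention for free energies.
#'
#' @param correlation_cutoff Descriptor selection threshold on `|r|`.
#' @param max_p Largest descriptor-subset size to enumerate (`NULL` = all
#'   retained descriptors).
#' @param outlier_threshold Residual magnitude above which a compound is
#'   flagged anomalous.
#' @param tanimoto_cutoff Similarity cut for fingerprint filtering.
#' @param lipinski_max_violations Maximum tolerated rule-of-five violations.
#' @param dg_sign_mode `"as_printed"` or `"thermodynamic"`, see
#'   [delta_g_from_ki()].
#' @param seed Integer seed for any stochastic step.
#' @param out_dir Optional directory for report files.
#' @return A list of class `qsar_config`.
#' @export
qsar_config <- function(correlation_cutoff = 0.4, max_p = NULL,
                        outlier_threshold = 0.4, tanimoto_cutoff = 0.35,
                        lipinski_max_violations = 1,
                        dg_sign_mode = c("as_printed", "thermodynamic"),
                        seed = 1, out_dir = NULL) {
  dg_sign_mode <- match.arg(dg_sign_mode)
  if (correlation_cutoff < 0 || outlier_threshold < 0 ||
      tanimoto_cutoff < 0 || tanimoto_cutoff > 1 ||
      lipinski_max_violations < 0) {
    stop("configuration value out of range", call. = FALSE)
  }
  structure(list(correlation_cutoff = correlation_cutoff, max_p = max_p,
                 outlier_threshold = outlier_threshold,
                 tanimoto_cutoff = tanimoto_cutoff,
                 lipinski_max_violations = lipinski_max_violations,
                 dg_sign_mode = dg_sign_mode, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "qsar_config")
}

#' Run the QSAR modelling stage
#'
#' Executes the full modelling chain on a training table: correlation
#' report, sign-blind descriptor selection, exhaustive subset enumeration
#' and fitting, leaderboard ranking, residual tables for the training and
#' (optionally) internal-validation compounds, outlier flagging, and
#' external validation. When `config$out_dir` is set, writes
#' `leaderboard.csv`, `best_model.json`, `residuals_training.csv`,
#' optionally `residuals_external.csv`, and `run_log.txt` (the only output
#' carrying a timestamp, so repeated runs are otherwise byte-identical).
#'
#' @param training A [compound_table()] with observed `pic50`; rows with
#'   role `pivot` or `training` form the fit set.
#' @param internal Optional table of internal-validation compounds with
#'   observed `pic50` and descriptors.
#' @param external Optional table containing `external_validation` rows.
#' @param config A [qsar_config()].
#' @return List of class `qsar_run`: `correlation`, `selected`,
#'   `leaderboard`, `best_model`, `residuals` (training + internal),
#'   `outliers` (list retained/flagged), `external` (or `NULL`).
#' @export
#' @examples
#' run <- run_qsar(cox2_training_set())
#' run$best_model$model_id
run_qsar <- function(training, internal = NULL, external = NULL,
                     config = qsar_config()) {
  stopifnot(inherits(training, "compound_table"),
            inherits(config, "qsar_config"))
  fit_set <- training[training$role %in% c("pivot", "training"), ,
                      drop = FALSE]
  fit_set <- compound_table(as.data.frame(fit_set),
                            descriptor_names = descriptor_names(training),
                            check_consistency = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  report <- stage("correlation", correlation_report(fit_set,
                                                    config$correlation_cutoff))
  selected <- stage("selection", select_descriptors(report))
  max_p <- if (is.null(config$max_p)) length(selected) else
    min(config$max_p, length(selected))
  lb <- stage("enumeration", model_leaderboard(fit_set, selected,
                                               max_p = max_p))
  best <- leaderboard_model(lb)
  res_train <- stage("residuals", residual_table(fit_set, best))
  res <- res_train
  if (!is.null(internal)) {
    res_int <- stage("internal validation", residual_table(internal, best))
    res_int$set <- "internal_validation"
    res_train$set <- "training"
    res <- rbind(res_train, res_int)
  }
  outliers <- flag_outliers(res, config$outlier_threshold)
  ext <- if (!is.null(external)) {
    stage("external validation", external_validation(best, external))
  }
  run <- structure(list(correlation = report, selected = selected,
                        leaderboard = lb, best_model = best,
                        residuals = res, outliers = outliers,
                        external = ext, config = config),
                   class = "qsar_run")
  if (!is.null(config$out_dir)) write_qsar_run(run, config$out_dir)
  run
}

write_qsar_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_leaderboard(run$leaderboard, file.path(dir, "leaderboard.csv"))
  write_qsar_model(run$best_model, file.path(dir, "best_model.json"))
  write.csv(run$residuals, file.path(dir, "residuals_training.csv"),
            row.names = FALSE)
  if (!is.null(run$external)) {
    write.csv(as.data.frame(run$external),
              file.path(dir, "residuals_external.csv"), row.names = FALSE)
  }
  cfg <- run$config
  log_lines <- c(
    paste0("cox2qsar ", as.character(utils::packageVersion("cox2qsar"))),
    paste0("time: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("R: ", R.version.string),
    paste0("correlation_cutoff: ", cfg$correlation_cutoff),
    paste0("max_p: ", ifelse(is.null(cfg$max_p), "all", cfg$max_p)),
    paste0("outlier_threshold: ", cfg$outlier_threshold),
    paste0("seed: ", cfg$seed),
    paste0("selected: ", paste(run$selected, collapse = ", ")),
    paste0("best_model: ", run$best_model$model_id))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.qsar_run <- function(x, ...) {
  cat("QSAR run: ", length(x$selected), " descriptors selected [",
      paste(x$selected, collapse = ", "), "], ", nrow(x$leaderboard),
      " models fitted\n", sep = "")
  cat("Best model:\n")
  print(x$best_model)
  if (nrow(x$outliers$flagged) > 0) {
    cat("Flagged |residual| > ", x$config$outlier_threshold, ": ",
        paste(x$outliers$flagged$compound_id, collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$external)) {
    cat("External validation: max |residual| = ",
        round(attr(x$external, "max_abs_residual"), 4), "\n", sep = "")
  }
  invisible(x)
}

#' Run the candidate screening stage
#'
#' Triages candidate compounds with the desk-scale filters and predicts
#' their activity with a chosen model: (1) Lipinski rule-of-five count on
#' the property table, excluding candidates above
#' `config$lipinski_max_violations`; (2) optional Tanimoto filter against a
#' reference fingerprint; (3) pIC50 prediction with `model`, ranked most
#' potent first. Every exclusion is recorded with compound id, rule and
#' observed value.
#'
#' @param model A `qsar_model` (fitted, or as-printed via
#'   [qsar_equation()]/[cox2_equation()]).
#' @param candidates A [compound_table()] of candidates with descriptor
#'   columns covering the model subset.
#' @param properties Optional property data frame (columns `id`, `mw`,
#'   `logp`/`milogp`, `n_hd`, `n_ha`) matched to candidates by id.
#' @param fingerprints Optional named list of [fingerprint()]s keyed by
#'   candidate id; requires `reference`.
#' @param reference Reference [fingerprint()] for the Tanimoto filter.
#' @param config A [qsar_config()].
#' @return List of class `screen_report`: `report` (ranked data frame with
#'   `id`, `predicted_pic50`, and any filter values) and `excluded`
#'   (data frame `id`, `rule`, `value`).
#' @export
#' @examples
#' rep <- run_screen(cox2_equation("tetra"), cox2_candidates(),
#'                   properties = cox2_properties())
#' rep$report[, c("id", "predicted_pic50")]
run_screen <- function(model, candidates, properties = NULL,
                       fingerprints = NULL, reference = NULL,
                       config = qsar_config()) {
  if (!inherits(model, "qsar_model")) {
    stop("run_qsar (or cox2_equation) must provide a model before screening",
         call. = FALSE)
  }
  stopifnot(inherits(candidates, "compound_table"))
  excluded <- data.frame(id = character(), rule = character(),
                         value = numeric(), stringsAsFactors = FALSE)
  keep <- candidates$id
  lip <- NULL
  if (!is.null(properties)) {
    if (!"logp" %in% names(properties) && "milogp" %in% names(properties)) {
      properties$logp <- properties$milogp
    }
    idx <- match(keep, properties$id)
    if (anyNA(idx)) {
      stop("no property profile for candidate(s): ",
           paste(keep[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    nv <- lipinski_violations(properties[idx, , drop = FALSE])
    lip <- setNames(nv, keep)
    bad <- nv > config$lipinski_max_violations
    if (any(bad)) {
      excluded <- rbind(excluded,
                        data.frame(id = keep[bad], rule = "lipinski",
                                   value = nv[bad]))
    }
    keep <- keep[!bad]
  }
  sims <- NULL
  if (!is.null(fingerprints)) {
    if (is.null(reference)) {
      stop("Tanimoto filtering needs a reference fingerprint", call. = FALSE)
    }
    fps <- fingerprints[keep]
    if (any(vapply(fps, is.null, logical(1)))) {
      stop("no fingerprint for candidate(s): ",
           paste(keep[vapply(fps, is.null, logical(1))], collapse = ", "),
           call. = FALSE)
    }
    s <- vapply(fps, function(f) tanimoto(f, reference), numeric(1))
    sims <- setNames(s, keep)
    bad <- !(s > config$tanimoto_cutoff)
    if (any(bad)) {
      excluded <- rbind(excluded,
                        data.frame(id = keep[bad], rule = "tanimoto",
                                   value = s[bad]))
    }
    keep <- keep[!bad]
  }
  retained <- candidates[candidates$id %in% keep, , drop = FALSE]
  report <- if (nrow(retained) > 0) {
    pred <- predict(model, retained)
    out <- data.frame(id = retained$id, role = retained$role,
                      as.data.frame(retained)[, model$descriptor_subset,
                                              drop = FALSE],
                      predicted_pic50 = pred, stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (!is.null(lip)) out$lipinski_violations <- lip[out$id]
    if (!is.null(sims)) out$tanimoto <- sims[out$id]
    out <- out[order(-out$predicted_pic50), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    warning("no candidate passed the filters; empty report", call. = FALSE)
    data.frame(id = character(), predicted_pic50 = numeric())
  }
  rownames(excluded) <- NULL
  structure(list(report = report, excluded = excluded,
                 model_id = model$model_id),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screen report (model ", x$model_id, "): ", nrow(x$report),
      " candidate(s) retained, ", nrow(x$excluded), " excluded\n", sep = "")
  print(x$report, ...)
  if (nrow(x$excluded) > 0) {
    cat("Excluded:\n")
    print(x$excluded, ...)
  }
  invisible(x)
}
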