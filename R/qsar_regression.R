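#' Pearson correlation with degenerate-input checking
#'
#' Sample Pearson correlation between two vectors,
#' `sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sd(x) * sd(y))`. Unlike
#' [stats::cor()], constant input raises an error instead of returning `NA`,
#' because a zero-variance descriptor carries no information for selection
#' and should be caught loudly.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' tr <- cox2_training_set()
#' round(pearson(tr$ATM, tr$pic50), 4)  # 0.7651
pearson <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("x and y must be numeric vectors of equal length", call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate input: zero sample variance", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sd(x) * sd(y))
  min(1, max(-1, r))
}

#' Descriptor/activity correlation report
#'
#' Computes the pairwise Pearson correlation matrix among the descriptors of
#' a compound table and the correlation of each descriptor with pIC50, the
#' quantities used to pre-select descriptors before model enumeration.
#'
#' @param table A [compound_table()] whose rows carry `pic50` and complete
#'   descriptors (at least 3 rows).
#' @param cutoff Non-negative selection threshold on `|r|` against activity
#'   (default 0.4). Stored in the report and consumed by
#'   [select_descriptors()].
#' @return An object of class `correlation_report`: list with
#'   `descriptor_names`, `pairwise` (symmetric matrix, unit diagonal),
#'   `vs_activity` (named vector) and `cutoff`.
#' @export
#' @examples
#' rep <- correlation_report(cox2_training_set(), cutoff = 0.4)
#' round(rep$vs_activity, 4)
correlation_report <- function(table, cutoff = 0.4) {
  stopifnot(inherits(table, "compound_table"))
  if (!"pic50" %in% names(table) || anyNA(table$pic50)) {
    stop("table must carry pic50 for every compound", call. = FALSE)
  }
  if (nrow(table) < 3) stop("need at least 3 compounds", call. = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0) {
    stop("cutoff must be a single non-negative number", call. = FALSE)
  }
  dn <- descriptor_names(table)
  for (d in dn) {
    if (sd(table[[d]]) == 0) {
      stop("descriptor '", d, "' is constant: zero sample variance",
           call. = FALSE)
    }
  }
  k <- length(dn)
  pairwise <- diag(1, k)
  dimnames(pairwise) <- list(dn, dn)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        pairwise[i, j] <- pairwise[j, i] <- pearson(table[[dn[i]]],
                                                    table[[dn[j]]])
      }
    }
  }
  vs <- vapply(dn, function(d) pearson(table[[d]], table$pic50), numeric(1))
  structure(list(descriptor_names = dn, pairwise = pairwise,
                 vs_activity = vs, cutoff = cutoff, n = nrow(table)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Correlation report (n = ", x$n, ", cutoff |r| >= ", x$cutoff, ")\n",
      sep = "")
  cat("vs pIC50:\n")
  print(round(x$vs_activity, 4))
  cat("pairwise:\n")
  print(round(x$pairwise, 4))
  invisible(x)
}

#' Select descriptors by correlation with activity
#'
#' Retains the descriptors whose absolute correlation with pIC50 meets the
#' report's cutoff, preserving input order. Selection is sign-blind: a
#' strongly anticorrelated descriptor (e.g. an H-bond acceptor count) is as
#' informative as a positively correlated one.
#'
#' @param report A [correlation_report()].
#' @return Character vector of retained descriptor names.
#' @export
select_descriptors <- function(report) {
  stopifnot(inherits(report, "correlation_report"))
  keep <- report$descriptor_names[abs(report$vs_activity) >= report$cutoff]
  if (length(keep) == 0) {
    stop("no descriptor passes |r| >= ", report$cutoff,
         "; modelling cannot proceed", call. = FALSE)
  }
  keep
}

#' Enumerate descriptor subsets of a given size
#'
#' All `choose(n, p)` subsets of `p` descriptors, in lexicographic order of
#' member indices, without repetition.
#'
#' @param descriptors Character vector of descriptor names.
#' @param p Subset size, `1 <= p <= length(descriptors)`.
#' @return List of character vectors.
#' @export
#' @examples
#' length(enumerate_subsets(c("ATM", "ARO", "DONN", "ACC"), 2))  # 6
enumerate_subsets <- function(descriptors, p) {
  n <- length(descriptors)
  if (!is.numeric(p) || length(p) != 1 || p != round(p) || p < 1 || p > n) {
    stop("p must be an integer in 1..", n, call. = FALSE)
  }
  idx <- combn(n, p, simplify = FALSE)
  lapply(idx, function(i) descriptors[i])
}

#' Fit a descriptor-subset MLR activity model
#'
#' Ordinary least squares of pIC50 on the chosen descriptor columns
#' (intercept included), with the usual regression quality statistics:
#' `R2 = 1 - SSE/SST`, `R = sqrt(R2)` (multiple correlation, non-negative),
#' `R2_adj = 1 - (1 - R2) (n - 1)/(n - p - 1)`,
#' `SEE = sqrt(SSE/(n - p - 1))` and
#' `F = (R2/p) / ((1 - R2)/(n - p - 1))`.
#'
#' @param table A [compound_table()] with `pic50` for every row.
#' @param subset Character vector of descriptor names to use as predictors.
#' @return An object of class `qsar_model`: list with `descriptor_subset`,
#'   `intercept`, `coefficients` (named), `n_train`, `stats` (R, R2, R2_adj,
#'   SEE, F) and `model_id` (e.g. `"ATM+ACC+DONN+ARO"`).
#' @export
#' @examples
#' m <- fit_mlr(cox2_training_set(), c("ATM", "ACC", "DONN", "ARO"))
#' round(m$stats$R2, 4)  # 0.9250
fit_mlr <- function(table, subset) {
  stopifnot(inherits(table, "compound_table"))
  if (!"pic50" %in% names(table) || anyNA(table$pic50)) {
    stop("table must carry pic50 for every compound", call. = FALSE)
  }
  missing_d <- setdiff(subset, descriptor_names(table))
  if (length(missing_d) > 0) {
    stop("not a descriptor of this table: ",
         paste(missing_d, collapse = ", "), call. = FALSE)
  }
  n <- nrow(table)
  p <- length(subset)
  if (n <= p + 1) {
    stop("insufficient degrees of freedom: n = ", n, " compounds for p = ",
         p, " descriptors (need n > p + 1)", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(table)[, subset, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("collinear design: column(s) ", paste(dep, collapse = ", "),
         " linearly dependent on the others", call. = FALSE)
  }
  dat <- data.frame(pic50 = table$pic50,
                    as.data.frame(table)[, subset, drop = FALSE],
                    check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", subset), response = "pic50")
  fit <- lm(fml, data = dat)
  y <- dat$pic50
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  stats <- list(R = sqrt(max(0, r2)),
                R2 = r2,
                R2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
                SEE = sqrt(sse / (n - p - 1)),
                F = (r2 / p) / ((1 - r2) / (n - p - 1)))
  cf <- coef(fit)
  structure(list(descriptor_subset = subset,
                 intercept = unname(cf[1]),
                 coefficients = setNames(unname(cf[-1]), subset),
                 n_train = n,
                 stats = stats,
                 model_id = paste(subset, collapse = "+"),
                 source = "fitted"),
            class = "qsar_model")
}

#' Build a prediction equation from published coefficients
#'
#' Wraps an intercept and named coefficients (typically coefficients as
#' printed in a paper, rounded to 4 decimals) into a `qsar_model` that can
#' be evaluated with [predict()] but carries no fit statistics. This is the
#' "as-printed" evaluation mode used to check predictions against published
#' tables at their printed precision.
#'
#' @param intercept Intercept of the affine equation.
#' @param coefficients Named numeric vector, one entry per descriptor.
#' @param id Optional model identifier; defaults to the joined subset names.
#' @return A `qsar_model`.
#' @export
#' @examples
#' eq <- qsar_equation(6.1250, c(ATM = 0.0907, ACC = -0.3721,
#'                               DONN = 0.3766, ARO = -0.0674))
#' predict(eq, list(ATM = 36, ARO = 2, DONN = 0, ACC = 4))  # 7.767
qsar_equation <- function(intercept, coefficients, id = NULL) {
  if (!is.numeric(intercept) || length(intercept) != 1 || is.na(intercept)) {
    stop("intercept must be a single number", call. = FALSE)
  }
  if (!is.numeric(coefficients) || is.null(names(coefficients)) ||
      any(!nzchar(names(coefficients))) || anyNA(coefficients)) {
    stop("coefficients must be a fully named numeric vector", call. = FALSE)
  }
  subset <- names(coefficients)
  structure(list(descriptor_subset = subset,
                 intercept = intercept,
                 coefficients = coefficients,
                 n_train = NA_integer_,
                 stats = NULL,
                 model_id = if (is.null(id)) paste(subset, collapse = "+") else id,
                 source = "printed"),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, digits = 4, ...) {
  terms <- sprintf("(%s × %s)", formatC(x$coefficients, format = "f",
                                             digits = digits),
                   names(x$coefficients))
  cat("QSAR model [", x$model_id, "]\n", sep = "")
  cat("  pIC50 = ", formatC(x$intercept, format = "f", digits = digits),
      " + ", paste(terms, collapse = " + "), "\n", sep = "")
  if (!is.null(x$stats)) {
    with(x$stats, cat(sprintf(
      "  n = %d  R = %.4f  R2 = %.4f  adj-R2 = %.4f  SEE = %.4f  F = %.4f\n",
      x$n_train, R, R2, R2_adj, SEE, F)))
  }
  invisible(x)
}

#' Predict pIC50 from a model
#'
#' Pure affine evaluation `intercept + sum(coefficient * descriptor)`.
#'
#' @param object A `qsar_model` (fitted or as-printed).
#' @param newdata A named list/vector of descriptor values, a data frame, or
#'   a [compound_table()]; must cover the model's descriptor subset.
#' @param ... Unused.
#' @return Numeric vector of predicted pIC50, one per row of `newdata`.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata)) {
    newdata <- as.data.frame(newdata)
  }
  if (!is.data.frame(newdata)) {
    if (is.numeric(newdata) && !is.null(names(newdata))) {
      newdata <- as.data.frame(as.list(newdata))
    } else {
      stop("newdata must be a data frame or named numeric", call. = FALSE)
    }
  }
  missing_d <- setdiff(object$descriptor_subset, names(newdata))
  if (length(missing_d) > 0) {
    stop("missing descriptor(s): ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(newdata[, object$descriptor_subset, drop = FALSE])
  as.numeric(object$intercept + X %*% object$coefficients)
}

#' Exhaustive model leaderboard
#'
#' Fits an MLR model for every descriptor subset of size 1..`max_p`
#' (`2^n - 1` models for `n` descriptors at `max_p = n`) and ranks them.
#' Within each subset size, models are sorted by decreasing `rank_by`
#' (default R2); the overall ordering breaks ties by smaller subset size
#' then lexicographic model id.
#'
#' @param table A [compound_table()].
#' @param descriptors Descriptors to enumerate over; defaults to all
#'   descriptors of the table.
#' @param max_p Largest subset size (default all).
#' @param rank_by Ranking statistic: one of `"R2"`, `"R2_adj"`, `"SEE"`,
#'   `"F"` (`SEE` ranks ascending, the others descending).
#' @return A data frame of class `qsar_leaderboard` with columns `model_id`,
#'   `p`, `R`, `R2`, `R2_adj`, `SEE`, `F`, ordered best-first; the fitted
#'   `qsar_model` objects are in `attr(, "models")`, keyed by model id.
#' @export
#' @examples
#' lb <- model_leaderboard(cox2_training_set())
#' lb$model_id[1]  # best model
model_leaderboard <- function(table, descriptors = NULL, max_p = NULL,
                              rank_by = c("R2", "R2_adj", "SEE", "F")) {
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(table, "compound_table"))
  if (is.null(descriptors)) descriptors <- descriptor_names(table)
  if (is.null(max_p)) max_p <- length(descriptors)
  if (max_p < 1 || max_p > length(descriptors)) {
    stop("max_p must be in 1..", length(descriptors), call. = FALSE)
  }
  models <- list()
  rows <- list()
  for (p in seq_len(max_p)) {
    for (sub in enumerate_subsets(descriptors, p)) {
      m <- fit_mlr(table, sub)
      models[[m$model_id]] <- m
      rows[[m$model_id]] <- data.frame(model_id = m$model_id, p = p,
                                       R = m$stats$R, R2 = m$stats$R2,
                                       R2_adj = m$stats$R2_adj,
                                       SEE = m$stats$SEE, F = m$stats$F,
                                       stringsAsFactors = FALSE)
    }
  }
  lb <- do.call(rbind, rows)
  key <- if (rank_by == "SEE") lb$SEE else -lb[[rank_by]]
  lb <- lb[order(key, lb$p, lb$model_id), , drop = FALSE]
  rownames(lb) <- NULL
  structure(lb, models = models, rank_by = rank_by,
            class = c("qsar_leaderboard", "data.frame"))
}

#' Extract a fitted model from a leaderboard
#'
#' @param leaderboard A [model_leaderboard()] result.
#' @param model_id Model to extract; default the top-ranked one.
#' @return A `qsar_model`.
#' @export
leaderboard_model <- function(leaderboard, model_id = NULL) {
  stopifnot(inherits(leaderboard, "qsar_leaderboard"))
  models <- attr(leaderboard, "models", exact = TRUE)
  if (is.null(model_id)) model_id <- leaderboard$model_id[1]
  m <- models[[model_id]]
  if (is.null(m)) stop("no model '", model_id, "' on leaderboard",
                       call. = FALSE)
  m
}

#' Observed/predicted/residual records
#'
#' Evaluates each model on each compound of the table that carries an
#' observed pIC50 and tabulates the residual (observed minus predicted).
#'
#' @param table A [compound_table()] with `pic50`.
#' @param models A `qsar_model` or list of them.
#' @return Data frame with columns `compound_id`, `model_id`, `observed`,
#'   `predicted`, `residual`, one row per compound x model.
#' @export
residual_table <- function(table, models) {
  stopifnot(inherits(table, "compound_table"))
  if (inherits(models, "qsar_model")) models <- list(models)
  if (!"pic50" %in% names(table) || anyNA(table$pic50)) {
    stop("table must carry an observed pic50 for every compound",
         call. = FALSE)
  }
  out <- lapply(models, function(m) {
    pred <- predict(m, table)
    data.frame(compound_id = table$id, model_id = m$model_id,
               observed = table$pic50, predicted = pred,
               residual = table$pic50 - pred, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Partition prediction records by residual magnitude
#'
#' Splits a residual table into retained records and flagged anomalies
#' (`|residual| > threshold`), preserving order. A threshold of 0.4 pIC50
#' units is the conventional cut for detecting anomalous samples in this
#' workflow.
#'
#' @param records A data frame with a `residual` column (see
#'   [residual_table()]).
#' @param threshold Non-negative flagging threshold (default 0.4).
#' @return List with elements `retained` and `flagged`.
#' @export
flag_outliers <- function(records, threshold = 0.4) {
  stopifnot(is.data.frame(records), "residual" %in% names(records))
  if (anyNA(records$residual)) {
    stop("residuals must be present for every record", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  hit <- abs(records$residual) > threshold
  list(retained = records[!hit, , drop = FALSE],
       flagged = records[hit, , drop = FALSE])
}

#' External validation of a model
#'
#' Applies [residual_table()] to the `external_validation` rows of a table
#' and summarises the residuals, the robustness check performed on a
#' held-out set of roughly 20-30% of the original compounds.
#'
#' @param model A `qsar_model`.
#' @param table A [compound_table()] containing rows with role
#'   `external_validation` (other rows are ignored).
#' @return The residual data frame restricted to the external set, of class
#'   `external_validation`, with attributes `max_abs_residual` and
#'   `mean_abs_residual`.
#' @export
external_validation <- function(model, table) {
  stopifnot(inherits(table, "compound_table"))
  ext <- table[table$role == "external_validation", , drop = FALSE]
  if (nrow(ext) == 0) {
    stop("table has no external_validation compounds", call. = FALSE)
  }
  ext <- compound_table(as.data.frame(ext),
                        descriptor_names = descriptor_names(table),
                        check_consistency = FALSE)
  res <- residual_table(ext, model)
  structure(res,
            max_abs_residual = max(abs(res$residual)),
            mean_abs_residual = mean(abs(res$residual)),
            class = c("external_validation", "data.frame"))
}

#' @export
print.external_validation <- function(x, ...) {
  cat("External validation (", nrow(x), " compounds): max |residual| = ",
      round(attr(x, "max_abs_residual"), 4), ", mean |residual| = ",
      round(attr(x, "mean_abs_residual"), 4), "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Serialize models and leaderboards
#'
#' A `qsar_model` round-trips through a small JSON document (subset,
#' intercept, coefficients, statistics, training size); a leaderboard is
#' written as a flat CSV, one row per model.
#'
#' @param model A `qsar_model`.
#' @param leaderboard A `qsar_leaderboard`.
#' @param path Output file.
#' @return `path`, invisibly (`read_qsar_model()` returns the model).
#' @export
write_qsar_model <- function(model, path) {
  stopifnot(inherits(model, "qsar_model"))
  doc <- list(model_id = model$model_id,
              descriptor_subset = model$descriptor_subset,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              n_train = model$n_train,
              stats = model$stats,
              source = model$source)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_qsar_model
#' @export
read_qsar_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- structure(list(descriptor_subset = doc$descriptor_subset,
                      intercept = doc$intercept,
                      coefficients = unlist(doc$coefficients),
                      n_train = if (is.null(doc$n_train)) NA_integer_ else doc$n_train,
                      stats = doc$stats,
                      model_id = doc$model_id,
                      source = doc$source),
                 class = "qsar_model")
  m
}

#' @rdname write_qsar_model
#' @export
write_leaderboard <- function(leaderboard, path) {
  stopifnot(inherits(leaderboard, "qsar_leaderboard"))
  write.csv(as.data.frame(leaderboard), path, row.names = FALSE)
  invisible(path)
}
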