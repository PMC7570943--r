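#' Compound/descriptor/activity tables
#'
#' A compound table is a data frame with one row per molecule carrying an
#' `id` column, a `role` column (`pivot`, `training`, `internal_validation`,
#' `external_validation`, `candidate` or `control`), integer pharmacophore
#' descriptor counts (typically `ATM`, `ARO`, `DONN`, `ACC`), and optionally
#' the measured activity as `ic50_nM` (nanomolar) and/or `pic50`
#' (-log10 molar). IC50 is stored in nanomolar, the unit the source tables
#' use; conversion to molar happens only inside [pic50_from_ic50()].
#'
#' @param x A data frame with at least an `id` column.
#' @param descriptor_names Character vector naming the descriptor columns.
#'   Defaults to every column that is not one of the reserved columns
#'   (`id`, `name`, `role`, `ic50_nM`, `pic50`, `note`).
#' @param check_consistency Warn when a row's stored pIC50 disagrees with
#'   its IC50 (default `TRUE`; internal re-subsetting disables it so a known
#'   discrepancy is reported once, at read time).
#'
#' @details Validation enforced at construction: ids are unique; descriptor
#'   values are non-negative integers with no missing entries; `ic50_nM` is
#'   positive where present. When a row carries both `ic50_nM` and `pic50`,
#'   the stored pIC50 is checked against the recomputed value to 4 decimals;
#'   a mismatch raises a warning naming the compound (the packaged external
#'   validation set contains one such historical inconsistency for celecoxib,
#'   which is preserved verbatim rather than silently corrected).
#'
#' @return `x` with class `compound_table` and a `descriptor_names`
#'   attribute.
#' @seealso [read_compound_table()], [pic50_from_ic50()]
#' @export
#' @examples
#' tbl <- compound_table(data.frame(
#'   id = c("a", "b", "c"), ATM = c(30, 40, 35), ACC = c(2, 4, 3),
#'   ic50_nM = c(10, 1, 5)
#' ))
#' descriptor_names(tbl)
compound_table <- function(x, descriptor_names = NULL,
                           check_consistency = TRUE) {
  stopifnot(is.data.frame(x))
  if (!"id" %in% names(x)) {
    stop("compound table must have an 'id' column", call. = FALSE)
  }
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id)) {
    stop("compound ids must be unique; duplicated: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!"role" %in% names(x)) x$role <- "training"
  bad_role <- setdiff(unique(x$role), compound_roles())
  if (length(bad_role) > 0) {
    stop("unknown compound role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  reserved <- c("id", "name", "role", "ic50_nM", "pic50", "note")
  if (is.null(descriptor_names)) {
    descriptor_names <- setdiff(names(x), reserved)
  }
  missing_desc <- setdiff(descriptor_names, names(x))
  if (length(missing_desc) > 0) {
    stop("descriptor column(s) absent from table: ",
         paste(missing_desc, collapse = ", "), call. = FALSE)
  }
  for (d in descriptor_names) {
    v <- x[[d]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("descriptor '", d, "' must be numeric with no missing values",
           call. = FALSE)
    }
    if (any(v < 0) || any(abs(v - round(v)) > 1e-8)) {
      stop("descriptor '", d, "' must hold non-negative integer counts",
           call. = FALSE)
    }
    x[[d]] <- as.integer(round(v))
  }
  if ("ic50_nM" %in% names(x)) {
    bad <- !is.na(x$ic50_nM) & x$ic50_nM <= 0
    if (any(bad)) {
      stop("ic50_nM must be positive; offending id(s): ",
           paste(x$id[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (check_consistency && all(c("ic50_nM", "pic50") %in% names(x))) {
    both <- !is.na(x$ic50_nM) & !is.na(x$pic50)
    if (any(both)) {
      mism <- both & abs(x$pic50 - pic50_from_ic50(pmax(x$ic50_nM, 1e-300))) > 1e-4
      if (any(mism)) {
        warning("stored pIC50 disagrees with -log10(IC50 [M]) beyond 4 ",
                "decimals for: ", paste(x$id[mism], collapse = ", "),
                call. = FALSE)
      }
    }
  }
  structure(x,
            descriptor_names = descriptor_names,
            class = c("compound_table", "data.frame"))
}

compound_roles <- function() {
  c("pivot", "training", "internal_validation", "external_validation",
    "candidate", "control")
}

#' Descriptor columns of a compound table
#'
#' @param x A `compound_table`.
#' @return Character vector of descriptor column names, in table order.
#' @export
descriptor_names <- function(x) {
  attr(x, "descriptor_names", exact = TRUE)
}

#' @export
print.compound_table <- function(x, ...) {
  cat("Compound table: ", nrow(x), " compounds, descriptors [",
      paste(descriptor_names(x), collapse = ", "), "]\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read and write compound tables
#'
#' Reads a delimited text table (UTF-8, "." decimal separator) with a header
#' row naming at least `id` plus descriptor columns, and optionally `role`,
#' `ic50_nM` and/or `pic50`. Row order is preserved. Parsing is
#' locale-independent; a non-numeric cell in a numeric column is reported
#' with its row and column.
#'
#' @param path File to read or write.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @param descriptor_names Optional explicit descriptor column names; by
#'   default every non-reserved column is treated as a descriptor.
#' @return A [compound_table()].
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_compound_table(cox2_training_set(), p)
#' identical(nrow(read_compound_table(p)), 20L)
read_compound_table <- function(path, delim = ",", descriptor_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = delim, colClasses = "character",
                  check.names = FALSE, strip.white = TRUE,
                  fileEncoding = "UTF-8")
  if (!"id" %in% names(raw)) {
    stop("missing required column 'id' in ", path, call. = FALSE)
  }
  reserved_chr <- c("id", "name", "role", "note")
  for (col in setdiff(names(raw), reserved_chr)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad) > 0) {
      stop("non-numeric value '", raw[[col]][bad[1]], "' in column '", col,
           "', row ", bad[1], " of ", path, call. = FALSE)
    }
    raw[[col]] <- v
  }
  compound_table(raw, descriptor_names = descriptor_names)
}

#' @param x A `compound_table` to write.
#' @rdname read_compound_table
#' @export
write_compound_table <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "compound_table"))
  out <- as.data.frame(x)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, format = "f", digits = 6))
  write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert between IC50 (nM) and pIC50
#'
#' `pic50_from_ic50()` returns -log10 of the molar concentration,
#' `ic50_from_pic50()` inverts it back to nanomolar. An IC50 of 1 nM is a
#' pIC50 of 9; lower IC50 (more potent) gives higher pIC50.
#'
#' @param ic50_nM Positive half-maximal inhibitory concentration(s), in
#'   nanomolar.
#' @param pic50 Activity on the -log10 molar scale.
#' @return Numeric vector.
#' @export
#' @examples
#' pic50_from_ic50(12)  # 7.9208...
#' ic50_from_pic50(9)   # 1 nM
pic50_from_ic50 <- function(ic50_nM) {
  if (!is.numeric(ic50_nM) || anyNA(ic50_nM) || any(ic50_nM <= 0)) {
    stop("ic50_nM must be positive", call. = FALSE)
  }
  -log10(ic50_nM * 1e-9)
}

#' @rdname pic50_from_ic50
#' @export
ic50_from_pic50 <- function(pic50) {
  if (!is.numeric(pic50) || anyNA(pic50)) {
    stop("pic50 must be numeric", call. = FALSE)
  }
  10^(9 - pic50)
}
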