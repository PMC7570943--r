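#' Binary fingerprints
#'
#' A fingerprint is a fixed-length vector of 0/1 bits identifying which
#' structural features a molecule presents; two molecules are compared with
#' the Tanimoto index on their bit vectors.
#'
#' @param id Text identifier.
#' @param bits Vector of 0/1 values (numeric, integer or logical), length
#'   at least 1.
#' @return An object of class `fingerprint`.
#' @export
#' @examples
#' fingerprint("a", c(1, 1, 0, 0))
fingerprint <- function(id, bits) {
  if (is.logical(bits)) bits <- as.integer(bits)
  if (!is.numeric(bits) || length(bits) < 1 || anyNA(bits) ||
      !all(bits %in% c(0, 1))) {
    stop("bits must be a non-empty vector of 0/1 values", call. = FALSE)
  }
  structure(list(id = as.character(id), bits = as.integer(bits)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("Fingerprint ", x$id, ": ", length(x$bits), " bits, ",
      sum(x$bits), " set\n", sep = "")
  invisible(x)
}

#' Read and write fingerprint files
#'
#' Plain-text format: one record per line, `id<TAB>bitstring`, the
#' bitstring being a run of `0`/`1` characters.
#'
#' @param path File to read or write.
#' @param fps List of [fingerprint()] objects (for writing).
#' @return A named list of fingerprints (reading); `path` invisibly
#'   (writing).
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fps <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2 || grepl("[^01]", parts[2])) {
      stop("malformed fingerprint line: ", ln, call. = FALSE)
    }
    fingerprint(parts[1], as.integer(strsplit(parts[2], "")[[1]]))
  })
  names(fps) <- vapply(fps, `[[`, character(1), "id")
  fps
}

#' @rdname read_fingerprints
#' @export
write_fingerprints <- function(fps, path) {
  if (inherits(fps, "fingerprint")) fps <- list(fps)
  lines <- vapply(fps, function(f) {
    paste0(f$id, "\t", paste(f$bits, collapse = ""))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Tanimoto similarity between two fingerprints
#'
#' `M11 / (M01 + M10 + M11)` where `M11` counts positions set in both
#' fingerprints and `M01`/`M10` positions set in exactly one. Bits set in
#' neither do not contribute. If both fingerprints are all-zero the index is
#' undefined; 0 is returned with a warning so batch filtering stays total.
#'
#' @param a,b [fingerprint()] objects or bare 0/1 vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
tanimoto <- function(a, b) {
  bits <- function(x) if (inherits(x, "fingerprint")) x$bits else
    fingerprint("x", x)$bits
  va <- bits(a)
  vb <- bits(b)
  if (length(va) != length(vb)) {
    stop("fingerprint lengths differ (", length(va), " vs ", length(vb), ")",
         call. = FALSE)
  }
  m11 <- sum(va == 1 & vb == 1)
  union <- sum(va == 1 | vb == 1)
  if (union == 0) {
    warning("both fingerprints are all-zero; Tanimoto undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  m11 / union
}

#' Filter candidate fingerprints by similarity to a reference
#'
#' Retains candidates whose Tanimoto index against the reference is strictly
#' greater than the cutoff, in stable input order. 0.35 is the conventional
#' final cut of this workflow (0.3 is a documented looser alternative).
#'
#' @param candidates List of [fingerprint()] objects.
#' @param reference Reference [fingerprint()].
#' @param cutoff Similarity cutoff in `[0, 1]` (default 0.35); retention is
#'   strict (`similarity > cutoff`).
#' @return The retained sublist, with the per-candidate similarities of all
#'   candidates in `attr(, "similarity")`.
#' @export
filter_by_tanimoto <- function(candidates, reference, cutoff = 0.35) {
  if (inherits(candidates, "fingerprint")) candidates <- list(candidates)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a single number in [0, 1]", call. = FALSE)
  }
  sims <- vapply(candidates, function(f) tanimoto(f, reference), numeric(1))
  names(sims) <- vapply(candidates, function(f) {
    if (inherits(f, "fingerprint")) f$id else NA_character_
  }, character(1))
  keep <- candidates[sims > cutoff]
  structure(keep, similarity = sims)
}

#' Paired-atom coordinate sets
#'
#' An ordered list of atoms with Cartesian coordinates in Angstrom, used
#' for RMSD between two poses of the same molecule. Atoms are compared by
#' index; no superposition or atom matching is performed, so the two sets
#' must arrive pre-paired (as docking programs emit them).
#'
#' @param id Text identifier.
#' @param coords Numeric matrix with 3 columns (x, y, z), one row per atom.
#' @param elements Optional element symbols, recycled to the atom count.
#' @return An object of class `coordinate_set`.
#' @export
coordinate_set <- function(id, coords, elements = "C") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) < 1 || !is.numeric(coords) ||
      any(!is.finite(coords))) {
    stop("coords must be a finite numeric matrix with 3 columns and >= 1 row",
         call. = FALSE)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(id = as.character(id), coords = coords,
                 elements = rep_len(elements, nrow(coords))),
            class = "coordinate_set")
}

#' @export
print.coordinate_set <- function(x, ...) {
  cat("Coordinate set ", x$id, ": ", nrow(x$coords), " atoms\n", sep = "")
  invisible(x)
}

#' Read and write XYZ coordinate files
#'
#' Standard XYZ text layout: atom count on the first line, a comment line
#' (used as the set id), then one `element x y z` line per atom.
#'
#' @param path File to read or write.
#' @param x A [coordinate_set()] (for writing).
#' @return A `coordinate_set` (reading); `path` invisibly (writing).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || length(lines) < n + 2) {
    stop("malformed XYZ file: ", path, call. = FALSE)
  }
  id <- trimws(lines[2])
  atoms <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  el <- vapply(atoms, `[`, character(1), 1)
  xyz <- t(vapply(atoms, function(a) as.numeric(a[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric coordinate in ", path, call. = FALSE)
  coordinate_set(if (nzchar(id)) id else basename(path), xyz, el)
}

#' @rdname read_xyz
#' @export
write_xyz <- function(x, path) {
  stopifnot(inherits(x, "coordinate_set"))
  lines <- c(nrow(x$coords), x$id,
             sprintf("%s %.6f %.6f %.6f", x$elements,
                     x$coords[, 1], x$coords[, 2], x$coords[, 3]))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' `sqrt(mean(delta_i^2))` with `delta_i` the Euclidean distance between
#' atom `i` of each set, in Angstrom. Used to validate that a computed pose
#' reproduces a reference pose (values up to about 2 Angstrom are the usual
#' acceptance band in redocking validation).
#'
#' @param a,b [coordinate_set()] objects (or bare n x 3 matrices) with equal
#'   atom counts, index-paired.
#' @return Non-negative RMSD in Angstrom.
#' @export
#' @examples
#' a <- coordinate_set("ref", diag(3))
#' rmsd(a, a)  # 0
rmsd <- function(a, b) {
  mat <- function(x) if (inherits(x, "coordinate_set")) x$coords else
    coordinate_set("x", x)$coords
  ma <- mat(a)
  mb <- mat(b)
  if (nrow(ma) != nrow(mb)) {
    stop("atom counts differ (", nrow(ma), " vs ", nrow(mb), ")",
         call. = FALSE)
  }
  sqrt(mean(rowSums((ma - mb)^2)))
}

#' Lipinski rule-of-five violation count
#'
#' Counts how many of the four oral-bioavailability rules a compound
#' violates: molecular weight > 500 g/mol, logP > 5, H-bond donors > 5,
#' H-bond acceptors > 10. Zero violations is full compliance; one violation
#' is commonly still tolerated.
#'
#' @param mw Molecular weight(s), g/mol (> 0). Alternatively a data frame
#'   with columns `mw`, `logp` (or `milogp`), `n_hd`, `n_ha`, in which case
#'   the remaining arguments are ignored.
#' @param logp Octanol/water partition coefficient(s).
#' @param n_hd,n_ha Hydrogen-bond donor and acceptor counts (>= 0).
#' @return Integer vector of violation counts in 0..4.
#' @export
#' @examples
#' lipinski_violations(cox2_properties())  # all 0
lipinski_violations <- function(mw, logp = NULL, n_hd = NULL, n_ha = NULL) {
  if (is.data.frame(mw)) {
    p <- mw
    if (!"logp" %in% names(p) && "milogp" %in% names(p)) p$logp <- p$milogp
    need <- c("mw", "logp", "n_hd", "n_ha")
    missing_c <- setdiff(need, names(p))
    if (length(missing_c) > 0) {
      stop("property table lacks column(s): ",
           paste(missing_c, collapse = ", "), call. = FALSE)
    }
    mw <- p$mw; logp <- p$logp; n_hd <- p$n_hd; n_ha <- p$n_ha
  }
  if (any(mw <= 0) || any(n_hd < 0) || any(n_ha < 0)) {
    stop("invalid property profile: need mw > 0 and n_hd, n_ha >= 0",
         call. = FALSE)
  }
  as.integer((mw > 500) + (logp > 5) + (n_hd > 5) + (n_ha > 10))
}
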