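# Run expr under a local RNG seed, leaving the caller's random state intact.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification for a synthetic descriptor/activity table
#'
#' Describes a linear data-generating process with the statistical structure
#' the QSAR workflow assumes: integer descriptor counts drawn uniformly on
#' per-descriptor ranges, and pIC50 formed as an affine combination of the
#' descriptors plus additive Gaussian noise. Defaults mirror the packaged
#' training set: 20 compounds, descriptor ranges ATM 29-50, ARO 1-4,
#' DONN 0-3, ACC 2-5, the published four-descriptor equation as generating
#' coefficients, and a noise standard deviation of 0.22 pIC50 units (the
#' residual scale of the fitted model).
#'
#' @param n_compounds Number of rows (must exceed the descriptor count + 1).
#' @param descriptor_ranges Named list of integer `c(lo, hi)` ranges.
#' @param intercept,coefficients Generating equation; `coefficients` must be
#'   named after descriptors present in `descriptor_ranges`.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (>= 0; 0 gives an exact linear table).
#' @param seed Integer seed; generation is a pure function of spec + seed.
#' @return An object of class `linear_generator_spec`.
#' @export
linear_generator_spec <- function(n_compounds = 20,
                                  descriptor_ranges = list(
                                    ATM = c(29, 50), ARO = c(1, 4),
                                    DONN = c(0, 3), ACC = c(2, 5)),
                                  intercept = 6.1250,
                                  coefficients = c(ATM = 0.0907,
                                                   ACC = -0.3721,
                                                   DONN = 0.3766,
                                                   ARO = -0.0674),
                                  noise_sd = 0.22,
                                  seed = 1) {
  if (is.null(names(descriptor_ranges)) ||
      any(!nzchar(names(descriptor_ranges)))) {
    stop("descriptor_ranges must be a fully named list", call. = FALSE)
  }
  for (d in names(descriptor_ranges)) {
    r <- descriptor_ranges[[d]]
    if (length(r) != 2 || any(r != round(r)) || r[1] > r[2] || any(r < 0)) {
      stop("range for '", d, "' must be non-negative integers c(lo, hi) ",
           "with lo <= hi", call. = FALSE)
    }
  }
  bad <- setdiff(names(coefficients), names(descriptor_ranges))
  if (length(bad) > 0) {
    stop("coefficient(s) without a descriptor range: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- length(coefficients)
  if (n_compounds < p + 2) {
    stop("n_compounds must be at least ", p + 2, " for ", p, " descriptors",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    stop("noise_sd must be a single non-negative number", call. = FALSE)
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 descriptor_ranges = descriptor_ranges,
                 intercept = intercept, coefficients = coefficients,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "linear_generator_spec")
}

#' Generate a synthetic descriptor/activity table
#'
#' Draws descriptors uniformly on their integer ranges, sets
#' `pic50 = intercept + sum(coef * descriptor) + N(0, noise_sd)` and
#' back-computes `ic50_nM = 10^(9 - pic50)`. Bit-identical for the same
#' spec and seed. With `noise_sd = 0` the full pipeline (selection,
#' enumeration, fitting) recovers the generating coefficients exactly.
#'
#' @param spec A [linear_generator_spec()].
#' @return A [compound_table()] with role `training`.
#' @export
#' @examples
#' tbl <- generate_training_table(linear_generator_spec(noise_sd = 0))
#' fit_mlr(tbl, c("ATM", "ACC", "DONN", "ARO"))$stats$R2  # 1
generate_training_table <- function(spec) {
  stopifnot(inherits(spec, "linear_generator_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_compounds
    dn <- names(spec$descriptor_ranges)
    desc <- lapply(spec$descriptor_ranges, function(r) {
      sample(seq(r[1], r[2]), n, replace = TRUE)
    })
    X <- as.data.frame(desc)
    pic50 <- spec$intercept +
      as.numeric(as.matrix(X[, names(spec$coefficients), drop = FALSE]) %*%
                   spec$coefficients) +
      rnorm(n, 0, spec$noise_sd)
    df <- data.frame(id = sprintf("SYN%03d", seq_len(n)),
                     role = "training", X,
                     pic50 = pic50, ic50_nM = 10^(9 - pic50),
                     check.names = FALSE)
    compound_table(df, descriptor_names = dn)
  })
}

#' Generate random binary fingerprints
#'
#' Independent Bernoulli(`density`) bits, reproducible from the seed.
#'
#' @param n Number of fingerprints (>= 1).
#' @param length Bits per fingerprint (>= 1).
#' @param density Probability that a bit is set, strictly in (0, 1).
#' @param seed Integer seed.
#' @return Named list of [fingerprint()] objects (`FP001`, `FP002`, ...).
#' @export
generate_fingerprints <- function(n, length, density = 0.5, seed = 1) {
  if (n < 1 || length < 1) stop("n and length must be >= 1", call. = FALSE)
  if (!is.numeric(density) || density <= 0 || density >= 1) {
    stop("density must lie strictly in (0, 1)", call. = FALSE)
  }
  with_local_seed(seed, {
    fps <- lapply(seq_len(n), function(i) {
      fingerprint(sprintf("FP%03d", i),
                  as.integer(runif(length) < density))
    })
    names(fps) <- vapply(fps, `[[`, character(1), "id")
    fps
  })
}

#' Generate a perturbed coordinate pair
#'
#' A base conformation with atoms placed uniformly in a 20-Angstrom box and
#' a copy displaced by independent Gaussian noise per coordinate, emulating
#' a redocked pose against its crystallographic reference. For large atom
#' counts the expected RMSD approaches `displacement_sd * sqrt(3)`.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param displacement_sd Per-coordinate displacement standard deviation,
#'   Angstrom (>= 0).
#' @param seed Integer seed.
#' @return List of two [coordinate_set()]s, `reference` and `displaced`.
#' @export
#' @examples
#' pair <- generate_coordinate_pair(100, 0.5, seed = 7)
#' rmsd(pair$reference, pair$displaced)
generate_coordinate_pair <- function(n_atoms, displacement_sd, seed = 1) {
  if (n_atoms < 1) stop("n_atoms must be >= 1", call. = FALSE)
  if (!is.numeric(displacement_sd) || displacement_sd < 0) {
    stop("displacement_sd must be >= 0", call. = FALSE)
  }
  with_local_seed(seed, {
    base <- matrix(runif(n_atoms * 3, -10, 10), ncol = 3)
    disp <- base + matrix(rnorm(n_atoms * 3, 0, displacement_sd), ncol = 3)
    list(reference = coordinate_set("reference", base),
         displaced = coordinate_set("displaced", disp))
  })
}
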