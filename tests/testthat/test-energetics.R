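test_that("free energy from Ki follows both sign conventions", {
  expect_equal(delta_g_from_ki(1, 310), 0)
  # direct arithmetic: -(1.987e-3 * 310) * ln(3.1e-7)
  expected <- -(1.987e-3 * 310) * log(310e-9)
  expect_equal(delta_g_from_ki(310e-9, 310), expected, tolerance = 1e-12)
  expect_equal(round(expected, 3), 9.231)
  expect_equal(delta_g_from_ki(310e-9, 310, mode = "thermodynamic"),
               -expected, tolerance = 1e-12)
  expect_error(delta_g_from_ki(0), "positive")
  expect_error(delta_g_from_ki(1e-9, -5), "positive")
})

test_that("the two sign modes are exact negations and strictly monotone", {
  ki <- 10^seq(-9, -1, length.out = 25)
  printed <- delta_g_from_ki(ki, 298)
  thermo <- delta_g_from_ki(ki, 298, mode = "thermodynamic")
  expect_equal(printed, -thermo, tolerance = 1e-12)
  # -RT ln(ki) falls as ki rises; the thermodynamic form rises
  expect_true(all(diff(printed) < 0))
  expect_true(all(diff(thermo) > 0))
})

test_that("MM-GBSA binding energy sums per-term differences", {
  zero <- energy_terms("zero")
  cpx <- energy_terms("cpx", -12, -30, -25, 18, -2.5, minus_t_ds = 4)
  expect_equal(as.numeric(mmgbsa_bind(cpx, cpx, zero)), 0)

  # term differences (-10, -20, -30, +15, -3) plus -TdS difference +5
  complex <- energy_terms("c", -10, -20, -30, 15, -3, minus_t_ds = 5)
  res <- mmgbsa_bind(complex, zero, zero)
  expect_equal(as.numeric(res), -43)
  expect_true(attr(res, "entropy_included"))

  # absent entropy term contributes 0 and is flagged
  no_ent <- mmgbsa_bind(energy_terms("c", -10, -20, -30, 15, -3),
                        zero, zero)
  expect_equal(as.numeric(no_ent), -48)
  expect_false(attr(no_ent, "entropy_included"))

  # moving a value between term slots leaves the total unchanged
  perm <- mmgbsa_bind(energy_terms("c", -30, -20, -10, 15, -3,
                                   minus_t_ds = 5), zero, zero)
  expect_equal(as.numeric(perm), as.numeric(res))
})

test_that("binding energy is linear in the end-state terms", {
  set.seed(7)
  v <- rnorm(18)
  mk <- function(x, lab) energy_terms(lab, x[1], x[2], x[3], x[4], x[5],
                                      minus_t_ds = x[6])
  cpx <- mk(v[1:6], "c"); rec <- mk(v[7:12], "r"); lig <- mk(v[13:18], "l")
  base <- as.numeric(mmgbsa_bind(cpx, rec, lig))
  for (c_scale in c(-2, 0.5, 3)) {
    scaled <- as.numeric(mmgbsa_bind(mk(v[1:6] * c_scale, "c"),
                                     mk(v[7:12] * c_scale, "r"),
                                     mk(v[13:18] * c_scale, "l")))
    expect_equal(scaled, c_scale * base, tolerance = 1e-10)
  }
  # end-state path equals summing pre-differenced terms
  delta <- v[1:6] - v[7:12] - v[13:18]
  expect_equal(base, sum(delta), tolerance = 1e-10)
})

test_that("per-residue decomposition totals and orders contributions", {
  one <- decompose_per_residue(data.frame(
    residue = "Arg513", e_vdw = -1.0, e_elec = -0.5, e_pol = 0.3,
    e_np = -0.1))
  expect_equal(one$total, -1.3)
  zero <- decompose_per_residue(data.frame(
    residue = "Gly512", e_vdw = 0, e_elec = 0, e_pol = 0, e_np = 0))
  expect_equal(zero$total, 0)

  set.seed(3)
  many <- data.frame(residue = paste0("R", 1:8),
                     e_vdw = rnorm(8), e_elec = rnorm(8),
                     e_pol = rnorm(8), e_np = rnorm(8))
  dec <- decompose_per_residue(many)
  expect_false(is.unsorted(dec$total))
  expect_equal(sum(dec$total),
               sum(many$e_vdw + many$e_elec + many$e_pol + many$e_np),
               tolerance = 1e-12)
  expect_error(decompose_per_residue(rbind(many, many[1, ])), "duplicate")
})

test_that("selectivity ratios are reciprocal and sign-correct", {
  expect_equal(selectivity_ratio(-8.40, -8.40),
               c(cox2_over_cox1 = 1, cox1_over_cox2 = 1))
  r <- selectivity_ratio(-8.60, -6.80)
  expect_equal(unname(r), c(-8.60 / -6.80, -6.80 / -8.60))
  expect_true(all(r > 0))
  expect_equal(unname(r[1] * r[2]), 1, tolerance = 1e-12)
  expect_error(selectivity_ratio(-8, 0), "nonzero")
})

test_that("energy-term CSVs load into term sets", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("label,e_internal,e_ele,e_vdw,g_gb,g_np",
               "complex,-5,-10,-20,12,-2", "receptor,0,0,0,0,0"), p)
  terms <- read_energy_terms(p)
  expect_named(terms, c("complex", "receptor"))
  expect_true(is.na(terms$complex$minus_t_ds))
  expect_equal(as.numeric(mmgbsa_bind(terms$complex, terms$receptor,
                                      energy_terms("lig"))), -25)
  writeLines("label,e_internal", p)
  expect_error(read_energy_terms(p), "lacks column")
})
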