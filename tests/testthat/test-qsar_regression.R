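tr <- cox2_training_set()

test_that("pearson reproduces the descriptor/activity correlations", {
  expect_printed(pearson(tr$ATM, tr$pic50), 0.7651)
  expect_printed(pearson(tr$ACC, tr$pic50), -0.6399)
  v <- c(1, 5, 2, 8)
  expect_equal(pearson(v, v), 1)
  # agrees with stats::cor away from the degenerate cases
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(10)
    y <- rnorm(10)
    expect_equal(pearson(x, y), cor(x, y), tolerance = 1e-12)
  }
  expect_error(pearson(rep(1, 5), 1:5), "degenerate")
  expect_error(pearson(1:4, 1:3), "equal length")
  expect_error(pearson(1:2, 2:3), "at least 3")
})

test_that("correlation report matches the published correlation block", {
  rep <- correlation_report(tr, cutoff = 0.4)
  expect_printed(unname(rep$vs_activity),
                 c(0.7651, 0.7358, 0.4743, -0.6399))
  printed <- c(ATM_ARO = 0.5659, ATM_DONN = 0.2027, ATM_ACC = -0.2280,
               ARO_DONN = 0.3559, ARO_ACC = -0.6492, DONN_ACC = -0.0423)
  got <- c(rep$pairwise["ATM", "ARO"], rep$pairwise["ATM", "DONN"],
           rep$pairwise["ATM", "ACC"], rep$pairwise["ARO", "DONN"],
           rep$pairwise["ARO", "ACC"], rep$pairwise["DONN", "ACC"])
  expect_printed(got, unname(printed), tol = 2e-4)
  expect_equal(diag(rep$pairwise), setNames(rep(1, 4), rep$descriptor_names))
  expect_lt(max(abs(rep$pairwise - t(rep$pairwise))), 1e-12)

  one <- compound_table(data.frame(id = letters[1:5], ATM = c(1, 3, 2, 5, 4),
                                   pic50 = c(7, 8, 7.5, 9, 8.5)))
  expect_equal(correlation_report(one)$pairwise,
               matrix(1, 1, 1, dimnames = list("ATM", "ATM")))
  const <- compound_table(data.frame(id = letters[1:5], ATM = rep(2, 5),
                                     pic50 = c(7, 8, 7.5, 9, 8.5)))
  expect_error(correlation_report(const), "'ATM'.*zero sample variance")
})

test_that("descriptor selection is sign-blind and order-preserving", {
  rep <- correlation_report(tr, cutoff = 0.4)
  expect_equal(select_descriptors(rep), c("ATM", "ARO", "DONN", "ACC"))
  rep$cutoff <- 0
  expect_equal(select_descriptors(rep), c("ATM", "ARO", "DONN", "ACC"))
  rep$cutoff <- 0.7
  expect_equal(select_descriptors(rep), c("ATM", "ARO"))
  rep$cutoff <- 0.99
  expect_error(select_descriptors(rep), "no descriptor passes")
})

test_that("subset enumeration is exhaustive, ordered and counted", {
  d <- c("ATM", "ARO", "DONN", "ACC")
  expect_length(enumerate_subsets(d, 2), 6)
  expect_equal(enumerate_subsets(d, 4), list(d))
  # power set minus the empty set
  all_subsets <- unlist(lapply(1:4, function(p) enumerate_subsets(d, p)),
                        recursive = FALSE)
  expect_length(all_subsets, 15)
  expect_equal(anyDuplicated(vapply(all_subsets, paste, character(1),
                                    collapse = "+")), 0L)
  expect_equal(enumerate_subsets(d, 2)[[1]], c("ATM", "ARO"))
  expect_equal(enumerate_subsets(d, 2)[[6]], c("DONN", "ACC"))
  expect_error(enumerate_subsets(d, 0), "p must be")
  expect_error(enumerate_subsets(d, 5), "p must be")
})

test_that("MLR refits reproduce the published model statistics", {
  mono <- fit_mlr(tr, "ATM")
  expect_printed(unlist(mono$stats),
                 c(R = 0.7651, R2 = 0.5854, R2_adj = 0.5623, SEE = 0.4804,
                   F = 25.4183))
  tetra <- fit_mlr(tr, c("ATM", "ACC", "DONN", "ARO"))
  expect_printed(tetra$stats$R2, 0.9250)
  expect_printed(tetra$stats$SEE, 0.2238)
  expect_equal(tetra$n_train, 20L)
  expect_equal(names(tetra$coefficients), c("ATM", "ACC", "DONN", "ARO"))
})

test_that("a noiseless linear response is fitted perfectly", {
  df <- data.frame(id = paste0("c", 1:6), ATM = c(1, 4, 2, 6, 3, 5))
  df$pic50 <- 5 + 0.3 * df$ATM
  m <- fit_mlr(compound_table(df), "ATM")
  expect_equal(m$stats$R2, 1, tolerance = 1e-12)
  expect_equal(m$stats$SEE, 0, tolerance = 1e-8)
  expect_equal(unname(m$coefficients["ATM"]), 0.3, tolerance = 1e-10)
})

test_that("degenerate designs raise informative errors", {
  small <- compound_table(data.frame(id = paste0("c", 1:4),
                                     ATM = c(1, 2, 3, 4), ARO = c(2, 1, 4, 3),
                                     DONN = c(0, 1, 0, 1),
                                     pic50 = c(7, 8, 8.5, 9)))
  expect_error(fit_mlr(small, c("ATM", "ARO", "DONN")),
               "insufficient degrees of freedom")
  dup <- as.data.frame(tr)
  dup$ATM2 <- dup$ATM
  dup <- compound_table(dup, check_consistency = FALSE)
  expect_error(fit_mlr(dup, c("ATM", "ATM2")), "collinear.*ATM2")
  expect_error(fit_mlr(tr, "HYD"), "not a descriptor")
})

test_that("fitted coefficients agree with a normal-equations oracle", {
  for (seed in 1:4) {
    n <- sample(5:8, 1)
    tbl <- random_small_table(n, c("ATM", "ACC"), seed)
    m <- fit_mlr(tbl, c("ATM", "ACC"))
    oracle <- ols_oracle(as.data.frame(tbl)[, c("ATM", "ACC")], tbl$pic50)
    expect_equal(c(m$intercept, unname(m$coefficients)), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("prediction is affine evaluation of the printed equations", {
  eq <- cox2_equation("tetra")
  expect_equal(predict(eq, list(ATM = 36, ARO = 2, DONN = 0, ACC = 4)),
               7.7670, tolerance = 1e-9)
  expect_equal(predict(eq, list(ATM = 43, ARO = 2, DONN = 2, ACC = 3)),
               9.5272, tolerance = 1e-9)
  expect_equal(predict(eq, list(ATM = 0, ARO = 0, DONN = 0, ACC = 0)),
               6.1250)
  expect_error(predict(eq, list(ATM = 36, ARO = 2, DONN = 0)),
               "missing descriptor.*ACC")
  # vectorized over a table
  expect_equal(predict(cox2_equation("mono"), cox2_candidates()),
               cox2_candidates()$mono, tolerance = 1e-9)
})

test_that("residual records reproduce the published validation residuals", {
  eq <- cox2_equation("tetra")
  mol12 <- tr[tr$id == "12", , drop = FALSE]
  res <- residual_table(compound_table(as.data.frame(mol12)), eq)
  expect_equal(res$residual, 0.0020, tolerance = 1e-9)

  mono <- cox2_equation("mono")
  pivot <- residual_table(
    compound_table(as.data.frame(tr[tr$role == "pivot", ])), mono)
  expect_equal(pivot$predicted, 8.2562, tolerance = 1e-9)
  expect_equal(pivot$residual, -0.3354, tolerance = 1e-9)

  exact <- compound_table(data.frame(id = "x", ATM = 10,
                                     pic50 = 4.2566 + 0.1111 * 10))
  expect_equal(residual_table(exact, mono)$residual, 0, tolerance = 1e-12)
})

test_that("outlier flagging partitions by absolute residual", {
  pred <- cox2_prediction_tables()$training_internal
  internal <- pred[pred$role == "internal_validation", ]
  rec <- data.frame(compound_id = internal$id, model_id = "tetra",
                    observed = internal$observed,
                    predicted = internal$tetra, residual = internal$d_tetra)
  out <- flag_outliers(rec, threshold = 0.4)
  expect_equal(nrow(out$flagged), 5L)
  expect_equal(abs(out$flagged$residual),
               c(0.5944, 0.4464, 0.5269, 0.5120, 0.5972))
  expect_equal(nrow(flag_outliers(rec, Inf)$flagged), 0L)
  expect_equal(nrow(flag_outliers(rec, 0)$flagged),
               sum(rec$residual != 0))
})

test_that("external validation summarises held-out residuals", {
  eq <- cox2_equation("tetra")
  ev <- external_validation(eq, celecoxib_external())
  expect_equal(ev$residual, 0.8449, tolerance = 1e-9)
  expect_equal(attr(ev, "max_abs_residual"), 0.8449, tolerance = 1e-9)
  expect_error(external_validation(eq, tr), "no external_validation")
  # external set identical to a training set gives the training residuals
  fake_ext <- as.data.frame(tr)
  fake_ext$role <- "external_validation"
  ev2 <- external_validation(eq, compound_table(fake_ext,
                                                check_consistency = FALSE))
  expect_equal(ev2$residual, residual_table(tr, eq)$residual)
})

test_that("model statistics are mutually consistent across the leaderboard", {
  lb <- model_leaderboard(tr)
  expect_equal(nrow(lb), 15L)  # 2^4 - 1 subsets
  n <- 20
  for (i in seq_len(nrow(lb))) {
    p <- lb$p[i]
    r2 <- lb$R2[i]
    expect_equal(lb$F[i], (r2 / p) / ((1 - r2) / (n - p - 1)),
                 tolerance = 1e-10)
    expect_equal(lb$R2_adj[i], 1 - (1 - r2) * (n - 1) / (n - p - 1),
                 tolerance = 1e-10)
    expect_equal(lb$R[i], sqrt(r2), tolerance = 1e-12)
    m <- leaderboard_model(lb, lb$model_id[i])
    res <- residual_table(tr, m)
    expect_lt(abs(sum(res$residual)), 1e-8)  # OLS residuals sum to zero
  }
  # mono model R equals |pearson| with the activity
  for (d in c("ATM", "ARO", "DONN", "ACC")) {
    expect_equal(leaderboard_model(lb, d)$stats$R,
                 abs(pearson(tr[[d]], tr$pic50)), tolerance = 1e-10)
  }
  # within each subset size the ranking key decreases
  for (p in 1:4) {
    expect_false(is.unsorted(rev(lb$R2[lb$p == p])))
  }
})

test_that("models serialize and round-trip through JSON", {
  m <- fit_mlr(tr, c("ATM", "ACC"))
  p <- tempfile(fileext = ".json")
  write_qsar_model(m, p)
  back <- read_qsar_model(p)
  expect_equal(back$model_id, m$model_id)
  expect_equal(predict(back, tr), predict(m, tr), tolerance = 1e-12)
  expect_equal(back$stats$R2, m$stats$R2, tolerance = 1e-12)
})
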