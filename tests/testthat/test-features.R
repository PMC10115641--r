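test_that("level metrics summarize a sample's positive somatic observations", {
  s <- mk_sample(afs = c(0.02, 0.01, 0.03))
  lv <- derive_level_metrics(s)
  expect_equal(lv[["mean_af"]], 0.02)
  expect_equal(lv[["max_af"]], 0.03)
  expect_equal(lv[["n_mut"]], 3)
  expect_equal(lv[["mtm"]], 0.02 * 10 / 0.0033)

  neg <- mk_sample()
  lvn <- derive_level_metrics(neg)
  expect_equal(lvn[["mtm"]], 0)
  expect_equal(lvn[["detected"]], 0)

  qcfail <- mk_sample(afs = 0.02, qc_pass = FALSE)
  expect_true(all(is.na(derive_level_metrics(qcfail))))
})

test_that("change metrics handle percent change, clearance and degenerate baselines", {
  cat <- metric_catalog()
  bl <- derive_level_metrics(mk_sample(afs = 0.0211, cfdna = 10))  # MTM 64.0
  tx <- derive_level_metrics(mk_sample(afs = 0.00634, cfdna = 10)) # MTM 19.2
  h <- data.frame(day = c(0, 42), mtm = c(bl[["mtm"]], tx[["mtm"]]))
  ch <- derive_change_metrics(bl, tx, h, cat)
  expect_equal(ch[["mtm_pct_change"]],
               100 * (tx[["mtm"]] - bl[["mtm"]]) / bl[["mtm"]])
  expect_equal(round(ch[["mtm_pct_change"]]), -70)

  # clearance below 1 MTM
  low <- derive_level_metrics(mk_sample(afs = numeric(0), mtm = 0.4))
  ch2 <- derive_change_metrics(bl, low, h, cat)
  expect_equal(ch2[["clearance"]], 1)

  # zero baseline: ratio metrics missing, absolute change still computed
  bl0 <- derive_level_metrics(mk_sample())
  tx5 <- derive_level_metrics(mk_sample(afs = 0.005, mtm = 5))
  ch3 <- derive_change_metrics(bl0, tx5, h, cat)
  expect_true(is.na(ch3[["mtm_pct_change"]]))
  expect_equal(ch3[["mtm_change"]], 5)
})

test_that("time-weighted MTM AUC is the trapezoid mean over the history", {
  cat <- metric_catalog()
  h <- data.frame(day = c(0, 21, 42), mtm = c(100, 50, 25))
  bl <- derive_level_metrics(mk_sample(afs = 0.033, mtm = 100))
  tx <- derive_level_metrics(mk_sample(afs = 0.008, mtm = 25))
  ch <- derive_change_metrics(bl, tx, h, cat)
  # oracle: (21*(100+50)/2 + 21*(50+25)/2) / 42
  expect_equal(ch[["auc_mtm"]], (21 * 75 + 21 * 37.5) / 42)
})

test_that("landmark assembly yields the catalog-determined column count", {
  proc <- processed_cohort(n = 30, seed = 8)
  cat <- metric_catalog()
  L <- length(cat$level); C <- length(cat$change)
  fm3 <- assemble_feature_matrix(proc, "C3D1", cat)
  expect_equal(ncol(fm3$x), L * 3 + C * 2)
  fm_bl <- assemble_feature_matrix(proc, "BL", cat)
  expect_equal(ncol(fm_bl$x), L)
  expect_error(assemble_feature_matrix(proc, "C9D9"), "unknown visit")

  # row present iff a landmark collection record exists
  with_c3 <- unique(proc$samples$patient_id[proc$samples$visit == "C3D1"])
  expect_setequal(rownames(fm3$x), with_c3)

  # QC-failed landmark sample keeps its row with missing ctDNA cells
  qcf <- proc$samples$patient_id[proc$samples$visit == "C3D1" &
                                   !proc$samples$qc_pass]
  if (length(qcf))
    expect_true(all(is.na(fm3$x[qcf[1], paste0("C3D1:", names(cat$level))])))
})

test_that("clinical columns include week-6 radiology at C3D1 landmarks", {
  proc <- processed_cohort(n = 30, seed = 8)
  fm <- assemble_feature_matrix(proc, "C3D1", include_clinical = TRUE)
  expect_true(all(c("clin:age", "clin:sld_bl", "clin:week6_sld_pct_change")
                  %in% colnames(fm$x)))
  fm_bl <- assemble_feature_matrix(proc, "BL", include_clinical = TRUE)
  expect_false("clin:week6_sld" %in% colnames(fm_bl$x))
})

test_that("median imputation fills from the fit population and keeps observed cells", {
  x <- matrix(c(1, 2, NA, 4,
                5, 5, 5, 5), ncol = 2,
              dimnames = list(paste0("p", 1:4), c("a", "b")))
  fm <- structure(list(x = x, mask = is.na(x)), class = "ctdna_features")
  imp <- impute_missing(fm)
  expect_equal(imp$x["p3", "a"], 2)  # median of {1,2,4}
  expect_identical(imp$x[c(1, 2, 4), ], x[c(1, 2, 4), ])
  expect_true(imp$mask["p3", "a"])

  # no missing -> identity
  fm2 <- structure(list(x = x[, 2, drop = FALSE], mask = is.na(x[, 2, drop = FALSE])),
                   class = "ctdna_features")
  expect_identical(impute_missing(fm2)$x, fm2$x)

  # all-missing column errors listing the feature
  x3 <- cbind(x, c = NA_real_)
  fm3 <- structure(list(x = x3, mask = is.na(x3)), class = "ctdna_features")
  expect_error(impute_missing(fm3), "c")

  # frozen medians from training apply to test without recomputation
  imp_frozen <- impute_missing(fm, medians = c(a = 99, b = 0))
  expect_equal(imp_frozen$x["p3", "a"], 99)
})

test_that("IQR scaling uses the stated quantile convention and freezes on train", {
  x <- matrix(0:100, ncol = 1, dimnames = list(NULL, "f"))
  fm <- structure(list(x = x, mask = is.na(x)), class = "ctdna_features")
  sc <- iqr_fit(fm)
  expect_equal(unname(sc$iqr["f"]), 50)  # linear-interpolation quartiles
  scaled <- iqr_apply(fm, sc)
  expect_equal(scaled$x[, "f"], (0:100) / 50, ignore_attr = TRUE)
  # scaled non-constant training features have IQR exactly 1
  expect_equal(diff(quantile(scaled$x[, "f"], c(0.25, 0.75), type = 7)),
               1, ignore_attr = TRUE)

  # constant features flagged, unscaled, with a warning
  xc <- cbind(x, k = 7)
  fmc <- structure(list(x = xc, mask = is.na(xc)), class = "ctdna_features")
  expect_warning(scc <- iqr_fit(fmc), "constant")
  expect_true(scc$constant[["k"]])
  expect_equal(iqr_apply(fmc, scc)$x[, "k"], rep(7, 101), ignore_attr = TRUE)

  # train scalers applied to test use the train IQR, not the test IQR
  test_fm <- structure(list(x = x * 10, mask = is.na(x)), class = "ctdna_features")
  expect_equal(iqr_apply(test_fm, sc)$x[, "f"], (0:100) * 10 / 50,
               ignore_attr = TRUE)
})

test_that("percent-change metrics are scale-invariant", {
  proc <- processed_cohort(n = 25, seed = 14)
  fm1 <- assemble_feature_matrix(proc, "C3D1")
  scaled <- proc
  scaled$samples$cfdna_ng_ml <- scaled$samples$cfdna_ng_ml * 3
  scaled$samples$mtm <- scaled$samples$mtm * 3
  fm2 <- assemble_feature_matrix(scaled, "C3D1")
  for (col in c("C3D1_change:mtm_pct_change", "C2D1_change:cfdna_conc_pct_change"))
    expect_equal(fm1$x[, col], fm2$x[, col])
})

test_that("feature columns depend on catalog and landmark, not data content", {
  a <- assemble_feature_matrix(processed_cohort(n = 20, seed = 1), "C2D1")
  b <- assemble_feature_matrix(processed_cohort(n = 35, seed = 99), "C2D1")
  expect_identical(colnames(a$x), colnames(b$x))
})
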