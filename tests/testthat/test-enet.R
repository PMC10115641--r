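# LOOCV elastic-net model, feature ranking, final fit and thresholds.

test_that("an informative feature is retained with positive gain and recovered sign", {
  sim <- sim_survival_matrix(n = 80, p = 6, beta = c(1, rep(0, 5)), seed = 301)
  fit <- loocv_enet_cox(sim$x, sim$data,
                        enet_control(nested_repeats = 3, seed = 302))
  rk <- rank_features(fit)
  expect_gte(rk$retention[rk$feature == "F01"], 0.5)
  expect_gt(rk$gain[rk$feature == "F01"], 0)
  expect_gt(fit$pooled_cindex$estimate, 0.55)

  final <- fit_final_model(sim$x, sim$data, rk$feature[rk$top])
  expect_gt(coef(final)[["F01"]], 0)
  expect_gte(final$train_cindex$estimate, 0.5)
})

test_that("all-constant features give empty selections and tie-convention c-index", {
  n <- 40
  x <- matrix(1, n, 3, dimnames = list(sprintf("P%02d", 1:n), c("a", "b", "c")))
  d <- data.frame(patient_id = rownames(x), time = rexp(n, 1 / 100),
                  event = rep(TRUE, n))
  fit <- loocv_enet_cox(x, d, enet_control(nested_repeats = 2, seed = 1))
  expect_true(all(vapply(fit$folds, function(f) length(f$selected) == 0,
                         logical(1))))
  expect_equal(unique(unname(fit$predictions)), 0)
  expect_equal(fit$pooled_cindex$estimate, 0.5)
})

test_that("too-small at-risk populations are refused", {
  sim <- sim_survival_matrix(n = 10, p = 3, seed = 5)
  expect_error(loocv_enet_cox(sim$x, sim$data, enet_control()), "at least 20")
})

test_that("fold preprocessing never uses held-out information", {
  sim <- sim_survival_matrix(n = 30, p = 4, seed = 7)
  x <- sim$x
  x[2, 2] <- NA  # exercise the imputation path
  train <- setdiff(seq_len(30), 5)
  prep1 <- ctdnakit:::fold_prepare(x, train)
  # perturb the held-out patient wildly: scalers must not move
  x2 <- x
  x2[5, ] <- x2[5, ] * 1000 + 99
  prep2 <- ctdnakit:::fold_prepare(x2, train)
  expect_identical(prep1$medians, prep2$medians)
  expect_identical(prep1$iqr, prep2$iqr)
  expect_identical(prep1$xtr, prep2$xtr)
  # held-out row is scaled with the training scalers
  expect_equal(prep2$xte, ((x2[5, , drop = FALSE] )) /
                 matrix(prep1$iqr, 1, 4), ignore_attr = TRUE)
})

test_that("retention arithmetic and never-selected features", {
  sim <- sim_survival_matrix(n = 40, p = 4, beta = c(2, 0, 0, 0), seed = 9)
  fit <- loocv_enet_cox(sim$x, sim$data,
                        enet_control(nested_repeats = 2, seed = 10))
  rk <- rank_features(fit)
  nf <- sum(!vapply(fit$folds, `[[`, logical(1), "flagged"))
  counts <- table(unlist(lapply(fit$folds, `[[`, "selected")))
  for (f in rk$feature[rk$retention > 0])
    expect_equal(rk$retention[rk$feature == f], counts[[f]] / nf)
  never <- rk$feature[rk$retention == 0]
  if (length(never)) {
    expect_true(all(is.na(rk$gain[rk$feature %in% never])))
    expect_false(any(rk$top[rk$feature %in% never]))
  }
})

test_that("final model predicts monotonically in a single feature", {
  sim <- sim_survival_matrix(n = 50, p = 3, beta = c(1.5, 0, 0), seed = 13)
  final <- fit_final_model(sim$x, sim$data, "F01")
  ord <- order(sim$x[, "F01"])
  expect_true(all(diff(predict(final, sim$x)[ord] *
                         sign(coef(final)[["F01"]])) >= 0))
  expect_error(fit_final_model(sim$x, sim$data, character(0)), "no features")
  expect_error(predict(final, sim$x[, 2:3]), "F01")
})

test_that("mPD threshold is the mean of the subgroup-optimal log-rank splits", {
  # constructed toy: scores perfectly separate short and long survivors at 0.5
  # in both subgroups, so the exhaustive split scan must choose 0.5 in each
  mk_group <- function(prefix, n = 24) {
    ids <- paste0(prefix, seq_len(n))
    sc <- c(seq(0.05, 0.45, length.out = n / 2),
            seq(0.55, 0.95, length.out = n / 2))
    # deterministic times: low scores survive long, high scores progress fast
    d <- data.frame(patient_id = ids,
                    time = c(400 + seq_len(n / 2), 20 + seq_len(n / 2)),
                    event = TRUE, stringsAsFactors = FALSE)
    list(scores = stats::setNames(sc, ids), data = d)
  }
  sdg <- mk_group("s"); prg <- mk_group("p")
  scores <- c(sdg$scores, prg$scores)
  recist <- stats::setNames(rep(c("SD", "PR"), each = 24), names(scores))
  thr <- select_mpd_threshold(scores, recist, rbind(sdg$data, prg$data))
  expect_equal(thr, 0.55)  # smallest score of the short-survivor side
  # subgroup optima averaging: shift the PR scores by +0.2
  prg2 <- prg; names(prg2$scores) <- names(prg$scores)
  prg2$scores <- prg2$scores + 0.2
  thr2 <- select_mpd_threshold(c(sdg$scores, prg2$scores), recist,
                               rbind(sdg$data, prg2$data))
  expect_equal(thr2, mean(c(0.55, 0.75)))
  # subgroup too small
  expect_error(select_mpd_threshold(sdg$scores[1:5],
                                    stats::setNames(rep("SD", 5),
                                                    names(sdg$scores)[1:5]),
                                    sdg$data[1:5, ]), "too small")
})

test_that("mResp threshold is the durable-survival percentile of the scores", {
  scores <- stats::setNames(as.numeric(1:100), paste0("p", 1:100))
  d <- data.frame(patient_id = names(scores),
                  time = c(rep(2000, 32), rep(100, 68)),
                  event = TRUE)
  thr <- select_mresp_threshold(scores, d)
  expect_equal(thr, unname(quantile(1:100, 0.32, type = 7)))
  # durable proportion one half on symmetric scores -> median
  d2 <- d; d2$time <- rep(c(2000, 100), 50)
  expect_equal(select_mresp_threshold(scores, d2), median(scores))
  # no durable survivors
  d3 <- d; d3$time <- rep(10, 100)
  expect_error(select_mresp_threshold(scores, d3), "durable")
})

test_that("molecular response binning follows the reference threshold rule", {
  m <- list(mresp_threshold = 0.036, mpd_threshold = 0.298)
  expect_equal(as.character(call_molecular_response(0.5, m)), "mPD")
  expect_equal(as.character(call_molecular_response(0.01, m)), "mResp")
  expect_equal(as.character(call_molecular_response(0.1, m)), "mSD")
  # boundaries belong to the higher-risk side
  expect_equal(as.character(call_molecular_response(0.036, m)), "mSD")
  expect_equal(as.character(call_molecular_response(0.298, m)), "mPD")
  expect_error(call_molecular_response(0.1, list(mresp_threshold = 0.4,
                                                 mpd_threshold = 0.3)),
               "below")
})

test_that("model transfer reproduces training scores and rejects missing features", {
  sim <- sim_survival_matrix(n = 60, p = 5, beta = c(1, 0.5, 0, 0, 0), seed = 19)
  final <- fit_final_model(sim$x, sim$data, c("F01", "F02"))
  final$mresp_threshold <- quantile(final$train_scores, 0.3)
  final$mpd_threshold <- quantile(final$train_scores, 0.7)
  tr <- transfer_model(final, sim$x)
  expect_equal(stats::setNames(tr$score, tr$patient_id), final$train_scores)
  expect_error(transfer_model(final, sim$x[, c("F01", "F03")]), "F02")
})

test_that("transferred calls stratify risk in an independently generated cohort", {
  sim <- sim_survival_matrix(n = 200, p = 4, beta = c(1.2, 0, 0, 0), seed = 23)
  final <- fit_final_model(sim$x[1:100, ], sim$data[1:100, ], c("F01", "F02"))
  final$mresp_threshold <- unname(quantile(final$train_scores, 0.32, type = 7))
  final$mpd_threshold <- unname(quantile(final$train_scores, 0.72, type = 7))
  # external cohort: the held-back half with shifted covariates
  ext_x <- sim$x[101:200, ]
  ext_d <- sim$data[101:200, ]
  tr <- transfer_model(final, ext_x)
  grp <- tr$call == "mPD"
  res <- km_cox_summary(grp, ext_d$time, ext_d$event)
  expect_gt(res$hr, 1)
  expect_lt(res$logrank_p, 0.05)
})
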