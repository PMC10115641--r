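#' Fit the final landmark survival model on the top features
#'
#' An unpenalized Cox proportional-hazards fit of the selected features on the
#' full (IQR-scaled) training set; the coefficients define the linear risk
#' score used for molecular response calling and external transfer. Higher
#' score means higher risk. If the fit is degenerate (collinear features,
#' non-convergence or undefined coefficients) a ridge-stabilized refit is
#' used with a warning.
#'
#' @param x Numeric feature matrix (imputed, IQR-scaled; rownames patient
#'   ids).
#' @param ld A [landmark_rebaseline()] result or data frame with
#'   `patient_id`, `time`, `event`.
#' @param features Character vector of model features (non-empty).
#' @return An object of class `ctdna_model`: `features`, `coefficients`,
#'   `train_cindex`, `mpd_threshold`/`mresp_threshold` (`NA` until set with
#'   [select_mpd_threshold()] / [select_mresp_threshold()]), and metadata.
#' @export
fit_final_model <- function(x, ld, features) {
  if (!length(features)) stop("no features to fit", call. = FALSE)
  d <- if (inherits(ld, "landmark_data")) ld$data else ld
  ids <- intersect(rownames(x), d$patient_id)
  d <- d[match(ids, d$patient_id), ]
  missing <- setdiff(features, colnames(x))
  if (length(missing))
    stop(sprintf("features absent from matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  xm <- x[ids, features, drop = FALSE]
  y <- survival::Surv(d$time, d$event)

  fit <- tryCatch(
    survival::coxph(y ~ xm, ties = "efron"),
    error = function(e) NULL, warning = function(w) NULL
  )
  coefs <- if (!is.null(fit)) stats::coef(fit) else NULL
  if (is.null(coefs) || any(is.na(coefs)) || any(abs(coefs) > 50)) {
    warning("degenerate final fit; using ridge-stabilized coefficients",
            call. = FALSE)
    rf <- glmnet::glmnet(xm, y, family = "cox", alpha = 0,
                         lambda = c(1, 0.1, 0.01))
    coefs <- drop(as.matrix(stats::coef(rf, s = 0.01)))
  }
  coefs <- stats::setNames(as.numeric(coefs), features)
  score <- drop(xm %*% coefs)
  ci <- concordance_index(score, d$time, d$event)
  structure(list(features = features, coefficients = coefs,
                 train_cindex = ci,
                 mpd_threshold = NA_real_, mresp_threshold = NA_real_,
                 train_scores = stats::setNames(score, ids),
                 endpoint = if (inherits(ld, "landmark_data")) ld$endpoint else NA,
                 n_train = length(ids)),
            class = "ctdna_model")
}

#' @export
print.ctdna_model <- function(x, ...) {
  cat(sprintf("ctDNA landmark risk model (%d features, n = %d)\n",
              length(x$features), x$n_train))
  for (f in x$features)
    cat(sprintf("  %-30s %+.4f\n", f, x$coefficients[[f]]))
  cat(sprintf("  training c-index %.3f\n", x$train_cindex$estimate))
  if (!is.na(x$mpd_threshold))
    cat(sprintf("  thresholds: mResp < %.4g <= mSD < %.4g <= mPD\n",
                x$mresp_threshold, x$mpd_threshold))
  invisible(x)
}

#' @export
summary.ctdna_model <- function(object, ...) {
  print(object)
  cat(sprintf("  c-index se %.4f, p vs 0.5 = %.3g\n",
              object$train_cindex$se, object$train_cindex$p_value))
  invisible(object)
}

#' @export
coef.ctdna_model <- function(object, ...) object$coefficients

#' Predict risk scores (and molecular response calls) from a fitted model
#'
#' @param object A `ctdna_model`.
#' @param newdata Numeric matrix (or `ctdna_features`) processed with the same
#'   censoring/imputation/IQR conventions as training; must contain all model
#'   features.
#' @param type `"score"` (linear risk score) or `"call"` (mPD/mSD/mResp).
#' @param ... Unused.
#' @return Named numeric scores, or a factor of risk calls.
#' @export
predict.ctdna_model <- function(object, newdata, type = c("score", "call"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "ctdna_features")) newdata$x else newdata
  missing <- setdiff(object$features, colnames(x))
  if (length(missing))
    stop(sprintf("matrix lacks model feature(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  score <- drop(x[, object$features, drop = FALSE] %*%
                  object$coefficients[object$features])
  if (type == "score") return(score)
  call_molecular_response(score, object)
}

#' Kaplan-Meier curves by molecular response group
#'
#' @param x A `ctdna_model` with thresholds set.
#' @param scores,time,event Evaluation scores and survival data (defaults to
#'   the training scores when only survival data are given).
#' @param ... Passed to `plot.survfit`.
#' @export
plot.ctdna_model <- function(x, scores = x$train_scores, time, event, ...) {
  calls <- call_molecular_response(scores, x)
  sf <- survival::survfit(survival::Surv(time, event) ~ calls)
  graphics::plot(sf, col = c("forestgreen", "orange", "red"), lwd = 2,
                 xlab = "days from landmark", ylab = "survival", ...)
  graphics::legend("topright", levels(calls), lwd = 2,
                   col = c("forestgreen", "orange", "red"), bty = "n")
  invisible(sf)
}

#' Choose the high-risk (mPD) score threshold
#'
#' Within the week-6 radiographic SD and PR subgroups separately, candidate
#' thresholds are the observed prediction values restricted to the interior
#' 10-90% quantile range; the optimal split maximizes the log-rank chi-square
#' of the induced two-group comparison (ties broken toward the smaller
#' threshold); the returned threshold is the mean of the two subgroup optima.
#'
#' @param scores Named prediction scores (names = patient ids).
#' @param recist_categories Named week-6 categories (`"SD"`, `"PR"`, ...).
#' @param ld Landmark survival data ([landmark_rebaseline()] result or data
#'   frame with `patient_id`, `time`, `event`).
#' @param min_subgroup Minimum at-risk patients per subgroup.
#' @return The mPD threshold (scores at or above it are called mPD).
#' @export
select_mpd_threshold <- function(scores, recist_categories, ld,
                                 min_subgroup = 10) {
  d <- if (inherits(ld, "landmark_data")) ld$data else ld
  optima <- vapply(c("SD", "PR"), function(g) {
    ids <- intersect(names(scores)[recist_categories[names(scores)] %in% g],
                     d$patient_id)
    if (length(ids) < min_subgroup)
      stop(sprintf("week-6 %s subgroup too small (%d < %d at risk)",
                   g, length(ids), min_subgroup), call. = FALSE)
    sc <- scores[ids]
    dd <- d[match(ids, d$patient_id), ]
    rng <- quantile7(sc, c(0.10, 0.90))
    cand <- sort(unique(sc[sc >= rng[1] & sc <= rng[2]]))
    cand <- cand[cand > min(sc)]  # both sides non-empty
    if (!length(cand))
      stop(sprintf("no interior candidate thresholds in subgroup %s", g),
           call. = FALSE)
    stat <- vapply(cand, function(thr) {
      grp <- sc >= thr
      if (!any(grp) || all(grp)) return(-Inf)
      sd_ <- tryCatch(
        survival::survdiff(survival::Surv(dd$time, dd$event) ~ grp),
        error = function(e) NULL
      )
      if (is.null(sd_)) -Inf else sd_$chisq
    }, numeric(1))
    cand[which.max(stat)]  # which.max takes the first, i.e. smaller, on ties
  }, numeric(1))
  mean(optima)
}

#' Choose the low-risk (mResp) score threshold
#'
#' The mResp threshold is the p-th percentile (linear interpolation) of the
#' training prediction scores, where p is the fraction of at-risk training
#' patients with observed survival of at least the durable horizon (3 years
#' by default). By construction the fraction of training patients called
#' mResp equals the durable-survival proportion up to one order-statistic
#' rank.
#'
#' @param scores Named prediction scores.
#' @param ld Landmark survival data.
#' @param durable_horizon_days Durable-survival horizon (default 36 months).
#' @return The mResp threshold (scores strictly below it are called mResp).
#' @export
select_mresp_threshold <- function(scores, ld,
                                   durable_horizon_days = 36 * DAYS_PER_MONTH) {
  if (!length(scores)) stop("no prediction scores", call. = FALSE)
  d <- if (inherits(ld, "landmark_data")) ld$data else ld
  d <- d[match(names(scores), d$patient_id), ]
  durable <- d$time >= durable_horizon_days
  p <- mean(durable)
  if (p == 0) stop("no durable survivors in the training set", call. = FALSE)
  quantile7(scores, p)
}

#' Bin a risk score into molecular response categories
#'
#' Score at or above the mPD threshold: molecular progressive disease (mPD);
#' strictly below the mResp threshold: molecular response (mResp); otherwise
#' molecular stable disease (mSD). Boundaries belong to the higher-risk side.
#'
#' @param score Numeric risk score(s).
#' @param model A `ctdna_model` with thresholds set, or a list/vector with
#'   `mresp_threshold` and `mpd_threshold`.
#' @return Factor with levels `mResp`, `mSD`, `mPD`.
#' @examples
#' m <- list(mresp_threshold = 0.036, mpd_threshold = 0.298)
#' call_molecular_response(c(0.5, 0.01, 0.036), m)  # mPD mResp mSD
#' @export
call_molecular_response <- function(score, model) {
  lo <- model$mresp_threshold
  hi <- model$mpd_threshold
  if (is.na(lo) || is.na(hi)) stop("thresholds not set", call. = FALSE)
  if (!(lo < hi)) stop("mresp_threshold must be below mpd_threshold", call. = FALSE)
  factor(ifelse(score >= hi, "mPD", ifelse(score < lo, "mResp", "mSD")),
         levels = c("mResp", "mSD", "mPD"))
}

#' Set both molecular-response thresholds on a fitted model
#'
#' Convenience wrapper running [select_mpd_threshold()] and
#' [select_mresp_threshold()] on the training scores.
#'
#' @param model A `ctdna_model`.
#' @param recist_categories Named week-6 categories for the mPD procedure.
#' @param ld Landmark survival data.
#' @param durable_horizon_days Passed to [select_mresp_threshold()].
#' @return The model with `mpd_threshold` and `mresp_threshold` set.
#' @export
set_thresholds <- function(model, recist_categories, ld,
                           durable_horizon_days = 36 * DAYS_PER_MONTH) {
  model$mpd_threshold <- select_mpd_threshold(model$train_scores,
                                              recist_categories, ld)
  model$mresp_threshold <- select_mresp_threshold(model$train_scores, ld,
                                                  durable_horizon_days)
  if (!(model$mresp_threshold < model$mpd_threshold))
    warning("mResp threshold not below mPD threshold; calls will error",
            call. = FALSE)
  model
}

#' Transfer a fitted model to an external cohort
#'
#' Applies the frozen coefficients and thresholds to an external feature
#' matrix that has been processed with the same censoring, imputation and
#' IQR conventions (the IQR scalers being fit on the external population).
#'
#' @param model A `ctdna_model` with thresholds set.
#' @param external A numeric matrix or `ctdna_features` containing all model
#'   features (an error lists any unmapped names).
#' @return Data frame with `patient_id`, `score`, `call`.
#' @export
transfer_model <- function(model, external) {
  score <- predict(model, external, type = "score")
  data.frame(patient_id = names(score) %||% seq_along(score),
             score = unname(score),
             call = call_molecular_response(score, model),
             stringsAsFactors = FALSE)
}
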