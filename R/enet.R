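#' Control parameters for the LOOCV elastic-net survival model
#'
#' @param alpha Elastic-net mixing weight; 0.5 gives equal lasso and ridge
#'   penalties.
#' @param nested_repeats Repeats of the nested k-fold cross-validation used to
#'   pick the penalty inside each leave-one-out fold; the error-minimizing
#'   lambda is averaged over repeats.
#' @param nested_k Folds of the nested cross-validation.
#' @param nlambda,lambda_min_ratio Length and span of the penalty path.
#' @param retention_threshold Minimum fraction of LOOCV folds a feature must
#'   be selected in to enter the top set.
#' @param min_at_risk Smallest at-risk sample size the model will fit.
#' @param seed Integer seed controlling the nested fold assignments.
#' @return A list of class `enet_control`.
#' @export
enet_control <- function(alpha = 0.5, nested_repeats = 10, nested_k = 5,
                         nlambda = 20, lambda_min_ratio = 0.05,
                         retention_threshold = 0.5, min_at_risk = 20,
                         seed = 1L) {
  if (alpha < 0 || alpha > 1) stop_config("alpha", "must be in [0, 1]")
  if (nested_repeats < 1) stop_config("nested_repeats", "must be >= 1")
  structure(list(alpha = alpha, nested_repeats = nested_repeats,
                 nested_k = nested_k, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 retention_threshold = retention_threshold,
                 min_at_risk = min_at_risk, seed = as.integer(seed)),
            class = "enet_control")
}

# Fold-local preprocessing: median imputation and IQR scaling are fit on the
# fold's training rows only and applied to the held-out rows, so no held-out
# information can leak into the scalers. Constant training columns are
# dropped for the fold.
fold_prepare <- function(x, train_idx) {
  xtr <- x[train_idx, , drop = FALSE]
  med <- apply(xtr, 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(xtr))) {
    m <- is.na(xtr[, j]); if (any(m)) xtr[m, j] <- med[[j]]
  }
  iqr <- apply(xtr, 2, function(col) diff(quantile7(col, c(0.25, 0.75))))
  keep <- which(!is.na(iqr) & iqr > 0)
  xtr <- sweep(xtr[, keep, drop = FALSE], 2, iqr[keep], "/")
  xte <- x[-train_idx, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    m <- is.na(xte[, j]); if (any(m)) xte[m, j] <- med[[keep[j]]]
    xte[, j] <- xte[, j] / iqr[keep[j]]
  }
  list(xtr = xtr, xte = xte, medians = med, iqr = iqr, keep = keep)
}

#' Leave-one-out cross-validated elastic-net Cox model
#'
#' For each leave-one-out fold: the feature matrix is imputed and IQR-scaled
#' on the fold's training portion; the penalty is chosen by nested k-fold
#' cross-validation of the partial-likelihood deviance, repeated
#' `nested_repeats` times with the error-minimizing lambda averaged across
#' repeats; the elastic-net Cox model is fit at that penalty; the held-out
#' patient receives the linear predictor. Pooling all held-out predictions
#' reconstructs the training set, on which the pooled concordance index is
#' computed. Per-fold feature selection and the next-door gain (worsening of
#' the fold's partial-likelihood deviance when a selected feature is forced
#' out and the model refit at the same penalty) feed [rank_features()].
#'
#' @param fm A `ctdna_features` object (raw; fold-wise preprocessing is
#'   internal) or a plain numeric matrix with patient-id rownames.
#' @param ld A [landmark_rebaseline()] result, or a data frame with
#'   `patient_id`, `time`, `event`.
#' @param control An [enet_control()].
#' @return An object of class `loocv_enet` with per-fold results, pooled
#'   held-out `predictions`, and `pooled_cindex`.
#' @export
loocv_enet_cox <- function(fm, ld, control = enet_control()) {
  x <- if (inherits(fm, "ctdna_features")) fm$x else fm
  d <- if (inherits(ld, "landmark_data")) ld$data else ld
  ids <- intersect(rownames(x), d$patient_id)
  if (length(ids) < control$min_at_risk)
    stop(sprintf("at least %d at-risk patients required (got %d)",
                 control$min_at_risk, length(ids)), call. = FALSE)
  x <- x[ids, , drop = FALSE]
  d <- d[match(ids, d$patient_id), ]
  y <- survival::Surv(d$time, d$event)
  n <- length(ids)

  set.seed(control$seed)
  fold_seeds <- sample.int(1e9L, n)

  folds <- vector("list", n)
  lp <- stats::setNames(rep(NA_real_, n), ids)
  for (i in seq_len(n)) {
    prep <- fold_prepare(x, setdiff(seq_len(n), i))
    ytr <- y[-i]
    res <- tryCatch(
      fit_one_fold(prep$xtr, ytr, control, fold_seeds[i]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      folds[[i]] <- list(selected = character(0), lambda = NA_real_,
                         gain = numeric(0), flagged = TRUE,
                         message = conditionMessage(res))
      next
    }
    lp[i] <- drop(prep$xte %*% res$beta[colnames(prep$xte)])
    folds[[i]] <- list(selected = res$selected, lambda = res$lambda,
                       gain = res$gain, flagged = FALSE)
  }

  ok <- !vapply(folds, `[[`, logical(1), "flagged")
  pooled <- concordance_index(lp[ok], d$time[ok], d$event[ok])
  structure(list(folds = folds, predictions = lp,
                 pooled_cindex = pooled,
                 feature_names = colnames(x),
                 data = d, control = control,
                 n_flagged = sum(!ok)),
            class = "loocv_enet")
}

# One LOOCV fold: nested repeated CV for lambda, elastic-net fit, next-door
# gains for the selected features.
fit_one_fold <- function(xtr, ytr, control, seed) {
  if (ncol(xtr) == 0L)
    return(list(selected = character(0), lambda = NA_real_,
                gain = numeric(0), beta = numeric(0)))
  fit0 <- glmnet::glmnet(xtr, ytr, family = "cox", alpha = control$alpha,
                         nlambda = control$nlambda,
                         lambda.min.ratio = control$lambda_min_ratio)
  set.seed(seed)
  ntr <- nrow(xtr)
  lams <- vapply(seq_len(control$nested_repeats), function(r) {
    foldid <- sample(rep(seq_len(control$nested_k), length.out = ntr))
    cv <- cv.glmnet_quiet(xtr, ytr, alpha = control$alpha,
                          lambda = fit0$lambda, foldid = foldid)
    cv$lambda.min
  }, numeric(1))
  lambda <- mean(lams)

  beta <- drop(as.matrix(stats::coef(fit0, s = lambda)))
  selected <- names(beta)[beta != 0]

  dev_full <- glmnet::coxnet.deviance(
    pred = stats::predict(fit0, xtr, s = lambda), y = ytr)
  # refit path truncated just below the fold's lambda: warm starts make the
  # short path cheap and the prediction at s = lambda stays interpolable
  lam_path <- c(fit0$lambda[fit0$lambda > lambda], lambda * c(1.0001, 1) )
  lam_path <- sort(unique(lam_path), decreasing = TRUE)
  gain <- stats::setNames(numeric(length(selected)), selected)
  for (f in selected) {
    fit_ex <- glmnet::glmnet(xtr, ytr, family = "cox", alpha = control$alpha,
                             lambda = lam_path,
                             exclude = match(f, colnames(xtr)))
    dev_ex <- glmnet::coxnet.deviance(
      pred = stats::predict(fit_ex, xtr, s = lambda), y = ytr)
    gain[f] <- dev_ex - dev_full
  }
  list(selected = selected, lambda = lambda, gain = gain, beta = beta)
}

cv.glmnet_quiet <- function(x, y, ...) {
  withCallingHandlers(
    glmnet::cv.glmnet(x, y, family = "cox", ...),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' @export
print.loocv_enet <- function(x, ...) {
  cat(sprintf("LOOCV elastic-net Cox model: %d folds (%d flagged)\n",
              length(x$folds), x$n_flagged))
  cat(sprintf("  pooled c-index %.3f (se %.3f, p vs 0.5 = %.3g)\n",
              x$pooled_cindex$estimate, x$pooled_cindex$se,
              x$pooled_cindex$p_value))
  top <- utils::head(rank_features(x), 5)
  cat("  top features by retention:\n")
  for (k in seq_len(nrow(top)))
    cat(sprintf("    %-28s retention %.2f  gain %+.2f\n",
                top$feature[k], top$retention[k], top$gain[k]))
  invisible(x)
}

#' Rank features by LOOCV retention and next-door gain
#'
#' Retention is the fraction of leave-one-out folds in which the feature was
#' selected; the gain is the mean, over selecting folds, of the worsening of
#' the partial-likelihood deviance when the feature is forced out and the
#' model refit at the fold's penalty. The top set contains features with
#' retention at or above the control threshold and positive gain.
#'
#' @param fit A [loocv_enet_cox()] result.
#' @return Data frame with `feature`, `retention`, `gain`, `top`, sorted by
#'   retention (features never selected have gain `NA` and are excluded from
#'   the top set).
#' @export
rank_features <- function(fit) {
  ok_folds <- Filter(function(f) !f$flagged, fit$folds)
  nf <- length(ok_folds)
  feats <- fit$feature_names
  sel_count <- gain_sum <- stats::setNames(numeric(length(feats)), feats)
  for (f in ok_folds) {
    sel_count[f$selected] <- sel_count[f$selected] + 1
    gain_sum[names(f$gain)] <- gain_sum[names(f$gain)] + f$gain
  }
  retention <- sel_count / nf
  gain <- ifelse(sel_count > 0, gain_sum / sel_count, NA_real_)
  out <- data.frame(feature = feats, retention = unname(retention),
                    gain = unname(gain), stringsAsFactors = FALSE)
  out$top <- out$retention >= fit$control$retention_threshold &
    !is.na(out$gain) & out$gain > 0
  out[order(-out$retention, -out$gain), , drop = FALSE]
}
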