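#' Two-group survival summary: hazard ratio, log-rank test, KM medians
#'
#' Univariable Cox proportional-hazards model (exact handling of tied event
#' times) with Wald 95% confidence interval, two-sided log-rank p-value, and
#' per-group Kaplan-Meier median survival (`NA` when the curve never reaches
#' 0.5).
#'
#' @param group Two-level grouping (factor or coercible); the hazard ratio is
#'   for the second level relative to the first.
#' @param time,event Survival data.
#' @return A list with `hr`, `ci_lower`, `ci_upper`, `logrank_p`, `medians`
#'   (named per group), `n`, `events`.
#' @export
km_cox_summary <- function(group, time, event) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop("exactly two groups required", call. = FALSE)
  ev_by_grp <- tapply(as.logical(event), group, sum)
  if (any(ev_by_grp == 0))
    stop("each group needs at least one event", call. = FALSE)
  y <- survival::Surv(time, event)
  cx <- survival::coxph(y ~ group, ties = "exact")
  hr <- unname(exp(stats::coef(cx)))
  se <- sqrt(unname(stats::vcov(cx)[1, 1]))
  ci <- exp(stats::coef(cx) + c(-1, 1) * stats::qnorm(0.975) * se)
  sd_ <- survival::survdiff(y ~ group)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  sf <- survival::survfit(y ~ group)
  med <- summary(sf)$table[, "median"]
  names(med) <- levels(group)
  list(hr = hr, ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
       logrank_p = p, medians = med, n = length(time),
       events = sum(as.logical(event)))
}

# One-sided log-rank p-value favoring the active arm (longer survival =
# fewer observed than expected events). Derived from the signed normal form
# of the log-rank statistic: z = (O_active - E_active) / sqrt(V); small p
# when the active arm does better. Degenerate inputs (no events, zero
# variance, or identical arms) return 1.
logrank_one_sided <- function(time, event, is_active) {
  event <- as.logical(event)
  if (!any(event) || !any(is_active) || all(is_active)) return(1)
  sd_ <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ is_active),
    error = function(e) NULL
  )
  if (is.null(sd_)) return(1)
  # row order follows factor levels FALSE, TRUE
  o <- sd_$obs[2]; e <- sd_$exp[2]
  v <- if (is.matrix(sd_$var)) sd_$var[2, 2] else sd_$var[2]
  if (!is.finite(v) || v <= 0) return(1)
  stats::pnorm((o - e) / sqrt(v))
}

# One-sided Fisher exact p-value that the active arm has MORE responders,
# computed as the exact hypergeometric upper tail P(X >= x_active) with the
# observed margins.
fisher_one_sided <- function(x_active, n_active, x_control, n_control) {
  m <- x_active + x_control
  stats::phyper(x_active - 1, m, n_active + n_control - m, n_active,
                lower.tail = FALSE)
}
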