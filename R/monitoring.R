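# Response calls and survival statistics from molecular scores: landmark
# median cuts, 75th-percentile fast-fail, change-direction grouping, limit
# of blank, Kaplan-Meier/log-rank, and multivariate Cox models.
#
# Survival time is measured from treatment initiation. Cut points are
# cohort-specific: a cut derived in one cohort is never transferred to
# another by default.

#' Assign roles to plasma draws relative to treatment start
#'
#' Baseline = latest draw on or before treatment start; fast-fail = first
#' draw after start; landmark = second draw after start. Duplicate-day
#' draws keep the first occurrence with a warning; patients missing a role
#' are flagged.
#'
#' @param draws Tibble: patient_id, draw_day (days relative to treatment
#'   start, or absolute when `treatment_start` is a column name).
#' @param treatment_start Day of treatment initiation (default 0), or the
#'   name of a column of `draws`.
#' @return `draws` with a `role` column
#'   (baseline/fast_fail/landmark/other/NA) plus attribute
#'   `patients_missing_roles`.
#' @export
select_timepoints <- function(draws, treatment_start = 0) {
  d <- tibble::as_tibble(draws)
  stopifnot(all(c("patient_id", "draw_day") %in% names(d)))
  if (is.character(treatment_start)) {
    start <- d[[treatment_start]]
  } else {
    start <- rep(treatment_start, nrow(d))
  }
  d$.rel <- d$draw_day - start
  dup <- duplicated(d[, c("patient_id", "draw_day")])
  if (any(dup)) {
    warn(sprintf("%d duplicate-day draw(s) dropped (earliest kept)",
                 sum(dup)))
    d <- d[!dup, ]
  }
  d <- d |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$.rel, .by_group = TRUE) |>
    dplyr::mutate(role = {
      r <- rep("other", dplyr::n())
      pre <- which(.data$.rel <= 0)
      if (length(pre)) r[max(pre)] <- "baseline"
      post <- which(.data$.rel > 0)
      if (length(post) >= 1) r[post[1]] <- "fast_fail"
      if (length(post) >= 2) r[post[2]] <- "landmark"
      r
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".rel")
  missing <- d |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      baseline = !"baseline" %in% .data$role,
      fast_fail = !"fast_fail" %in% .data$role,
      landmark = !"landmark" %in% .data$role, .groups = "drop") |>
    dplyr::filter(.data$baseline | .data$fast_fail | .data$landmark)
  attr(d, "patients_missing_roles") <- missing
  d
}

#' Landmark median-cut molecular response call
#'
#' The cut point is the cohort median of the landmark scores; patients
#' strictly below the cut are molecular responders, patients at or above
#' it (including ties at the cut) are nonresponders.
#'
#' @param data Tibble of landmark rows (one per patient).
#' @param score Unquoted score column.
#' @return `data` with a `group` factor
#'   (responder/nonresponder) appended; attribute `cut` holds the cut
#'   value.
#' @examples
#' d <- tibble::tibble(s = c(0.1, 0.2, 0.3, 0.4))
#' table(landmark_median_cut(d, s)$group)
#' @export
landmark_median_cut <- function(data, score) {
  s <- dplyr::pull(data, {{ score }})
  if (length(s) < 2 || anyNA(s)) {
    abort("need >= 2 non-missing landmark scores")
  }
  cut <- median(s)
  out <- dplyr::mutate(
    data,
    group = factor(dplyr::if_else(s < cut, "responder", "nonresponder"),
                   levels = c("nonresponder", "responder")))
  attr(out, "cut") <- cut
  out
}

#' Fast-fail call at the first on-treatment draw
#'
#' Flags patients whose score lies strictly above the cohort's
#' `q`-quantile (default 75th percentile, linear-interpolation convention)
#' as high — likely nonresponders after a single treatment cycle.
#'
#' @param data Tibble of first on-treatment rows.
#' @param score Unquoted score column.
#' @param q Quantile (default 0.75).
#' @param convention "linear" (R type 7) or "nearest_rank" (type 1); both
#'   give the same split on distinct scores at the default q.
#' @return `data` with a `group` factor (high/low); attribute `threshold`.
#' @export
fast_fail_cut <- function(data, score, q = 0.75,
                          convention = c("linear", "nearest_rank")) {
  convention <- match.arg(convention)
  s <- dplyr::pull(data, {{ score }})
  if (length(s) < 4 || anyNA(s)) {
    abort("need >= 4 non-missing scores for a quantile cut")
  }
  thr <- quantile(s, q, type = if (convention == "linear") 7 else 1,
                  names = FALSE)
  out <- dplyr::mutate(
    data,
    group = factor(dplyr::if_else(s > thr, "high", "low"),
                   levels = c("high", "low")))
  attr(out, "threshold") <- thr
  out
}

#' Classify score change direction between baseline and landmark
#'
#' Increasing iff the landmark score strictly exceeds baseline; equal
#' scores fall in the decreasing group and are flagged as ties.
#'
#' @param data Tibble with baseline and landmark score columns.
#' @param baseline,landmark Unquoted columns.
#' @return `data` with `direction` (increasing/decreasing) and `tie`
#'   columns.
#' @export
change_direction <- function(data, baseline, landmark) {
  b <- dplyr::pull(data, {{ baseline }})
  l <- dplyr::pull(data, {{ landmark }})
  if (anyNA(b) || anyNA(l)) abort("both scores must be present")
  dplyr::mutate(
    data,
    direction = factor(dplyr::if_else(l > b, "increasing", "decreasing"),
                       levels = c("increasing", "decreasing")),
    tie = l == b)
}

#' Limit of blank from analyte-negative samples
#'
#' The limit of blank (LoB) is the maximum score observed in designated
#' ctDNA-negative samples; a sample calls positive only when its score
#' strictly exceeds the LoB, so negatives have zero false positives by
#' construction.
#'
#' @param negative_scores Numeric scores of >= 3 negative samples.
#' @return The LoB (numeric scalar).
#' @export
limit_of_blank <- function(negative_scores) {
  s <- as.numeric(negative_scores)
  if (length(s) < 3 || anyNA(s)) {
    abort("need >= 3 non-missing negative-sample scores")
  }
  max(s)
}

#' @rdname limit_of_blank
#' @param scores Scores to call.
#' @param lob A limit of blank.
#' @return For `call_positive()`: logical vector, TRUE = positive.
#' @export
call_positive <- function(scores, lob) {
  scores > lob
}

#' Kaplan-Meier stratification with log-rank test and univariate Cox HR
#'
#' Product-limit median survival per group, two-group (or k-group)
#' log-rank statistic, and a univariate Cox hazard ratio with Wald CI for
#' the second group level relative to the first.
#'
#' @param data Cohort tibble, one row per patient.
#' @param time,event,group Unquoted columns: survival days (> 0), event
#'   flag (1 = event), group factor.
#' @param level CI level (default 0.95).
#' @return A `stratification_result`: `groups` tibble (group, n, events,
#'   median_survival), hr, ci_low, ci_high, logrank_chisq, logrank_p, and
#'   the underlying survfit.
#' @export
km_logrank <- function(data, time, event, group, level = 0.95) {
  df <- tibble::tibble(
    time = dplyr::pull(data, {{ time }}),
    event = as.integer(dplyr::pull(data, {{ event }})),
    group = dplyr::pull(data, {{ group }}))
  df <- df[complete.cases(df), ]
  if (any(df$time <= 0)) abort("survival times must be > 0")
  if (length(unique(df$group)) < 2) {
    abort("need at least two groups", class = "cfmonitor_single_group")
  }
  if (sum(df$event) < 1) {
    abort("no events observed; survival analysis is degenerate",
          class = "cfmonitor_no_events")
  }
  df$group <- droplevels(factor(df$group))
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(sd_$n)
  chisq <- sd_$chisq
  p <- pchisq(chisq, df = k - 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ group, data = df)
  z <- qnorm(1 - (1 - level) / 2)
  b <- coef(cx)[1]
  se <- sqrt(diag(cx$var))[1]
  med <- summary(sf)$table
  med_col <- if (is.matrix(med)) med[, "median"] else med["median"]
  grp_tab <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$event),
                     .groups = "drop")
  grp_tab$median_survival <- as.numeric(med_col)
  structure(list(
    groups = grp_tab,
    hr = exp(unname(b)),
    ci_low = exp(unname(b - z * se)),
    ci_high = exp(unname(b + z * se)),
    logrank_chisq = unname(chisq),
    logrank_p = unname(p),
    level = level,
    survfit = sf,
    data = df
  ), class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat("<stratification_result>\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  cat(sprintf("  HR %.3g (%g%% CI %.3g-%.3g), log-rank chisq %.3g, p %.3g\n",
              x$hr, 100 * x$level, x$ci_low, x$ci_high,
              x$logrank_chisq, x$logrank_p))
  invisible(x)
}

#' @export
tidy.stratification_result <- function(x, ...) {
  x$groups
}

#' @export
glance.stratification_result <- function(x, ...) {
  tibble::tibble(hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high,
                 logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p)
}

#' @describeIn km_logrank Kaplan-Meier curves per group.
#' @param object A `stratification_result`.
#' @param ... Unused.
#' @export
autoplot.stratification_result <- function(object, ...) {
  sf <- object$survfit
  strata <- rep(names(sf$strata), sf$strata)
  df <- tibble::tibble(
    time = sf$time, surv = sf$surv,
    group = sub("^group=", "", strata))
  base <- tibble::tibble(time = 0, surv = 1,
                         group = unique(df$group))
  df <- dplyr::bind_rows(base, df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days from treatment start",
                  y = "survival probability", color = NULL) +
    ggplot2::theme_minimal()
}

#' Multivariate Cox proportional-hazards model
#'
#' Fits overall survival against molecular scores and clinical covariates.
#' Covariates constant across patients are dropped with a warning (in
#' cohorts where, e.g., no patient has elevated bilirubin the term is
#' inestimable); duplicated (perfectly collinear) covariate columns are an
#' error. Continuous scores can be standardized (z-transform) before
#' entry, the convention for genome-wide MAF scores; probability-scale
#' ensemble scores enter raw.
#'
#' @param data Cohort tibble, one row per patient.
#' @param time,event Column names (strings) of survival days and event
#'   flag.
#' @param covariates Character vector of covariate column names.
#' @param standardize Character vector of covariates to z-transform.
#' @param level CI level.
#' @return A `cfm_cox` object; `tidy()` gives per-term HR, CI and p.
#' @export
cox_multivariate <- function(data, time, event, covariates,
                             standardize = character(), level = 0.95) {
  df <- tibble::as_tibble(data)
  stopifnot(all(c(time, event, covariates) %in% names(df)))
  if (sum(df[[event]], na.rm = TRUE) < 1) {
    abort("no events", class = "cfmonitor_no_events")
  }
  dropped <- character(0)
  for (cv in covariates) {
    v <- df[[cv]]
    if (length(unique(v[!is.na(v)])) < 2) {
      dropped <- c(dropped, cv)
    }
  }
  if (length(dropped)) {
    warn(paste0("dropping constant covariate(s): ",
                paste(dropped, collapse = ", ")))
    covariates <- setdiff(covariates, dropped)
  }
  if (!length(covariates)) abort("no usable covariates")
  # duplicated numeric columns => perfect collinearity
  num <- covariates[vapply(df[covariates], is.numeric, TRUE)]
  if (length(num) > 1) {
    mat <- as.matrix(df[num])
    cc <- suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    if (any(abs(cc) > 0.999)) {
      abort("collinear covariates detected",
            class = "cfmonitor_collinear")
    }
  }
  for (cv in intersect(standardize, covariates)) {
    df[[cv]] <- as.numeric(scale(df[[cv]]))
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  structure(list(fit = fit, covariates = covariates, dropped = dropped,
                 standardized = intersect(standardize, covariates),
                 level = level),
            class = "cfm_cox")
}

#' @export
tidy.cfm_cox <- function(x, ...) {
  fit <- x$fit
  b <- coef(fit)
  se <- sqrt(diag(fit$var))
  z <- qnorm(1 - (1 - x$level) / 2)
  tibble::tibble(
    term = names(b),
    estimate = unname(exp(b)),
    log_hr = unname(b),
    std_error = unname(se),
    ci_low = unname(exp(b - z * se)),
    ci_high = unname(exp(b + z * se)),
    p_value = unname(2 * pnorm(-abs(b / se))))
}

#' @export
glance.cfm_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n = s$n, n_events = s$nevent,
    concordance = unname(s$concordance[1]),
    logtest_p = unname(s$logtest["pvalue"]))
}

#' @export
print.cfm_cox <- function(x, ...) {
  cat("<cfm_cox> multivariate proportional-hazards fit\n")
  print(as.data.frame(tidy(x)), row.names = FALSE, digits = 3)
  if (length(x$dropped)) {
    cat("  dropped constant covariates:",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
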