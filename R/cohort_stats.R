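#' Per-subject percent change between conditions
#'
#' 100 * (exercise - rest) / rest, computed per subject. Group
#' summaries of exercise response must average these per-subject
#' changes, not take the percent change of group means (the two differ
#' whenever baselines and changes correlate).
#'
#' @param rest Rest-condition values (nonzero).
#' @param exercise Exercise-condition values, same length.
#' @return Percent change, same length.
#' @export
percent_change <- function(rest, exercise) {
  if (length(rest) != length(exercise))
    stop("rest and exercise must have equal length")
  if (any(rest == 0, na.rm = TRUE))
    stop("undefined-change error: rest value of zero")
  100 * (exercise - rest) / rest
}

#' Age-adjusted two-group comparison by linear regression
#'
#' Ordinary least squares of y on an intercept, age, and a 0/1 group
#' dummy (term = 0, preterm = 1), so the group coefficient is the
#' adjusted preterm-minus-term difference. Solved by QR decomposition.
#' The group effect is tested with a two-sided t test (n - 3 residual
#' degrees of freedom) of the null that its coefficient is zero. An
#' exact fit (zero residual variance) is reported with se = 0, p = 0
#' and a degenerate-fit flag rather than an error.
#'
#' @param y Response values.
#' @param age Age in years, same length.
#' @param group 0/1 dummy (or logical / factor with two levels; second
#'   level = 1).
#' @return An object of class \code{age_adjusted_fit}: \code{coef}
#'   (intercept, age, group), \code{beta_group}, \code{se},
#'   \code{t_stat}, \code{p_value}, \code{n}, \code{dof},
#'   \code{sigma}, \code{degenerate}.
#' @export
age_adjusted_fit <- function(y, age, group) {
  if (is.factor(group)) group <- as.integer(group) - 1L
  group <- as.numeric(group)
  if (!all(group %in% c(0, 1))) stop("group must be a 0/1 dummy")
  ok <- stats::complete.cases(y, age, group)
  y <- y[ok]; age <- age[ok]; group <- group[ok]
  n <- length(y)
  if (n < 4) stop("need at least 4 complete observations")
  X <- cbind(intercept = 1, age = age, group = group)
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("design error: rank-deficient design (age or group constant)")
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  dof <- n - 3L
  rss <- sum(res^2)
  sigma2 <- rss / dof
  XtX_inv <- matrix(0, 3, 3)
  XtX_inv[qrX$pivot, qrX$pivot] <- chol2inv(qr.R(qrX))
  se_group <- sqrt(sigma2 * XtX_inv[3, 3])
  tol <- 1e-12 * max(sum(y^2), 1)
  degenerate <- rss <= tol
  if (degenerate) {
    se_group <- 0; t_stat <- Inf; p <- 0
  } else {
    t_stat <- beta[3] / se_group
    p <- 2 * stats::pt(-abs(t_stat), dof)
  }
  structure(list(coef = beta, beta_group = unname(beta[3]),
                 se = se_group, t_stat = unname(t_stat),
                 p_value = unname(p), n = n, dof = dof,
                 sigma = sqrt(sigma2), degenerate = degenerate),
            class = "age_adjusted_fit")
}

#' @export
print.age_adjusted_fit <- function(x, ...) {
  cat(sprintf(paste0("<age_adjusted_fit> n = %d, adjusted group difference ",
                     "%.4g +/- %.3g (t = %.3g, df = %d, p = %.3g)%s\n"),
              x$n, x$beta_group, x$se, x$t_stat, x$dof, x$p_value,
              if (x$degenerate) " [degenerate exact fit]" else ""))
  invisible(x)
}

#' @export
coef.age_adjusted_fit <- function(object, ...) object$coef

#' @export
summary.age_adjusted_fit <- function(object, ...) {
  cat("Age-adjusted group comparison (OLS on [1, age, group])\n")
  print(object)
  cat(sprintf("  coefficients: intercept %.4g, age %.4g, group %.4g\n",
              object$coef[1], object$coef[2], object$coef[3]))
  cat(sprintf("  residual SD %.4g on %d df\n", object$sigma, object$dof))
  invisible(object)
}

#' Grouped summary table with age-adjusted p-values
#'
#' One row per metric and condition with the term and preterm mean and
#' SD and the age-adjusted group p-value from
#' \code{\link{age_adjusted_fit}}; for subjects measured at both rest
#' and exercise a per-subject percent-change row per metric is added.
#' Rows are computed on complete cases per metric; p-values are
#' deliberately not corrected for multiple comparisons (flagged in the
#' attributes).
#'
#' @param records Data frame with columns \code{subject_id},
#'   \code{group} ("term"/"preterm"), \code{age_years}, \code{condition}
#'   ("rest"/"exercise") and one column per metric.
#' @param metrics Character vector of metric column names; default all
#'   non-design columns.
#' @return A data.frame of class \code{cohort_summary} with columns
#'   metric, condition, term_mean, term_sd, preterm_mean, preterm_sd,
#'   n_term, n_preterm, p_value. Attributes:
#'   \code{multiplicity_correction} ("none") and \code{incomplete}
#'   (per-metric counts of missing values).
#' @export
summary_table <- function(records, metrics = NULL) {
  need <- c("subject_id", "group", "age_years", "condition")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (!all(records$group %in% c("term", "preterm")))
    stop("group must be 'term' or 'preterm'")
  if (!all(records$condition %in% c("rest", "exercise")))
    stop("condition must be 'rest' or 'exercise'")
  for (g in c("term", "preterm")) for (cond in unique(records$condition)) {
    if (sum(records$group == g & records$condition == cond) < 2)
      stop(sprintf("need at least 2 '%s' subjects in condition '%s'", g, cond))
  }
  if (is.null(metrics))
    metrics <- setdiff(names(records), c(need, "bsa_m2"))
  rows <- list()
  incomplete <- vapply(metrics, function(m) sum(is.na(records[[m]])), 1L)
  add_row <- function(metric, condition, df) {
    val <- df[[metric]]
    ok <- !is.na(val)
    df <- df[ok, ]; val <- val[ok]
    fit <- age_adjusted_fit(val, df$age_years, df$group == "preterm")
    data.frame(metric = metric, condition = condition,
               term_mean = mean(val[df$group == "term"]),
               term_sd = stats::sd(val[df$group == "term"]),
               preterm_mean = mean(val[df$group == "preterm"]),
               preterm_sd = stats::sd(val[df$group == "preterm"]),
               n_term = sum(df$group == "term"),
               n_preterm = sum(df$group == "preterm"),
               p_value = fit$p_value)
  }
  for (m in metrics) {
    for (cond in intersect(c("rest", "exercise"), unique(records$condition)))
      rows[[paste(m, cond)]] <- add_row(m, cond, records[records$condition == cond, ])
    # percent change for subjects seen in both conditions
    r <- records[records$condition == "rest", c("subject_id", "group", "age_years", m)]
    e <- records[records$condition == "exercise", c("subject_id", m)]
    both <- merge(r, e, by = "subject_id", suffixes = c("_rest", "_ex"))
    if (nrow(both) >= 4 &&
        sum(both$group == "term") >= 2 && sum(both$group == "preterm") >= 2) {
      pc <- percent_change(both[[paste0(m, "_rest")]], both[[paste0(m, "_ex")]])
      df <- data.frame(subject_id = both$subject_id, group = both$group,
                       age_years = both$age_years, condition = "percent_change",
                       val = pc)
      names(df)[names(df) == "val"] <- m
      rows[[paste(m, "change")]] <- add_row(m, "percent_change", df)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "multiplicity_correction") <- "none"
  attr(out, "incomplete") <- incomplete
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat("Group summaries (mean +/- sd) with age-adjusted p-values\n")
  cat("(p-values uncorrected for multiple comparisons)\n\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
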