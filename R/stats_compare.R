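#' Linear regression of natural frequency on equivalent pressure
#'
#' Ordinary least-squares fit of `f0 = intercept + slope * p` for one
#' group x stage cell, with exact closed-form standard errors.
#'
#' @param p equivalent pressures, mmHg (or a 2-column data frame whose first
#'   two columns are predictor and response).
#' @param y responses (natural frequency, Hz).
#' @return Object of class `fo_linfit`: slope, intercept, their SEs, `n`,
#'   residual sum of squares `rss`, `df`, and the underlying data.
#' @export
fit_linear <- function(p, y = NULL) {
  if (is.data.frame(p)) { y <- p[[2L]]; p <- p[[1L]] }
  ok <- is.finite(p) & is.finite(y)
  p <- p[ok]; y <- y[ok]
  n <- length(p)
  if (n < 3L) stop("linear fit needs at least 3 points")
  if (length(unique(p)) < 2L) stop("rank-deficient fit: all predictors equal")
  fit <- lm(y ~ p)
  cf <- coef(fit)
  rss <- sum(fit$residuals^2)
  # closed-form standard errors (avoids summary.lm's perfect-fit warning on
  # noise-free data)
  sxx <- sum((p - mean(p))^2)
  s2 <- rss / (n - 2L)
  structure(list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
                 slope_se = sqrt(s2 / sxx),
                 intercept_se = sqrt(s2 * (1 / n + mean(p)^2 / sxx)),
                 n = n, rss = rss, df = n - 2L,
                 data = data.frame(p = p, y = y)),
            class = "fo_linfit")
}

#' @export
print.fo_linfit <- function(x, ...) {
  cat(sprintf(
    "linear fit: y = %.4g (+/- %.3g) + %.4g (+/- %.3g) * p   [n = %d, RSS = %.4g]\n",
    x$intercept, x$intercept_se, x$slope, x$slope_se, x$n, x$rss))
  invisible(x)
}

#' @export
coef.fo_linfit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.fo_linfit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$data$p else
    if (is.data.frame(newdata)) newdata$p else newdata
  object$intercept + object$slope * p
}

#' Exponential regression of the dynamic modulus on equivalent pressure
#'
#' Least-squares fit of the two-parameter growth model `E'(p) = a exp(b p)`,
#' initialised from the log-linear regression and fitted by
#' Levenberg-Marquardt least squares. Non-convergence is flagged rather than
#' raised, so that flagged fits can be excluded from comparisons.
#'
#' @param p equivalent pressures, mmHg (or a 2-column data frame).
#' @param y dynamic moduli (any consistent unit; all positive).
#' @return Object of class `fo_expfit`: `a`, `b`, their SEs, `n`, `rss`,
#'   `df`, `converged`, and the data.
#' @export
fit_exponential <- function(p, y = NULL) {
  if (is.data.frame(p)) { y <- p[[2L]]; p <- p[[1L]] }
  ok <- is.finite(p) & is.finite(y)
  p <- p[ok]; y <- y[ok]
  n <- length(p)
  if (n < 3L) stop("exponential fit needs at least 3 points")
  if (any(y <= 0)) stop("all responses must be positive for the exponential model")
  if (length(unique(p)) < 2L) stop("rank-deficient fit: all predictors equal")

  start_fit <- lm(log(y) ~ p)
  start <- list(a = exp(unname(coef(start_fit)[1L])),
                b = unname(coef(start_fit)[2L]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * p), start = start,
                      data = data.frame(p = p, y = y),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(a = start$a, b = start$b, a_se = NA_real_,
                          b_se = NA_real_, n = n, rss = NA_real_, df = n - 2L,
                          converged = FALSE, data = data.frame(p = p, y = y)),
                     class = "fo_expfit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 a_se = unname(se[1L]), b_se = unname(se[2L]), n = n,
                 rss = sum(stats::resid(fit)^2), df = n - 2L,
                 converged = is.null(fit$convInfo) ||
                   isTRUE(fit$convInfo$isConv),
                 data = data.frame(p = p, y = y)),
            class = "fo_expfit")
}

#' @export
print.fo_expfit <- function(x, ...) {
  cat(sprintf(
    "exponential fit: y = %.4g * exp(%.4g * p)   [n = %d, RSS = %.4g%s]\n",
    x$a, x$b, x$n, x$rss, if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}

#' @export
coef.fo_expfit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.fo_expfit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$data$p else
    if (is.data.frame(newdata)) newdata$p else newdata
  object$a * exp(object$b * p)
}

comparison_row <- function(contrast, test, F, df1, df2, alpha) {
  p <- pf(F, df1, df2, lower.tail = FALSE)
  data.frame(contrast = contrast, test = test, F = F, df1 = df1, df2 = df2,
             p_value = p, significant = is.finite(p) & p < alpha,
             stringsAsFactors = FALSE)
}

#' Compare two fitted lines (ANCOVA slope and elevation tests)
#'
#' Classic two-line comparison: an F test of equal slopes (separate lines
#' against a common-slope model); when the slopes do not differ significantly,
#' a second F test of equal elevations (common slope against a single common
#' line). The elevation test is only reported under a non-significant slope
#' test, since elevations are not comparable across unequal slopes.
#'
#' @param fitA,fitB `fo_linfit` objects carrying their data.
#' @param alpha significance level for the slope-test gate and the
#'   `significant` column.
#' @param contrast label carried into the result rows.
#' @return Data frame with one row per performed test: `contrast`, `test`
#'   (`"slopes"`, `"elevations"`), `F`, `df1`, `df2`, `p_value`,
#'   `significant`.
#' @export
compare_lines <- function(fitA, fitB, alpha = 0.05, contrast = "A_vs_B") {
  stopifnot(inherits(fitA, "fo_linfit"), inherits(fitB, "fo_linfit"))
  dat <- rbind(cbind(fitA$data, g = "A"), cbind(fitB$data, g = "B"))
  n <- nrow(dat)
  rss_sep <- fitA$rss + fitB$rss              # separate slopes + intercepts
  df_sep <- n - 4L
  if (df_sep < 1L) stop("too few points for the slope comparison")
  m_cs <- lm(y ~ p + g, data = dat)           # common slope
  rss_cs <- sum(m_cs$residuals^2)
  m_cl <- lm(y ~ p, data = dat)               # single common line
  rss_cl <- sum(m_cl$residuals^2)

  F_slope <- max(0, (rss_cs - rss_sep)) / (rss_sep / df_sep)
  out <- comparison_row(contrast, "slopes", F_slope, 1L, df_sep, alpha)
  if (!isTRUE(out$significant[1L])) {
    F_elev <- max(0, (rss_cl - rss_cs)) / (rss_cs / (n - 3L))
    out <- rbind(out, comparison_row(contrast, "elevations", F_elev, 1L,
                                     n - 3L, alpha))
  }
  out
}

#' Compare two exponential regression curves (extra-sum-of-squares F test)
#'
#' Tests whether one shared `(a, b)` pair describes both datasets against
#' separate pairs per dataset: `F = ((RSS_shared - RSS_separate) / 2) /
#' (RSS_separate / (nA + nB - 4))`.
#'
#' @param fitA,fitB converged `fo_expfit` objects carrying their data.
#' @param alpha significance level for the `significant` column.
#' @param contrast label carried into the result row.
#' @return One-row data frame (`test = "curves"`) as in [compare_lines()].
#' @export
compare_curves <- function(fitA, fitB, alpha = 0.05, contrast = "A_vs_B") {
  stopifnot(inherits(fitA, "fo_expfit"), inherits(fitB, "fo_expfit"))
  if (!fitA$converged || !fitB$converged)
    stop("cannot compare non-converged exponential fits")
  dat <- rbind(fitA$data, fitB$data)
  n <- nrow(dat)
  if (n - 4L < 1L) stop("too few points for the curve comparison")
  shared <- fit_exponential(dat$p, dat$y)
  if (!shared$converged) stop("shared-curve fit did not converge")
  rss_sep <- fitA$rss + fitB$rss
  F_curves <- max(0, (shared$rss - rss_sep) / 2) / (rss_sep / (n - 4L))
  comparison_row(contrast, "curves", F_curves, 2L, n - 4L, alpha)
}

#' Default contrast plan
#'
#' The comparison layout of the study: within each group, every non-control
#' stage against that group's control; and between the two groups at every
#' stage (only emitted when both groups are present in the data).
#'
#' @param stages stage labels in protocol order (first one taken as control
#'   when named `"control"`).
#' @param groups group labels present.
#' @return Data frame with columns `type` (`"between"`, `"within"`), `groupA`,
#'   `stageA`, `groupB`, `stageB`.
#' @export
default_contrast_plan <- function(stages = treatment_stages(),
                                  groups = c("sham", "pin")) {
  plan <- list()
  if (length(groups) >= 2L) {
    plan <- c(plan, lapply(stages, function(s)
      data.frame(type = "between", groupA = groups[1L], stageA = s,
                 groupB = groups[2L], stageB = s, stringsAsFactors = FALSE)))
  }
  if ("control" %in% stages) {
    for (g in groups) {
      plan <- c(plan, lapply(setdiff(stages, "control"), function(s)
        data.frame(type = "within", groupA = g, stageA = s, groupB = g,
                   stageB = "control", stringsAsFactors = FALSE)))
    }
  }
  do.call(rbind, plan)
}

cell_points <- function(points, group, stage) {
  points[points$group == group & points$stage == stage &
           (points$qc_flags == "" | is.na(points$qc_flags)), , drop = FALSE]
}

#' Run the planned regression comparisons over a points table
#'
#' For every planned contrast, fits the linear f0-pressure relation and the
#' exponential modulus-pressure relation in both cells (points pooled across
#' the animals of a cell) and runs [compare_lines()] for f0 and
#' [compare_curves()] for the modulus. QC-flagged points are excluded.
#' Contrasts with fewer than 3 usable points in either cell, with a missing
#' group, or with non-converged exponential fits are skipped with a reason.
#'
#' @param points tidy observation table as produced by [assemble_points()]
#'   (or the generator): columns `subject`, `group`, `stage`, `p_mmHg`,
#'   `f0_Hz`, `Eprime_MPa`, `qc_flags`.
#' @param plan contrast plan as [default_contrast_plan()]; defaults to the
#'   plan spanned by the groups and stages present in `points`.
#' @param alpha per-comparison significance level.
#' @param adjust `"none"` (default; per-comparison p-values) or `"holm"`
#'   (family-wise adjustment across each response's contrasts).
#' @return Object of class `fo_report`: list with `results` (one row per
#'   performed test: contrast, response, test, F, dfs, p, significance),
#'   `fits` (per-cell fit parameters), `skipped` (contrast, reason), `alpha`,
#'   `adjust`.
#' @export
run_comparisons <- function(points, plan = NULL, alpha = 0.05,
                            adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(points))
  need <- c("subject", "group", "stage", "p_mmHg", "f0_Hz", "Eprime_MPa")
  if (length(miss <- setdiff(need, names(points))))
    stop("points table lacks columns: ", paste(miss, collapse = ", "))
  if (!"qc_flags" %in% names(points)) points$qc_flags <- ""
  groups_here <- intersect(c("sham", "pin"), unique(points$group))
  stages_here <- intersect(treatment_stages(), unique(points$stage))
  if (is.null(plan))
    plan <- default_contrast_plan(stages_here, groups_here)

  results <- list(); fits <- list(); skipped <- list()
  fit_cache <- new.env(parent = emptyenv())
  get_fits <- function(group, stage) {
    keyname <- paste0(group, "\r", stage)
    if (!is.null(fit_cache[[keyname]])) return(fit_cache[[keyname]])
    d <- cell_points(points, group, stage)
    if (nrow(d) < 3L) {
      fit_cache[[keyname]] <- list(error = sprintf(
        "cell %s/%s has %d usable points (need >= 3)", group, stage, nrow(d)))
      return(fit_cache[[keyname]])
    }
    lin <- tryCatch(fit_linear(d$p_mmHg, d$f0_Hz), error = function(e) e)
    ex <- tryCatch(fit_exponential(d$p_mmHg, d$Eprime_MPa),
                   error = function(e) e)
    res <- if (inherits(lin, "error")) list(error = conditionMessage(lin))
           else if (inherits(ex, "error")) list(error = conditionMessage(ex))
           else if (!ex$converged)
             list(error = sprintf("exponential fit for %s/%s did not converge",
                                  group, stage))
           else list(lin = lin, ex = ex)
    fit_cache[[keyname]] <- res
    res
  }

  for (i in seq_len(nrow(plan))) {
    ct <- plan[i, ]
    label <- sprintf("%s/%s vs %s/%s", ct$groupA, ct$stageA, ct$groupB,
                     ct$stageB)
    if (ct$type == "between" && length(groups_here) < 2L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(contrast = label, reason = "only one group in the study",
                   stringsAsFactors = FALSE)
      next
    }
    fA <- get_fits(ct$groupA, ct$stageA)
    fB <- get_fits(ct$groupB, ct$stageB)
    if (!is.null(fA$error) || !is.null(fB$error)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(contrast = label, reason = fA$error %||% fB$error,
                   stringsAsFactors = FALSE)
      next
    }
    lines_res <- compare_lines(fA$lin, fB$lin, alpha = alpha, contrast = label)
    lines_res$response <- "f0"
    curves_res <- tryCatch(
      compare_curves(fA$ex, fB$ex, alpha = alpha, contrast = label),
      error = function(e) e)
    if (inherits(curves_res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(contrast = label, reason = conditionMessage(curves_res),
                   stringsAsFactors = FALSE)
      curves_res <- NULL
    } else {
      curves_res$response <- "Eprime"
    }
    results[[length(results) + 1L]] <- rbind(lines_res, curves_res)
  }

  results <- if (length(results)) do.call(rbind, results) else
    data.frame(contrast = character(), test = character(), F = numeric(),
               df1 = integer(), df2 = integer(), p_value = numeric(),
               significant = logical(), response = character(),
               stringsAsFactors = FALSE)
  results <- results[, c("contrast", "response", "test", "F", "df1", "df2",
                         "p_value", "significant")]
  if (adjust == "holm" && nrow(results)) {
    for (resp in unique(results$response)) {
      sel <- results$response == resp
      results$p_value[sel] <- stats::p.adjust(results$p_value[sel],
                                              method = "holm")
      results$significant[sel] <- results$p_value[sel] < alpha
    }
  }

  for (keyname in ls(fit_cache)) {
    fc <- fit_cache[[keyname]]
    if (!is.null(fc$error)) next
    gs <- strsplit(keyname, "\r", fixed = TRUE)[[1L]]
    fits[[length(fits) + 1L]] <- data.frame(
      group = gs[1L], stage = gs[2L], n = fc$lin$n,
      f0_intercept = fc$lin$intercept, f0_slope = fc$lin$slope,
      f0_intercept_se = fc$lin$intercept_se, f0_slope_se = fc$lin$slope_se,
      E_a_MPa = fc$ex$a, E_b_per_mmHg = fc$ex$b, E_a_se = fc$ex$a_se,
      E_b_se = fc$ex$b_se, stringsAsFactors = FALSE)
  }
  fits <- if (length(fits)) do.call(rbind, fits) else NULL
  if (!is.null(fits))
    fits <- fits[order(match(fits$group, c("sham", "pin")),
                       match(fits$stage, treatment_stages())), ]
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(contrast = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(results = results, fits = fits, skipped = skipped,
                 alpha = alpha, adjust = adjust),
            class = "fo_report")
}

#' @export
print.fo_report <- function(x, ...) {
  cat(sprintf("comparison report: %d tests over %d contrasts (alpha = %g%s)\n",
              nrow(x$results), length(unique(x$results$contrast)), x$alpha,
              if (x$adjust != "none") paste0(", ", x$adjust) else ""))
  sig <- x$results[x$results$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s [%s, %s]: F = %.3g, p = %.4g\n", sig$contrast[i],
                  sig$response[i], sig$test[i], sig$F[i], sig$p_value[i]))
  } else cat("no significant contrasts\n")
  if (nrow(x$skipped))
    cat(sprintf("skipped %d contrast(s); see $skipped\n", nrow(x$skipped)))
  invisible(x)
}

#' @export
summary.fo_report <- function(object, ...) {
  object$results
}
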