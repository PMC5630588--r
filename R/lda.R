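#' Fit the single-hit Poisson model to a limiting-dilution table
#'
#' Estimates the frequency `f` of active cells (e.g. long-term repopulating
#' HSCs) from a dose-response table in which `n_tested` recipients each
#' receive `dose` cells and `n_responding` of them respond (e.g. show
#' long-term engraftment). Under the single-hit Poisson model the
#' probability that a recipient carries no active cell is
#' `P(negative) = exp(-f * dose)`, so the complementary log-log of the
#' response probability is linear in `log(dose)` with unit slope:
#' `cloglog(p) = log(f) + log(dose)`. The model is fitted by binomial
#' regression with a complementary log-log link and `log(dose)` as an
#' offset; the intercept is `log(f)`.
#'
#' Doses at which no recipient was negative are informative and are kept in
#' the likelihood (no ad-hoc correction); they are flagged in the result and
#' drawn distinctly by [plot.lda_fit()]. Two boundary cases have no interior
#' maximum likelihood estimate and are returned as one-sided results rather
#' than errors: when every recipient responds the data only bound `f` from
#' below, and when none responds only from above (the upper bound has the
#' closed form `-log(alpha) / sum(n_tested * dose)`).
#'
#' @param table data frame with columns `dose`, `n_tested`, `n_responding`
#'   (a `group` column is allowed and may be selected with `group`).
#' @param ci_level confidence level for the interval on `f`.
#' @param ci_method `"wald"` (normal interval on `log f`, default) or
#'   `"profile"` (profile likelihood).
#' @param group optional value of `table$group` to filter on.
#' @return object of class `lda_fit` with elements `frequency` (the MLE of
#'   `f`; `NA` in the boundary cases), `ci` (`c(lower, upper)` on the `f`
#'   scale), `log_frequency`, `se_log_frequency`, `status` (`"ok"`,
#'   `"all_responding"`, `"all_negative"`), `zero_negative_doses`,
#'   `log_fraction` (per-dose `dose`, `frac_negative`, `log_frac_negative`,
#'   `zero_negative`), `cru` (competitive repopulation units, interpreted as
#'   total cells transplanted times `f`), the filtered `table` and the
#'   underlying `glm` fit. Supports `print`, `summary`, `coef`, `confint`,
#'   `predict`, `plot`, `simulate` and `residuals`.
#' @export
#' @examples
#' tab <- data.frame(dose = 10, n_tested = 10, n_responding = 2)
#' fit <- lda_fit(tab)
#' fit$frequency            # -log(0.8) / 10
#' 1 / fit$frequency        # "1 in N" scale
lda_fit <- function(table, ci_level = 0.95,
                    ci_method = c("wald", "profile"), group = NULL) {
  ci_method <- match.arg(ci_method)
  stopifnot_scalar(ci_level, "ci_level")
  if (ci_level <= 0 || ci_level >= 1) stop("'ci_level' must lie in (0, 1)")
  table <- as.data.frame(table)
  if (!is.null(group)) {
    if (!"group" %in% names(table)) stop("no 'group' column to filter on")
    table <- table[table$group == group, , drop = FALSE]
    if (!nrow(table)) stop("no rows for group '", group, "'")
  }
  req <- c("dose", "n_tested", "n_responding")
  if (!all(req %in% names(table)))
    stop("table must have columns dose, n_tested, n_responding")
  d <- table$dose; n <- table$n_tested; r <- table$n_responding
  if (any(d <= 0)) stop("doses must be positive")
  if (any(n <= 0)) stop("'n_tested' must be positive")
  if (any(r < 0 | r > n)) stop("'n_responding' must lie in [0, n_tested]")
  neg <- n - r
  alpha <- 1 - ci_level
  z <- qnorm(1 - alpha / 2)
  logfrac <- data.frame(dose = d, frac_negative = neg / n,
                        log_frac_negative = ifelse(neg > 0, log(neg / n), -Inf),
                        zero_negative = neg == 0)
  zn_doses <- d[neg == 0]

  base <- list(table = table, ci_level = ci_level, ci_method = ci_method,
               group = group, log_fraction = logfrac,
               zero_negative_doses = zn_doses)

  if (sum(r) == 0) {
    # no responders anywhere: f is only bounded above
    # P(all negative | f) = exp(-f * sum(n*d)) = alpha  =>  f_upper
    f_up <- -log(alpha) / sum(n * d)
    fit <- c(base, list(frequency = NA_real_, ci = c(0, f_up),
                        log_frequency = NA_real_, se_log_frequency = NA_real_,
                        status = "all_negative", cru = NA_real_, glm = NULL))
    return(structure(fit, class = "lda_fit"))
  }
  if (sum(neg) == 0) {
    # every recipient responded: f is only bounded below
    loglik_allresp <- function(f) sum(n * log1p(-exp(-f * d))) - log(alpha)
    f_lo <- uniroot(loglik_allresp, lower = 1e-12, upper = 1e6,
                    extendInt = "upX", tol = 1e-12)$root
    fit <- c(base, list(frequency = NA_real_, ci = c(f_lo, NA_real_),
                        log_frequency = NA_real_, se_log_frequency = NA_real_,
                        status = "all_responding", cru = NA_real_, glm = NULL))
    return(structure(fit, class = "lda_fit"))
  }

  gfit <- glm(cbind(r, neg) ~ 1 + offset(log(d)),
              family = binomial(link = "cloglog"),
              control = list(epsilon = 1e-12, maxit = 100))
  b <- unname(coef(gfit)[1])
  se <- sqrt(vcov(gfit)[1, 1])
  ci_log <- if (ci_method == "wald") {
    c(b - z * se, b + z * se)
  } else {
    pr <- tryCatch(suppressMessages(confint(gfit, level = ci_level)),
                   error = function(e) NULL)
    if (is.null(pr) || anyNA(pr)) c(b - z * se, b + z * se) else unname(pr)
  }
  f_hat <- exp(b)
  cru <- f_hat * sum(n * d)
  fit <- c(base, list(frequency = f_hat, ci = exp(ci_log),
                      log_frequency = b, se_log_frequency = se,
                      status = "ok", cru = cru, glm = gfit))
  structure(fit, class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("Single-hit Poisson limiting-dilution fit\n")
  if (!is.null(x$group)) cat("  group:", x$group, "\n")
  switch(x$status,
    ok = {
      cat(sprintf("  Estimated frequency: %.6g  (1 in %.4g)\n",
                  x$frequency, 1 / x$frequency))
      cat(sprintf("  %.0f%% CI: %.6g to %.6g  (1 in %.4g to 1 in %.4g)\n",
                  100 * x$ci_level, x$ci[1], x$ci[2],
                  1 / x$ci[2], 1 / x$ci[1]))
    },
    all_negative = cat(sprintf(
      "  No recipient responded: frequency is not identified;\n  one-sided %.0f%% upper bound %.6g (at least 1 in %.4g)\n",
      100 * x$ci_level, x$ci[2], 1 / x$ci[2])),
    all_responding = cat(sprintf(
      "  Every recipient responded: frequency is not identified;\n  one-sided %.0f%% lower bound %.6g (at most 1 in %.4g)\n",
      100 * x$ci_level, x$ci[1], 1 / x$ci[1]))
  )
  if (length(x$zero_negative_doses))
    cat("  doses with zero negative responses:",
        paste(x$zero_negative_doses, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lda_fit <- function(object, ...) {
  print(object)
  cat("\nPer-dose data:\n")
  tab <- object$table
  tab$frac_negative <- object$log_fraction$frac_negative
  print(tab, row.names = FALSE)
  if (object$status == "ok") {
    cat(sprintf("\nCompetitive repopulation units (total cells x f): %.4g\n",
                object$cru))
    cat(sprintf("Residual deviance: %.4g on %d df\n",
                object$glm$deviance, object$glm$df.residual))
  }
  invisible(object)
}

#' @export
coef.lda_fit <- function(object, ...) {
  c(log_frequency = object$log_frequency)
}

#' @export
confint.lda_fit <- function(object, parm = "frequency", level = NULL, ...) {
  out <- matrix(object$ci, 1, 2,
                dimnames = list("frequency", c("lower", "upper")))
  out
}

#' Expected response probabilities at new doses
#'
#' @param object an [lda_fit()].
#' @param newdata data frame with a `dose` column; defaults to the fitted
#'   doses.
#' @param ... unused.
#' @return vector of `P(response) = 1 - exp(-f * dose)` at the estimate.
#' @export
predict.lda_fit <- function(object, newdata = NULL, ...) {
  if (object$status != "ok")
    stop("frequency not identified (status '", object$status, "')")
  d <- if (is.null(newdata)) object$table$dose else newdata$dose
  1 - exp(-object$frequency * d)
}

#' @export
residuals.lda_fit <- function(object, type = "deviance", ...) {
  if (is.null(object$glm)) return(rep(NA_real_, nrow(object$table)))
  residuals(object$glm, type = type)
}

#' Simulate dose-response tables from a fitted frequency
#'
#' @param object an [lda_fit()].
#' @param nsim number of tables.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of data frames shaped like the fitted table.
#' @export
simulate.lda_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$status != "ok")
    stop("frequency not identified (status '", object$status, "')")
  run <- function() {
    tab <- object$table
    p <- 1 - exp(-object$frequency * tab$dose)
    tab$n_responding <- rbinom(nrow(tab), tab$n_tested, p)
    tab
  }
  if (!is.null(seed)) with_seed(seed, replicate(nsim, run(), simplify = FALSE))
  else replicate(nsim, run(), simplify = FALSE)
}

#' Log-fraction plot of a limiting-dilution fit
#'
#' Draws the standard limiting-dilution summary: the natural log of the
#' fraction of negative recipients against dose, with the fitted line
#' through the origin whose slope is `-f` (the log-active-cell fraction per
#' dose unit) and dotted lines at the confidence bounds. Doses with zero
#' negative recipients have no finite log fraction; they are drawn as
#' downward-pointing triangles on the fitted line, as a display convention
#' only (they enter the likelihood exactly, not at the plotted position).
#'
#' @param x an [lda_fit()].
#' @param ... forwarded to [plot()].
#' @export
plot.lda_fit <- function(x, ...) {
  lf <- x$log_fraction
  finite <- !lf$zero_negative
  xmax <- max(lf$dose) * 1.05
  slope <- if (x$status == "ok") -x$frequency else NA_real_
  yfin <- lf$log_frac_negative[finite]
  ymin <- min(c(yfin, if (!is.na(slope)) slope * xmax, -1), na.rm = TRUE)
  plot(NA, xlim = c(0, xmax), ylim = c(ymin * 1.1, 0),
       xlab = "dose (cells)", ylab = "ln(fraction negative)", ...)
  if (!is.na(slope)) {
    abline(0, slope)
    if (!anyNA(x$ci)) {
      abline(0, -x$ci[1], lty = 3)
      abline(0, -x$ci[2], lty = 3)
    }
  }
  points(lf$dose[finite], yfin, pch = 16)
  if (any(lf$zero_negative)) {
    d0 <- lf$dose[lf$zero_negative]
    y0 <- if (!is.na(slope)) slope * d0 else rep(ymin, length(d0))
    points(d0, y0, pch = 25, bg = "black")
  }
  invisible(x)
}

#' Compare active-cell frequencies between two groups
#'
#' Fits each group under the single-hit Poisson model and tests equality of
#' their frequencies with a likelihood-ratio test (shared-frequency null vs
#' one frequency per group). The fold enrichment is the ratio of the two
#' frequency estimates.
#'
#' @param table_a,table_b dose-response tables (columns `dose`, `n_tested`,
#'   `n_responding`) for the two groups.
#' @param labels length-2 character vector naming the groups.
#' @param ci_level confidence level passed to [lda_fit()].
#' @return object of class `lda_contrast`: the two fits,
#'   `fold_enrichment = f_A / f_B`, and the LRT `chisq`, `df`, `p_value`.
#'   When a group's frequency is unidentified the fold is reported as a
#'   one-sided bound (`fold_bound`, with `bound_side`), and the LRT is
#'   omitted.
#' @export
#' @examples
#' a <- simulate_lda_table(0.03, c(20, 50), 24, seed = 1, group_label = "treated")
#' b <- simulate_lda_table(0.01, c(20, 50), 24, seed = 2, group_label = "control")
#' lda_compare(a, b, labels = c("treated", "control"))
lda_compare <- function(table_a, table_b, labels = c("A", "B"),
                        ci_level = 0.95) {
  fa <- lda_fit(table_a, ci_level = ci_level)
  fb <- lda_fit(table_b, ci_level = ci_level)
  out <- list(labels = labels, fit_a = fa, fit_b = fb,
              fold_enrichment = NA_real_, chisq = NA_real_, df = NA_integer_,
              p_value = NA_real_, fold_bound = NA_real_,
              bound_side = NA_character_, note = NULL)
  if (fa$status == "ok" && fb$status == "ok") {
    out$fold_enrichment <- fa$frequency / fb$frequency
    ta <- fa$table; tb <- fb$table
    d <- c(ta$dose, tb$dose)
    r <- c(ta$n_responding, tb$n_responding)
    neg <- c(ta$n_tested - ta$n_responding, tb$n_tested - tb$n_responding)
    grp <- factor(rep(labels, c(nrow(ta), nrow(tb))))
    alt <- glm(cbind(r, neg) ~ grp + offset(log(d)),
               family = binomial(link = "cloglog"))
    null <- glm(cbind(r, neg) ~ 1 + offset(log(d)),
                family = binomial(link = "cloglog"))
    # deviance difference can be a tiny negative number for identical
    # groups; clamp before the chi-square tail
    out$chisq <- max(0, null$deviance - alt$deviance)
    out$df <- null$df.residual - alt$df.residual
    out$p_value <- pchisq(out$chisq, out$df, lower.tail = FALSE)
  } else if (fa$status == "ok" && fb$status == "all_negative") {
    out$fold_bound <- fa$frequency / fb$ci[2]
    out$bound_side <- "lower"
    out$note <- sprintf("'%s' had no responders; fold is a one-sided lower bound", labels[2])
  } else if (fa$status == "all_negative" && fb$status == "ok") {
    out$fold_bound <- fa$ci[2] / fb$frequency
    out$bound_side <- "upper"
    out$note <- sprintf("'%s' had no responders; fold is a one-sided upper bound", labels[1])
  } else if (fa$status == "ok" && fb$status == "all_responding") {
    out$fold_bound <- fa$frequency / fb$ci[1]
    out$bound_side <- "upper"
    out$note <- sprintf("'%s' was saturated; fold is a one-sided upper bound", labels[2])
  } else if (fa$status == "all_responding" && fb$status == "ok") {
    out$fold_bound <- fa$ci[1] / fb$frequency
    out$bound_side <- "lower"
    out$note <- sprintf("'%s' was saturated; fold is a one-sided lower bound", labels[1])
  } else {
    out$note <- "neither group's frequency is identified"
  }
  structure(out, class = "lda_contrast")
}

#' @export
print.lda_contrast <- function(x, ...) {
  cat(sprintf("Limiting-dilution contrast: %s vs %s\n", x$labels[1], x$labels[2]))
  fmt_freq <- function(f) {
    if (f$status == "ok") sprintf("%.6g (1 in %.4g)", f$frequency, 1 / f$frequency)
    else sprintf("[%s]", f$status)
  }
  cat(sprintf("  %s: %s\n", x$labels[1], fmt_freq(x$fit_a)))
  cat(sprintf("  %s: %s\n", x$labels[2], fmt_freq(x$fit_b)))
  if (!is.na(x$fold_enrichment)) {
    cat(sprintf("  fold enrichment = %.3f\n", x$fold_enrichment))
    cat(sprintf("  LRT: chisq = %.4g, df = %d, p = %s\n",
                x$chisq, x$df, format.pval(x$p_value)))
  } else if (!is.na(x$fold_bound)) {
    cat(sprintf("  fold enrichment %s bound = %.3f\n", x$bound_side, x$fold_bound))
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
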