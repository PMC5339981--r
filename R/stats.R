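#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with the 95% confidence interval obtained from
#' the Fisher z-transform (standard error `1/sqrt(n - 3)`) and a two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` — the machinery behind
#' [stats::cor.test()], which performs the computation.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite, non-constant.
#' @return One-row tibble: `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
pearson_ci <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA_real_, NA_real_)
  tibble::tibble(r = unname(ct$estimate), ci_low = ci[1], ci_high = ci[2],
                 p = ct$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `method - reference` (so a method that underestimates the
#' reference yields a negative bias); bias is their mean, `sd` the sample
#' standard deviation (n - 1 denominator), and the 95% limits of agreement
#' `bias +/- 1.96 * sd`.
#'
#' @param method,reference Numeric vectors of equal length, n >= 2.
#' @return One-row tibble: `bias`, `sd`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(method, reference) {
  if (length(method) != length(reference)) stop("length mismatch")
  if (length(method) < 2) stop("need at least 2 paired observations")
  d <- method - reference
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d))
}

#' Compare two correlation coefficients
#'
#' `"fisher_independent"` treats the correlations as coming from independent
#' samples: `z = (z1 - z2) / sqrt(2 / (n - 3))` on Fisher-transformed values.
#' `"steiger_dependent"` is Steiger's Z for overlapping dependent
#' correlations sharing one variable (here both CMR methods are correlated
#' against the same TTE measurements), which requires `r12`, the correlation
#' between the two non-shared variables. Steiger is the default because the
#' compared correlations share the reference sample.
#'
#' @param r1,r2 Correlations to compare, |r| < 1.
#' @param n Sample size (>= 4).
#' @param method `"steiger_dependent"` (default) or `"fisher_independent"`.
#' @param r12 Correlation between the two method variables (Steiger only).
#' @return One-row tibble: `z`, `p`, `method`.
#' @export
compare_correlations <- function(r1, r2, n,
                                 method = c("steiger_dependent",
                                            "fisher_independent"),
                                 r12 = NULL) {
  method <- match.arg(method)
  if (n < 4) stop("n must be >= 4")
  if (r1 == r2)   # identical coefficients are trivially not different
    return(tibble::tibble(z = 0, p = 1, method = method))
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  z1 <- atanh(r1); z2 <- atanh(r2)
  if (method == "fisher_independent") {
    z <- (z1 - z2) / sqrt(2 / (n - 3))
  } else {
    if (is.null(r12)) stop("steiger_dependent requires r12")
    rbar2 <- (r1^2 + r2^2) / 2
    cov12 <- (r12 * (1 - 2 * rbar2) - 0.5 * rbar2 * (1 - 2 * rbar2 - r12^2)) /
      (1 - rbar2)^2
    z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov12))
  }
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)), method = method)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic against a normal distribution with the sample
#' mean and standard deviation. Because the parameters are estimated from
#' the same data, the asymptotic KS p-value is conservative (the Lilliefors
#' situation); the returned object carries this caveat.
#'
#' @param x Numeric vector, n >= 5, non-constant.
#' @return One-row tibble: `statistic`, `p`, `n`, plus a `"caveat"`
#'   attribute.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("zero variance")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  out <- tibble::tibble(statistic = unname(kt$statistic), p = kt$p.value,
                        n = length(x))
  attr(out, "caveat") <-
    "normal parameters estimated from the sample: asymptotic KS p-value is conservative (Lilliefors situation)"
  out
}

.comparison_parameters <- c(
  Vmean = "vmean_ms", Vpeak = "vpeak_ms", MG = "mg_mmhg", PG = "pg_mmhg",
  VTI = "vti_cm", SV = "sv_ml", AVA_Cine = "ava_cine_cm2",
  AVA_Flow = "ava_flow_cm2")

.parameter_units <- c(
  Vmean = "m/s", Vpeak = "m/s", MG = "mmHg", PG = "mmHg",
  VTI = "cm", SV = "mL", AVA_Cine = "cm^2", AVA_Flow = "cm^2")

# reference values for one parameter: TTE for velocity-derived measures and
# valve areas; cine stroke volume for the SV row (SV is not a TTE measure)
.reference_values <- function(reports, param) {
  col <- .comparison_parameters[[param]]
  cmr1 <- dplyr::filter(reports, .data$method == "1Dir")
  tte <- dplyr::filter(reports, .data$method == "TTE")
  tte <- tte[match(cmr1$subject, tte$subject), ]
  if (param == "SV") {
    cmr1$sv_cine_ml
  } else if (param %in% c("AVA_Cine", "AVA_Flow")) {
    tte$ava_cm2
  } else {
    tte[[col]]
  }
}

#' Cohort comparison table (CMR methods vs TTE)
#'
#' Assembles, per hemodynamic parameter, the agreement of each CMR analysis
#' mode against the reference: Pearson r with 95% CI and p, Bland-Altman
#' bias +/- SD with limits of agreement, and a p-value comparing the two
#' correlation coefficients (which share the reference sample, hence the
#' dependent-correlation default). The reference is TTE for velocities,
#' gradients, VTI and valve areas, and the cine stroke volume for SV.
#'
#' @param reports Tibble with one row per subject x method: columns
#'   `subject`, `method` (`"1Dir"`, `"3Dir"`, `"TTE"`), the parameter
#'   columns of `quantify_subject()`/`simulate_tte()`, optionally
#'   `severity`.
#' @param severity_filter Optional character vector of severity labels to
#'   retain (e.g. `c("moderate", "severe")` for the disease-subgroup
#'   sub-analysis).
#' @param parameters Parameters to tabulate (default all eight).
#' @param r_comparison Method passed to [compare_correlations()].
#' @return Object of class `flow_comparison`: a tibble with one row per
#'   parameter x CMR method.
#' @export
cohort_table <- function(reports, severity_filter = NULL,
                         parameters = names(.comparison_parameters),
                         r_comparison = "steiger_dependent") {
  stopifnot(all(c("subject", "method") %in% names(reports)))
  if (!is.null(severity_filter)) {
    if (!"severity" %in% names(reports))
      stop("severity filter requested but reports carry no severity column")
    reports <- dplyr::filter(reports, .data$severity %in% severity_filter)
  }
  if ("excluded" %in% names(reports))
    reports <- dplyr::filter(reports, !.data$excluded | .data$method == "TTE")
  complete <- reports |>
    dplyr::count(.data$subject) |>
    dplyr::filter(.data$n == 3) |>
    dplyr::pull(.data$subject)
  reports <- dplyr::filter(reports, .data$subject %in% complete)
  n_sub <- length(complete)
  if (n_sub < 4)
    stop("insufficient subjects with all three methods (", n_sub, " < 4)")

  rows <- list()
  for (param in parameters) {
    col <- .comparison_parameters[[param]]
    ref <- .reference_values(reports, param)
    m1 <- dplyr::filter(reports, .data$method == "1Dir")
    m3 <- dplyr::filter(reports, .data$method == "3Dir")
    m3 <- m3[match(m1$subject, m3$subject), ]
    v1 <- m1[[col]]; v3 <- m3[[col]]
    ok <- is.finite(v1) & is.finite(v3) & is.finite(ref)
    if (sum(ok) < 4) next
    v1 <- v1[ok]; v3 <- v3[ok]; refk <- ref[ok]

    # zero-variance columns (e.g. a constant reference) yield NA correlation
    # rows but keep the agreement statistics
    safe_pearson <- function(a, b) {
      tryCatch(pearson_ci(a, b), error = function(e)
        tibble::tibble(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p = NA_real_, n = length(a)))
    }
    p1 <- safe_pearson(v1, refk); b1 <- bland_altman(v1, refk)
    p3 <- safe_pearson(v3, refk); b3 <- bland_altman(v3, refk)
    r12 <- suppressWarnings(stats::cor(v1, v3))
    cmp <- if (is.finite(p1$r) && is.finite(p3$r) && is.finite(r12) &&
                 (p1$r == p3$r || (abs(p1$r) < 1 && abs(p3$r) < 1))) {
      compare_correlations(p1$r, p3$r, sum(ok), method = r_comparison,
                           r12 = r12)
    } else {
      tibble::tibble(z = NA_real_, p = NA_real_, method = r_comparison)
    }
    for (info in list(list(m = "1Dir", p = p1, b = b1),
                      list(m = "3Dir", p = p3, b = b3))) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = param, units = .parameter_units[[param]],
        method = info$m, n = sum(ok),
        r = info$p$r, ci_low = info$p$ci_low, ci_high = info$p$ci_high,
        p_r = info$p$p,
        bias = info$b$bias, sd = info$b$sd,
        loa_low = info$b$loa_low, loa_high = info$b$loa_high,
        p_r_comparison = cmp$p)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("flow_comparison", class(out))
  attr(out, "n_subjects") <- n_sub
  attr(out, "r_comparison") <- r_comparison
  out
}

#' @export
print.flow_comparison <- function(x, ...) {
  cat(sprintf("Flow method comparison (%d subjects, r comparison: %s)\n\n",
              attr(x, "n_subjects"), attr(x, "r_comparison")))
  df <- as.data.frame(x)
  df$`r (95% CI)` <- sprintf("%.2f (%.2f-%.2f)", df$r, df$ci_low, df$ci_high)
  df$`bias +/- SD` <- sprintf("%+.2f +/- %.2f %s", df$bias, df$sd, df$units)
  print(df[, c("parameter", "method", "n", "r (95% CI)", "p_r",
               "bias +/- SD", "p_r_comparison")], row.names = FALSE)
  invisible(x)
}

#' Tidy a flow comparison table
#'
#' @param x A `flow_comparison`.
#' @param ... Unused.
#' @return The underlying tibble, one row per parameter x method.
#' @method tidy flow_comparison
#' @export
tidy.flow_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "flow_comparison")
  out
}

#' One-line summary of a flow comparison
#'
#' @param x A `flow_comparison`.
#' @param ... Unused.
#' @return One-row tibble with subject count, parameter count, and the range
#'   of correlations per method.
#' @method glance flow_comparison
#' @export
glance.flow_comparison <- function(x, ...) {
  tb <- tidy(x)
  tibble::tibble(
    n_subjects = attr(x, "n_subjects"),
    n_parameters = length(unique(tb$parameter)),
    r_min_1dir = min(tb$r[tb$method == "1Dir"]),
    r_max_1dir = max(tb$r[tb$method == "1Dir"]),
    r_min_3dir = min(tb$r[tb$method == "3Dir"]),
    r_max_3dir = max(tb$r[tb$method == "3Dir"]))
}
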