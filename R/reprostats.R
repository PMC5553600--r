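## Reproducibility statistics over a measurement table of infarct sizes
## indexed by patient x reader x method: per-patient averaged absolute
## differences, the coefficient of variation built on them, ICC(2,1) with an
## F-based confidence interval, Bland-Altman limits of agreement, one-way
## variance components, the two-arm trial sample-size formula
## n = 2 sigma^2 (z_{alpha/2} + z_beta)^2 / delta^2, and the assembled
## per-method report.

check_table <- function(table, method, value = "percent_lv") {
  need <- c("patient", "reader", "method", value)
  if (!all(need %in% names(table))) stopf("measurement table lacks columns: %s",
                                          paste(setdiff(need, names(table)), collapse = ", "))
  t2 <- table[table$method == method, , drop = FALSE]
  if (nrow(t2) == 0) stopf("no rows for method %s", method)
  wide <- tapply(t2[[value]], list(t2$patient, t2$reader), mean)
  if (any(is.na(wide))) {
    bad <- rownames(wide)[apply(is.na(wide), 1, any)]
    stopf("method %s: incomplete reader crossing for patient(s) %s",
          method, paste(bad, collapse = ", "))
  }
  wide
}

#' Per-patient averaged absolute differences
#'
#' For each patient, the mean of the absolute pairwise differences between
#' readers; then the population mean and SD (n-1) of those per-patient
#' values - the quantity on which the study's CV is built.
#'
#' @param table measurement data.frame (patient, reader, method, value
#'   columns).
#' @param method method tag to analyse.
#' @param value measurement column (default `"percent_lv"`).
#' @return List: `per_patient` (named vector), `mean`, `sd`.
#' @export
per_patient_diffs <- function(table, method, value = "percent_lv") {
  wide <- check_table(table, method, value)
  if (ncol(wide) < 2) stopf("need at least 2 readers")
  pp <- apply(wide, 1, function(x) mean(abs(as.vector(dist(x)))))
  list(per_patient = pp, mean = mean(pp), sd = sd(pp))
}

#' Coefficient of variation of a method
#'
#' 100 x SD of the per-patient averaged absolute differences, divided by the
#' mean infarct size measured by the method.
#'
#' @inheritParams per_patient_diffs
#' @return CV in percent.
#' @export
cv <- function(table, method, value = "percent_lv") {
  wide <- check_table(table, method, value)
  m <- mean(wide)
  if (m <= 0) stopf("method %s has nonpositive mean size; CV undefined", method)
  d <- per_patient_diffs(table, method, value)
  100 * d$sd / m
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC with
#' its F-based 95% confidence interval. Mean squares come from the two-way
#' ANOVA `value ~ patient + reader`.
#'
#' @inheritParams per_patient_diffs
#' @param conf confidence level.
#' @return List: `icc`, `lower`, `upper`, `ms` (named mean squares).
#' @export
icc <- function(table, method, value = "percent_lv", conf = 0.95) {
  wide <- check_table(table, method, value)
  n <- nrow(wide); k <- ncol(wide)
  if (n < 2 || k < 2) stopf("ICC needs >= 2 patients and >= 2 readers")
  long <- data.frame(y = as.vector(wide),
                     patient = factor(rep(rownames(wide), k)),
                     reader = factor(rep(colnames(wide), each = n)))
  ms <- suppressWarnings(anova(aov(y ~ patient + reader, data = long))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf
  a <- k * val / (n * (1 - val))
  b <- 1 + k * val * (n - 1) / (n * (1 - val))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = val, lower = lower, upper = upper,
       ms = c(patients = msr, readers = msc, error = mse))
}

#' Bland-Altman analysis for a reader pair
#'
#' Bias (mean difference), SD of differences, 95% limits of agreement
#' (bias +/- 1.96 SD), and the paired two-sided t-test p-value.
#'
#' @inheritParams per_patient_diffs
#' @param readers length-2 vector naming the reader pair.
#' @return List: `bias`, `sd`, `loa` (length 2), `p`, `n`.
#' @export
bland_altman <- function(table, method, readers, value = "percent_lv") {
  wide <- check_table(table, method, value)
  if (!all(readers %in% colnames(wide)))
    stopf("readers %s not found for method %s", paste(readers, collapse = ", "), method)
  d <- wide[, readers[1]] - wide[, readers[2]]
  if (length(d) < 2) stopf("Bland-Altman needs >= 2 patients")
  bias <- mean(d); s <- sd(d)
  p <- if (s == 0) NA_real_ else t.test(d)$p.value
  list(bias = bias, sd = s, loa = bias + c(-1.96, 1.96) * s, p = p,
       n = length(d))
}

#' One-way variance components
#'
#' Moment estimators from the one-way random-effects ANOVA of value on
#' patient: within-patient variance `sigma_e2 = MS_within`, between-patient
#' variance `sigma_T2 = max(0, (MS_between - MS_within) / k)` for `k`
#' readers, and the within-patient share of total variance.
#'
#' @inheritParams per_patient_diffs
#' @return List: `sigma_T2`, `sigma_e2`, `within_share`.
#' @export
variance_components <- function(table, method, value = "percent_lv") {
  wide <- check_table(table, method, value)
  n <- nrow(wide); k <- ncol(wide)
  if (n < 2) stopf("variance components need >= 2 patients")
  long <- data.frame(y = as.vector(wide),
                     patient = factor(rep(rownames(wide), k)))
  ms <- suppressWarnings(anova(aov(y ~ patient, data = long))[["Mean Sq"]])
  msb <- ms[1]; msw <- ms[2]
  sigma_e2 <- msw
  sigma_T2 <- max(0, (msb - msw) / k)
  tot <- sigma_T2 + sigma_e2
  ## a numerically constant table has no variance to apportion
  if (tot <= 1e-12 * (1 + mean(wide)^2))
    return(list(sigma_T2 = 0, sigma_e2 = 0, within_share = 0))
  list(sigma_T2 = sigma_T2, sigma_e2 = sigma_e2,
       within_share = sigma_e2 / tot)
}

#' Two-arm trial sample size per arm
#'
#' `n = ceiling(2 sigma^2 (z_{alpha/2} + z_beta)^2 / delta^2)` with
#' two-sided alpha. `sigma` may be given directly or via its components
#' `sigma_T` (between-patient) and `sigma_e` (method), combined as
#' `sqrt(sigma_T^2 + sigma_e^2)`.
#'
#' @param delta expected absolute reduction in infarct size, %LV.
#' @param sigma SD of infarct size, %LV (optional if components given).
#' @param sigma_T,sigma_e variance components, %LV.
#' @param alpha,beta error rates.
#' @return Integer patients per arm.
#' @export
sample_size <- function(delta, sigma = NULL, sigma_T = NULL, sigma_e = NULL,
                        alpha = 0.05, beta = 0.2) {
  if (delta <= 0) stopf("delta must be positive")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stopf("alpha and beta must lie in (0, 1)")
  if (is.null(sigma)) {
    if (is.null(sigma_T) || is.null(sigma_e))
      stopf("supply sigma, or both sigma_T and sigma_e")
    sigma <- sqrt(sigma_T^2 + sigma_e^2)
  }
  if (sigma == 0) {
    warnf("sigma is 0: sample size degenerates to 0")
    return(0L)
  }
  z <- qnorm(1 - alpha / 2) + qnorm(1 - beta)
  as.integer(ceiling(2 * sigma^2 * z^2 / delta^2))
}

#' Correlation between image quality and measurement variability
#'
#' Pearson correlation (with least-squares slope and intercept) between
#' per-patient variability and a per-patient image-quality measure (SNR or
#' CNR).
#'
#' @param variability numeric vector (e.g. per-patient averaged absolute
#'   differences, %LV).
#' @param quality numeric vector of equal length (SNR or CNR).
#' @return List: `r`, `slope`, `intercept`, `n`.
#' @export
quality_correlation <- function(variability, quality) {
  if (length(variability) != length(quality)) stopf("lists must have equal length")
  if (length(variability) < 3) stopf("need at least 3 patients")
  if (sd(variability) == 0 || sd(quality) == 0)
    stopf("zero variance: correlation undefined")
  fit <- lm(variability ~ quality)
  list(r = cor(quality, variability),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(quality))
}

#' Full reproducibility report
#'
#' Per method: mean and SD of infarct size, the per-patient difference
#' summary, CV, ICC(2,1) with CI, all pairwise Bland-Altman entries,
#' variance components, and sample sizes for deltas of 3, 5 and 7 %LV.
#'
#' @param table measurement data.frame.
#' @param value measurement column.
#' @param deltas absolute reductions (%LV) for the sample-size table.
#' @param sigma_source `"total"` (`sqrt(sigma_T^2 + sigma_e^2)`, default) or
#'   `"between"` (`sigma_T` alone) for the sample-size sigma.
#' @return An object of class `lge_repro_report`: named list of per-method
#'   reports plus a `sample_sizes` data.frame.
#' @export
run_reproducibility <- function(table, value = "percent_lv",
                                deltas = c(3, 5, 7),
                                sigma_source = c("total", "between")) {
  sigma_source <- match.arg(sigma_source)
  methods <- unique(table$method)
  out <- list()
  ss_rows <- list()
  for (m in methods) {
    wide <- check_table(table, m, value)
    d <- per_patient_diffs(table, m, value)
    vc <- variance_components(table, m, value)
    ic <- icc(table, m, value)
    readers <- colnames(wide)
    pairs <- utils::combn(readers, 2, simplify = FALSE)
    ba <- lapply(pairs, function(p) c(list(readers = p),
                                      bland_altman(table, m, p, value)))
    sig <- if (sigma_source == "total") sqrt(vc$sigma_T2 + vc$sigma_e2)
           else sqrt(vc$sigma_T2)
    ns <- vapply(deltas, function(dd) sample_size(dd, sigma = sig), integer(1))
    out[[m]] <- list(method = m, mean_size = mean(wide), sd_size = sd(as.vector(wide)),
                     mean_abs_diff = d$mean, sd_of_diffs = d$sd,
                     cv = cv(table, m, value),
                     icc = ic$icc, icc_lower = ic$lower, icc_upper = ic$upper,
                     bland_altman = ba,
                     sigma_T2 = vc$sigma_T2, sigma_e2 = vc$sigma_e2,
                     within_share = vc$within_share,
                     sample_sizes = stats::setNames(ns, paste0("delta_", deltas)))
    ss_rows[[m]] <- data.frame(method = m, t(ns))
  }
  ss <- do.call(rbind, ss_rows)
  names(ss)[-1] <- paste0("delta_", deltas)
  rownames(ss) <- NULL
  structure(list(methods = out, sample_sizes = ss, value = value),
            class = "lge_repro_report")
}

#' Summary table of a reproducibility report
#'
#' One row per method: mean and SD of infarct size, CV, ICC with its 95% CI,
#' and the within-patient variance share.
#'
#' @param report an [run_reproducibility()] result.
#' @return A data.frame.
#' @export
report_summary <- function(report) {
  do.call(rbind, lapply(report$methods, function(m)
    data.frame(method = m$method, mean_size = m$mean_size, sd_size = m$sd_size,
               mean_abs_diff = m$mean_abs_diff, sd_of_diffs = m$sd_of_diffs,
               cv = m$cv, icc = m$icc, icc_lower = m$icc_lower,
               icc_upper = m$icc_upper, within_share = m$within_share,
               row.names = NULL)))
}

#' Pairwise Bland-Altman table of a reproducibility report
#'
#' One row per (method, reader pair): bias, SD, limits of agreement and the
#' paired t-test p-value.
#'
#' @param report an [run_reproducibility()] result.
#' @return A data.frame.
#' @export
report_pairwise <- function(report) {
  do.call(rbind, lapply(report$methods, function(m)
    do.call(rbind, lapply(m$bland_altman, function(b)
      data.frame(method = m$method, reader_a = b$readers[1],
                 reader_b = b$readers[2], bias = b$bias, sd = b$sd,
                 loa_low = b$loa[1], loa_high = b$loa[2], p = b$p,
                 row.names = NULL)))))
}

#' @export
print.lge_repro_report <- function(x, ...) {
  cat(sprintf("<lge_repro_report> (%s)\n", x$value))
  cat(sprintf("%-16s %8s %8s %6s %18s %8s\n",
              "method", "mean", "sd", "CV%", "ICC [95% CI]", "within%"))
  for (m in x$methods) {
    cat(sprintf("%-16s %8.2f %8.2f %6.1f %5.2f [%.2f, %.2f] %7.1f\n",
                m$method, m$mean_size, m$sd_size, m$cv,
                m$icc, m$icc_lower, m$icc_upper, 100 * m$within_share))
  }
  cat("\nSample size per arm:\n")
  print(x$sample_sizes, row.names = FALSE)
  invisible(x)
}
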