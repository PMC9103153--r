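#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the survival step
#' function as a plain table. The estimator is non-increasing with S(0) = 1;
#' censored times do not create steps (steps occur only where `n_event > 0`).
#'
#' @param time non-negative follow-up times (one unit throughout).
#' @param event logical or 0/1; `TRUE` = death observed, `FALSE` = censored.
#' @return an object of class `km_curve`: data.frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, one row per distinct observed
#'   time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty survival table", call. = FALSE)
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
plot.km_curve <- function(x, ..., xlab = "time", ylab = "S(t)") {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1),
                 main = "Kaplan-Meier estimate", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Sums observed-minus-expected events over the risk set at each distinct
#' event time with the hypergeometric variance; the statistic
#' `(O - E)^2 / V` is referred to a chi-square distribution with one degree
#' of freedom. Computed via [survival::survdiff()]. Censored subjects at an
#' event time remain in the risk set at that time. When no risk set is
#' comparable (zero variance) the test is uninformative: p = 1 with a
#' warning.
#'
#' @param time non-negative follow-up times, both groups pooled.
#' @param event logical or 0/1 event indicators.
#' @param group two-level grouping vector.
#' @return list with components `chisq` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("exactly two non-empty groups required", call. = FALSE)
  if (sum(as.integer(event)) < 1L)
    stop("at least one event required", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  chisq <- unname(fit$chisq)
  if (!is.finite(chisq)) {
    warning("log-rank variance is zero; no comparable risk sets",
            call. = FALSE)
    return(list(chisq = 0, p = 1))
  }
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Optimal-cutoff survival stratification
#'
#' The cutoff-scanning procedure popularized by the Cutoff Finder web tool:
#' every midpoint between consecutive distinct expression values that leaves
#' at least `min_group_frac` of the samples on each side is a candidate
#' threshold; the marker is dichotomized at each candidate, groups are
#' compared by the log-rank test, and the cutoff minimizing the p-value is
#' reported. Ties on the minimum are broken toward the cutoff closest to the
#' median expression. The reported `optimal_p` is **unadjusted** for the scan
#' multiplicity and is anti-conservative as a hypothesis test; it is a
#' stratification device, not a calibrated p-value.
#'
#' @param table data.frame with columns `time`, `event`, `expression` (a
#'   `sample_id` column is carried along if present).
#' @param min_group_frac minimum fraction of samples per side (default 0.10).
#' @return an object of class `cutoff_scan`: list with `scan` (data.frame
#'   `cutoff`, `n_low`, `n_high`, `chisq`, `p`), `optimal_cutoff`,
#'   `optimal_p`, `n` and `min_group_frac`.
#' @export
optimal_cutoff <- function(table, min_group_frac = 0.10) {
  stopifnot(all(c("time", "event", "expression") %in% colnames(table)))
  n <- nrow(table)
  if (n < ceiling(1 / min_group_frac))
    stop("need at least ", ceiling(1 / min_group_frac),
         " samples for min_group_frac = ", min_group_frac, call. = FALSE)
  if (sum(as.integer(table$event)) < 2L)
    stop("at least 2 observed events required", call. = FALSE)
  xs <- sort(unique(table$expression))
  if (length(xs) < 2L)
    stop("expression is constant; no admissible cutoff", call. = FALSE)
  cand <- (xs[-length(xs)] + xs[-1L]) / 2
  n_low <- vapply(cand, function(c) sum(table$expression <= c), 0L)
  ok <- n_low / n >= min_group_frac & (n - n_low) / n >= min_group_frac
  cand <- cand[ok]
  n_low <- n_low[ok]
  if (length(cand) == 0L)
    stop("no admissible cutoff at min_group_frac = ", min_group_frac,
         call. = FALSE)
  res <- vapply(cand, function(c) {
    lr <- suppressWarnings(
      logrank_test(table$time, table$event, table$expression > c))
    c(lr$chisq, lr$p)
  }, numeric(2L))
  scan <- data.frame(cutoff = cand, n_low = n_low, n_high = n - n_low,
                     chisq = res[1L, ], p = res[2L, ])
  best <- which(scan$p == min(scan$p))
  if (length(best) > 1L)   # tie: take the cutoff nearest the marker median
    best <- best[which.min(abs(scan$cutoff[best] -
                                 stats::median(table$expression)))]
  structure(list(scan = scan, optimal_cutoff = scan$cutoff[best],
                 optimal_p = scan$p[best], n = n,
                 min_group_frac = min_group_frac),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat("Optimal-cutoff scan (", nrow(x$scan), " admissible cutoffs, n = ",
      x$n, ")\n", sep = "")
  cat("  optimal cutoff: ", format(x$optimal_cutoff), "\n", sep = "")
  cat("  log-rank p at optimum (UNADJUSTED for scan multiplicity): ",
      format(x$optimal_p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.cutoff_scan <- function(x, ...) {
  graphics::plot(x$scan$cutoff, -log10(x$scan$p), type = "l",
                 xlab = "expression cutoff", ylab = "-log10 log-rank p",
                 main = "Cutoff scan", ...)
  graphics::abline(v = x$optimal_cutoff, lty = 2)
  invisible(x)
}

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of mid-ranks (average ranks on ties) with a two-sided
#' p-value from the t-transform on n - 2 degrees of freedom — the form used
#' for semiquantitative scores such as in situ hybridization scoring, where
#' ties are pervasive.
#'
#' @param x,y paired numeric score vectors, length >= 3.
#' @return list with components `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant vector; rank correlation undefined", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p = correlation_pvalue(rho, length(x)))
}

#' Read / write a survival table
#'
#' TSV with header columns `sample_id`, `time`, `event` (0/1), `expression`.
#'
#' @param path file path.
#' @return data.frame with those columns; `event` is integer 0/1.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("sample_id", "time", "event", "expression")
  if (!all(need %in% colnames(df)))
    stop("unknown column layout in ", path, ": expected headers ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- df[need]
  if (anyNA(df)) stop("missing fields in survival table", call. = FALSE)
  if (any(df$time < 0)) stop("negative survival time", call. = FALSE)
  df$event <- as.integer(df$event)
  df
}

#' @rdname read_survival_table
#' @param table survival data.frame.
#' @export
write_survival_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
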