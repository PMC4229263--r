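# Test-retest reliability: one-way random-effects, single-measures
# intraclass correlation (ICC(1,1)) with F-based 95% confidence intervals,
# applied per measured parameter across two capture sessions.

#' One-way single-measures intraclass correlation
#'
#' ICC(1,1) from a one-way random-effects ANOVA on an n x k table
#' (subjects x sessions): ICC = (MSB - MSW) / (MSB + (k-1) MSW), with MSB
#' the between-subject mean square (df n-1) and MSW the within-subject
#' mean square (df n(k-1)).
#'
#' @param x numeric n x k matrix, one row per subject, one column per
#'   session; no missing cells.
#' @return An object of class `fm_icc`: `icc`, `msb`, `msw`, `n`, `k`,
#'   `undefined` (TRUE when the table has zero total variance).
#' @export
icc_oneway <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2)
    stop("need at least 2 subjects and 2 sessions", call. = FALSE)
  if (anyNA(x))
    stop("missing cells are not allowed (exclude incomplete subjects)",
         call. = FALSE)
  rm_ <- rowMeans(x)
  grand <- mean(x)
  msb <- k * sum((rm_ - grand)^2) / (n - 1)
  msw <- sum((x - rm_)^2) / (n * (k - 1))
  undefined <- msb == 0 && msw == 0
  icc <- if (undefined) NA_real_ else (msb - msw) / (msb + (k - 1) * msw)
  structure(list(icc = icc, msb = msb, msw = msw, n = n, k = k,
                 undefined = undefined), class = "fm_icc")
}

#' @export
print.fm_icc <- function(x, ...) {
  if (x$undefined) cat("ICC(1,1): undefined (zero total variance)\n")
  else cat(sprintf("ICC(1,1) = %.3f  (MSB %.4g, MSW %.4g, n %d, k %d)\n",
                   x$icc, x$msb, x$msw, x$n, x$k))
  invisible(x)
}

#' F-based confidence interval for a one-way single-measures ICC
#'
#' From the observed F = (1 + (k-1) ICC) / (1 - ICC), the bounds come
#' from dividing by / multiplying with the upper alpha/2 F quantiles with
#' (n-1, n(k-1)) and (n(k-1), n-1) degrees of freedom, each mapped back
#' through ICC = (F - 1) / (F + k - 1).
#'
#' @param icc point estimate (an `fm_icc` or a number < 1).
#' @param n,k subjects and sessions (taken from the `fm_icc` if given).
#' @param alpha two-sided level (default 0.05 for a 95% interval).
#' @return `c(lower, upper)`. For ICC = 1 the interval is degenerate and
#'   `c(lower, 1)` is returned.
#' @export
icc_confint <- function(icc, n = NULL, k = NULL, alpha = 0.05) {
  if (inherits(icc, "fm_icc")) {
    n <- icc$n; k <- icc$k; icc <- icc$icc
  }
  stopifnot(is.numeric(icc), length(icc) == 1, !is.null(n), !is.null(k),
            n >= 2, k >= 2)
  if (is.na(icc)) return(c(NA_real_, NA_real_))
  if (icc >= 1) return(c(1, 1))  # degenerate perfect agreement
  Fobs <- (1 + (k - 1) * icc) / (1 - icc)
  FL <- Fobs / qf(1 - alpha / 2, n - 1, n * (k - 1))
  FU <- Fobs * qf(1 - alpha / 2, n * (k - 1), n - 1)
  c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
}

#' Test-retest reliability table
#'
#' Pairs two sessions' measurements by subject and parameter and computes,
#' for every parameter, the one-way single-measures ICC with its 95%
#' confidence interval, plus per-class averages (distance / angle /
#' direction), mirroring the reporting layout of the static reliability
#' table.
#'
#' @param session1,session2 data.frames with columns `subject`,
#'   `parameter`, `value` and optionally `class`.
#' @param alpha two-sided level for the intervals.
#' @return A data.frame `(parameter, class, n, icc, lower, upper)` with an
#'   attribute `class_averages` (mean ICC per parameter class).
#' @export
reliability_table <- function(session1, session2, alpha = 0.05) {
  for (d in list(session1, session2))
    if (!all(c("subject", "parameter", "value") %in% names(d)))
      stop("sessions need columns subject, parameter, value", call. = FALSE)
  p1 <- unique(session1$parameter); p2 <- unique(session2$parameter)
  if (!setequal(p1, p2))
    stop("mismatched parameter sets between sessions: ",
         paste(c(setdiff(p1, p2), setdiff(p2, p1)), collapse = ", "),
         call. = FALSE)
  cls <- if ("class" %in% names(session1))
    session1$class[match(p1, session1$parameter)] else NA_character_
  rows <- lapply(seq_along(p1), function(i) {
    par <- p1[i]
    d1 <- session1[session1$parameter == par, ]
    d2 <- session2[session2$parameter == par, ]
    subj <- intersect(d1$subject, d2$subject)
    dropped <- length(union(d1$subject, d2$subject)) - length(subj)
    if (dropped > 0)
      message(par, ": ", dropped, " subject(s) excluded (missing session)")
    x <- cbind(d1$value[match(subj, d1$subject)],
               d2$value[match(subj, d2$subject)])
    ic <- icc_oneway(x)
    ci <- icc_confint(ic, alpha = alpha)
    data.frame(parameter = par, class = cls[i], n = length(subj),
               icc = ic$icc, lower = ci[1], upper = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!all(is.na(out$class)))
    attr(out, "class_averages") <-
      tapply(out$icc, out$class, mean, na.rm = TRUE)
  out
}

#' Simulate a two-session measurement cohort
#'
#' Generates per-subject "true" parameter values plus independent
#' per-session measurement noise, the variance-components model under
#' which ICC(1,1) estimates sigma_b^2 / (sigma_b^2 + sigma_w^2). Used for
#' parameter-recovery testing of the reliability machinery.
#'
#' @param n_subjects cohort size (the reliability study used 19).
#' @param k sessions per subject (default 2).
#' @param mean_value population mean of the parameter.
#' @param sigma_between between-subject SD (mm).
#' @param sigma_within within-subject (session) SD (mm).
#' @param seed RNG seed.
#' @return An n x k matrix of measurements.
#' @export
simulate_reliability_cohort <- function(n_subjects = 19, k = 2,
                                        mean_value = 100,
                                        sigma_between = 5,
                                        sigma_within = 0.5, seed = 1) {
  with_seed(seed, {
    truth <- rnorm(n_subjects, mean_value, sigma_between)
    matrix(rnorm(n_subjects * k, rep(truth, k), sigma_within),
           n_subjects, k)
  })
}
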