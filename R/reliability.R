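#' Pair control questions with their originals
#'
#' Builds the repeated-measurement table behind intra-observer reliability:
#' one row per control question per observer, joining the observer's
#' original answer with their repeat. Stage-2 choices are encoded as an
#' orientation-normalized binary value (1 when the observer preferred the
#' lexicographically first model of the pair) so that the encoding is
#' invariant to left/right presentation; stage-1 answers are encoded as the
#' grade or the correctness indicator.
#'
#' @param responses Response data frame (stage 1 responses should already be
#'   graded via [grade_responses()] when `measure` is `"grade"` or
#'   `"correctness"`).
#' @param measure `"choice"` (stage 2), `"grade"` or `"correctness"`
#'   (stage 1).
#' @return Data frame of class `paired_administration` with columns
#'   `observer_id`, `item`, `original`, `repeated`; the number of control
#'   rows dropped for a dangling `source_question_id` is stored in
#'   attribute `n_dropped`.
#' @export
pair_controls <- function(responses, measure = c("choice", "grade",
                                                 "correctness")) {
  measure <- match.arg(measure)
  encode <- function(df) {
    switch(measure,
           choice = as.numeric(df$chosen == pmin(df$model_a, df$model_b)),
           grade = as.numeric(df$grade),
           correctness = as.numeric(df$is_correct))
  }
  ctrl <- responses[responses$is_control &
                      !is.na(responses$source_question_id), , drop = FALSE]
  orig <- responses[!responses$is_control, , drop = FALSE]
  okey <- paste(orig$observer_id, orig$question_id, sep = "\r")
  ckey <- paste(ctrl$observer_id, ctrl$source_question_id, sep = "\r")
  hit <- match(ckey, okey)
  n_dropped <- sum(is.na(hit))
  if (n_dropped > 0)
    warning(n_dropped, " control response(s) had no matching original",
            call. = FALSE)
  ctrl <- ctrl[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]
  out <- data.frame(observer_id = ctrl$observer_id,
                    item = ctrl$source_question_id,
                    original = encode(orig[hit, , drop = FALSE]),
                    repeated = encode(ctrl),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("paired_administration", "data.frame")
  out
}

as_reliability_matrix <- function(m) {
  if (inherits(m, "paired_administration"))
    m <- cbind(original = m$original, repeated = m$repeated)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 items", call. = FALSE)
  if (anyNA(m)) stop("missing values in reliability matrix", call. = FALSE)
  m
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient for an items-by-columns score matrix:
#' `alpha = k/(k-1) * (1 - sum(var_i) / var(rowsums))` with sample (n-1)
#' variances. For test-retest data the two columns are the original and
#' repeated administrations over the control items.
#'
#' @param m Numeric matrix (rows = items, columns = administrations or
#'   parts), or a `paired_administration`.
#' @return Alpha in (-Inf, 1\]; `NA` when the total variance is zero.
#' @export
cronbach_alpha <- function(m) {
  m <- as_reliability_matrix(m)
  k <- ncol(m)
  vt <- stats::var(rowSums(m))
  if (vt == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' Guttman's lambda-6
#'
#' Reliability from squared multiple correlations: `lambda6 = 1 -
#' sum(var_i * (1 - smc_i)) / var(rowsums)` where `smc_i` is the squared
#' multiple correlation of column i regressed on the remaining columns (for
#' two columns, the squared inter-column correlation).
#'
#' @inheritParams cronbach_alpha
#' @return Lambda-6 in (-Inf, 1\]; `NA` for a zero total variance or a
#'   singular column correlation matrix.
#' @export
guttman_lambda6 <- function(m) {
  m <- as_reliability_matrix(m)
  vt <- stats::var(rowSums(m))
  if (vt == 0) return(NA_real_)
  vars <- apply(m, 2, stats::var)
  if (any(vars == 0)) return(NA_real_)
  # smc via per-column regression R^2: equals 1 - 1/diag(solve(cor(m))) when
  # the correlation matrix is invertible, and degrades gracefully to 1 for
  # perfectly collinear columns (identical columns give lambda6 = 1)
  smc <- vapply(seq_len(ncol(m)), function(i) {
    fit <- stats::lm.fit(cbind(1, m[, -i, drop = FALSE]), m[, i])
    1 - sum(fit$residuals^2) / ((nrow(m) - 1) * vars[i])
  }, numeric(1))
  1 - sum(vars * (1 - smc)) / vt
}

#' Feldt confidence interval for coefficient alpha
#'
#' F-distribution pivot: with n items and k columns, `(1 - alpha)` follows a
#' scaled F with `n - 1` and `(n - 1)(k - 1)` degrees of freedom, giving
#' `low = 1 - (1 - alpha) * F_{1-a/2}` and
#' `high = 1 - (1 - alpha) * F_{a/2}`.
#'
#' @param alpha Point estimate (must be < 1).
#' @param n_items Number of items (rows), at least 3.
#' @param k Number of columns.
#' @param confidence Coverage, default 0.95.
#' @return Numeric `c(low, high)`.
#' @export
feldt_ci <- function(alpha, n_items, k, confidence = 0.95) {
  if (n_items < 3L) stop("need at least 3 items", call. = FALSE)
  if (!is.finite(alpha) || alpha >= 1)
    stop("alpha must be finite and < 1", call. = FALSE)
  a <- 1 - confidence
  df1 <- n_items - 1
  df2 <- (n_items - 1) * (k - 1)
  c(low = 1 - (1 - alpha) * stats::qf(1 - a / 2, df1, df2),
    high = 1 - (1 - alpha) * stats::qf(a / 2, df1, df2))
}

#' Asymptotic (delta-method) confidence interval for alpha
#'
#' Normal-theory interval from the asymptotic standard error of coefficient
#' alpha derived from the sample covariance matrix (the
#' Duhachek–Iacobucci estimator). Cross-check against the bootstrap
#' interval on small samples, where the normal approximation can be
#' optimistic.
#'
#' @inheritParams cronbach_alpha
#' @param confidence Coverage, default 0.95.
#' @return `c(low, high, se)`.
#' @export
duhachek_ci <- function(m, confidence = 0.95) {
  m <- as_reliability_matrix(m)
  n <- nrow(m); k <- ncol(m)
  S <- stats::cov(m)
  j <- rep(1, k)
  jSj <- drop(crossprod(j, S %*% j))
  if (jSj <= 0) stop("degenerate covariance matrix", call. = FALSE)
  S2 <- S %*% S
  num <- jSj * (sum(diag(S2)) + sum(diag(S))^2) -
    2 * sum(diag(S)) * drop(crossprod(j, S2 %*% j))
  ase2 <- (2 * k^2 / ((k - 1)^2 * jSj^3)) * num / n
  se <- sqrt(max(ase2, 0))
  alpha <- k / (k - 1) * (1 - sum(diag(S)) / jSj)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  c(low = alpha - z * se, high = alpha + z * se, se = se)
}

#' Bootstrap percentile confidence interval for alpha
#'
#' Resamples items (rows) with replacement, recomputing alpha each time,
#' and reports the percentile interval. Deterministic for a fixed seed.
#'
#' @inheritParams cronbach_alpha
#' @param n_boot Bootstrap replicates, default 2000.
#' @param confidence Coverage, default 0.95.
#' @param seed Integer seed.
#' @return `c(low, high)`.
#' @export
bootstrap_alpha_ci <- function(m, n_boot = 2000L, confidence = 0.95,
                               seed = NULL) {
  m <- as_reliability_matrix(m)
  n <- nrow(m)
  alphas <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    mb <- m[sample.int(n, n, replace = TRUE), , drop = FALSE]
    vt <- stats::var(rowSums(mb))
    if (vt == 0) return(1)  # resample collapsed to identical rows
    ncol(mb) / (ncol(mb) - 1) * (1 - sum(apply(mb, 2, stats::var)) / vt)
  }, numeric(1)))
  a <- 1 - confidence
  q <- stats::quantile(alphas, c(a / 2, 1 - a / 2), na.rm = TRUE,
                       names = FALSE)
  c(low = q[1], high = q[2])
}

#' Full reliability report for a repeated-measurement table
#'
#' Computes alpha and lambda-6 with Feldt, asymptotic and bootstrap
#' confidence intervals, either pooled over all observers or separately per
#' observer (both views matter: pooled reliability can mask a single
#' observer's stability).
#'
#' @param paired A `paired_administration` from [pair_controls()].
#' @param by_observer Report each observer separately?
#' @param n_boot,confidence,seed Passed to the interval methods.
#' @return A `reliability_report` (list) or, with `by_observer = TRUE`, a
#'   named list of them.
#' @export
reliability_report <- function(paired, by_observer = FALSE, n_boot = 2000L,
                               confidence = 0.95, seed = NULL) {
  if (by_observer) {
    obs <- sort(unique(paired$observer_id))
    out <- lapply(obs, function(o)
      reliability_report(paired[paired$observer_id == o, , drop = FALSE],
                         n_boot = n_boot, confidence = confidence,
                         seed = seed))
    return(stats::setNames(out, obs))
  }
  m <- as_reliability_matrix(paired)
  alpha <- cronbach_alpha(m)
  rep <- list(
    alpha = alpha,
    lambda6 = guttman_lambda6(m),
    feldt = if (is.finite(alpha) && alpha < 1)
      feldt_ci(alpha, nrow(m), ncol(m), confidence) else c(low = NA, high = NA),
    duhachek = duhachek_ci(m, confidence),
    bootstrap = bootstrap_alpha_ci(m, n_boot, confidence, seed),
    n_items = nrow(m), n_columns = ncol(m),
    bootstrap_n = n_boot, confidence = confidence, seed = seed
  )
  class(rep) <- "reliability_report"
  rep
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("alpha = %.3f  lambda6 = %.3f  (n = %d items)\n",
              x$alpha, x$lambda6, x$n_items))
  cat(sprintf("  %g%% CI (Feldt)     : %.3f .. %.3f\n", 100 * x$confidence,
              x$feldt[["low"]], x$feldt[["high"]]))
  cat(sprintf("  %g%% CI (asymptotic): %.3f .. %.3f\n", 100 * x$confidence,
              x$duhachek[["low"]], x$duhachek[["high"]]))
  cat(sprintf("  %g%% CI (bootstrap %d): %.3f .. %.3f\n", 100 * x$confidence,
              x$bootstrap_n, x$bootstrap[["low"]], x$bootstrap[["high"]]))
  invisible(x)
}

#' Build a subjects-by-raters panel from pairwise responses
#'
#' Treats each (image, unordered model pair) as one subject and each
#' observer as a rater; the rating is their preference within the pair,
#' encoded orientation-normalized as `"first"`/`"second"` (whether the
#' lexicographically first model of the pair was preferred), so that the
#' chance-agreement baseline is the binary choice the observers actually
#' faced. Control duplicates are omitted as redundant, and subjects not
#' rated by every rater are dropped so the panel is complete.
#'
#' @param responses Stage-2 response data frame.
#' @return Character matrix (subjects x raters) suitable for
#'   [fleiss_kappa()].
#' @export
pairwise_rater_panel <- function(responses) {
  r <- responses[!responses$is_control, , drop = FALSE]
  pair <- paste(pmin(r$model_a, r$model_b), pmax(r$model_a, r$model_b),
                sep = " vs ")
  subject <- paste(r$image_id, pair, sep = " | ")
  raters <- sort(unique(r$observer_id))
  rating <- ifelse(r$chosen == pmin(r$model_a, r$model_b),
                   "first", "second")
  tab <- tapply(rating, list(subject, factor(r$observer_id, raters)),
                function(x) x[[1]])
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  tab
}

#' Fleiss' kappa for m raters
#'
#' Chance-corrected agreement among m raters assigning categorical ratings
#' to n subjects: `kappa = (P_bar - Pe_bar) / (1 - Pe_bar)` from the
#' per-subject observed agreement and the squared category marginals, with
#' the large-sample z statistic and two-sided p-value.
#'
#' @param panel Matrix (subjects x raters) of categorical ratings, e.g.
#'   from [pairwise_rater_panel()].
#' @return A `kappa_report`: list with `kappa`, `z`, `p_value`,
#'   `n_subjects`, `n_raters`, `n_categories`. `kappa` is `NA` when all
#'   raters always use a single category (expected agreement 1).
#' @export
fleiss_kappa <- function(panel) {
  panel <- as.matrix(panel)
  if (anyNA(panel)) {
    panel <- panel[stats::complete.cases(panel), , drop = FALSE]
  }
  ns <- nrow(panel); nr <- ncol(panel)
  if (ns < 2L || nr < 2L)
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  cats <- sort(unique(as.vector(panel)))
  if (length(cats) < 2L)
    return(structure(list(kappa = NA_real_, z = NA_real_,
                          p_value = NA_real_, n_subjects = ns,
                          n_raters = nr, n_categories = length(cats)),
                     class = "kappa_report"))
  counts <- t(vapply(seq_len(ns), function(i)
    as.integer(table(factor(panel[i, ], levels = cats))),
    integer(length(cats))))
  p_bar <- mean((rowSums(counts^2) - nr) / (nr * (nr - 1)))
  pj <- colSums(counts) / (ns * nr)
  pe_bar <- sum(pj^2)
  if (pe_bar >= 1) {
    kappa <- NA_real_; z <- NA_real_; p <- NA_real_
  } else {
    kappa <- (p_bar - pe_bar) / (1 - pe_bar)
    qj <- 1 - pj
    vark <- (2 / (sum(pj * qj)^2 * ns * nr * (nr - 1))) *
      (sum(pj * qj)^2 - sum(pj * qj * (qj - pj)))
    z <- kappa / sqrt(vark)
    p <- 2 * (1 - stats::pnorm(abs(z)))
  }
  structure(list(kappa = kappa, z = z, p_value = p, n_subjects = ns,
                 n_raters = nr, n_categories = length(cats)),
            class = "kappa_report")
}

#' @export
print.kappa_report <- function(x, ...) {
  cat(sprintf("Fleiss kappa = %.4f (z = %.3f, p = %.3g); %d subjects, %d raters, %d categories\n",
              x$kappa, x$z, x$p_value, x$n_subjects, x$n_raters,
              x$n_categories))
  invisible(x)
}
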