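# Brain-age-gap summaries and the rank-based statistical battery:
# Mann-Whitney U (exact enumeration and normal approximation), Spearman
# correlation, partial Spearman correlation with covariate adjustment,
# Bonferroni correction, Bland-Altman limits of agreement, and the grouped
# clinical-variable comparison tables.

#' Brain age gap
#'
#' `bag = predicted - chronological`: positive values indicate an
#' older-appearing brain.
#'
#' @param predicted,chronological ages in years (vectorized).
#' @return BAG in years.
#' @export
bag <- function(predicted, chronological) predicted - chronological

#' Mean absolute error of age predictions
#'
#' @param records data.frame with a `bag` column (see [predict_records()]).
#' @return MAE in years.
#' @export
mae <- function(records) {
  if (nrow(records) < 1) stop("need at least one record")
  mean(abs(records$bag))
}

#' Mean and SD of the brain age gap
#'
#' @param records data.frame with a `bag` column.
#' @return list with `mean` and `sd` (sample SD, n - 1 denominator).
#' @export
mean_bag <- function(records) {
  if (nrow(records) < 1) stop("need at least one record")
  list(mean = mean(records$bag),
       sd = if (nrow(records) >= 2) stats::sd(records$bag) else NA_real_)
}

#' Bland-Altman agreement summary
#'
#' Limits of agreement are `mean_diff +/- 1.96 sd_diff` where the
#' difference is predicted - chronological (the BAG) and sd is the sample
#' standard deviation. Also emits the (mean of the two ages, difference)
#' pairs used for plotting.
#'
#' @param records data.frame with `age`, `predicted_age` (>= 2 rows).
#' @return a `bland_altman` list: `mean_diff`, `sd_diff`, `lower_limit`,
#'   `upper_limit`, `points` (data.frame `mean_age`, `diff`).
#' @export
bland_altman <- function(records) {
  if (nrow(records) < 2) stop("need at least two records")
  d <- records$predicted_age - records$age
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 lower_limit = m - 1.96 * s, upper_limit = m + 1.96 * s,
                 points = data.frame(mean_age = (records$age +
                                                   records$predicted_age) / 2,
                                     diff = d)),
            class = "bland_altman")
}

stat_result <- function(statistic, p_value, method, n, estimate = NULL,
                        corrected_alpha = NULL) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n, estimate = estimate, corrected_alpha = corrected_alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

# Midranks (average ranks for ties).
midrank <- function(x) rank(x, ties.method = "average")

#' Mann-Whitney U test
#'
#' Two-sided test of distributional shift. `exact` mode enumerates all
#' `choose(n + m, n)` label assignments over the pooled midranks and
#' returns the probability mass with `|U - nm/2|` at least as extreme as
#' observed (ties handled by enumeration over midranks). `normal_approx`
#' uses the tie-corrected normal approximation with continuity correction.
#' `auto` picks exact when `n + m <= 16`.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return a `stat_result` (statistic = U of sample `x`).
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both samples must be non-empty")
  if (mode == "auto") mode <- if (n + m <= 16) "exact" else "normal_approx"
  pooled <- c(x, y)
  r <- midrank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (mode == "exact") {
    combs <- utils::combn(n + m, n)
    stat <- apply(combs, 2, function(ix) sum(r[ix])) - n * (n + 1) / 2
    center <- n * m / 2
    p <- mean(abs(stat - center) >= abs(U - center) - 1e-12)
    return(stat_result(U, p, "Mann-Whitney U (exact)", c(n, m)))
  }
  # normal approximation with tie and continuity corrections
  N <- n + m
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  mu <- n * m / 2
  if (sigma2 <= 0) return(stat_result(U, 1, "Mann-Whitney U (normal approx)",
                                      c(n, m)))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  stat_result(U, p, "Mann-Whitney U (normal approx)", c(n, m))
}

#' Spearman rank correlation
#'
#' Midranks for ties; p-value from the t approximation with `n - 2` degrees
#' of freedom (`exact_perm = TRUE` enumerates all permutations, only
#' sensible for `n <= 10`).
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @param exact_perm use the exact permutation null instead of the t
#'   approximation.
#' @return a `stat_result` with `estimate` = rho.
#' @export
spearman <- function(x, y, exact_perm = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need n >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("rho undefined for a constant input vector")
  rx <- midrank(x); ry <- midrank(y)
  rho <- stats::cor(rx, ry)
  if (exact_perm) {
    if (n > 10) stop("exact permutation p only supported for n <= 10")
    perms <- permn_matrix(n)
    rhos <- apply(perms, 2, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(stat_result(rho, p, "Spearman (exact permutation)", n,
                       estimate = rho))
  }
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  stat_result(rho, p, "Spearman (t approximation)", n, estimate = rho)
}

# All permutations of 1..n as columns (n! <= 3.6e6 for n = 10).
permn_matrix <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permn_matrix(n - 1)
  # insert n into every slot of each permutation of 1..(n-1)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0
  for (j in seq_len(ncol(sub))) for (pos in 0:(n - 1)) {
    k <- k + 1
    out[, k] <- append(sub[, j], n, after = pos)
  }
  out
}

#' Partial Spearman correlation
#'
#' Ranks are computed for `x`, `y` and each numeric covariate (binary
#' covariates such as sex enter as 0/1); the x- and y-ranks are each
#' residualized on the covariate columns by least squares with intercept,
#' and the result is the Pearson correlation of the residuals. The p-value
#' is a t test with `n - k - 2` degrees of freedom, `k` covariates. With no
#' covariates this reduces exactly to [spearman()].
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame (or matrix) of covariates, possibly empty.
#' @return a `stat_result` with `estimate` = partial rho.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n <= k + 2) stop("need n > number of covariates + 2")
  rx <- midrank(x); ry <- midrank(y)
  if (k == 0) {
    rho <- stats::cor(rx, ry)
  } else {
    cv <- as.data.frame(covariates)
    Z <- vapply(cv, function(col) {
      if (is.character(col) || is.factor(col) || is.logical(col)) {
        u <- unique(col)
        if (length(u) > 2) stop("non-numeric covariate with > 2 levels: encode it")
        as.numeric(col == u[max(1, length(u))])
      } else if (length(unique(col)) <= 2) as.numeric(col)
      else midrank(col)
    }, numeric(n))
    Z <- cbind(1, Z)
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      drop <- setdiff(seq_len(ncol(Z)), qrz$pivot[seq_len(qrz$rank)])
      stop("rank-deficient covariate matrix; collinear columns: ",
           paste(c("(intercept)", names(cv))[drop], collapse = ", "))
    }
    ex <- stats::residuals(stats::lm.fit(Z, rx))
    ey <- stats::residuals(stats::lm.fit(Z, ry))
    rho <- stats::cor(ex, ey)
  }
  df <- n - k - 2
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  }
  stat_result(rho, p, sprintf("partial Spearman (%d covariates)", k), n,
              estimate = rho)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

# Q3 - Q1 with linear-interpolation quantiles.
iqr_q3q1 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  q[2] - q[1]
}

#' Grouped clinical-variable comparison
#'
#' For a two-level grouping of the records (e.g. BAG < 0 vs BAG >= 0):
#' per-variable group medians and IQRs (Q3 - Q1) with a two-sided
#' Mann-Whitney p; and, against a continuous outcome (default `bag`),
#' per-variable univariate Spearman plus partial Spearman with the
#' configured covariate set.
#'
#' @param records data.frame holding the variables, the outcome and the
#'   covariates.
#' @param grouping logical vector (or name of a logical column) defining
#'   the two groups.
#' @param variables character vector of variable names to compare.
#' @param outcome outcome column for the correlation table (default "bag").
#' @param covariate_sets named list: for each variable, the covariate
#'   column names used in the partial correlation (default: `age` and
#'   `sex` for every variable, the convention for clinical covariates;
#'   supply e.g. `list(age_at_onset = "sex")` to override single entries).
#' @param mw_mode Mann-Whitney mode passed to [mann_whitney_u()].
#' @return list with `group_table` and `correlation_table` data.frames.
#' @export
compare_groups <- function(records, grouping, variables, outcome = "bag",
                           covariate_sets = NULL,
                           mw_mode = "normal_approx") {
  if (is.character(grouping) && length(grouping) == 1)
    grouping <- records[[grouping]]
  grouping <- as.logical(grouping)
  if (!any(grouping) || !any(!grouping))
    stop("grouping must yield two non-empty groups")
  miss <- setdiff(c(variables, outcome), names(records))
  if (length(miss))
    stop("variables absent from manifest: ", paste(miss, collapse = ", "))

  gt <- do.call(rbind, lapply(variables, function(v) {
    a <- records[[v]][grouping]; b <- records[[v]][!grouping]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    mw <- mann_whitney_u(a, b, mode = mw_mode)
    data.frame(variable = v,
               median_group1 = stats::median(a), iqr_group1 = iqr_q3q1(a),
               median_group2 = stats::median(b), iqr_group2 = iqr_q3q1(b),
               p_value = mw$p_value, stringsAsFactors = FALSE)
  }))

  default_cov <- intersect(c("age", "sex"), names(records))
  ct <- do.call(rbind, lapply(variables, function(v) {
    covs <- if (!is.null(covariate_sets) && v %in% names(covariate_sets))
      covariate_sets[[v]] else default_cov
    ok <- stats::complete.cases(records[, c(v, outcome, covs), drop = FALSE])
    uni <- spearman(records[[v]][ok], records[[outcome]][ok])
    par <- partial_spearman(records[[v]][ok], records[[outcome]][ok],
                            records[ok, covs, drop = FALSE])
    data.frame(variable = v, rho = uni$estimate, p_value = uni$p_value,
               partial_rho = par$estimate, partial_p = par$p_value,
               covariates = paste(covs, collapse = "+"),
               n = sum(ok), stringsAsFactors = FALSE)
  }))
  list(group_table = gt, correlation_table = ct)
}
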