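# Learning-curve fits, plateau detection, outcome-conditioned contrasts,
# de-adaptation indices, and the run-versus-reference correlation table.

#' Fit an exponential learning curve
#'
#' Nonlinear least squares of `a * exp(-x / b) + c` with multi-start
#' initialization. The time constant `b` is the learning rate in trials.
#' Fits with a negative time constant are flagged `negative_b`; fits whose
#' time constant exceeds five times the trial span (indistinguishable from
#' a straight line over the data) are flagged `linear_fit`.
#'
#' @param series per-trial metric values.
#' @param x trial indices (defaults to `1:length(series)`).
#' @return an object of class `exp_fit`: `a`, `b`, `c`, `plateau_trial`,
#'   `converged`, `excluded_reason` (`NA`, `"negative_b"` or
#'   `"linear_fit"`).
#' @export
fit_learning_curve <- function(series, x = seq_along(series)) {
  stopifnot(length(series) >= 5, length(x) == length(series))
  span <- diff(range(x))
  a0 <- series[1] - series[length(series)]
  c0 <- series[length(series)]
  if (abs(a0) < .Machine$double.eps) a0 <- sd(series) + .Machine$double.eps
  best <- NULL
  for (mult in c(1, 0.5, 2, 0.25, 4, -1, -0.5, -2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-x / b) + c,
                        data = data.frame(x = x, y = series),
                        start = list(a = a0, b = span / 3 * mult, c = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    # exactly collinear data defeats every start (singular gradient);
    # a near-perfect straight-line fit is the infinite-learning-rate case
    lf <- lm(series ~ x)
    r2 <- suppressWarnings(summary(lf)$r.squared)
    reason <- if (is.finite(r2) && r2 > 0.98) "linear_fit"
              else NA_character_
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          plateau_trial = NA_real_, converged = FALSE,
                          excluded_reason = reason),
                     class = "exp_fit"))
  }
  cf <- coef(best$fit)
  reason <- NA_character_
  if (abs(cf[["b"]]) > 5 * span) {
    reason <- "linear_fit"  # indistinguishable from a straight line
  } else if (cf[["b"]] < 0) {
    reason <- "negative_b"
  }
  plateau <- if (is.na(reason) && cf[["b"]] > 0) cf[["b"]] * log(20)
             else NA_real_
  if (!is.na(reason)) plateau <- NA_real_
  if (abs(cf[["a"]]) < .Machine$double.eps) plateau <- 0
  structure(list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                 plateau_trial = plateau, converged = TRUE,
                 excluded_reason = reason),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> a = %.4g, b = %.4g trials, c = %.4g\n",
              x$a, x$b, x$c))
  if (!is.na(x$excluded_reason)) cat("  excluded:", x$excluded_reason, "\n")
  else cat(sprintf("  plateau at trial %.2f\n", x$plateau_trial))
  invisible(x)
}

#' Plateau trial of a fitted learning curve
#'
#' First trial at which the curve has covered 95 % of its asymptotic
#' change: `|a| exp(-x/b) <= 0.05 |a|`, i.e. `x = b * log(20)`.
#'
#' @param fit an `exp_fit` from [fit_learning_curve()].
#' @return plateau trial (real).
#' @export
plateau_trial <- function(fit) {
  if (!fit$converged || !is.na(fit$excluded_reason) || fit$b <= 0) {
    stop("plateau_trial: fit not valid for plateau detection")
  }
  if (abs(fit$a) < .Machine$double.eps) return(0)
  fit$b * log(20)
}

# successful-trial pairs of a perturbed-block outcome sequence;
# forward-direction failures are excluded from pair construction
.pair_deltas <- function(outcome, metric) {
  keep <- outcome != "failure_forward"
  outcome <- outcome[keep]
  metric <- metric[keep]
  succ <- which(outcome == "success")
  d_ss <- c()
  d_sfs <- c()
  if (length(succ) >= 2) {
    for (k in 2:length(succ)) {
      i <- succ[k - 1]; j <- succ[k]
      delta <- metric[j] - metric[i]
      if (j - i == 1) d_ss <- c(d_ss, delta) else d_sfs <- c(d_sfs, delta)
    }
  }
  list(ss = d_ss, sfs = d_sfs)
}

#' Outcome-conditioned metric contrasts
#'
#' For each run, sums the metric changes between consecutive successful
#' trials (S-S) and between successful trials separated by at least one
#' failure (S-F-S) over the perturbed block, then compares the two sums
#' across runs with a paired t-test. Forward-direction failures are
#' excluded from pair construction.
#'
#' @param runs a [run_population()] result, a list of [run_experiment()]
#'   results, or a single run.
#' @param metric_name metric column of `trials_df`.
#' @return an object of class `contrast_result`: per-run sums `sum_ss`,
#'   `sum_sfs`, population means `mean_delta_SS`, `mean_delta_SFS`,
#'   `t_statistic`, `p_value`, `n`.
#' @export
outcome_contrasts <- function(runs, metric_name = "trajectory_area") {
  if (inherits(runs, "population_result")) runs <- runs$runs
  if (inherits(runs, "run_result")) runs <- list(runs)
  sums <- lapply(runs, function(run) {
    df <- run$trials_df[run$trials_df$block == "perturbed", ]
    d <- .pair_deltas(df$outcome, df[[metric_name]])
    c(ss = sum(d$ss), sfs = sum(d$sfs),
      ok = as.numeric(length(d$ss) + length(d$sfs) > 0))
  })
  m <- do.call(rbind, sums)
  m <- m[m[, "ok"] > 0, , drop = FALSE]
  if (nrow(m) == 0) {
    return(structure(list(empty = TRUE), class = "contrast_result"))
  }
  tt <- if (nrow(m) >= 2 && sd(m[, "sfs"] - m[, "ss"]) > 0) {
    paired_t(m[, "sfs"], m[, "ss"])
  } else {
    list(t = NA_real_, p = NA_real_)
  }
  structure(list(empty = FALSE, sum_ss = unname(m[, "ss"]),
                 sum_sfs = unname(m[, "sfs"]),
                 mean_delta_SS = mean(m[, "ss"]),
                 mean_delta_SFS = mean(m[, "sfs"]),
                 t_statistic = tt$t, p_value = tt$p, n = nrow(m)),
            class = "contrast_result")
}

#' Relative reduction of an adaptation measure at de-adaptation
#'
#' `RD = 1 - (A_D1 - A_B) / (A_C - A_B)` with `A_D1` the first
#' de-adaptation trial, `A_C` the catch trial and `A_B` the baseline value.
#'
#' @param A_D1,A_C,A_B measure values (cm^2).
#' @return dimensionless relative reduction.
#' @export
relative_reduction <- function(A_D1, A_C, A_B) {
  if (A_C == A_B) {
    stop("relative_reduction: undefined, catch equals baseline")
  }
  1 - (A_D1 - A_B) / (A_C - A_B)
}

#' Paired t-test
#'
#' @param x,y paired samples of equal length (n >= 2).
#' @return list with `t` and two-sided `p`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0) {
    stop("paired_t: zero variance of differences, t undefined")
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Run-versus-reference Pearson correlation table
#'
#' Correlates every simulated metric series with every reference series on
#' the common normalized trial grid, mirroring the all-pairs procedure used
#' to compare a stochastic simulator against a cohort.
#'
#' @param sim_runs matrix, simulated runs in rows, grid trials in columns.
#' @param ref_runs matrix, reference runs in rows, same number of columns.
#' @param alpha significance level for the non-significant count.
#' @return an object of class `correlation_table`: long data frame `pairs`
#'   (`sim`, `ref`, `r`, `p`) and `per_reference` summary (min/mean/max r,
#'   `n_nonsig`).
#' @export
run_reference_correlations <- function(sim_runs, ref_runs, alpha = 0.05) {
  sim_runs <- as.matrix(sim_runs); ref_runs <- as.matrix(ref_runs)
  stopifnot(ncol(sim_runs) == ncol(ref_runs))
  pairs <- expand.grid(sim = seq_len(nrow(sim_runs)),
                       ref = seq_len(nrow(ref_runs)))
  res <- mapply(function(i, j) {
    a <- sim_runs[i, ]; b <- ref_runs[j, ]
    if (sd(a) == 0 || sd(b) == 0) return(c(r = NA_real_, p = NA_real_))
    ct <- cor.test(a, b)
    c(r = unname(ct$estimate), p = ct$p.value)
  }, pairs$sim, pairs$ref)
  pairs$r <- res["r", ]
  pairs$p <- res["p", ]
  per_ref <- do.call(rbind, lapply(split(pairs, pairs$ref), function(d) {
    all_na <- all(is.na(d$r))
    data.frame(ref = d$ref[1],
               r_min = if (all_na) NA_real_ else min(d$r, na.rm = TRUE),
               r_mean = if (all_na) NA_real_ else mean(d$r, na.rm = TRUE),
               r_max = if (all_na) NA_real_ else max(d$r, na.rm = TRUE),
               n_nonsig = sum(is.na(d$p) | d$p >= alpha | d$r <= 0))
  }))
  rownames(per_ref) <- NULL
  structure(list(pairs = pairs, per_reference = per_ref, alpha = alpha),
            class = "correlation_table")
}

#' Adjust a vector of p-values
#'
#' Convenience wrapper over [stats::p.adjust()]; Bonferroni for post-hoc
#' pairwise tests and Benjamini-Hochberg for large tables.
#'
#' @param p p-values.
#' @param method `"bonferroni"` or `"BH"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "BH")) {
  stats::p.adjust(p, match.arg(method))
}
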