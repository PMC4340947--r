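# Rhythm-detection statistics: a periodogram g-test at the Fourier frequency
# nearest a fixed dominant period, dual-condition selection with a permutation
# estimate of the false discovery rate, grid cosinor regression with an
# F-test, one-way ANOVA across timepoints, spectral total-intensity scaling
# and the FPKM fold-change filter.

#' Periodogram g-test for a fixed dominant period
#'
#' The statistic is the periodogram ordinate at the Fourier frequency nearest
#' `1 / dominant_period`, divided by the sum of all ordinates (frequencies
#' `k / span` for `k = 1 .. floor((n-1)/2)`; the Nyquist ordinate of an even
#' series is excluded so that all retained ordinates share one null law).
#' Because the tested frequency is fixed in advance, the ratio is exactly
#' `Beta(1, K-1)` under Gaussian white noise and the reported p-value
#' `(1 - g)^(K-1)` is exactly calibrated. The p-value is invariant to additive
#' and multiplicative rescaling of the series.
#'
#' @param x Numeric series, one value per timepoint (use per-timepoint means
#'   when replicates exist).
#' @param timepoints Sampling times in hours; must be evenly spaced, length
#'   >= 8.
#' @param dominant_period Period of interest in hours (default 24).
#' @return A one-row tibble: `g` (spectral ratio), `k` (tested Fourier
#'   index), `n_ordinates`, `p_value`, `degenerate` (`TRUE` for a
#'   zero-variance series, reported with `p_value = 1`).
#' @examples
#' t <- seq(0, 44, by = 4)
#' gtest_periodicity(cos(2 * pi * t / 24), t)
#' @export
gtest_periodicity <- function(x, timepoints, dominant_period = 24) {
  if (length(x) != length(timepoints)) {
    stop("x and timepoints must have the same length", call. = FALSE)
  }
  interval <- check_even_spacing(timepoints, n_min = 8)
  ord <- order(timepoints)
  res <- gtest_matrix(matrix(x[ord], nrow = 1), interval, dominant_period)
  tibble::tibble(
    g = res$g[1], k = res$k, n_ordinates = res$n_ordinates,
    p_value = res$p[1], degenerate = res$degenerate[1]
  )
}

check_even_spacing <- function(timepoints, n_min) {
  if (length(timepoints) < n_min) {
    stop("need at least ", n_min, " timepoints", call. = FALSE)
  }
  steps <- diff(sort(timepoints))
  if (any(steps <= 0) ||
      max(abs(steps - steps[1])) > 1e-8 * max(steps[1], 1)) {
    stop("timepoints must be distinct and evenly spaced", call. = FALSE)
  }
  steps[1]
}

# Vectorised core: rows of `m` are features, columns are sorted timepoints.
gtest_matrix <- function(m, interval, dominant_period) {
  n <- ncol(m)
  K <- floor((n - 1) / 2)
  centered <- m - rowMeans(m)
  ft <- stats::mvfft(t(centered))
  I <- Mod(ft[seq(2, K + 1), , drop = FALSE])^2
  span <- n * interval
  k_star <- min(max(round(span / dominant_period), 1), K)
  total <- colSums(I)
  degenerate <- total <= 0
  g <- ifelse(degenerate, NA_real_, I[k_star, ] / total)
  p <- ifelse(degenerate, 1, (1 - g)^(K - 1))
  list(g = g, p = p, k = k_star, n_ordinates = K, degenerate = degenerate)
}

#' Dual-condition circadian selection
#'
#' A feature is called circadian when its g-test p-value is strictly below
#' `cutoff` in both conditions (light/dark and constant darkness).
#'
#' @param p_ld,p_dd g-test p-values under the two conditions (vectorised).
#' @param cutoff Strict upper bound (default 0.3).
#' @return Logical vector.
#' @export
select_circadian <- function(p_ld, p_dd, cutoff = 0.3) {
  stopifnot(all(p_ld >= 0 & p_ld <= 1), all(p_dd >= 0 & p_dd <= 1))
  p_ld < cutoff & p_dd < cutoff
}

prepare_condition_means <- function(expr, samples, condition) {
  sheet <- samples[samples$condition == condition, , drop = FALSE]
  mat <- as.matrix(expr[, sheet$sample, drop = FALSE])
  tps <- sort(unique(sheet$timepoint_h))
  means <- vapply(tps, function(tp) {
    cols <- sheet$sample[sheet$timepoint_h == tp]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  if (nrow(expr) == 1) means <- matrix(means, nrow = 1)
  list(means = means, timepoints = tps)
}

check_expr_samples <- function(expr, samples) {
  expr_samples <- setdiff(names(expr), "feature")
  missing_meta <- setdiff(expr_samples, samples$sample)
  missing_data <- setdiff(samples$sample, expr_samples)
  if (length(missing_meta) > 0 || length(missing_data) > 0) {
    stop("expression matrix and sample sheet disagree; ",
         "samples without metadata: ",
         paste(missing_meta, collapse = ", "), "; ",
         "metadata without samples: ",
         paste(missing_data, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-feature rhythm detection across conditions
#'
#' Runs the g-test per condition on per-timepoint means and applies the
#' dual-condition selection rule. With a single condition the call reduces to
#' `p < cutoff` in that condition.
#'
#' @param expr Expression tibble: `feature` column plus one column per sample.
#' @param samples Sample sheet tibble (`sample`, `timepoint_h`, `condition`,
#'   `replicate`).
#' @param dominant_period Period of interest in hours (default 24).
#' @param cutoff Strict g-test p-value cutoff (default 0.3).
#' @return A tibble: `feature`, one `g_p_<condition>` column per condition,
#'   and `is_circadian`.
#' @export
detect_rhythms <- function(expr, samples, dominant_period = 24, cutoff = 0.3) {
  check_expr_samples(expr, samples)
  conditions <- unique(samples$condition)
  out <- tibble::tibble(feature = expr$feature)
  pvals <- list()
  for (cond in conditions) {
    prep <- prepare_condition_means(expr, samples, cond)
    interval <- check_even_spacing(prep$timepoints, n_min = 8)
    res <- gtest_matrix(prep$means, interval, dominant_period)
    pvals[[cond]] <- res$p
    out[[paste0("g_p_", cond)]] <- res$p
  }
  out$is_circadian <- if (length(conditions) >= 2) {
    select_circadian(pvals[[1]], pvals[[2]], cutoff = cutoff)
  } else {
    pvals[[1]] < cutoff
  }
  out
}

#' Permutation estimate of the false discovery rate
#'
#' Shuffles the timepoint labels of the samples within each condition
#' (independently per condition, with the identical shuffle applied to every
#' feature), re-runs the dual-condition selection, and estimates
#' `FDR = mean(null pass count) / observed pass count`, capped at 1. With
#' zero observed passes the FDR is reported as 1 with a warning.
#'
#' @inheritParams detect_rhythms
#' @param n_perm Number of permutations (>= 10; default 1000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A one-row tibble: `n_observed`, `mean_null_pass`, `fdr`.
#' @export
permutation_fdr <- function(expr, samples, dominant_period = 24, cutoff = 0.3,
                            n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 10)
  check_expr_samples(expr, samples)
  observed <- sum(detect_rhythms(expr, samples, dominant_period,
                                 cutoff)$is_circadian)
  null_pass <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      shuffled <- samples |>
        dplyr::group_by(.data$condition) |>
        dplyr::mutate(timepoint_h = sample(.data$timepoint_h)) |>
        dplyr::ungroup()
      sum(detect_rhythms(expr, shuffled, dominant_period,
                         cutoff)$is_circadian)
    }, numeric(1))
  })
  if (observed == 0) {
    warning("no feature passes the observed selection; FDR reported as 1",
            call. = FALSE)
    fdr <- 1
  } else {
    fdr <- min(mean(null_pass) / observed, 1)
  }
  tibble::tibble(n_observed = observed, mean_null_pass = mean(null_pass),
                 fdr = fdr)
}

#' Grid cosinor fit
#'
#' Least-squares fit of `mesor + amplitude * cos(2*pi*(t - acrophase)/period)`
#' over a grid of candidate periods, implemented in closed form through
#' cosine/sine covariates at each period (equivalent to shifting the phase
#' continuously). The best grid point by residual sum of squares is retained
#' and its p-value comes from the F-test against the intercept-only model.
#'
#' @param t Timepoints in hours.
#' @param y Observed values (use per-timepoint means when replicates exist);
#'   at least 4 points.
#' @param periods Candidate periods in hours (default 20-28 h in 0.5 h steps).
#' @return A one-row tibble of class `cosine_fit`: `period`, `acrophase`
#'   (hours in `[0, period)`), `amplitude`, `mesor`, `rss`, `df_residual`,
#'   `p_value`.
#' @examples
#' t <- seq(0, 24, by = 6)
#' fit_cosine(t, 5 + 2 * cos(2 * pi * (t - 7) / 24))
#' @export
fit_cosine <- function(t, y, periods = seq(20, 28, by = 0.5)) {
  if (length(t) != length(y)) {
    stop("t and y must have the same length", call. = FALSE)
  }
  if (length(y) < 4) {
    stop("need at least 4 timepoints to fit mesor, amplitude and acrophase",
         call. = FALSE)
  }
  if (!all(is.finite(t)) || !all(is.finite(y))) {
    stop("t and y must be finite", call. = FALSE)
  }
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  best <- NULL
  for (period in periods) {
    X <- cbind(1, cos(2 * pi * t / period), sin(2 * pi * t / period))
    qr_x <- qr(X)
    if (qr_x$rank < 3) next # aliased period at this sampling design
    coefs <- qr.coef(qr_x, y)
    rss <- sum((y - drop(X %*% coefs))^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(period = period, coefs = coefs, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("all candidate periods are aliased at this sampling design",
         call. = FALSE)
  }
  b0 <- best$coefs[1]; bc <- best$coefs[2]; bs <- best$coefs[3]
  df2 <- n - 3
  f_stat <- ((tss - best$rss) / 2) / (best$rss / df2)
  p <- stats::pf(f_stat, 2, df2, lower.tail = FALSE)
  out <- tibble::tibble(
    period = best$period,
    acrophase = (atan2(bs, bc) * best$period / (2 * pi)) %% best$period,
    amplitude = sqrt(bc^2 + bs^2),
    mesor = b0,
    rss = best$rss,
    df_residual = df2,
    p_value = p
  )
  attr(out, "data") <- tibble::tibble(t = t, y = y)
  class(out) <- c("cosine_fit", class(out))
  out
}

#' One-way ANOVA across timepoint groups
#'
#' @param values Observed values.
#' @param timepoint_h Timepoint label per value; at least 2 groups with at
#'   least 2 replicates each and positive within-group variance.
#' @return The F-test p-value.
#' @export
anova_timepoints <- function(values, timepoint_h) {
  if (length(values) != length(timepoint_h)) {
    stop("values and timepoint_h must have the same length", call. = FALSE)
  }
  groups <- factor(timepoint_h)
  if (nlevels(groups) < 2) {
    stop("need at least 2 timepoint groups", call. = FALSE)
  }
  if (any(table(groups) < 2)) {
    stop("every timepoint group needs at least 2 replicates", call. = FALSE)
  }
  within_var <- tapply(values, groups, stats::var)
  if (max(within_var) <= .Machine$double.eps * max(abs(values), 1)^2) {
    stop("within-group variance is zero; ANOVA undefined", call. = FALSE)
  }
  tab <- stats::anova(stats::lm(values ~ groups))
  tab[["Pr(>F)"]][1]
}

#' Joint cosine + ANOVA circadian call for metabolites
#'
#' `TRUE` when both the cosinor fit p-value and the ANOVA p-value are
#' strictly below `alpha`. No multiple-testing adjustment is applied (raw
#' cutoffs; see the methods vignette).
#'
#' @param cosine_p,anova_p P-values (vectorised).
#' @param alpha Strict significance threshold (default 0.05).
#' @return Logical vector.
#' @export
classify_circadian_metabolite <- function(cosine_p, anova_p, alpha = 0.05) {
  stopifnot(all(cosine_p >= 0 & cosine_p <= 1),
            all(anova_p >= 0 & anova_p <= 1))
  cosine_p < alpha & anova_p < alpha
}

#' Scale spectra to total intensity
#'
#' Divides each row (spectrum) by its total so that row sums equal 1;
#' within-spectrum ratios are preserved and the operation is idempotent.
#'
#' @param x Numeric matrix or data frame, spectra in rows; every row total
#'   must be positive.
#' @return Object of the same shape with unit row sums.
#' @export
scale_total_intensity <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) {
    stop("x must be numeric", call. = FALSE)
  }
  totals <- rowSums(m)
  if (any(!is.finite(totals)) || any(totals <= 0)) {
    stop("every spectrum must have a positive finite total intensity",
         call. = FALSE)
  }
  scaled <- m / totals
  if (is.data.frame(x)) {
    out <- x
    out[] <- as.data.frame(scaled)
    out
  } else {
    scaled
  }
}

#' Abundance and fold-change filter for differential expression
#'
#' A transcript is `"excluded"` when every sample (case and control) has
#' FPKM below `min_fpkm`; otherwise it is `"significant"` when the absolute
#' log2 ratio of mean case to mean control FPKM exceeds `log2_cut`, else
#' `"not_significant"`. When either group mean is zero a pseudocount is added
#' to both before taking the ratio (set `use_pseudocount = FALSE` to let the
#' ratio be infinite instead).
#'
#' @param fpkm_case,fpkm_control Nonnegative per-sample FPKM values.
#' @param min_fpkm Low-abundance threshold (default 1).
#' @param log2_cut Strict absolute log2 fold-change threshold (default 2).
#' @param pseudocount Value added to both means when one is zero.
#' @param use_pseudocount Whether to apply the pseudocount policy.
#' @return One of `"excluded"`, `"significant"`, `"not_significant"`.
#' @export
filter_differential <- function(fpkm_case, fpkm_control, min_fpkm = 1,
                                log2_cut = 2, pseudocount = 0.1,
                                use_pseudocount = TRUE) {
  vals <- c(fpkm_case, fpkm_control)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("FPKM values must be finite and nonnegative", call. = FALSE)
  }
  if (all(vals < min_fpkm)) {
    return("excluded")
  }
  m_case <- mean(fpkm_case)
  m_ctrl <- mean(fpkm_control)
  if ((m_case == 0 || m_ctrl == 0) && use_pseudocount) {
    m_case <- m_case + pseudocount
    m_ctrl <- m_ctrl + pseudocount
  }
  ratio <- log2(m_case / m_ctrl)
  if (is.nan(ratio)) ratio <- 0 # both means zero without pseudocount
  if (abs(ratio) > log2_cut) "significant" else "not_significant"
}
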