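#' Differences between full-design and subsampled indicators
#'
#' Pairs the two indicator tables by `(plot_id, event_id, indicator)` and
#' computes `d = full - subsample`, so a positive difference means the
#' reduced design underestimates the indicator. Events where either value
#' is undefined (`NA`) are excluded pairwise for that indicator.
#'
#' @param full Indicator tibble of the full design
#'   ([compute_indicator_set()]).
#' @param sub Indicator tibble of the reduced design ([apply_scenario()]).
#' @param sc Optional [scenario()] whose design fields are attached as
#'   columns.
#' @return A tibble `plot_id`, `event_id`, `indicator`, `d` (plus scenario
#'   columns when `sc` is given).
#' @export
compute_differences <- function(full, sub, sc = NULL) {
  d <- dplyr::inner_join(
    dplyr::rename(full, full_value = "value"),
    dplyr::rename(sub, sub_value = "value"),
    by = c("plot_id", "event_id", "indicator")
  )
  if (nrow(d) == 0) {
    stop_transectopt("no overlapping (plot, event, indicator) keys",
                     "transectopt_empty_input")
  }
  d <- d |>
    dplyr::filter(!is.na(.data$full_value), !is.na(.data$sub_value)) |>
    dplyr::mutate(d = .data$full_value - .data$sub_value) |>
    dplyr::select("plot_id", "event_id", "indicator", "d")
  if (!is.null(sc)) {
    d$n_transects <- sc$n_transects
    d$length_m <- cm_to_m(sc$length_cm)
    d$lpi_interval_m <- cm_to_m(sc$lpi_interval_cm)
    d$height_interval_m <- cm_to_m(sc$height_interval_cm)
    d$seed <- sc$seed
  }
  d
}

#' Nested limits of agreement for repeated-measures differences
#'
#' Bland-Altman limits of agreement for full-minus-subsample differences
#' observed repeatedly within plots: plots are the nesting subjects, their
#' sampling events the replicates. The total difference variance is
#' partitioned into a between-plot component (`sigma_b2`) and a within-plot,
#' event-to-event component (`sigma_e2`) by an unbalanced one-way
#' random-effects decomposition:
#' \itemize{
#'   \item bias = unweighted mean of the per-plot mean differences (plots
#'     are the inferential subjects, equally weighted under imbalance), with
#'     a t-based CI on `k - 1` degrees of freedom;
#'   \item `sigma_e2` = pooled within-plot variance (df `N - k`);
#'   \item `sigma_b2` = variance of plot means minus its within-plot
#'     contribution, truncated at zero;
#'   \item agreement half-width = `z * sqrt(sigma_b2 + sigma_e2)` at the
#'     agreement proportion `level`; limits = bias +/- half-width.
#' }
#' Outer confidence bounds on the limits are built by the MOVER (method of
#' variance estimates recovery) composition: a one-sided level-`level` bound
#' on the bias is combined with a one-sided modified-large-sample chi-square
#' bound on the total standard deviation (components on `k - 1` and `N - k`
#' df), so that the outer bound covers the true limit with probability
#' `level`.
#'
#' When every plot has a single difference (`N == k`) the fit degenerates to
#' the classical unreplicated Bland-Altman analysis: `sigma_e2` is taken as
#' zero and the total variance is the variance of the differences.
#'
#' @param diffs Data frame with columns `plot_id` (subject) and `d`
#'   (difference); typically one indicator's rows from
#'   [compute_differences()].
#' @param level Agreement proportion and confidence level in `(0, 1)`
#'   (0.95 or 0.80 in the standard analysis).
#' @return An object of class `nested_loa`: a list with `bias`, `bias_lo`,
#'   `bias_hi`, `sigma_b2`, `sigma_e2`, `agree_halfwidth`, `limit_lo`,
#'   `limit_hi`, `mover_lo`, `mover_hi`, `level`, `k`, `N`.
#' @export
fit_nested_loa <- function(diffs, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (!all(c("plot_id", "d") %in% names(diffs))) {
    stop_transectopt("diffs must have columns 'plot_id' and 'd'",
                     "transectopt_format_error")
  }
  d <- diffs$d
  if (anyNA(d) || any(!is.finite(d))) {
    stop_transectopt("differences must be finite", "transectopt_format_error")
  }
  plot <- as.character(diffs$plot_id)
  k <- length(unique(plot))
  N <- length(d)
  if (k < 2) {
    stop_transectopt("nested LoA needs at least 2 plots (subjects)",
                     "transectopt_insufficient_subjects")
  }

  n_i <- tapply(d, plot, length)
  dbar_i <- tapply(d, plot, mean)
  bias <- mean(dbar_i)
  v_bar <- stats::var(as.numeric(dbar_i))          # variance of plot means, df k-1
  se_bias <- sqrt(v_bar / k)

  if (N > k) {
    sse <- sum((d - dbar_i[plot])^2)
    sigma_e2 <- sse / (N - k)
  } else {
    sigma_e2 <- 0                                  # classical unreplicated case
  }
  m <- mean(1 / n_i)                               # within-plot share of v_bar
  sigma_b2 <- max(0, v_bar - sigma_e2 * m)
  sigma_tot2 <- sigma_b2 + sigma_e2
  sigma_tot <- sqrt(sigma_tot2)

  alpha2 <- (1 - level) / 2
  t_two <- stats::qt(1 - alpha2, df = k - 1)
  bias_lo <- bias - t_two * se_bias
  bias_hi <- bias + t_two * se_bias

  z <- stats::qnorm((1 + level) / 2)
  halfwidth <- z * sigma_tot
  limit_lo <- bias - halfwidth
  limit_hi <- bias + halfwidth

  # One-sided MOVER outer bounds at `level`:
  # MLS upper bound for sigma_b2 + sigma_e2 = v_bar + (1 - m) * sigma_e2,
  # chi-square components on k-1 and N-k df.
  a1 <- 1 - level
  g1 <- v_bar * ((k - 1) / stats::qchisq(a1, df = k - 1) - 1)
  g2 <- if (N > k) {
    (1 - m) * sigma_e2 * ((N - k) / stats::qchisq(a1, df = N - k) - 1)
  } else 0
  sigma_up <- sqrt(sigma_tot2 + sqrt(g1^2 + g2^2))
  t_one <- stats::qt(level, df = k - 1)
  mover_pad <- sqrt((t_one * se_bias)^2 + z^2 * (sigma_up - sigma_tot)^2)
  mover_lo <- limit_lo - mover_pad
  mover_hi <- limit_hi + mover_pad

  structure(
    list(bias = bias, bias_lo = bias_lo, bias_hi = bias_hi,
         sigma_b2 = sigma_b2, sigma_e2 = sigma_e2,
         agree_halfwidth = halfwidth,
         limit_lo = limit_lo, limit_hi = limit_hi,
         mover_lo = mover_lo, mover_hi = mover_hi,
         level = level, k = k, N = N),
    class = "nested_loa"
  )
}

#' @export
print.nested_loa <- function(x, ...) {
  cat(sprintf("<nested_loa> level %.2f, k = %d plots, N = %d differences\n",
              x$level, x$k, x$N))
  cat(sprintf("  bias %.4f [%.4f, %.4f]\n", x$bias, x$bias_lo, x$bias_hi))
  cat(sprintf("  sigma_b2 %.4f, sigma_e2 %.4f, half-width %.4f\n",
              x$sigma_b2, x$sigma_e2, x$agree_halfwidth))
  cat(sprintf("  limits [%.4f, %.4f], MOVER outer [%.4f, %.4f]\n",
              x$limit_lo, x$limit_hi, x$mover_lo, x$mover_hi))
  invisible(x)
}

#' Acceptable-difference criteria
#'
#' The pass thresholds applied to each indicator family, matching the
#' acceptable difference limits used for field crew calibration: agreement
#' bounds within 5 percentage points for total foliar cover and the canopy
#' gap classes, 5 cm for vegetation height, and 2 species for the species
#' count; plus the requirement that the bias CI contains zero.
#'
#' @param cover,gap,height,species Per-family half-width thresholds.
#' @param require_unbiased Also require the bias CI to contain 0.
#' @return A list of class `acceptance_criteria`.
#' @export
acceptance_criteria <- function(cover = 5, gap = 5, height = 5, species = 2,
                                require_unbiased = TRUE) {
  stopifnot(cover > 0, gap > 0, height > 0, species > 0)
  structure(
    list(thresholds = c(cover = cover, gap = gap, height = height,
                        species = species),
         require_unbiased = isTRUE(require_unbiased)),
    class = "acceptance_criteria"
  )
}

#' Evaluate the acceptable-difference criteria for one agreement result
#'
#' @param result A `nested_loa` fit.
#' @param indicator Indicator name (determines the threshold family).
#' @param criteria An [acceptance_criteria()] object.
#' @return A list with logical flags `unbiased` (bias CI contains 0),
#'   `interval` (largest MOVER bound distance from bias within the family
#'   threshold), and `pass` (both, or `interval` alone when
#'   `require_unbiased` is off).
#' @export
evaluate_criteria <- function(result, indicator,
                              criteria = acceptance_criteria()) {
  fam <- indicator_family(indicator)
  thr <- criteria$thresholds[[fam]]
  unbiased <- result$bias_lo <= 0 && result$bias_hi >= 0
  interval <- max(abs(result$mover_lo - result$bias),
                  abs(result$mover_hi - result$bias)) <= thr
  pass <- interval && (unbiased || !criteria$require_unbiased)
  list(unbiased = unbiased, interval = interval, pass = pass)
}

#' Shapiro-Wilk normality diagnostics for difference samples
#'
#' The limits-of-agreement model assumes normally distributed differences;
#' this reports the Shapiro-Wilk statistic per group as a diagnostic. It
#' never gates the analysis. Groups that are constant (zero variance) or too
#' small for the test are reported with `NA` and a note.
#'
#' @param diffs Difference tibble with a `d` column.
#' @param by Grouping columns (default `indicator` if present).
#' @return A tibble with the group columns, `n`, `statistic`, `p_value`,
#'   `note`.
#' @export
check_difference_normality <- function(diffs,
                                       by = intersect("indicator", names(diffs))) {
  groups <- if (length(by) > 0) {
    dplyr::distinct(diffs[, by, drop = FALSE])
  } else {
    tibble::tibble(.rows = 1)
  }
  res <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(diffs))
    for (col in by) {   # NA-safe equality: NA group values match NA cells
      x <- diffs[[col]]; g <- groups[[col]][i]
      sel <- sel & ((!is.na(x) & !is.na(g) & x == g) | (is.na(x) & is.na(g)))
    }
    d <- diffs$d[sel]
    out <- tibble::tibble(n = length(d), statistic = NA_real_,
                          p_value = NA_real_, note = "")
    if (length(d) < 3) {
      out$note <- "fewer than 3 differences; test undefined"
    } else if (stats::sd(d) == 0) {
      out$note <- "constant differences; test undefined"
    } else {
      sw <- stats::shapiro.test(if (length(d) > 5000) d[seq_len(5000)] else d)
      out$statistic <- unname(sw$statistic)
      out$p_value <- sw$p.value
    }
    dplyr::bind_cols(groups[i, , drop = FALSE], out)
  })
  dplyr::bind_rows(res)
}
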