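#' Run the full sampling-error analysis over a scenario grid
#'
#' Orchestrates the whole pipeline on one study: computes the full-design
#' indicators, applies every subsampling scenario of the grid (combinations
#' of transect number, transect length, and measurement intervals),
#' computes full-minus-subsample differences per plot sampling event, fits
#' the nested limits of agreement at each confidence level, evaluates the
#' acceptable-difference criteria, and derives minimum-design
#' recommendations.
#'
#' Within one base scenario (a transect number and length), all three
#' methods share the same random transect subset per plot event — as a
#' field crew laying out fewer physical lines would — and measurement
#' thinning is applied on top per interval. Transect subsets derive from
#' `seed` through independent per-(plot, event, scenario) sub-streams, so
#' adding scenarios never perturbs existing ones. The full-design scenario
#' (all transects, full length, base intervals) is part of the default grid
#' and must come out with zero bias and zero half-width; it is emitted as a
#' self-check row.
#'
#' @param study A full-design `transect_study`.
#' @param n_transects,length_cm Base scenario grid (crossed).
#' @param lpi_interval_cm Pin-drop intervals evaluated for the LPI
#'   indicators.
#' @param height_interval_cm Intervals evaluated for mean height.
#' @param levels Confidence/agreement levels.
#' @param criteria [acceptance_criteria()].
#' @param scheme,nonplant Indicator configuration.
#' @param seed Master seed for transect omission.
#' @param by_plot If `TRUE`, run a separate per-plot analysis in which the
#'   plot's events are the subjects (classical unreplicated limits of
#'   agreement per plot); results gain a `plot_id` column and no
#'   recommendations are derived.
#' @return A list of class `scenario_grid_run` with `results` (one row per
#'   method x indicator x design x level), `differences` (long difference
#'   table), `normality` (Shapiro-Wilk diagnostics per indicator x design),
#'   and `recommendations` ([recommend_designs()] output; `NULL` when
#'   `by_plot`).
#' @export
run_scenario_grid <- function(study,
                              n_transects = 1:3,
                              length_cm = c(2500, 5000, 10000),
                              lpi_interval_cm = c(25, 50, 100, 200),
                              height_interval_cm = c(200, 400, 800, 1600, 2000),
                              levels = c(0.80, 0.95),
                              criteria = acceptance_criteria(),
                              scheme = gap_class_scheme(),
                              nonplant = nonplant_codes(),
                              seed = 1L,
                              by_plot = FALSE) {
  stopifnot(length(levels) >= 1, all(levels > 0 & levels < 1))
  full_ind <- compute_indicator_set(study, scheme, nonplant)
  base_grid <- tidyr::crossing(n_transects = sort(unique(n_transects)),
                               length_cm = sort(unique(length_cm)))

  diff_rows <- list()
  for (b in seq_len(nrow(base_grid))) {
    nt <- base_grid$n_transects[b]
    len <- base_grid$length_cm[b]
    base_sub <- study |>
      select_transects(nt, seed = seed, stream_salt = c(nt, len)) |>
      truncate_transects(len)

    add_diffs <- function(vals, method, interval_cm, n_meas) {
      d <- dplyr::inner_join(
        dplyr::rename(dplyr::filter(full_ind,
                                    .data$indicator %in% unique(vals$indicator)),
                      full_value = "value"),
        dplyr::rename(vals, sub_value = "value"),
        by = c("plot_id", "event_id", "indicator"))
      d <- d |>
        dplyr::filter(!is.na(.data$full_value), !is.na(.data$sub_value)) |>
        dplyr::mutate(d = .data$full_value - .data$sub_value,
                      method = method,
                      n_transects = nt, length_m = cm_to_m(len),
                      interval_m = if (is.na(interval_cm)) NA_real_ else cm_to_m(interval_cm),
                      n_measurements = n_meas) |>
        dplyr::select("method", "indicator", "n_transects", "length_m",
                      "interval_m", "n_measurements",
                      "plot_id", "event_id", "d")
      diff_rows[[length(diff_rows) + 1]] <<- d
    }

    # canopy gap: continuous, no interval thinning
    add_diffs(gaps_by_event(base_sub$gap, base_sub$sampled_layout, scheme),
              method = "Gap intercept", interval_cm = NA,
              n_meas = nt)

    for (iv in sort(unique(lpi_interval_cm))) {
      thinned <- dplyr::filter(base_sub$lpi, .data$position_cm %% iv == 0)
      n_meas <- nt * (len %/% iv)
      add_diffs(cover_by_event(thinned, nonplant), "LPI", iv, n_meas)
      add_diffs(species_by_event(thinned, nonplant), "LPI", iv, n_meas)
    }

    for (hv in sort(unique(height_interval_cm))) {
      thinned <- dplyr::filter(base_sub$height, .data$position_cm %% hv == 0)
      add_diffs(height_by_event(thinned), "Vegetation height", hv,
                nt * (len %/% hv))
    }
  }
  differences <- dplyr::bind_rows(diff_rows)

  design_cols <- c("method", "indicator", "n_transects", "length_m",
                   "interval_m", "n_measurements")
  normality <- check_difference_normality(differences, by = design_cols)

  # An indicator can be undefined for whole plots under a sparse design
  # (e.g. no measured heights on a near-bare plot); if fewer than 2 plots
  # survive pairwise exclusion the cell is skipped rather than aborting.
  fit_one <- function(d, level) {
    fit <- tryCatch(fit_nested_loa(d, level = level),
                    transectopt_insufficient_subjects = function(e) NULL)
    if (is.null(fit)) return(NULL)
    flags <- evaluate_criteria(fit, d$indicator[1], criteria)
    tibble::tibble(
      level = level, k = fit$k, N = fit$N,
      bias = fit$bias, bias_lo = fit$bias_lo, bias_hi = fit$bias_hi,
      sigma_b2 = fit$sigma_b2, sigma_e2 = fit$sigma_e2,
      agree_halfwidth = fit$agree_halfwidth,
      limit_lo = fit$limit_lo, limit_hi = fit$limit_hi,
      mover_lo = fit$mover_lo, mover_hi = fit$mover_hi,
      pass_unbiased = flags$unbiased, pass_interval = flags$interval,
      pass = flags$pass)
  }

  groups <- dplyr::distinct(differences[, design_cols])
  res_rows <- list()
  for (g in seq_len(nrow(groups))) {
    d <- dplyr::semi_join(differences, groups[g, ], by = design_cols)
    if (by_plot) {
      for (pid in unique(d$plot_id)) {
        dp <- dplyr::filter(d, .data$plot_id == pid)
        dp$plot_id <- dp$event_id   # events become the subjects
        if (dplyr::n_distinct(dp$plot_id) < 2) next
        for (lv in levels) {
          row <- fit_one(dp, lv)
          if (is.null(row)) next
          res_rows[[length(res_rows) + 1]] <-
            dplyr::bind_cols(groups[g, ], tibble::tibble(plot_id = pid), row)
        }
      }
    } else {
      for (lv in levels) {
        row <- fit_one(d, lv)
        if (is.null(row)) next
        res_rows[[length(res_rows) + 1]] <-
          dplyr::bind_cols(groups[g, ], row)
      }
    }
  }
  results <- dplyr::bind_rows(res_rows)

  recommendations <- if (by_plot) NULL else recommend_designs(results)
  structure(list(results = results, differences = differences,
                 normality = normality, recommendations = recommendations),
            class = "scenario_grid_run")
}

#' @export
print.scenario_grid_run <- function(x, ...) {
  cat("<scenario_grid_run>\n")
  cat("  result rows:      ", nrow(x$results), "\n")
  cat("  difference rows:  ", nrow(x$differences), "\n")
  if (!is.null(x$recommendations)) {
    cat("  recommendations:  ", nrow(x$recommendations), "\n")
  }
  invisible(x)
}
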