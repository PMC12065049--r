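#' Select the minimum-effort passing sample design
#'
#' Given the pass flags of every scenario for one indicator at one
#' confidence level, returns the lowest-effort design meeting the
#' acceptable-difference criteria. Effort is ordered lexicographically:
#' total transect length first, then number of measurements; ties and
#' trade-offs are exposed through the Pareto-minimal set.
#'
#' @param scenarios A tibble with one row per scenario and columns
#'   `pass` (logical), `total_length_cm`, `n_measurements`, plus any design
#'   descriptor columns (`n_transects`, `length_cm`, `interval_cm`, ...)
#'   carried through to the output. For the continuous gap-intercept method
#'   `n_measurements` should be the number of transect lines read (it has no
#'   measurement interval).
#' @return An object of class `design_recommendation`: a list with
#'   `primary` (one-row tibble, or `NULL` when nothing passes) and
#'   `alternates` (tibble of Pareto-minimal passing scenarios on
#'   `(total_length_cm, n_measurements)`, including the primary).
#' @export
select_minimum_design <- function(scenarios) {
  need <- c("pass", "total_length_cm", "n_measurements")
  missing <- setdiff(need, names(scenarios))
  if (length(missing) > 0) {
    stop_transectopt(
      sprintf("scenarios table is missing column(s): %s",
              paste(missing, collapse = ", ")),
      "transectopt_format_error")
  }
  passing <- dplyr::filter(scenarios, .data$pass)
  if (nrow(passing) == 0) {
    return(structure(list(primary = NULL,
                          alternates = passing),
                     class = "design_recommendation"))
  }
  passing <- dplyr::arrange(passing, .data$total_length_cm, .data$n_measurements)
  dominated <- vapply(seq_len(nrow(passing)), function(i) {
    any(passing$total_length_cm <= passing$total_length_cm[i] &
        passing$n_measurements <= passing$n_measurements[i] &
        (passing$total_length_cm < passing$total_length_cm[i] |
         passing$n_measurements < passing$n_measurements[i]))
  }, logical(1))
  alternates <- passing[!dominated, , drop = FALSE]
  structure(list(primary = passing[1, , drop = FALSE],
                 alternates = alternates),
            class = "design_recommendation")
}

#' @export
print.design_recommendation <- function(x, ...) {
  if (is.null(x$primary)) {
    cat("<design_recommendation> no passing scenario\n")
    return(invisible(x))
  }
  cat("<design_recommendation>\n  primary:\n")
  print(as.data.frame(x$primary))
  if (nrow(x$alternates) > 1) {
    cat("  Pareto-minimal alternates:\n")
    print(as.data.frame(x$alternates))
  }
  invisible(x)
}

#' Minimum designs for every indicator and level of a results table
#'
#' Applies [select_minimum_design()] per `(indicator, level)` over a results
#' table from [run_scenario_grid()] and returns a flat recommendations
#' table.
#'
#' @param results Results tibble with columns `indicator`, `level`, `pass`,
#'   design and effort columns.
#' @return A tibble `indicator`, `level`, `rank` (1 = primary, then the
#'   other Pareto-minimal alternates by effort order), `n_transects`,
#'   `length_m`, `interval_m`, `total_length_m`, `n_measurements`. Indicator
#'   x level combinations with no passing scenario are omitted.
#' @export
recommend_designs <- function(results) {
  results <- dplyr::mutate(
    results,
    total_length_cm = .data$n_transects * .data$length_m * 100,
    n_measurements = .data$n_measurements
  )
  combos <- dplyr::distinct(results, .data$indicator, .data$level)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- dplyr::filter(results,
                         .data$indicator == combos$indicator[i],
                         .data$level == combos$level[i])
    rec <- select_minimum_design(sub)
    if (is.null(rec$primary)) return(NULL)
    alt <- rec$alternates
    alt$rank <- seq_len(nrow(alt))
    dplyr::transmute(
      alt,
      indicator = combos$indicator[i], level = combos$level[i],
      rank = .data$rank, n_transects = .data$n_transects,
      length_m = .data$length_m, interval_m = .data$interval_m,
      total_length_m = .data$total_length_cm / 100,
      n_measurements = .data$n_measurements)
  })
  dplyr::bind_rows(rows)
}
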