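#' Define a subsampling scenario
#'
#' A scenario is one reduced plot sample design: how many transects are laid
#' out, how long each is, and how densely the point-based methods are
#' measured along it. The default arguments are the full design (three
#' 100-m transects, pins every 0.25 m, heights every 2 m), which reproduces
#' the full dataset exactly.
#'
#' @param n_transects Number of transects retained (1-3 in the standard
#'   grid).
#' @param length_cm Transect length in cm, measured from the plot center
#'   outward (grid: 2500, 5000, 10000).
#' @param lpi_interval_cm Pin-drop interval in cm; multiple of 25.
#' @param height_interval_cm Height-point interval in cm; multiple of 200.
#' @param seed Seed governing the random choice of which transects to keep.
#' @return An object of class `scenario`.
#' @export
scenario <- function(n_transects = 3, length_cm = TRANSECT_LENGTH_CM,
                     lpi_interval_cm = LPI_BASE_CM,
                     height_interval_cm = HEIGHT_BASE_CM, seed = 1L) {
  if (n_transects < 1) {
    stop_transectopt("n_transects must be >= 1", "transectopt_parameter_error")
  }
  if (length_cm <= 0) {
    stop_transectopt("length_cm must be > 0", "transectopt_parameter_error")
  }
  if (lpi_interval_cm %% LPI_BASE_CM != 0 || lpi_interval_cm <= 0) {
    stop_transectopt(
      sprintf("lpi_interval_cm must be a positive multiple of %d", LPI_BASE_CM),
      "transectopt_parameter_error")
  }
  if (height_interval_cm %% HEIGHT_BASE_CM != 0 || height_interval_cm <= 0) {
    stop_transectopt(
      sprintf("height_interval_cm must be a positive multiple of %d", HEIGHT_BASE_CM),
      "transectopt_parameter_error")
  }
  structure(
    list(n_transects = as.integer(n_transects),
         length_cm = as.integer(length_cm),
         lpi_interval_cm = as.integer(lpi_interval_cm),
         height_interval_cm = as.integer(height_interval_cm),
         seed = as.integer(seed)),
    class = "scenario"
  )
}

#' Effort metrics of a scenario
#'
#' @param sc A [scenario()].
#' @return A list with `total_length_cm` (summed transect length),
#'   `n_lpi_points` and `n_height_points` (measurement counts implied by the
#'   intervals).
#' @export
scenario_effort <- function(sc) {
  list(
    total_length_cm = sc$n_transects * sc$length_cm,
    n_lpi_points = sc$n_transects * (sc$length_cm %/% sc$lpi_interval_cm),
    n_height_points = sc$n_transects * (sc$length_cm %/% sc$height_interval_cm)
  )
}

#' @export
print.scenario <- function(x, ...) {
  eff <- scenario_effort(x)
  cat(sprintf(
    "<scenario> %d x %g m, LPI every %g m (%d pins), height every %g m (%d points)\n",
    x$n_transects, cm_to_m(x$length_cm), cm_to_m(x$lpi_interval_cm),
    eff$n_lpi_points, cm_to_m(x$height_interval_cm), eff$n_height_points))
  invisible(x)
}

#' Randomly omit transects from a study
#'
#' Restricts every method's records to a uniformly random size-`n` subset of
#' each plot sampling event's transects, emulating a crew laying out fewer
#' physical lines. The same subset applies to all three methods of an
#' event. Draws are deterministic given `seed` and independent per
#' `(plot_id, event_id)` (sub-streams derived with [derive_seed()]).
#'
#' @param study A `transect_study`.
#' @param n Number of transects to keep per event.
#' @param seed Integer seed.
#' @param stream_salt Extra labels mixed into the per-event sub-stream, so
#'   different scenarios draw independent subsets.
#' @return The subsampled `transect_study`.
#' @export
select_transects <- function(study, n, seed = 1L, stream_salt = NULL) {
  avail <- study$sampled_layout |>
    dplyr::summarise(n_avail = dplyr::n_distinct(.data$transect_id),
                     .by = c("plot_id", "event_id"))
  if (any(n > avail$n_avail)) {
    stop_transectopt(
      sprintf("cannot select %d transects: an event has only %d",
              n, min(avail$n_avail)),
      "transectopt_parameter_error")
  }
  keep <- study$sampled_layout |>
    dplyr::distinct(.data$plot_id, .data$event_id, .data$transect_id)
  keep <- dplyr::reframe(
    keep,
    transect_id = {
      s <- derive_seed(seed, .data$plot_id[1], .data$event_id[1],
                       "n_transects", n,
                       paste(stream_salt %||% "", collapse = "/"))
      with_seed(s, sort(sample(sort(.data$transect_id), n)))
    },
    .by = c("plot_id", "event_id")
  )
  filter_by_keep <- function(df) {
    dplyr::semi_join(df, keep, by = c("plot_id", "event_id", "transect_id"))
  }
  study$lpi <- filter_by_keep(study$lpi)
  study$gap <- filter_by_keep(study$gap)
  study$height <- filter_by_keep(study$height)
  study$sampled_layout <- filter_by_keep(study$sampled_layout)
  study
}

#' Truncate transects from the plot center outward
#'
#' Keeps pins and height points at positions up to `length_cm`, clips gap
#' records at the new transect end, drops clipped fragments shorter than the
#' 5-cm minimum gap, and updates the sampled transect lengths so canopy-gap
#' denominators use the truncated length.
#'
#' @param study A `transect_study`.
#' @param length_cm New transect length in cm (`0 < length_cm`).
#' @return The truncated `transect_study`.
#' @export
truncate_transects <- function(study, length_cm) {
  if (length_cm <= 0) {
    stop_transectopt("length_cm must be > 0", "transectopt_parameter_error")
  }
  trunc_len <- as.integer(length_cm)
  study$lpi <- dplyr::filter(study$lpi, .data$position_cm <= .env$trunc_len)
  study$height <- dplyr::filter(study$height, .data$position_cm <= .env$trunc_len)
  study$gap <- study$gap |>
    dplyr::filter(.data$start_cm < .env$trunc_len) |>
    dplyr::mutate(end_cm = pmin(.data$end_cm, .env$trunc_len)) |>
    dplyr::filter(.data$end_cm - .data$start_cm >= MIN_GAP_CM)
  study$sampled_layout <- dplyr::mutate(
    study$sampled_layout,
    length_cm = pmin(.data$length_cm, .env$trunc_len))
  study
}

#' Thin point-based measurements to a sparser interval
#'
#' Keeps pins whose position is a multiple of `lpi_interval_cm` and height
#' points whose position is a multiple of `height_interval_cm`. Gap records
#' are untouched: gap intercept is a continuous method with no measurement
#' interval.
#'
#' @param study A `transect_study`.
#' @param lpi_interval_cm Pin interval (multiple of 25 cm).
#' @param height_interval_cm Height interval (multiple of 200 cm).
#' @return The thinned `transect_study`.
#' @export
thin_points <- function(study, lpi_interval_cm = LPI_BASE_CM,
                        height_interval_cm = HEIGHT_BASE_CM) {
  if (lpi_interval_cm %% LPI_BASE_CM != 0 ||
      height_interval_cm %% HEIGHT_BASE_CM != 0) {
    stop_transectopt("intervals must be multiples of the base intervals (25 / 200 cm)",
                     "transectopt_parameter_error")
  }
  study$lpi <- dplyr::filter(study$lpi, .data$position_cm %% lpi_interval_cm == 0)
  study$height <- dplyr::filter(study$height,
                                .data$position_cm %% height_interval_cm == 0)
  study
}

#' Apply a subsampling scenario to a full study
#'
#' Composes transect selection, truncation and point thinning, then computes
#' the indicator set of the reduced design. Applying the full-design
#' scenario reproduces the full-data indicators exactly.
#'
#' @param study A full `transect_study`.
#' @param sc A [scenario()].
#' @param scheme Gap class scheme.
#' @param nonplant Non-plant code set.
#' @return Indicator tibble as from [compute_indicator_set()].
#' @export
apply_scenario <- function(study, sc, scheme = gap_class_scheme(),
                           nonplant = nonplant_codes()) {
  sub <- subsample_study(study, sc)
  compute_indicator_set(sub, scheme = scheme, nonplant = nonplant)
}

#' @rdname apply_scenario
#' @return `subsample_study()`: the reduced `transect_study` itself.
#' @export
subsample_study <- function(study, sc) {
  study |>
    select_transects(sc$n_transects, seed = sc$seed,
                     stream_salt = c(sc$n_transects, sc$length_cm)) |>
    truncate_transects(sc$length_cm) |>
    thin_points(sc$lpi_interval_cm, sc$height_interval_cm)
}
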