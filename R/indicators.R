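#' Canopy gap size-class scheme
#'
#' The standard all-plant canopy gap size classes, in integer centimeters:
#' 5-24, 25-50, 51-100, 101-200, and >200 cm. Class membership is by the
#' integer gap length (field protocols record whole centimeters), so a 24-cm
#' gap falls in the first class and a 25-cm gap in the second.
#'
#' @return A tibble with columns `class` (label used in indicator names),
#'   `lower`, `upper` (inclusive bounds in cm; last upper is `Inf`).
#' @export
gap_class_scheme <- function() {
  tibble::tibble(
    class = c("5_24", "25_50", "51_100", "101_200", "200_plus"),
    lower = c(5, 25, 51, 101, 201),
    upper = c(24, 50, 100, 200, Inf)
  )
}

# Canonical indicator vocabulary used in every output table.
gap_indicator_names <- function(scheme = gap_class_scheme()) {
  paste0("GapPct_", scheme$class)
}

#' @rdname indicator_family
#' @export
indicator_names <- function(scheme = gap_class_scheme()) {
  c("AH_TotalFoliarCover", "NumSpecies", gap_indicator_names(scheme),
    "Hgt_Mean_cm")
}

#' Indicator families and vocabulary
#'
#' Maps each indicator to its family (`cover`, `species`, `gap`, `height`),
#' which determines the acceptable-difference threshold applied to it.
#'
#' @param indicator Character vector of indicator names.
#' @param scheme Gap class scheme, for `indicator_names()`.
#' @return `indicator_family()`: character vector of families;
#'   `indicator_names()`: the full indicator vocabulary.
#' @export
indicator_family <- function(indicator) {
  fam <- dplyr::case_when(
    indicator == "AH_TotalFoliarCover" ~ "cover",
    indicator == "NumSpecies" ~ "species",
    startsWith(indicator, "GapPct_") ~ "gap",
    indicator == "Hgt_Mean_cm" ~ "height",
    .default = NA_character_
  )
  if (anyNA(fam)) {
    stop_transectopt(
      sprintf("unknown indicator(s): %s",
              paste(unique(indicator[is.na(fam)]), collapse = ", ")),
      "transectopt_config_error")
  }
  fam
}

# Collapse a tall LPI table to one row per pin, flagging plant interception.
pin_level <- function(lpi, nonplant) {
  keys <- intersect(c("plot_id", "event_id", "transect_id", "position_cm"),
                    names(lpi))
  lpi |>
    dplyr::mutate(is_plant = !(.data$code %in% nonplant)) |>
    dplyr::summarise(any_plant = any(.data$is_plant),
                     .by = dplyr::all_of(keys))
}

#' Percent total foliar cover from line-point intercept records
#'
#' A pin counts as foliar cover when any of its intercepted layers carries a
#' plant code; pins whose layers are all non-plant (or the `"NONE"` marker)
#' count toward the denominator only.
#'
#' @param lpi Tall LPI table for a single plot sampling event.
#' @param nonplant Character vector of non-plant codes ([nonplant_codes()]).
#' @return Percent of pins with at least one plant interception, in
#'   `[0, 100]`.
#' @export
total_foliar_cover <- function(lpi, nonplant = nonplant_codes()) {
  if (nrow(lpi) == 0) {
    stop_transectopt("total foliar cover is undefined on an empty pin set",
                     "transectopt_undefined_indicator")
  }
  pins <- pin_level(lpi, nonplant)
  100 * mean(pins$any_plant)
}

#' Number of plant species detected by line-point intercept
#'
#' Counts distinct plant codes over all layers of all pins. Non-plant codes
#' are excluded. Monotone non-decreasing as pins are added, so every
#' subsample detects at most as many species as the full design.
#'
#' @inheritParams total_foliar_cover
#' @return Non-negative integer species count.
#' @export
species_count <- function(lpi, nonplant = nonplant_codes()) {
  if (nrow(lpi) == 0) {
    stop_transectopt("species count is undefined on an empty pin set",
                     "transectopt_undefined_indicator")
  }
  length(setdiff(unique(lpi$code), nonplant))
}

#' Percent of the plot in each canopy gap size class
#'
#' For each size class, the summed length of gaps whose (integer) length
#' falls in the class, as a percent of the total sampled transect length.
#'
#' @param gap Gap table for a single plot sampling event (`start_cm`,
#'   `end_cm`).
#' @param sampled_length_cm Integer vector of sampled transect lengths (cm);
#'   the denominator is their sum.
#' @param scheme Gap class scheme ([gap_class_scheme()]).
#' @return Named numeric vector, one percent per class, names from
#'   `indicator_names()`'s gap entries.
#' @export
gap_class_cover <- function(gap, sampled_length_cm, scheme = gap_class_scheme()) {
  total <- sum(as.numeric(sampled_length_cm))
  if (!is.finite(total) || total <= 0) {
    stop_transectopt("gap cover is undefined with zero sampled transect length",
                     "transectopt_undefined_indicator")
  }
  len <- gap$end_cm - gap$start_cm
  out <- vapply(seq_len(nrow(scheme)), function(i) {
    100 * sum(len[len >= scheme$lower[i] & len <= scheme$upper[i]]) / total
  }, numeric(1))
  names(out) <- gap_indicator_names(scheme)
  out
}

#' Mean vegetation height
#'
#' Arithmetic mean of recorded heights at points with a rooted plant; points
#' with no plant (`NA` height) are excluded rather than imputed as zero, so
#' the indicator is the mean height of plants, not of points.
#'
#' @param height Height table for a single plot sampling event.
#' @return Mean height in cm.
#' @export
mean_height <- function(height) {
  h <- height$height_cm
  h <- h[!is.na(h)]
  if (length(h) == 0) {
    stop_transectopt("mean height is undefined with no measured plants",
                     "transectopt_undefined_indicator")
  }
  mean(h)
}

#' Compute all indicators for every plot sampling event of a study
#'
#' Computes the four indicator families (total foliar cover, species count,
#' gap size-class cover, mean height) per `(plot_id, event_id)`. An
#' indicator whose input is empty for an event (e.g. no measured heights) is
#' reported as `NA`, never as zero. Canopy-gap denominators come from the
#' study's `sampled_layout`, so subsampled (truncated / fewer-transect)
#' studies are handled correctly.
#'
#' @param study A `transect_study` (full or subsampled).
#' @param scheme Gap class scheme.
#' @param nonplant Non-plant code set.
#' @return A tibble `plot_id`, `event_id`, `indicator`, `value` covering
#'   every event and indicator.
#' @export
compute_indicator_set <- function(study, scheme = gap_class_scheme(),
                                  nonplant = nonplant_codes()) {
  events <- study$events
  grid <- tidyr::crossing(events, indicator = indicator_names(scheme))
  vals <- dplyr::bind_rows(
    cover_by_event(study$lpi, nonplant),
    species_by_event(study$lpi, nonplant),
    gaps_by_event(study$gap, study$sampled_layout, scheme),
    height_by_event(study$height)
  )
  grid |>
    dplyr::left_join(vals, by = c("plot_id", "event_id", "indicator")) |>
    dplyr::arrange(.data$plot_id, .data$event_id, .data$indicator)
}

# Per-family per-event computations (long output: plot_id, event_id,
# indicator, value). Shared by compute_indicator_set() and the grid runner.

cover_by_event <- function(lpi, nonplant) {
  pin_level(lpi, nonplant) |>
    dplyr::summarise(value = 100 * mean(.data$any_plant),
                     .by = c("plot_id", "event_id")) |>
    dplyr::mutate(indicator = "AH_TotalFoliarCover") |>
    dplyr::select("plot_id", "event_id", "indicator", "value")
}

species_by_event <- function(lpi, nonplant) {
  # events with pins but no plant hits count 0 species
  has_pins <- dplyr::distinct(lpi, .data$plot_id, .data$event_id)
  lpi |>
    dplyr::filter(!(.data$code %in% nonplant)) |>
    dplyr::distinct(.data$plot_id, .data$event_id, .data$code) |>
    dplyr::count(.data$plot_id, .data$event_id, name = "value") |>
    dplyr::right_join(has_pins, by = c("plot_id", "event_id")) |>
    dplyr::mutate(value = as.numeric(dplyr::coalesce(.data$value, 0L)),
                  indicator = "NumSpecies") |>
    dplyr::select("plot_id", "event_id", "indicator", "value")
}

gaps_by_event <- function(gap, sampled_layout, scheme = gap_class_scheme()) {
  denom <- sampled_layout |>
    dplyr::summarise(total_cm = sum(as.numeric(.data$length_cm)),
                     .by = c("plot_id", "event_id"))
  glen <- dplyr::mutate(gap, len = .data$end_cm - .data$start_cm)
  rows <- lapply(seq_len(nrow(scheme)), function(i) {
    glen |>
      dplyr::filter(.data$len >= scheme$lower[i], .data$len <= scheme$upper[i]) |>
      dplyr::summarise(gap_cm = sum(as.numeric(.data$len)),
                       .by = c("plot_id", "event_id")) |>
      dplyr::right_join(denom, by = c("plot_id", "event_id")) |>
      dplyr::mutate(
        value = ifelse(.data$total_cm > 0,
                       100 * dplyr::coalesce(.data$gap_cm, 0) / .data$total_cm,
                       NA_real_),
        indicator = gap_indicator_names(scheme)[i]
      ) |>
      dplyr::select("plot_id", "event_id", "indicator", "value")
  })
  dplyr::bind_rows(rows)
}

height_by_event <- function(height) {
  height |>
    dplyr::filter(!is.na(.data$height_cm)) |>
    dplyr::summarise(value = mean(.data$height_cm),
                     .by = c("plot_id", "event_id")) |>
    dplyr::mutate(indicator = "Hgt_Mean_cm") |>
    dplyr::select("plot_id", "event_id", "indicator", "value")
}
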