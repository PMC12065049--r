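#' Configuration of the synthetic vegetation-plot simulator
#'
#' The simulator emulates the statistical structure the sampling-error
#' analysis assumes: a network of 1-ha plots, each with three 100-m radial
#' transects, revisited over repeated sampling events; clustered plant
#' canopies spanning sparse, playa-like (near-0% cover) to dense (~95%
#' cover) conditions across plots; and between-plot versus within-plot
#' (event-to-event) variance structure in the resulting indicators.
#'
#' Plants are disks placed by a Thomas cluster process: cluster centers
#' ("parents") form a Poisson process, each spawning a Poisson number of
#' plants displaced by an isotropic Gaussian. Setting `cluster_sd_cm = Inf`
#' collapses this to a homogeneous Poisson (Boolean) model. Canopy radii
#' are lognormal; each plant draws a species from the pool and a height
#' from that species' lognormal height distribution.
#'
#' Across the network, per-plot canopy intensity follows a log-spaced
#' gradient between the `cover_range` Boolean-cover targets, jittered by a
#' lognormal plot random effect (`sigma_plot`), which creates the
#' between-plot variance. Within a plot, each sampling event perturbs the
#' base map by moving and re-drawing a fraction `sigma_event` of plants, so
#' events are correlated repeat measures rather than independent redraws.
#'
#' @param n_plots Number of plots in the network (study network: 13).
#' @param events_min,events_max Per-plot sampling-event counts are drawn
#'   uniformly from this range (study network: at least 5 events per plot,
#'   151 events over 13 plots, i.e. ~11.6 on average).
#' @param parent_per_ha Parent (cluster) intensity per hectare used by
#'   [generate_plant_map()] when no explicit intensity is supplied.
#' @param cluster_mu Mean plants per cluster.
#' @param cluster_sd_cm Isotropic cluster spread (cm); `Inf` = Poisson.
#' @param radius_meanlog,radius_sdlog Lognormal canopy-radius parameters
#'   (cm; default median 60 cm).
#' @param species Species pool: tibble with `code`, `abundance` (relative,
#'   summing to 1), `height_meanlog`, `height_sdlog` (lognormal heights,
#'   cm).
#' @param cover_range Boolean-cover targets spanned by the plot gradient.
#' @param sigma_plot Lognormal SD of the per-plot intensity multiplier.
#' @param sigma_event Fraction of plants moved/re-drawn between events.
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_plots = 13,
                             events_min = 5, events_max = 18,
                             parent_per_ha = 30,
                             cluster_mu = 8,
                             cluster_sd_cm = 300,
                             radius_meanlog = log(60),
                             radius_sdlog = 0.4,
                             species = default_species_pool(),
                             cover_range = c(0.02, 0.95),
                             sigma_plot = 0.25,
                             sigma_event = 0.15,
                             seed = 1L) {
  stopifnot(n_plots >= 1, events_min >= 1, events_max >= events_min,
            parent_per_ha >= 0, cluster_mu > 0,
            cluster_sd_cm > 0, radius_sdlog >= 0,
            length(cover_range) == 2, all(cover_range > 0 & cover_range < 1),
            cover_range[1] <= cover_range[2],
            sigma_plot >= 0, sigma_event >= 0, sigma_event <= 1)
  if (abs(sum(species$abundance) - 1) > 1e-8) {
    stop_transectopt("species abundances must sum to 1",
                     "transectopt_parameter_error")
  }
  if (any(species$code %in% nonplant_codes())) {
    stop_transectopt("species codes must be disjoint from non-plant codes",
                     "transectopt_parameter_error")
  }
  structure(
    list(n_plots = as.integer(n_plots),
         events_min = as.integer(events_min), events_max = as.integer(events_max),
         parent_per_ha = parent_per_ha, cluster_mu = cluster_mu,
         cluster_sd_cm = cluster_sd_cm,
         radius_meanlog = radius_meanlog, radius_sdlog = radius_sdlog,
         species = tibble::as_tibble(species),
         cover_range = cover_range,
         sigma_plot = sigma_plot, sigma_event = sigma_event,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default synthetic species pool
#'
#' Ten species with USDA-style codes spanning shrubs, grasses and forbs,
#' with decreasing relative abundance and species-typical lognormal height
#' distributions (cm).
#' @return A tibble `code`, `abundance`, `height_meanlog`, `height_sdlog`.
#' @export
default_species_pool <- function() {
  tibble::tibble(
    code = c("ARTR2", "ATCA2", "BOER4", "HECO26", "SPAI",
             "ERNA10", "PLJA", "GUSA2", "SPCO", "PRGL2"),
    abundance = c(0.22, 0.16, 0.15, 0.12, 0.09, 0.08, 0.07, 0.05, 0.03, 0.03),
    height_meanlog = log(c(80, 100, 30, 45, 60, 70, 25, 40, 20, 120)),
    height_sdlog = c(0.35, 0.35, 0.3, 0.3, 0.3, 0.35, 0.3, 0.3, 0.3, 0.4)
  )
}

# Second moment of the lognormal canopy radius (cm^2).
radius_second_moment <- function(config) {
  exp(2 * config$radius_meanlog + 2 * config$radius_sdlog^2)
}

#' Expected Boolean-model cover of a plant map configuration
#'
#' Closed-form coverage probability of a Boolean model of lognormal disks:
#' `1 - exp(-lambda * pi * E[r^2])` with `lambda` the plant intensity.
#'
#' @param plants_per_ha Realized plant intensity per hectare.
#' @param config A [synthetic_config()] (for the radius distribution).
#' @return Expected cover as a proportion in `[0, 1)`.
#' @export
expected_boolean_cover <- function(plants_per_ha, config = synthetic_config()) {
  lambda_cm2 <- plants_per_ha / 1e8   # 1 ha = 1e8 cm^2
  1 - exp(-lambda_cm2 * pi * radius_second_moment(config))
}

# Plant intensity (per ha) whose Boolean cover equals `cover`.
intensity_for_cover <- function(cover, config) {
  -log(1 - cover) * 1e8 / (pi * radius_second_moment(config))
}

#' Generate a synthetic plant map
#'
#' Simulates clustered plant canopies over the region reached by the plot's
#' radial transects (a square of half-width 10000 cm plus a canopy buffer,
#' centered on the plot center). Parents are Poisson over the buffered
#' region, offspring counts Poisson(`cluster_mu`), displacements isotropic
#' Gaussian(`cluster_sd_cm`); with `cluster_sd_cm = Inf` plants are placed
#' as a homogeneous Poisson process of the same realized intensity.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (deterministic map given the seed).
#' @param parent_per_ha Parent intensity per ha; defaults to the config
#'   value.
#' @return A tibble of class `plant_map` with columns `x_cm`, `y_cm`,
#'   `radius_cm`, `species`, `height_cm`, and attribute `half_extent_cm`.
#' @export
generate_plant_map <- function(config = synthetic_config(), seed = config$seed,
                               parent_per_ha = config$parent_per_ha) {
  if (parent_per_ha < 0 || !is.finite(parent_per_ha)) {
    stop_transectopt("parent_per_ha must be finite and >= 0",
                     "transectopt_parameter_error")
  }
  buffer <- exp(config$radius_meanlog + 4 * config$radius_sdlog)
  half <- TRANSECT_LENGTH_CM + buffer
  with_seed(seed, {
    if (is.infinite(config$cluster_sd_cm)) {
      area_ha <- (2 * half)^2 / 1e8
      n <- stats::rpois(1, parent_per_ha * config$cluster_mu * area_ha)
      x <- stats::runif(n, -half, half)
      y <- stats::runif(n, -half, half)
    } else {
      margin <- 3 * config$cluster_sd_cm
      phalf <- half + margin
      area_ha <- (2 * phalf)^2 / 1e8
      n_par <- stats::rpois(1, parent_per_ha * area_ha)
      px <- stats::runif(n_par, -phalf, phalf)
      py <- stats::runif(n_par, -phalf, phalf)
      n_off <- stats::rpois(n_par, config$cluster_mu)
      x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, config$cluster_sd_cm)
      y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, config$cluster_sd_cm)
      keep <- abs(x) <= half & abs(y) <= half
      x <- x[keep]; y <- y[keep]
      n <- length(x)
    }
    sp_idx <- sample.int(nrow(config$species), n, replace = TRUE,
                         prob = config$species$abundance)
    map <- tibble::tibble(
      x_cm = x, y_cm = y,
      radius_cm = stats::rlnorm(n, config$radius_meanlog, config$radius_sdlog),
      species = config$species$code[sp_idx],
      height_cm = stats::rlnorm(n, config$species$height_meanlog[sp_idx],
                                config$species$height_sdlog[sp_idx])
    )
    attr(map, "half_extent_cm") <- half
    class(map) <- c("plant_map", class(map))
    map
  })
}

# Perturb a base map for one sampling event: a sigma_event fraction of
# plants is moved (Gaussian cluster-scale displacement) and re-drawn in
# radius and height, keeping the rest identical -> correlated repeats.
perturb_map <- function(map, config, seed) {
  frac <- config$sigma_event
  if (frac <= 0 || nrow(map) == 0) return(map)
  with_seed(seed, {
    n <- nrow(map)
    idx <- sample.int(n, size = round(frac * n))
    if (length(idx) > 0) {
      sd_move <- if (is.finite(config$cluster_sd_cm)) config$cluster_sd_cm else 500
      map$x_cm[idx] <- map$x_cm[idx] + stats::rnorm(length(idx), 0, sd_move)
      map$y_cm[idx] <- map$y_cm[idx] + stats::rnorm(length(idx), 0, sd_move)
      map$radius_cm[idx] <- stats::rlnorm(length(idx), config$radius_meanlog,
                                          config$radius_sdlog)
      sp <- match(map$species[idx], config$species$code)
      map$height_cm[idx] <- stats::rlnorm(length(idx),
                                          config$species$height_meanlog[sp],
                                          config$species$height_sdlog[sp])
    }
    map
  })
}

#' Read the three field methods along a plot's transects from a plant map
#'
#' Runs the virtual field crew: along each transect (a spoke from the plot
#' center at its azimuth), a pin at position `p` intercepts every plant
#' whose canopy disk contains the pin's plot coordinates; layer codes are
#' the species of intercepting plants ordered by height (top canopy first),
#' or `"NONE"`. Canopy gaps are the maximal uncovered sub-intervals of the
#' transect, kept when at least 5 cm after rounding inward to integer cm.
#' Height points record the maximum canopy height among intercepting
#' plants, rounded to 0.1 cm, and no value where no plant intercepts.
#'
#' @param map A `plant_map`.
#' @param layout Layout rows for one plot ([default_layout()]).
#' @param event_id Event identifier stamped on the records.
#' @return A list with tall tibbles `lpi`, `gap`, `height` for the plot.
#' @export
sample_transects <- function(map, layout, event_id = "E01") {
  lpi_rows <- list(); gap_rows <- list(); hgt_rows <- list()
  for (i in seq_len(nrow(layout))) {
    L <- layout$length_cm[i]
    theta <- layout$azimuth_deg[i] * pi / 180
    # rotate into transect frame: t along, s perpendicular
    tt <- map$x_cm * sin(theta) + map$y_cm * cos(theta)  # azimuth from north
    ss <- map$x_cm * cos(theta) - map$y_cm * sin(theta)
    r <- map$radius_cm
    near <- which(abs(ss) < r)
    h_half <- sqrt(r[near]^2 - ss[near]^2)
    lo <- tt[near] - h_half
    hi <- tt[near] + h_half
    # keep only plants whose canopy chord actually overlaps [0, L]
    on_line <- hi > 0 & lo < L
    near <- near[on_line]
    lo <- lo[on_line]
    hi <- hi[on_line]

    base <- list(plot_id = layout$plot_id[i], event_id = event_id,
                 transect_id = layout$transect_id[i])

    # --- LPI pins -----------------------------------------------------
    pin_pos <- seq(LPI_BASE_CM, L, by = LPI_BASE_CM)
    first_pin <- pmax(1, ceiling(lo / LPI_BASE_CM))
    last_pin <- pmin(length(pin_pos), floor(hi / LPI_BASE_CM))
    nhits <- pmax(0L, last_pin - first_pin + 1L)
    if (sum(nhits) > 0) {
      plant_of_hit <- rep(seq_along(near), nhits)
      pin_of_hit <- sequence(nhits, from = first_pin)
      hit_height <- map$height_cm[near][plant_of_hit]
      hit_code <- map$species[near][plant_of_hit]
      ord <- order(pin_of_hit, -hit_height)
      pin_of_hit <- pin_of_hit[ord]; hit_code <- hit_code[ord]
      layer_rank <- stats::ave(seq_along(pin_of_hit), pin_of_hit,
                               FUN = seq_along)
      layer <- ifelse(layer_rank == 1, "TopCanopy",
                      paste0("Lower", layer_rank - 1))
      hit_tbl <- tibble::tibble(
        plot_id = base$plot_id, event_id = base$event_id,
        transect_id = base$transect_id,
        position_cm = as.integer(pin_pos[pin_of_hit]),
        layer = layer, code = hit_code)
    } else {
      hit_tbl <- NULL
      pin_of_hit <- integer(0)
    }
    empty_pins <- setdiff(seq_along(pin_pos), unique(pin_of_hit))
    none_tbl <- tibble::tibble(
      plot_id = base$plot_id, event_id = base$event_id,
      transect_id = base$transect_id,
      position_cm = as.integer(pin_pos[empty_pins]),
      layer = "None", code = "NONE")
    lpi_rows[[i]] <- dplyr::bind_rows(hit_tbl, none_tbl)

    # --- canopy gaps --------------------------------------------------
    cov <- merge_intervals(pmax(lo, 0), pmin(hi, L))
    gs <- c(0, cov$hi)          # gap starts
    ge <- c(cov$lo, L)          # gap ends
    g_start <- as.integer(ceiling(gs))
    g_end <- as.integer(floor(ge))
    keep <- g_end - g_start >= MIN_GAP_CM
    gap_rows[[i]] <- tibble::tibble(
      plot_id = base$plot_id, event_id = base$event_id,
      transect_id = base$transect_id,
      start_cm = g_start[keep], end_cm = g_end[keep])

    # --- vegetation height points ------------------------------------
    hp <- seq(HEIGHT_BASE_CM, L, by = HEIGHT_BASE_CM)
    hval <- rep(NA_real_, length(hp))
    if (length(near) > 0) {
      for (j in seq_along(hp)) {
        covering <- lo <= hp[j] & hi >= hp[j]
        if (any(covering)) {
          hval[j] <- round(max(map$height_cm[near][covering]), 1)
        }
      }
    }
    hgt_rows[[i]] <- tibble::tibble(
      plot_id = base$plot_id, event_id = base$event_id,
      transect_id = base$transect_id,
      position_cm = as.integer(hp), height_cm = hval)
  }
  list(lpi = dplyr::bind_rows(lpi_rows),
       gap = dplyr::bind_rows(gap_rows),
       height = dplyr::bind_rows(hgt_rows))
}

# Union of intervals [lo, hi]; returns sorted disjoint intervals.
merge_intervals <- function(lo, hi) {
  if (length(lo) == 0) return(list(lo = numeric(0), hi = numeric(0)))
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  cmax <- cummax(hi)
  new_run <- c(TRUE, lo[-1] > cmax[-length(cmax)])
  grp <- cumsum(new_run)
  list(lo = lo[new_run],
       hi = as.numeric(tapply(hi, grp, max)))
}

#' Generate a full synthetic multi-plot, multi-event study
#'
#' Builds the plot network: per plot, a base plant map at an intensity from
#' the sparse-to-dense gradient (times the lognormal plot effect), then one
#' perturbed map per sampling event, each read by the virtual field crew
#' ([sample_transects()]). All randomness derives from `config$seed`
#' through per-(plot, event) sub-streams, so output is byte-identical for
#' identical configs.
#'
#' @param config A [synthetic_config()].
#' @return A validated `transect_study` covering all plots and events.
#' @export
generate_study <- function(config = synthetic_config()) {
  n <- config$n_plots
  plot_ids <- sprintf("P%02d", seq_len(n))
  layout <- default_layout(plot_ids)

  # log-spaced cover gradient -> per-plot intensity
  a <- -log(1 - config$cover_range)
  targets <- if (n == 1) mean(a) else exp(seq(log(a[1]), log(a[2]), length.out = n))
  covers <- 1 - exp(-targets)
  base_int <- intensity_for_cover(covers, config)

  lpi <- list(); gap <- list(); hgt <- list()
  for (p in seq_len(n)) {
    s_plot <- derive_seed(config$seed, "plot", plot_ids[p])
    mult <- with_seed(s_plot, exp(stats::rnorm(1, 0, config$sigma_plot)))
    n_events <- with_seed(derive_seed(s_plot, "n_events"),
                          sample(seq(config$events_min, config$events_max), 1))
    base_map <- generate_plant_map(
      config, seed = derive_seed(s_plot, "map"),
      parent_per_ha = base_int[p] * mult / config$cluster_mu)
    play <- layout[layout$plot_id == plot_ids[p], ]
    for (e in seq_len(n_events)) {
      event_id <- sprintf("E%02d", e)
      emap <- perturb_map(base_map, config,
                          seed = derive_seed(s_plot, "event", event_id))
      rec <- sample_transects(emap, play, event_id = event_id)
      key <- paste(p, e)
      lpi[[key]] <- rec$lpi; gap[[key]] <- rec$gap; hgt[[key]] <- rec$height
    }
  }
  transect_study(layout = layout,
                 lpi = dplyr::bind_rows(lpi),
                 gap = dplyr::bind_rows(gap),
                 height = dplyr::bind_rows(hgt))
}

#' Simulate nested difference samples directly
#'
#' Draws `d_ij = mu + b_i + e_ij` with plot effects
#' `b_i ~ N(0, sigma_b^2)` and event residuals `e_ij ~ N(0, sigma_e^2)`:
#' the generative model the nested limits-of-agreement analysis assumes.
#' Used to validate the agreement module against known truth.
#'
#' @param mu True bias.
#' @param sigma_b,sigma_e Between-plot and within-plot SDs (>= 0).
#' @param k Number of plots (>= 2).
#' @param n_i Replicates per plot; length 1 (recycled) or `k`.
#' @param seed Integer seed.
#' @return A tibble `plot_id`, `event_id`, `d`.
#' @export
simulate_differences <- function(mu, sigma_b, sigma_e, k, n_i, seed = 1L) {
  stopifnot(sigma_b >= 0, sigma_e >= 0, k >= 2)
  n_i <- rep_len(as.integer(n_i), k)
  with_seed(seed, {
    b <- stats::rnorm(k, 0, sigma_b)
    tibble::tibble(
      plot_id = rep(sprintf("P%02d", seq_len(k)), n_i),
      event_id = unlist(lapply(n_i, function(m) sprintf("E%02d", seq_len(m)))),
      d = mu + rep(b, n_i) + stats::rnorm(sum(n_i), 0, sigma_e)
    )
  })
}
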