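# Independent brute-force indicator implementations (naive loops, no shared
# code with the package internals) plus randomized fixture generators.

oracle_cover <- function(lpi, nonplant) {
  keyvec <- paste(lpi$plot_id, lpi$event_id, lpi$transect_id, lpi$position_cm)
  keys <- unique(keyvec)
  hit <- 0
  for (k in keys) {
    is_plant <- FALSE
    for (r in which(keyvec == k)) {
      if (!(lpi$code[r] %in% nonplant)) is_plant <- TRUE
    }
    if (is_plant) hit <- hit + 1
  }
  100 * hit / length(keys)
}

oracle_species <- function(lpi, nonplant) {
  seen <- character(0)
  for (r in seq_len(nrow(lpi))) {
    code <- lpi$code[r]
    if (!(code %in% nonplant) && !(code %in% seen)) seen <- c(seen, code)
  }
  length(seen)
}

oracle_gap <- function(gap, sampled_length_cm, scheme) {
  total <- sum(sampled_length_cm)
  out <- rep(0, nrow(scheme))
  for (r in seq_len(nrow(gap))) {
    len <- gap$end_cm[r] - gap$start_cm[r]
    for (i in seq_len(nrow(scheme))) {
      if (len >= scheme$lower[i] && len <= scheme$upper[i]) {
        out[i] <- out[i] + len
      }
    }
  }
  100 * out / total
}

oracle_height <- function(height) {
  tot <- 0; n <- 0
  for (r in seq_len(nrow(height))) {
    h <- height$height_cm[r]
    if (!is.na(h)) { tot <- tot + h; n <- n + 1 }
  }
  if (n == 0) NA_real_ else tot / n
}

# --- randomized single-event fixtures --------------------------------------

fixture_plant_codes <- c("ARTR2", "BOER4", "SPAI", "PLJA", "HECO26",
                         "ATCA2", "GUSA2", "ORHY", "SPCR", "ERNA10")
fixture_nonplant_extra <- c("L", "S", "R", "WL")

random_lpi_fixture <- function(seed) {
  set.seed(seed)
  n_tr <- sample(1:3, 1)
  rows <- list()
  for (tr in seq_len(n_tr)) {
    n_pins <- sample(5:400, 1)
    pos <- sort(sample(seq(25, 10000, by = 25), n_pins))
    for (p in pos) {
      n_plant <- sample(0:3, 1, prob = c(0.45, 0.3, 0.15, 0.1))
      codes <- if (n_plant > 0) sample(fixture_plant_codes, n_plant) else character(0)
      if (stats::runif(1) < 0.3) codes <- c(codes, sample(fixture_nonplant_extra, 1))
      if (length(codes) == 0) codes <- "NONE"
      rows[[length(rows) + 1]] <- data.frame(
        plot_id = "P1", event_id = "E1", transect_id = paste0("T", tr),
        position_cm = p,
        layer = c("TopCanopy", paste0("Lower", seq_len(max(0, length(codes) - 1)))),
        code = codes)
    }
  }
  do.call(rbind, rows)
}

random_gap_fixture <- function(seed) {
  set.seed(seed)
  n_tr <- sample(1:3, 1)
  lengths <- sample(c(2500, 5000, 10000), n_tr, replace = TRUE)
  rows <- list()
  for (tr in seq_len(n_tr)) {
    pos <- 0
    while (pos < lengths[tr] - 10) {
      pos <- pos + sample(5:600, 1)              # covered stretch
      glen <- sample(5:500, 1)                   # gap
      if (pos + glen > lengths[tr]) break
      rows[[length(rows) + 1]] <- data.frame(
        plot_id = "P1", event_id = "E1", transect_id = paste0("T", tr),
        start_cm = pos, end_cm = pos + glen)
      pos <- pos + glen
    }
  }
  list(gap = if (length(rows)) do.call(rbind, rows) else
         data.frame(plot_id = character(0), event_id = character(0),
                    transect_id = character(0), start_cm = integer(0),
                    end_cm = integer(0)),
       sampled_length_cm = lengths)
}

random_height_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(3:150, 1)
  data.frame(
    plot_id = "P1", event_id = "E1", transect_id = "T1",
    position_cm = seq(200, by = 200, length.out = n),
    height_cm = ifelse(stats::runif(n) < 0.4, NA_real_,
                       round(stats::rlnorm(n, log(40), 0.5), 1)))
}

# --- shared study fixtures (built once per test run) -----------------------

.fixture_env <- new.env(parent = emptyenv())

# Default-condition synthetic study (13 plots, sparse-to-dense gradient).
default_study <- function() {
  if (is.null(.fixture_env$default_study)) {
    .fixture_env$default_study <- generate_study(synthetic_config(seed = 101))
  }
  .fixture_env$default_study
}

# Smaller study for structural tests where size is irrelevant.
small_study <- function() {
  if (is.null(.fixture_env$small_study)) {
    .fixture_env$small_study <- generate_study(
      synthetic_config(n_plots = 4, events_min = 3, events_max = 4,
                       cover_range = c(0.1, 0.7), seed = 202))
  }
  .fixture_env$small_study
}

# Pass-flag grids transcribed from the published full-network agreement
# tables for the two LPI indicators (pass = bias CI contains 0 AND the
# agreement bound is within the acceptable-difference criterion).
lpi_flag_grid <- function(passing, lpi_intervals = c(0.25, 0.5, 1, 2)) {
  grid <- expand.grid(n_transects = 1:3, length_m = c(25, 50, 100),
                      interval_m = lpi_intervals)
  grid$total_length_cm <- grid$n_transects * grid$length_m * 100
  grid$n_measurements <- grid$n_transects * grid$length_m / grid$interval_m
  key <- paste(grid$n_transects, grid$length_m, grid$interval_m)
  grid$pass <- key %in% passing
  grid
}

flags_cover_95 <- function() {
  lpi_flag_grid(c("2 100 0.5", "3 100 0.5", "3 100 1"))
}
flags_species_95 <- function() {
  lpi_flag_grid(c("2 100 0.25", "2 100 0.5", "3 100 0.5"))
}
# The 80%-level table is supplementary; flags are reconstructed from the
# stated passing designs (one 100-m @0.25 m, three 50-m @0.5 m) plus the
# designs already passing at 95%.
flags_cover_80 <- function() {
  lpi_flag_grid(c("1 100 0.25", "3 50 0.5", "2 100 0.5", "3 100 0.5",
                  "3 100 1"))
}
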