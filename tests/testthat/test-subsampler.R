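test_that("scenario validates its parameters and reports effort", {
  sc <- scenario(2, 10000, 50, 200, seed = 9)
  eff <- scenario_effort(sc)
  expect_equal(eff$total_length_cm, 20000)
  expect_equal(eff$n_lpi_points, 400)   # two 100-m transects at 0.5 m
  expect_equal(eff$n_height_points, 100)
  expect_error(scenario(0), class = "transectopt_parameter_error")
  expect_error(scenario(2, 10000, 30), class = "transectopt_parameter_error")
  expect_error(scenario(2, 10000, 50, 300), class = "transectopt_parameter_error")
})

test_that("the full-design scenario reproduces the full data exactly", {
  st <- small_study()
  full <- compute_indicator_set(st)
  for (s in c(1, 77)) {
    sub <- apply_scenario(st, scenario(3, 10000, 25, 200, seed = s))
    expect_identical(sub, full)
  }
})

test_that("transect selection is deterministic and shared across methods", {
  st <- small_study()
  a <- select_transects(st, 1, seed = 42)
  b <- select_transects(st, 1, seed = 42)
  expect_identical(a$lpi, b$lpi)
  expect_identical(a$gap, b$gap)
  # all three methods keep the same transects per event
  key <- function(df) unique(paste(df$plot_id, df$event_id, df$transect_id))
  expect_setequal(key(a$lpi), key(a$height))
  expect_true(all(key(a$gap) %in% key(a$lpi)))
  expect_error(select_transects(st, 4, seed = 1),
               class = "transectopt_parameter_error")
})

test_that("single-transect selection is uniform over the three transects", {
  # one plot, 3000 events, one pin per transect: one call draws 3000
  # independent per-event subsets
  n_ev <- 3000
  layout <- default_layout("P1")
  ev <- sprintf("E%04d", seq_len(n_ev))
  lpi <- expand.grid(event_id = ev, transect_id = paste0("T", 1:3),
                     stringsAsFactors = FALSE)
  lpi$plot_id <- "P1"; lpi$position_cm <- 25L
  lpi$layer <- "None"; lpi$code <- "NONE"
  st <- transect_study(layout, lpi,
                       data.frame(plot_id = character(0), event_id = character(0),
                                  transect_id = character(0),
                                  start_cm = integer(0), end_cm = integer(0)),
                       data.frame(plot_id = character(0), event_id = character(0),
                                  transect_id = character(0),
                                  position_cm = integer(0),
                                  height_cm = numeric(0)))
  sel <- select_transects(st, 1, seed = 7)
  counts <- table(sel$lpi$transect_id)
  bound <- 3 * sqrt(n_ev * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n_ev / 3) <= bound))
})

test_that("truncation clips gaps and re-applies the 5-cm minimum", {
  layout <- default_layout("P1")
  lpi <- data.frame(plot_id = "P1", event_id = "E1", transect_id = "T1",
                    position_cm = seq(25, 10000, 25),
                    layer = "None", code = "NONE")
  gap <- data.frame(plot_id = "P1", event_id = "E1",
                    transect_id = c("T1", "T1"),
                    start_cm = c(2490L, 2700L), end_cm = c(2600L, 2800L))
  height <- data.frame(plot_id = "P1", event_id = "E1", transect_id = "T1",
                       position_cm = seq(200, 10000, 200), height_cm = 10)
  st <- transect_study(layout, lpi, gap, height)

  tr <- truncate_transects(st, 2500)
  expect_equal(tr$gap$start_cm, 2490L)
  expect_equal(tr$gap$end_cm, 2500L)         # clipped to 10 cm, kept
  expect_equal(max(tr$lpi$position_cm), 2500L)
  expect_equal(max(tr$height$position_cm), 2400L)
  expect_true(all(tr$sampled_layout$length_cm == 2500L))

  st$gap$start_cm[1] <- 2498L                 # 2-cm fragment after clipping
  st2 <- transect_study(st$layout, st$lpi, st$gap, st$height)
  tr2 <- truncate_transects(st2, 2500)
  expect_equal(nrow(tr2$gap), 0)

  # identity at full length
  expect_identical(truncate_transects(st, 10000)$gap, st$gap)
})

test_that("thinning keeps the documented point counts", {
  st <- small_study()
  th <- thin_points(st, 100, 2000)
  one_ev <- st$events[1, ]
  pins <- dplyr::semi_join(th$lpi, one_ev, by = c("plot_id", "event_id"))
  pins <- dplyr::distinct(pins, transect_id, position_cm)
  expect_equal(nrow(pins), 3 * 100)          # 100 pins per 100-m transect
  hts <- dplyr::semi_join(th$height, one_ev, by = c("plot_id", "event_id"))
  expect_equal(nrow(hts), 3 * 5)             # 5 points per transect at 20 m
  expect_identical(thin_points(st, 25, 200)$lpi, st$lpi)
  expect_error(thin_points(st, 30, 200), class = "transectopt_parameter_error")
})

test_that("truncation and thinning commute", {
  st <- small_study()
  a <- thin_points(truncate_transects(st, 5000), 50, 400)
  b <- truncate_transects(thin_points(st, 50, 400), 5000)
  expect_identical(a$lpi, b$lpi)
  expect_identical(a$gap, b$gap)
  expect_identical(a$height, b$height)
})

test_that("gap denominators equal transects x truncated length", {
  st <- small_study()
  sub <- subsample_study(st, scenario(2, 2500, 25, 200, seed = 5))
  denom <- dplyr::summarise(sub$sampled_layout,
                            total = sum(length_cm),
                            .by = c("plot_id", "event_id"))
  expect_true(all(denom$total == 2 * 2500))
})

test_that("scenario composition equals composing the ops by hand", {
  st <- small_study()
  sc <- scenario(1, 2500, 50, 200, seed = 11)
  via_scenario <- apply_scenario(st, sc)
  by_hand <- st |>
    select_transects(1, seed = 11, stream_salt = c(1L, 2500L)) |>
    truncate_transects(2500) |>
    thin_points(50, 200) |>
    compute_indicator_set()
  expect_identical(via_scenario, by_hand)
})

test_that("subsampled species counts never exceed the full count", {
  st <- small_study()
  full <- compute_indicator_set(st)
  fsp <- full[full$indicator == "NumSpecies", ]
  for (sc in list(scenario(1, 2500, 200, 2000, seed = 2),
                  scenario(2, 5000, 50, 400, seed = 3))) {
    sub <- apply_scenario(st, sc)
    ssp <- sub[sub$indicator == "NumSpecies", ]
    m <- merge(fsp, ssp, by = c("plot_id", "event_id"))
    expect_true(all(m$value.y <= m$value.x))
  }
})
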