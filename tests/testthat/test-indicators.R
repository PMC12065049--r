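np <- nonplant_codes()

test_that("indicator calculators agree exactly with brute-force oracles", {
  scheme <- gap_class_scheme()
  for (seed in 1:60) {
    lpi <- random_lpi_fixture(seed)
    expect_equal(total_foliar_cover(lpi, np), oracle_cover(lpi, np),
                 tolerance = 1e-12)
    expect_identical(species_count(lpi, np), oracle_species(lpi, np))
    gf <- random_gap_fixture(seed)
    expect_equal(unname(gap_class_cover(gf$gap, gf$sampled_length_cm, scheme)),
                 oracle_gap(gf$gap, gf$sampled_length_cm, scheme),
                 tolerance = 1e-12)
    hf <- random_height_fixture(seed)
    if (all(is.na(hf$height_cm))) {
      expect_error(mean_height(hf), class = "transectopt_undefined_indicator")
    } else {
      expect_equal(mean_height(hf), oracle_height(hf), tolerance = 1e-12)
    }
  }
})

test_that("total foliar cover counts pins with any plant layer", {
  mk <- function(codes) data.frame(
    plot_id = "P1", event_id = "E1", transect_id = "T1",
    position_cm = seq(25, by = 25, length.out = length(codes)),
    layer = "TopCanopy", code = codes)
  expect_equal(total_foliar_cover(mk(rep("NONE", 100)), np), 0)
  expect_equal(total_foliar_cover(mk(rep("ARTR2", 400)), np), 100)
  expect_equal(total_foliar_cover(mk(c(rep("ARTR2", 123), rep("NONE", 277))), np),
               30.75)
  # a pin with only non-plant interceptions is denominator-only
  two <- rbind(mk(c("L", "ARTR2")))
  expect_equal(total_foliar_cover(two, np), 50)
  empty <- mk("NONE")[0, ]
  expect_error(total_foliar_cover(empty, np),
               class = "transectopt_undefined_indicator")
})

test_that("species count is the distinct plant-code count and is monotone", {
  mk <- function(codes) data.frame(
    plot_id = "P1", event_id = "E1", transect_id = "T1",
    position_cm = seq(25, by = 25, length.out = length(codes)),
    layer = "TopCanopy", code = codes)
  expect_equal(species_count(mk(c("ARTR2", "BOER4", "ARTR2")), np), 2)
  expect_equal(species_count(mk(c("NONE", "L", "NONE")), np), 0)
  for (seed in 1:20) {
    lpi <- random_lpi_fixture(seed)
    set.seed(seed + 1000)
    keep <- sort(sample(nrow(lpi), floor(nrow(lpi) / 2)))
    expect_lte(species_count(lpi[keep, ], np), species_count(lpi, np))
    expect_gte(total_foliar_cover(lpi, np), 0)
    expect_lte(total_foliar_cover(lpi, np), 100)
  }
})

test_that("gap class cover follows the size-class arithmetic", {
  scheme <- gap_class_scheme()
  mkgap <- function(start, end) data.frame(
    plot_id = "P1", event_id = "E1", transect_id = "T1",
    start_cm = start, end_cm = end)
  # no gaps at all
  expect_equal(unname(gap_class_cover(mkgap(0, 10000)[0, ], rep(10000, 3),
                                      scheme)),
               rep(0, 5))
  # one full-transect gap, single transect
  expect_equal(unname(gap_class_cover(mkgap(0, 10000), 10000, scheme)),
               c(0, 0, 0, 0, 100))
  # 2500-cm transect with gaps of 20, 50, 250 cm
  g <- mkgap(c(0, 500, 1000), c(20, 550, 1250))
  expect_equal(unname(gap_class_cover(g, 2500, scheme)),
               c(100 * 20 / 2500, 100 * 50 / 2500, 0, 0, 100 * 250 / 2500))
  # class membership at integer boundaries: 24 -> first class, 25 -> second
  expect_equal(unname(gap_class_cover(mkgap(0, 24), 1000, scheme))[1:2],
               c(2.4, 0))
  expect_equal(unname(gap_class_cover(mkgap(0, 25), 1000, scheme))[1:2],
               c(0, 2.5))
  expect_error(gap_class_cover(mkgap(0, 100), 0, scheme),
               class = "transectopt_undefined_indicator")
})

test_that("gap cover is additive over transect splits", {
  scheme <- gap_class_scheme()
  for (seed in 1:10) {
    gf <- random_gap_fixture(seed)
    whole <- gap_class_cover(gf$gap, gf$sampled_length_cm, scheme)
    tr_ids <- unique(gf$gap$transect_id)
    total <- sum(gf$sampled_length_cm)
    parts <- 0
    for (i in seq_along(gf$sampled_length_cm)) {
      tid <- paste0("T", i)
      sub <- gf$gap[gf$gap$transect_id == tid, ]
      parts <- parts + gap_class_cover(sub, total, scheme)
    }
    expect_equal(unname(whole), unname(parts))
  }
})

test_that("mean height excludes plantless points, never imputes zero", {
  mkh <- function(h) data.frame(
    plot_id = "P1", event_id = "E1", transect_id = "T1",
    position_cm = seq(200, by = 200, length.out = length(h)), height_cm = h)
  expect_equal(mean_height(mkh(c(10, 20, 30))), 20)
  expect_equal(mean_height(mkh(rep(42, 7))), 42)
  expect_equal(mean_height(mkh(c(15, NA, NA))), 15)
  expect_error(mean_height(mkh(c(NA_real_, NA_real_))),
               class = "transectopt_undefined_indicator")
})

test_that("compute_indicator_set handles an empty-vegetation plot", {
  layout <- default_layout("P1")
  lpi <- data.frame(plot_id = "P1", event_id = "E1",
                    transect_id = rep(paste0("T", 1:3), each = 400),
                    position_cm = rep(seq(25, 10000, 25), 3),
                    layer = "None", code = "NONE")
  gap <- data.frame(plot_id = "P1", event_id = "E1",
                    transect_id = paste0("T", 1:3),
                    start_cm = 0L, end_cm = 10000L)
  height <- data.frame(plot_id = "P1", event_id = "E1",
                       transect_id = rep(paste0("T", 1:3), each = 50),
                       position_cm = rep(seq(200, 10000, 200), 3),
                       height_cm = NA_real_)
  st <- transect_study(layout, lpi, gap, height)
  ind <- compute_indicator_set(st)
  w <- setNames(ind$value, ind$indicator)
  expect_equal(unname(w["AH_TotalFoliarCover"]), 0)
  expect_equal(unname(w["NumSpecies"]), 0)
  expect_equal(unname(w["GapPct_200_plus"]), 100)
  expect_equal(unname(w["GapPct_5_24"]), 0)
  expect_true(is.na(w["Hgt_Mean_cm"]))
})

test_that("compute_indicator_set matches per-component calculators", {
  st <- small_study()
  ind <- compute_indicator_set(st)
  ev <- st$events[2, ]
  sel <- function(df) dplyr::semi_join(df, ev, by = c("plot_id", "event_id"))
  get <- function(name) ind$value[ind$plot_id == ev$plot_id &
                                  ind$event_id == ev$event_id &
                                  ind$indicator == name]
  expect_equal(get("AH_TotalFoliarCover"), total_foliar_cover(sel(st$lpi), np))
  expect_equal(get("NumSpecies"), species_count(sel(st$lpi), np))
  expect_equal(get("Hgt_Mean_cm"), mean_height(sel(st$height)))
  lens <- sel(st$sampled_layout)$length_cm
  gp <- gap_class_cover(sel(st$gap), lens)
  for (nm in names(gp)) expect_equal(get(nm), unname(gp[nm]))
})
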