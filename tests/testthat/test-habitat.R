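suit_raster <- function(v, nr, nc, cellsize = 1, xll = 0, yll = 0) {
  new_raster(matrix(v, nr, nc, byrow = TRUE),
             grid_spec(nc, nr, xll, yll, cellsize), "suit")
}

test_that("classification uses left-closed bands with the top closed at 1", {
  r <- suit_raster(c(0.10, 0.25, 0.49, 0.5, 0.74, 0.75, 1.0, NA, 0), 3, 3)
  cm <- classify_suitability(r)
  expect_equal(as.vector(t(cm$values)),
               c(0, 1, 1, 2, 2, 3, 3, NA, 0))
  expect_error(classify_suitability(suit_raster(c(1.2, rep(0, 3)), 2, 2)),
               "outside", class = "nichetrack_validation_error")
})

test_that("class areas partition the mapped area exactly", {
  # all-high one-cell map at the equator, 1 degree cells
  one <- classify_suitability(suit_raster(0.9, 1, 1, 1, 0, 0))
  a1 <- class_areas(one)
  expect_equal(a1$area_high * 1e4, cell_area_km2(one$spec, 1))
  expect_equal(a1$area_non, 0)
  expect_equal(a1$area_total_suitable, a1$area_high)

  # checkerboard non/high: high = half the area within one cell's area
  nr <- 10; nc <- 10
  chk <- suit_raster(rep(c(0.9, 0.1), length.out = nr * nc), nr, nc, 0.5,
                     100, 30)
  cmc <- classify_suitability(chk)
  ac <- class_areas(cmc)
  total <- sum(cell_area_km2(cmc$spec, rep(1:nr, each = nc))) / 1e4
  expect_lt(abs(ac$area_high - total / 2) * 1e4,
            cell_area_km2(cmc$spec, 1))

  # partition on random rasters: four classes sum to the masked area
  withr::with_seed(14, {
    for (i in 1:5) {
      v <- runif(nr * nc)
      v[sample(nr * nc, 7)] <- NA
      cm <- classify_suitability(suit_raster(v, nr, nc, 0.5, 100, 30))
      a <- class_areas(cm)
      cellrows <- rep(1:nr, times = nc)[!is.na(as.vector(cm$values))]
      masked <- sum(cell_area_km2(cm$spec, cellrows)) / 1e4
      expect_equal(a$area_non + a$area_total_suitable, masked,
                   tolerance = 1e-9)
    }
  })
})

test_that("percent change reproduces printed-table arithmetic conventions", {
  expect_equal(percent_change(89.37, 98.38), -9.16)
  expect_equal(percent_change(1.30, 1.62), -19.75)
  expect_equal(percent_change(5, 5), 0)
  # half-away-from-zero at the second decimal
  expect_equal(percent_change(100.125, 100), 0.13)
  expect_equal(percent_change(99.875, 100), -0.13)
  expect_warning(out <- percent_change(1, 0), "undefined")
  expect_true(is.na(out))
})

test_that("change maps partition cells and satisfy the count identities", {
  # hand-built 3x3 pair: 2 gains, 3 losses, 1 stable
  base <- classify_suitability(suit_raster(
    c(0.6, 0.6, 0.6, 0.6, 0.1, 0.1, 0.1, 0.1, 0.1), 3, 3))
  scen <- classify_suitability(suit_raster(
    c(0.6, 0.1, 0.1, 0.1, 0.6, 0.6, 0.1, 0.1, 0.1), 3, 3))
  ch <- change_map(base, scen)
  cs <- change_summary(ch)
  expect_equal(cs$cells[cs$state == "expansion"], 2)
  expect_equal(cs$cells[cs$state == "stable"], 1)
  expect_equal(cs$cells[cs$state == "contraction"], 3)
  expect_equal(cs$cells[cs$state == "never_suitable"], 3)

  # identities on random map pairs
  withr::with_seed(77, {
    for (i in 1:5) {
      b <- classify_suitability(suit_raster(runif(64), 8, 8))
      s <- classify_suitability(suit_raster(runif(64), 8, 8))
      ch <- change_map(b, s)
      cs <- setNames(change_summary(ch)$cells, change_summary(ch)$state)
      base_suit <- sum(b$values >= 1)
      scen_suit <- sum(s$values >= 1)
      expect_equal(cs[["stable"]] + cs[["contraction"]], base_suit)
      expect_equal(cs[["stable"]] + cs[["expansion"]], scen_suit)
      expect_equal(sum(cs), 64)
    }
  })

  # identical maps: nothing moves
  ch0 <- change_map(base, base)
  cs0 <- change_summary(ch0)
  expect_equal(cs0$cells[cs0$state %in% c("expansion", "contraction")],
               c(0, 0))
  expect_error(change_map(base, classify_suitability(
    suit_raster(runif(4), 2, 2))), class = "nichetrack_alignment_error")
})

test_that("centroids are area-weighted means of suitable cell centers", {
  # single suitable cell: its center
  single <- classify_suitability(suit_raster(c(0.9, 0, 0, 0), 2, 2, 1, 10, 40))
  expect_equal(habitat_centroid(single), tibble::tibble(lon = 10.5, lat = 41.5))

  # symmetric region on an equator-centered grid: the grid center
  sym <- classify_suitability(suit_raster(rep(0.6, 16), 4, 4, 1, -2, -2))
  expect_equal(habitat_centroid(sym), tibble::tibble(lon = 0, lat = 0))

  # two suitable cells with centers at lat 0 and 60: area weighting pulls
  # toward the equator cell; closed-form weighted mean of the band areas
  spec <- grid_spec(1, 61, 110, -0.5, 1)
  v <- matrix(0, 61, 1)
  v[61, 1] <- 0.9 # center lat 0
  v[1, 1] <- 0.9  # center lat 60
  cmap <- classify_suitability(new_raster(v, spec, "s"))
  cent <- habitat_centroid(cmap)
  w0 <- sin(0.5 * pi / 180) - sin(-0.5 * pi / 180)
  w60 <- sin(60.5 * pi / 180) - sin(59.5 * pi / 180)
  expect_equal(cent$lat, 60 * w60 / (w0 + w60), tolerance = 1e-9)
  expect_equal(round(cent$lat, 1), 20.0)

  expect_error(habitat_centroid(classify_suitability(
    suit_raster(rep(0.1, 4), 2, 2))), "no suitable",
    class = "nichetrack_data_error")

  # union property: centroid of A+B lies between centroid(A) and centroid(B)
  a <- classify_suitability(suit_raster(c(0.9, 0, 0, 0), 2, 2, 1, 0, 0))
  b <- classify_suitability(suit_raster(c(0, 0, 0, 0.9), 2, 2, 1, 0, 0))
  ab <- classify_suitability(suit_raster(c(0.9, 0, 0, 0.9), 2, 2, 1, 0, 0))
  ca <- habitat_centroid(a); cb <- habitat_centroid(b)
  cab <- habitat_centroid(ab)
  t <- (cab$lon - ca$lon) / (cb$lon - ca$lon)
  expect_gt(t, 0); expect_lt(t, 1)
  expect_equal(cab$lat, ca$lat + t * (cb$lat - ca$lat), tolerance = 1e-6)
})

test_that("centroid tracks report haversine displacements and bearings", {
  m1 <- classify_suitability(suit_raster(c(0.9, 0, 0, 0), 2, 2, 1, 10, 40))
  m2 <- classify_suitability(suit_raster(c(0, 0.9, 0, 0), 2, 2, 1, 10, 40))
  tr <- centroid_track(list(a = m1, b = m2, c = m2))
  expect_equal(nrow(tr), 3L)
  expect_true(is.na(tr$displacement_km[1]))
  expect_equal(tr$displacement_km[3], 0)
  # eastward one-degree step at lat 41.5
  expect_equal(tr$displacement_km[2],
               geosphere::distHaversine(c(10.5, 41.5), c(11.5, 41.5),
                                        r = 6371.0088))
  expect_equal(tr$bearing_deg[2], geosphere::bearing(c(10.5, 41.5),
                                                     c(11.5, 41.5)))

  # printed mid-Holocene -> current centroid coordinates: ~39 km westward
  d <- geosphere::distHaversine(c(111.42, 25.63), c(111.04, 25.71),
                                r = 6371.0088)
  expect_lt(abs(d - 39), 1.5)
  expect_error(centroid_track(list(a = m1)), "at least 2",
               class = "nichetrack_data_error")
})

test_that("scenario reports recompute their ratio columns exactly", {
  withr::local_seed(55)
  base <- classify_suitability(suit_raster(runif(100, 0, 1), 10, 10, 0.5,
                                           100, 25))
  scen <- classify_suitability(suit_raster(runif(100, 0, 0.6), 10, 10, 0.5,
                                           100, 25))
  rep1 <- scenario_report(list(current = base, future = scen),
                          baseline = "current")
  areas <- rep1$areas
  expect_equal(nrow(areas), 2L)
  expect_true(all(is.na(areas[areas$scenario == "current",
                              grep("^ratio", names(areas))])))
  fut <- areas[areas$scenario == "future", ]
  cur <- areas[areas$scenario == "current", ]
  for (cls in c("non", "low", "medium", "high", "total_suitable")) {
    expect_equal(fut[[paste0("ratio_", cls)]],
                 percent_change(fut[[paste0("area_", cls)]],
                                cur[[paste0("area_", cls)]]))
  }
  expect_named(rep1$change_maps, "future")
  expect_equal(nrow(rep1$centroids), 2L)

  # identical scenario: zero ratios, empty change classes
  rep0 <- scenario_report(list(current = base, same = base), "current")
  same <- rep0$areas[rep0$areas$scenario == "same", ]
  expect_equal(unname(unlist(same[grep("^ratio", names(same))])),
               rep(0, 5))
  cs <- change_summary(rep0$change_maps$same)
  expect_equal(cs$cells[cs$state %in% c("expansion", "contraction")], c(0, 0))
})
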