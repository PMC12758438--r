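test_that("hole geometry matches hand-computed shapes", {
  # uniform 10 px x 20 rows rectangle, spacing (5, 10)
  geom <- extract_hole_geometry(rect_hole())
  expect_equal(geom[c("mld_um", "bd_um", "height_um", "e_um", "area_um2")],
               list(mld_um = 100, bd_um = 100, height_um = 100, e_um = 0,
                    area_um2 = 10000))
  # trapezoid narrowing 20 -> 10 px over 11 rows; oracle: explicit row scan
  sc <- trapezoid_hole()
  widths <- apply(sc$grid == 1L, 1, sum)
  widths <- widths[widths > 0]
  expect_equal(length(widths), 11)
  geom <- extract_hole_geometry(sc)
  expect_equal(geom$bd_um, 200)
  expect_equal(geom$mld_um, 100)
  expect_equal(geom$e_um, 50)
  expect_equal(geom$height_um, 55)
  expect_equal(geom$area_um2, sum(widths) * 5 * 10)
  # absence
  empty <- extract_hole_geometry(mk_scan(matrix(0L, 5, 5)))
  expect_false(empty$present)
  expect_true(all(is.na(unlist(empty[c("mld_um", "bd_um", "e_um",
                                       "height_um", "area_um2")]))))
  # degenerate single pixel
  g <- matrix(0L, 5, 5); g[3, 3] <- 1L
  one <- extract_hole_geometry(mk_scan(g))
  expect_equal(one[c("mld_um", "bd_um", "height_um", "e_um")],
               list(mld_um = 10, bd_um = 10, height_um = 5, e_um = 0))
})

test_that("row widths are lateral extents and stray islands are discarded", {
  # interior island (operculum remnant) must not shrink widths
  sc <- rect_hole()
  sc$grid[10, 14:16] <- 0L
  expect_equal(extract_hole_geometry(sc)$mld_um, 100)
  # small far-away island is discarded from the largest component
  g <- matrix(0L, 30, 40)
  g[5:24, 11:20] <- 1L
  g[2, 35:36] <- 1L
  expect_message(geom <- extract_hole_geometry(mk_scan(g)),
                 "discarding 2 pixel")
  expect_equal(geom$area_um2, 200 * 50)
})

test_that("band defect is the largest interior gap, absence is missing", {
  sc <- band_scan(8L, span = 1:100, gaps = 41:60)
  expect_equal(extract_band_defect(sc, "EZ")$defect_length_um, 200)
  expect_equal(extract_band_defect(band_scan(8L), "EZ")$defect_length_um, 0)
  ab <- extract_band_defect(band_scan(8L), "ELM")
  expect_false(ab$band_present)
  expect_true(is.na(ab$defect_length_um))
  # two gaps: largest vs sum mode
  sc2 <- band_scan(7L, span = 1:100, gaps = c(11:15, 41:60))
  expect_equal(extract_band_defect(sc2, "ELM")$defect_length_um, 200)
  expect_equal(extract_band_defect(sc2, "ELM", mode = "sum")$defect_length_um,
               250)
})

test_that("region areas and qualitative flags follow pixel counts", {
  g <- matrix(0L, 20, 40)
  g[3:5, 1:10] <- 2L   # 30 px
  g[10:11, 1:10] <- 2L # 20 px, disjoint
  sc <- mk_scan(g)
  expect_equal(extract_region_area(sc, "pseudocyst")$area_um2, 50 * 50)
  expect_equal(extract_region_area(sc, "ERM")$area_um2, 0)
  g2 <- matrix(3L, 5, 5)
  expect_equal(extract_region_area(mk_scan(g2, spacing = c(1, 1)),
                                   "ERM")$area_um2, 25)
  # qualitative threshold boundary at min_pixels
  g3 <- matrix(0L, 10, 40); g3[1, 1:25] <- 3L
  expect_true(extract_qualitative(mk_scan(g3))$erm_present)
  g3[1, 20:25] <- 0L  # now 19 px
  q <- extract_qualitative(mk_scan(g3))
  expect_false(q$erm_present)
  expect_false(q$space_present)
})

test_that("measurements are scale-equivariant and satisfy invariants", {
  set.seed(11)
  for (i in 1:20) {
    sc <- trapezoid_hole(base_w = sample(10:30, 1), top_w = sample(3:9, 1),
                         n_rows = sample(5:15, 1))
    g1 <- extract_hole_geometry(sc)
    sc2 <- sc; sc2$spacing_um <- sc$spacing_um * c(1, 2)
    g2 <- extract_hole_geometry(sc2)
    expect_equal(g2$mld_um, 2 * g1$mld_um)
    expect_equal(g2$bd_um, 2 * g1$bd_um)
    expect_equal(g2$height_um, g1$height_um)
    expect_equal(g2$area_um2, 2 * g1$area_um2)
    expect_lte(g1$e_um, g1$height_um)
    expect_true(g1$area_um2 > 0)
  }
})
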