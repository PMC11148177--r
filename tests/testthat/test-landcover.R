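make_lc <- function(codes, cell = 30) {
  flux_raster(codes, cell, "landcover_raster")
}

test_that("fine classes recode onto the printed IGBP aggregation", {
  # spot-check the aggregation rows, including every alias family
  m <- glc_igbp_map()
  lut <- setNames(m$igbp_code, m$glc_code)
  expect_equal(unname(lut[c("10", "11", "12", "20")]), rep(12L, 4))
  expect_equal(unname(lut[c("70", "71", "72")]), rep(1L, 3))
  expect_equal(unname(lut["130"]), 10L)
  expect_equal(unname(lut[c("150", "152", "153", "140", "200", "201",
                            "202")]), rep(16L, 7))
  expect_equal(unname(lut["250"]), 17L)
  expect_equal(unname(lut[c("80", "81", "82")]), rep(3L, 3))

  r <- make_lc(matrix(c(10, 130, 70, 250), 2, 2))
  out <- aggregate_to_igbp(r)
  expect_equal(sort(unique(as.vector(out$values))), c(1, 10, 12, 17))

  bad <- make_lc(matrix(c(10, 999, 998, 130), 2, 2))
  expect_error(aggregate_to_igbp(bad), "998, 999")
})

test_that("weighted cover is the footprint-weighted class share", {
  # two cells in the mask, weights 0.6/0.4, classes grass/crop
  acfc <- flux_raster(matrix(c(0.6, 0.4, 0, 0), 2, 2), 30, "acfc")
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  contours <- structure(list(masks = list(`80` = mask), cell = 30),
                        class = "contour_set")
  igbp <- aggregate_to_igbp(make_lc(matrix(c(130, 10, 10, 10), 2, 2)))
  cover <- weighted_cover(acfc, contours, igbp)
  expect_equal(cover$pct[cover$igbp_code == 10], 60)
  expect_equal(cover$pct[cover$igbp_code == 12], 40)
  expect_equal(sum(cover$pct), 100, tolerance = 1e-9)

  # invariant to positive rescaling of the weights
  acfc2 <- acfc
  acfc2$values <- acfc$values * 1234
  expect_equal(weighted_cover(acfc2, contours, igbp)$pct, cover$pct)

  # a uniform raster is 100% one class
  uni <- weighted_cover(acfc, contours,
                        aggregate_to_igbp(make_lc(matrix(70, 2, 2))))
  expect_equal(uni$pct, 100)
  expect_equal(uni$igbp_code, 1L)
})

test_that("recoding commutes with footprint weighting", {
  withr::with_seed(31, {
    n <- 70
    codes <- matrix(sample(glc_igbp_map()$glc_code, n^2, replace = TRUE),
                    n, n)
    raw <- make_lc(codes)
    w <- matrix(rexp(n^2), n, n)
    acfc <- flux_raster(w / sum(w), 30, "acfc")
    mask <- matrix(TRUE, n, n)
    contours <- structure(list(masks = list(`80` = mask), cell = 30),
                          class = "contour_set")
    # weight per fine class, then merge
    xy <- fluxrep:::raster_xy(acfc)
    fine <- tibble::tibble(
      code = raster_sample(raw, xy$x[mask], xy$y[mask]),
      w = acfc$values[mask]
    ) |>
      dplyr::left_join(glc_igbp_map(), by = c(code = "glc_code")) |>
      dplyr::group_by(igbp_code) |>
      dplyr::summarise(pct = 100 * sum(w), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(pct), igbp_code)
    merged <- weighted_cover(acfc, contours, aggregate_to_igbp(raw))
    expect_equal(merged$igbp_code, fine$igbp_code)
    expect_equal(merged$pct, fine$pct, tolerance = 1e-9)
  })
})

test_that("dominant type honours the savanna/shrubland alias corrections", {
  cover_dbf <- tibble::tibble(igbp_code = c(4L, 10L), abbrev = c("DBF", "GRA"),
                              igbp_name = c("x", "y"), pct = c(70, 30))
  # woody savanna site whose raster aggregates to DBF: alias match
  wsa <- resolve_dominant(cover_dbf, site_igbp = 8)
  expect_true(wsa$match)
  expect_true(wsa$alias_applied)
  # grassland dominant at a grassland site: plain match
  cover_gra <- tibble::tibble(igbp_code = 10L, abbrev = "GRA",
                              igbp_name = "y", pct = 100)
  gra <- resolve_dominant(cover_gra, site_igbp = 10)
  expect_true(gra$match)
  expect_false(gra$alias_applied)
  # cropland dominant at an ENF site: mismatch, flagged not dropped
  cover_cro <- tibble::tibble(igbp_code = 12L, abbrev = "CRO",
                              igbp_name = "z", pct = 100)
  enf <- resolve_dominant(cover_cro, site_igbp = 1)
  expect_false(enf$match)
  # savanna site dominated by ENF: alias match
  sav <- resolve_dominant(
    tibble::tibble(igbp_code = 1L, abbrev = "ENF", igbp_name = "e",
                   pct = 90),
    site_igbp = 9
  )
  expect_true(sav$match)
  expect_true(sav$alias_applied)
  # ties break towards the smaller IGBP code, with a message
  tie <- tibble::tibble(igbp_code = c(10L, 4L), abbrev = c("GRA", "DBF"),
                        igbp_name = c("y", "x"), pct = c(50, 50))
  expect_message(out <- resolve_dominant(tie, site_igbp = 4), "tie")
  expect_equal(out$dominant_code, 4L)
})
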