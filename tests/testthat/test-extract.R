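test_that("uniform zones are read back exactly and noisy means converge", {
  lay <- test_layout()
  # deterministic fill (200, 50, 80) in every zone via degenerate anchors
  m <- color_response_model(anchor_blank = c(200, 50, 80),
                            anchor_adequate = c(200, 50, 80),
                            anchor_excessive = c(200, 50, 80),
                            score_noise_sd = 0)
  img <- render_card(lay, card_assignments(150, lay), m, noiseless_imaging())
  st <- extract_zone_stats(img, lay, attr(img, "transform"))
  expect_true(all(st$mean_r == 200 & st$mean_g == 50 & st$mean_b == 80))
  expect_equal(st$score, rep(120, 9))
  expect_true(all(st$n_pixels > 0))

  # with pixel noise sd 5 over >= 500 px the zone means stay within 0.5
  # (0.5 is > 2 standard errors of the mean at the smallest zones here)
  imgn <- render_card(lay, card_assignments(150, lay), m,
                      imaging_model(pixel_noise_sd = 5, seed = 23))
  stn <- extract_zone_stats(imgn, lay, attr(imgn, "transform"))
  expect_true(all(stn$n_pixels >= 500))
  expect_true(all(abs(stn$mean_r - 200) < 0.5))
  expect_true(all(abs(stn$mean_b - 80) < 0.5))
})

test_that("a zone straddling the image edge is flagged, not fatal", {
  lay <- test_layout()
  img <- render_card(lay, card_assignments(150, lay),
                     imaging = noiseless_imaging())
  shifted <- registration_transform(translation_px = c(-120, 0),
                                    center_px = attr(img, "transform")$center_px)
  st <- extract_zone_stats(img, lay, shifted)
  expect_true(any(st$out_of_frame))
  expect_false(all(st$out_of_frame))
  expect_true(all(is.na(st$mean_r[st$out_of_frame])))
  expect_true(all(is.finite(st$score[!st$out_of_frame])))
})

test_that("rb_score subtracts blue from red and ignores gray offsets", {
  expect_equal(rb_score(c(200, 50, 80)), 120)
  expect_equal(rb_score(c(77, 77, 77)), 0)
  # invariance to a uniform channel offset (below clipping)
  base <- c(120, 60, 90)
  expect_equal(rb_score(base + 40), rb_score(base))
  # score recomputable from stored means
  lay <- test_layout()
  img <- render_card(lay, card_assignments(250, lay),
                     imaging = imaging_model(pixel_noise_sd = 2, seed = 2))
  st <- extract_zone_stats(img, lay, attr(img, "transform"))
  expect_equal(st$score, st$mean_r - st$mean_b, tolerance = 1e-12)
  expect_equal(rb_score(st), st$score, tolerance = 1e-12)
})

test_that("default anchors score negative for blanks, positive for 300", {
  m <- color_response_model()
  expect_lt(sk_score(0, 3, m), 0)
  expect_gt(sk_score(300, 3, m), 0)
})

test_that("colour-standard patches are reported for diagnostics when asked", {
  lay <- test_layout()
  img <- render_card(lay, card_assignments(150, lay),
                     imaging = noiseless_imaging())
  st <- extract_zone_stats(img, lay, attr(img, "transform"),
                           read_patches = TRUE)
  patches <- st[st$role == "patch", ]
  expect_equal(nrow(patches), nrow(lay$color_patches))
  expect_equal(patches$mean_r, lay$color_patches$r, tolerance = 1e-12)
})
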