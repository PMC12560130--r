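test_that("default layout satisfies the chip's structural invariants", {
  lay <- default_layout()
  roles <- lay$aperture_roles
  expect_identical(lay$n_apertures, 55L)
  expect_equal(sum(roles == "sensor"), 24)
  expect_equal(sum(roles == "reference"), 23)
  expect_equal(sum(roles == "edge_blank"), 8)
  expect_true(all(roles[c(1:4, 52:55)] == "edge_blank"))
  inner <- roles[5:51]
  expect_identical(inner[c(1, 47)], c("sensor", "sensor"))
  expect_true(all(inner[seq(1, 47, 2)] == "sensor"))
  expect_true(all(inner[seq(2, 46, 2)] == "reference"))
  expect_setequal(lay$sensor_ids[roles == "sensor"], 1:24)
  expect_equal(lay$pitch_um, 750)
  # corrupted layouts are rejected
  bad <- lay; bad$aperture_roles[5] <- "reference"
  expect_error(validate_layout(bad), "alternate")
})

test_that("reference pairing is total over the 24 sensors and adjacent", {
  lay <- default_layout()
  refs <- pair_references(lay)
  expect_length(refs, 24)
  expect_true(all(lay$aperture_roles[refs] == "reference"))
  sensors <- which(lay$aperture_roles == "sensor")
  sensors <- sensors[order(lay$sensor_ids[sensors])]
  expect_true(all(abs(refs - sensors) == 1))
})

test_that("default catalog has the study roster and is seed-deterministic", {
  cat35 <- default_catalog(seed = 42)
  classes <- vapply(cat35, `[[`, "", "class_label")
  counts <- table(classes[classes != "di_water"])
  expect_equal(sum(classes != "di_water"), 35)
  expect_equal(unname(counts[c("mineral_water", "beer", "white_wine",
                               "whiskey", "vodka", "gin")]),
               c(6, 6, 8, 5, 4, 6), ignore_attr = TRUE)
  expect_identical(default_catalog(seed = 42), cat35)
  expect_false(identical(default_catalog(seed = 43), cat35))
  di <- cat35[["DI"]]
  expect_true(all(unclass(di$composition) == 0))
  expect_equal(di$refractive_index, RI_WATER_25C)
})

test_that("composition_to_ri reproduces its table and is feature-monotone", {
  # table endpoints and nodes are reproduced exactly
  expect_equal(composition_to_ri(analyte_composition()), 1.33250)
  expect_equal(composition_to_ri(analyte_composition(abv = 40)), 1.34920)
  expect_equal(composition_to_ri(analyte_composition(abv = 100)), 1.35940)
  # interpolation stays between neighbouring nodes
  ri5 <- composition_to_ri(analyte_composition(abv = 5))
  expect_gt(ri5, 1.33250); expect_lt(ri5, 1.33620)
  # monotone nondecreasing in every dissolved-solid feature
  base <- analyte_composition(abv = 12, sugars = 3)
  ri0 <- composition_to_ri(base)
  for (f in analyte_features()) {
    args <- as.list(unclass(base))
    args[[f]] <- args[[f]] + 5
    expect_gt(composition_to_ri(do.call(analyte_composition, args)), ri0)
  }
  expect_error(analyte_composition(abv = 120), "abv")
  expect_error(analyte_composition(sugars = -1), "nonnegative")
})

test_that("equilibrium_shift obeys its closed forms and bounds", {
  chem <- default_chemistries(seed = 1)
  model <- response_model()
  di <- liquid_sample("DI", "di_water", analyte_composition())
  for (i in c(1, 13, 24))
    expect_equal(equilibrium_shift(chem[i, ], di, model), 0)

  # single feature at its half-saturation with negligible bulk: A/2
  tiny_bulk <- response_model(bulk_sensitivity = 1e-9)
  s_half <- liquid_sample("half", "custom",
                          analyte_composition(sugars = chem$k_sugars[9]))
  expect_equal(equilibrium_shift(chem[9, ], s_half, tiny_bulk),
               chem$aff_sugars[9] / 2, tolerance = 1e-6)

  # saturation: huge concentration approaches bulk + affinity
  s_sat <- liquid_sample("sat", "custom",
                         analyte_composition(sugars = 1e9))
  shift <- equilibrium_shift(chem[9, ], s_sat, model)
  bulk <- model$bulk_sensitivity * (s_sat$refractive_index - RI_WATER_25C)
  expect_equal(shift, bulk + chem$aff_sugars[9], tolerance = 1e-4)

  # bounded above by bulk + total affinity, for an arbitrary sample
  mats <- chemistry_matrices(chem)
  s <- liquid_sample("x", "custom",
                     analyte_composition(abv = 10, sugars = 50,
                                         divalent_cations = 1,
                                         organic_acids = 10,
                                         aroma_compounds = 2))
  bulk_s <- model$bulk_sensitivity * (s$refractive_index - RI_WATER_25C)
  for (i in 1:24)
    expect_lt(equilibrium_shift(chem[i, ], s, model),
              bulk_s + sum(mats$affinity[i, ]) + 1e-12)
})

test_that("kinetic_shift follows the single-exponential on-curve", {
  expect_equal(kinetic_shift(3, 0.01, 0), 0)
  expect_equal(kinetic_shift(3, 0.01, 1e7), 3)
  expect_equal(kinetic_shift(3, 0.01, 100), 3 * (1 - exp(-1)))
  t <- seq(0, 600, by = 30)
  y <- kinetic_shift(2.5, 0.02, t)
  expect_true(all(diff(y) > 0))
  expect_error(kinetic_shift(3, 0.01, -5), "nonnegative")
  # composed time response approaches the equilibrium shift
  chem <- default_chemistries(1)
  beer <- tiny_catalog()[[2]]
  expect_equal(shift_at_time(chem[16, ], beer, 1e7),
               equilibrium_shift(chem[16, ], beer), tolerance = 1e-9)
})

test_that("per-element water resonances honour the 709 +/- 4 nm spread", {
  chem <- default_chemistries(seed = 7)
  expect_true(all(abs(chem$resonance_water - 709) < 4 * 4))
  expect_equal(mean(default_chemistries(1)$resonance_water), 709,
               tolerance = 0.01)  # tolerance in relative units of 709
})

test_that("render_frame puts the analytic dip where the oracle says", {
  lay <- default_layout()
  centers <- seq(650, 760, length.out = 24)
  fr <- render_frame(lay, centers, noiseless_model(),
                     calibration = coarse_cal(), seed = 1)
  wl <- fr$calibration$intercept +
    fr$calibration$slope * (seq_len(nrow(fr$intensity)) - 1)
  lamp <- lamp_profile(wl)
  roles <- lay$aperture_roles
  # reference column: exactly the lamp profile
  ref_col <- lay$column_pixel_map[which(roles == "reference")[1], 1]
  expect_equal(fr$intensity[, ref_col], lamp)
  # sensor column: argmin at the injected centre (dense-grid oracle)
  a <- which(roles == "sensor")[3]
  col <- fr$intensity[, lay$column_pixel_map[a, 1]]
  i_min <- which.min(col / lamp)
  truth <- oracle_argmin(centers[lay$sensor_ids[a]], from = 600, to = 800)
  expect_lt(abs(wl[i_min] - truth), fr$calibration$slope)
  # seeded determinism with noise on
  f1 <- render_frame(lay, centers, response_model(),
                     calibration = coarse_cal(), seed = 9)
  f2 <- render_frame(lay, centers, response_model(),
                     calibration = coarse_cal(), seed = 9)
  expect_identical(f1$intensity, f2$intensity)
  expect_error(render_frame(lay, rep(1000, 24), noiseless_model(),
                            calibration = coarse_cal()),
               "outside")
})
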