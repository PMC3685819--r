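# Hindrance factors for the three substructure models, geometry inversion
# and relative hindrance. Frozen values computed with direct evaluation /
# bisection oracles on the closed forms.

test_that("channel and slit hindrance hit the exact endpoint identities", {
  # coefficient sums are exactly -1, so H(1) = 0 exactly; H(0) = 1 exactly
  expect_identical(hindrance_channel(0), 1)
  expect_identical(hindrance_channel(1), 0)
  expect_identical(hindrance_slit(0), 1)
  expect_identical(hindrance_slit(1), 0)
  # solute larger than the pore cannot enter
  expect_identical(hindrance_channel(1.7), 0)
  expect_identical(hindrance_slit(3), 0)
})

test_that("channel and slit hindrance match direct-evaluation oracles", {
  expect_equal(hindrance_channel(0.5), 0.0474472, tolerance = 1e-6)
  expect_equal(hindrance_slit(0.5), 0.2445086, tolerance = 1e-6)
  # 1000-fold level of the slit model sits at lambda ~ 0.99508
  expect_equal(hindrance_slit(0.9950839), 1e-3, tolerance = 1e-5)
})

test_that("hindrance curves decrease strictly and channels hinder more than slits", {
  grid <- seq(1e-3, 1 - 1e-3, length.out = 1000)
  hc <- hindrance_channel(grid)
  hs <- hindrance_slit(grid)
  # the channel polynomial's rounded coefficients leave a ~1e-6 amplitude
  # wiggle in the far tail (lambda ~ 0.95-0.99); strict decrease holds
  # above that numerical noise floor and the tail stays below it
  expect_true(all(diff(hc[grid <= 0.94]) < 0))
  expect_true(all(hc[grid > 0.94] < 3e-6))
  expect_true(all(diff(hs) < 0))
  expect_true(all(hc <= hs))
  expect_true(all(hc >= 0 & hc <= 1))
  expect_true(all(hs >= 0 & hs <= 1))
  expect_error(hindrance_channel(-0.1), "lambda_ratio")
  expect_error(hindrance_slit(-1), "lambda_ratio")
})

test_that("hydrogel hindrance matches its oracle and is monotone in phi and radius", {
  # unhindered at zero polymer fraction for any solute
  expect_identical(hindrance_hydrogel(5, hydrogel_geometry(0)), 1)
  expect_identical(hindrance_hydrogel(0.1, hydrogel_geometry(0)), 1)
  # direct evaluation oracle of the reconstructed expression
  expect_equal(hindrance_hydrogel(5, hydrogel_geometry(0.2, fiber_radius = 15)),
               0.1863, tolerance = 1e-3)
  # monotone decreasing in volume fraction under both conventions
  phis <- seq(0.05, 0.6, by = 0.05)
  for (conv in c("solute_over_fiber", "fiber_over_solute")) {
    hs <- vapply(phis, function(p) {
      hindrance_hydrogel(5, hydrogel_geometry(p, lambda_convention = conv))
    }, numeric(1))
    expect_true(all(diff(hs) < 0))
  }
  expect_error(hydrogel_geometry(1.2), "volume_fraction")
  expect_error(hydrogel_geometry(-0.1), "volume_fraction")
})

test_that("the hydrogel size-selectivity anomaly is present and documented", {
  # known limitation of the reconstructed gel expression (see vignette):
  # over the sugar size range it does NOT hinder larger solutes more --
  # the default convention gives slightly higher H for larger radii, so no
  # size-based filtering claim is derivable from the gel model here
  hs <- vapply(c(4.38, 5.37, 6.17), function(r) {
    hindrance_hydrogel(r, hydrogel_geometry(0.49))
  }, numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_true(all(hs > 0 & hs < 0.1))  # strong but near-uniform hindrance
})

test_that("invert_geometry is a two-sided inverse of the forward evaluation", {
  # bisection-oracle anchors from the stachyose radius 6.1 A at H = 1e-3
  expect_equal(invert_geometry("channel", 6.1, 1e-3), 7.723, tolerance = 1e-3)
  expect_equal(invert_geometry("slit", 6.1, 1e-3), 6.130, tolerance = 1e-3)
  for (model in c("channel", "slit")) {
    h_fun <- if (model == "channel") hindrance_channel else hindrance_slit
    for (target in c(0.5, 1e-2, 1e-3, 1e-6)) {
      dim <- invert_geometry(model, 4.38, target)
      expect_equal(h_fun(4.38 / dim), target, tolerance = 1e-9)
    }
  }
  expect_error(invert_geometry("slit", 6.1, 1), "no finite solution")
  expect_error(invert_geometry("slit", 6.1, 0), "target_h")
  # near-unity targets push the dimension above the bracket ceiling
  expect_error(invert_geometry("slit", 6.1, 1 - 1e-12), "no finite solution")
})

test_that("relative hindrance reproduces the slit ratio and degenerates safely", {
  # raffinose vs sucrose in a 6.1 A half-width slit: ~3.16-fold
  expect_equal(relative_hindrance(slit_geometry(6.1), SOLUTES$raffinose,
                                  SOLUTES$sucrose), 3.16, tolerance = 0.01)
  # identical solutes: exactly 1
  expect_equal(relative_hindrance(slit_geometry(6.1), SOLUTES$sucrose,
                                  SOLUTES$sucrose), 1)
  # channel at the same dimension is far more size-sensitive (tens-fold)
  ratio <- relative_hindrance(channel_geometry(6.1), SOLUTES$raffinose,
                              SOLUTES$sucrose)
  expect_gt(ratio, 10)
  # blocked large solute vs passing small one -> Inf with a warning
  expect_warning(
    r <- relative_hindrance(slit_geometry(5), SOLUTES$stachyose, SOLUTES$sucrose),
    "fully blocked")
  expect_identical(r, Inf)
  # both blocked -> undefined
  expect_error(relative_hindrance(slit_geometry(2), SOLUTES$stachyose,
                                  SOLUTES$sucrose), "undefined ratio")
})

test_that("hindrance_factor dispatches per geometry with consistent metadata", {
  hf <- hindrance_factor(CHANNEL_MATCHED, SOLUTES$fluorescein)
  expect_equal(hf$lambda_ratio, 4.9 / 6.4)
  expect_equal(hf$model_id, "channel")
  expect_equal(hf$apparent_diffusivity,
               hf$hindrance * d_cytosol(SOLUTES$fluorescein))
  hf2 <- hindrance_factor(HYDROGEL_MATCHED, SOLUTES$sucrose)
  expect_equal(hf2$model_id, "hydrogel")
  expect_true(hf2$hindrance > 0 && hf2$hindrance <= 1)
})

test_that("hindrance curve export covers all models with expected anchors", {
  curve <- hindrance_curve(SOLUTES, dimensions = c(5.2, 6.1, 20),
                           models = c("channel", "slit"))
  expect_named(curve, c("model", "dimension_angstrom", "solute", "lambda",
                        "hindrance"))
  # slit at 20 A half-width passes sucrose at ~56%
  row <- curve[curve$model == "slit" & curve$dimension_angstrom == 20 &
                 curve$solute == "sucrose", ]
  expect_equal(row$hindrance, 0.5554, tolerance = 1e-3)
  # fully-blocked rows appear (stachyose in the 5.2 A slit)
  blocked <- curve[curve$model == "slit" & curve$dimension_angstrom == 5.2 &
                     curve$solute == "stachyose", ]
  expect_identical(blocked$hindrance, 0)
})
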