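test_that("tissue class specs validate their parameter space", {
  expect_error(tissueClassSpec("astrocytoma"), "unknown class_name")
  expect_error(tissueClassSpec("gland", redox_mean = 1.2), "redoxMean")
  expect_error(tissueClassSpec("gland",
                               band_amplitudes = c("1234" = 0.5)),
               "ramanBandCatalog")
  expect_error(tissueClassSpec("gland",
                               band_amplitudes = c("1445" = -1)),
               "amplitudes")
  sp <- tissueClassSpec("gland")
  expect_s4_class(sp, "TissueClassSpec")
  expect_equal(sp@redoxMean, 0.40)
  expect_equal(tissueClassSpec("corticotroph")@redoxMean, 0.86)
})

test_that("generated planes satisfy the construction identities", {
  for (cl in c("gland", "gonadotroph", "corticotroph")) {
    pl <- generatePlane(tissueClassSpec(cl), seed = 5)
    expect_equal(modalityImage(pl, "MPM"),
                 modalityImage(pl, "SHG") + modalityImage(pl, "TPEF"),
                 tolerance = 0)
    expect_equal(modalityImage(pl, "TPEF"), nadhImage(pl) + fadImage(pl),
                 tolerance = 0)
    expect_true(all(vapply(pl@images, function(m) all(m >= 0),
                           logical(1))))
    expect_gt(sum(tissueMask(pl)), 0)
  }
})

test_that("plane generation is deterministic and seed-sensitive", {
  sp <- tissueClassSpec("gland")
  a <- generatePlane(sp, seed = 9)
  b <- generatePlane(sp, seed = 9)
  c <- generatePlane(sp, seed = 10)
  expect_identical(a@images, b@images)
  expect_identical(a@nadh, b@nadh)
  expect_false(identical(a@images$TPEF, c@images$TPEF))
})

test_that("gland planes carry multiple bright cell nests", {
  sp <- tissueClassSpec("gland", nest_density = 12)
  pl <- generatePlane(sp, seed = 1)
  tpef <- modalityImage(pl, "TPEF")
  ncomp <- countBrightComponents(tpef, max(tpef) / 2)
  expect_gte(ncomp, 8)
})

test_that("noise-free planes recover the exact redox ratio", {
  sp <- tissueClassSpec("gland", noise_sd = 0, redox_sd = 0,
                        redox_mean = 0.5)
  pl <- generatePlane(sp, seed = 3)
  expect_equal(mean(nadhImage(pl)) /
                 (mean(nadhImage(pl)) + mean(fadImage(pl))), 0.5)
})

test_that("plane generation rejects invalid acquisition factors", {
  sp <- tissueClassSpec("gland")
  expect_error(generatePlane(sp, seed = 1, acquisition = list(
    nadh = c(laser_power = 0, gain = 1, detector_response = 1),
    fad = c(laser_power = 1, gain = 1, detector_response = 1))),
    "positive")
  expect_error(generatePlane(sp, shape = c(16, 16), seed = 1), "32")
})

test_that("the default composition reproduces the study cohort counts", {
  comp <- defaultComposition()
  expect_equal(sum(comp$n_planes), 174)
  expect_equal(sum(comp$n_planes[comp$class_name == "gland"]), 25)
  expect_equal(sum(comp$n_planes[comp$class_name != "gland"]), 149)
  expect_equal(length(unique(comp$biopsy_id[comp$class_name != "gland"])),
               25)
})

test_that("cohort generation respects composition and grouping", {
  comp <- data.frame(biopsy_id = c("g1", "lac1"),
                     class_name = c("gland", "lactotroph"),
                     n_planes = c(1L, 2L))
  co <- generateCohort(composition = comp, seed = 1, shape = c(48, 48),
                       raman_positions = 5)
  expect_equal(length(planes(co)), 3)
  bid <- vapply(planes(co), function(p) p@biopsyId, character(1))
  cl <- vapply(planes(co), className, character(1))
  expect_true(all(tapply(cl, bid, function(x) length(unique(x)) == 1)))
  expect_equal(length(ramanMaps(co)), 2)
  ## same composition, different seed: same counts, different pixels
  co2 <- generateCohort(composition = comp, seed = 2, shape = c(48, 48),
                        raman_positions = 0)
  expect_equal(length(planes(co2)), 3)
  expect_false(identical(planes(co)[[1]]@images$TPEF,
                         planes(co2)[[1]]@images$TPEF))
  expect_error(generateCohort(composition = data.frame(
    biopsy_id = "x", class_name = "nonexistent", n_planes = 1L)),
    "class_specs missing")
})

test_that("raman maps place bands where the spec puts them", {
  sp <- tissueClassSpec("gland", band_amplitudes = c("1004" = 1),
                        baseline_coeffs = 0, noise_sd = 0)
  m <- generateRamanMap(sp, n_positions = 1, seed = 1)
  expect_equal(wavenumbers(m)[which.max(spectra(m)[1, ])], 1004)
  expect_true(all(spectra(m) >= 0))
  m2 <- generateRamanMap(tissueClassSpec("gland"), n_positions = 2100,
                         seed = 1, axis = seq(600, 3100, by = 5))
  expect_equal(nrow(spectra(m2)), 2100)
  expect_error(generateRamanMap(sp, n_positions = 0), "n_positions")
})

test_that("generator truth encodes the reported lipid elevation", {
  gland <- tissueClassSpec("gland")
  lacto <- tissueClassSpec("lactotroph")
  r3 <- function(s) idealBandIntensity(s, 1445) / idealBandIntensity(s, 720)
  expect_lt(r3(gland), r3(lacto))
})

test_that("raman map generation is deterministic given (spec, seed)", {
  sp <- tissueClassSpec("null_cell")
  a <- generateRamanMap(sp, n_positions = 7, seed = 4)
  b <- generateRamanMap(sp, n_positions = 7, seed = 4)
  expect_identical(spectra(a), spectra(b))
})

test_that("downstream class separability degrades with generator noise", {
  accs <- vapply(c(0.05, 0.4, 1.2), function(ns) {
    X <- NULL; labs <- character(0)
    for (cl in c("gland", "lactotroph", "corticotroph")) {
      sp <- tissueClassSpec(cl, noise_sd = ns)
      pm <- preprocessMap(generateRamanMap(sp, n_positions = 30,
                                           seed = match(cl,
                                                        pituitaryClasses()),
                                           axis = seq(600, 3100, by = 4)))
      X <- rbind(X, spectra(pm))
      labs <- c(labs, rep(cl, nrow(spectra(pm))))
    }
    rep <- ramanSubtypeCV(X, labs, n_folds = 3, seed = 1)
    sum(diag(rep@confusion)) / sum(rep@confusion)
  }, numeric(1))
  expect_true(all(diff(accs) <= 1e-9))
})
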