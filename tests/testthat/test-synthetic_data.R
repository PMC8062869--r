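test_that("a noiseless hard-edged scene gives exactly two-valued channels", {
  sc <- grain_scene(width_px = 120, height_px = 160, noise_sd = 0,
                    psf_sigma_px = 0, seed = 1)
  m <- make_element_map(sc)
  for (k in m$channels)
    expect_lte(length(unique(as.vector(m$values[[k]]))), 2)
  expect_equal(sort(unique(as.vector(m$values$Fe))), c(2, 30))
})

test_that("generators are pure functions of (parameters, seed)", {
  sc <- grain_scene(width_px = 100, height_px = 120, seed = 14)
  expect_identical(make_element_map(sc), make_element_map(sc))
  m <- make_element_map(sc)
  p1 <- simulate_selective_cells(m, beta = c(S = 1), target_n = 80, seed = 6)
  p2 <- simulate_selective_cells(m, beta = c(S = 1), target_n = 80, seed = 6)
  expect_identical(p1$x, p2$x)
  mk1 <- suppressWarnings(make_feature_mask(p1, seed = 4))
  mk2 <- suppressWarnings(make_feature_mask(p2, seed = 4))
  expect_identical(mk1$labels, mk2$labels)
})

test_that("grain/matrix signal contrast survives noise", {
  sc <- grain_scene(width_px = 200, height_px = 250, seed = 3,
                    psf_sigma_px = 0, noise_smooth_px = 0)
  m <- make_element_map(sc)
  gm <- grain_mask(sc)
  ratio <- mean(m$values$Fe[gm]) / mean(m$values$Fe[!gm])
  expect_equal(ratio, 15, tolerance = 0.1) # 30 vs 2, truncation shifts slightly
})

test_that("zero selectivity gives a homogeneous pattern with the Poisson mean", {
  sc <- grain_scene(width_px = 100, height_px = 100, seed = 8)
  m <- make_element_map(sc)
  ns <- vapply(1:100, function(s) {
    n_points(simulate_selective_cells(m, beta = c(S = 0), beta0 = log(150 / window_area(m$window)),
                                      seed = s))
  }, numeric(1))
  expect_lt(abs(mean(ns) - 150), 3 * sqrt(150 / 100))
  tr <- attr(simulate_selective_cells(m, beta = c(S = 0),
                                      beta0 = log(150 / window_area(m$window)),
                                      seed = 1), "truth")
  expect_equal(tr$expected_n, 150, tolerance = 1e-9)
})

test_that("strong selectivity concentrates cells on the grain", {
  sc <- grain_scene(width_px = 200, height_px = 250, seed = 9,
                    psf_sigma_px = 0, noise_sd = 0)
  m <- make_element_map(sc)
  gm <- grain_mask(sc)
  # calibrate beta for a 10:1 in/out intensity contrast on the two-valued S
  zvals <- sort(unique(as.vector(biofilmspat:::standardized_channels(m, "S")$S)))
  beta_s <- log(10) / diff(zvals)
  frac_area <- mean(gm)
  expected_inside <- 10 * frac_area / (10 * frac_area + (1 - frac_area))
  ins <- tot <- 0
  for (s in 1:20) {
    pat <- simulate_selective_cells(m, beta = c(S = beta_s), target_n = 300,
                                    seed = 400 + s)
    ij <- biofilmspat:::px_index(m$window, pat$x, pat$y)
    ins <- ins + sum(gm[ij]); tot <- tot + n_points(pat)
  }
  expect_equal(ins / tot, expected_inside, tolerance = 0.05)
  expect_gte(ins / tot, 0.8 * expected_inside)
  # runaway intensities are rejected
  expect_error(simulate_selective_cells(m, beta = c(S = 30), target_n = 2e6),
               "runaway|1e|exceed")
})

test_that("stamped masks round-trip through morphology classification", {
  sc <- grain_scene(width_px = 300, height_px = 300, seed = 2)
  m <- make_element_map(sc)
  pat <- simulate_selective_cells(m, beta = c(S = 0), target_n = 60, seed = 3)
  # pure cocci: every feature classifies as cocci
  mk <- suppressWarnings(
    make_feature_mask(pat, morphology_mix = c(cocci = 1), seed = 5))
  met <- feature_metrics(mk)
  expect_true(all(met$morphology == "cocci"))
  expect_equal(nrow(met), n_points(pat))
  # a 60/40 rod/cocci mix is recovered within binomial bounds; stamp sizes
  # are kept above the digitization floor (~r 6 px) where circularity
  # classification is reliable
  pat2 <- simulate_selective_cells(m, beta = c(S = 0), target_n = 250, seed = 7)
  mk2 <- suppressWarnings(
    make_feature_mask(pat2, morphology_mix = c(rod = 0.6, cocci = 0.4),
                      mean_area_um2 = 0.3, seed = 11))
  truth <- attr(mk2, "truth_class")
  met2 <- feature_metrics(mk2)
  agree <- mean(met2$morphology == truth[met2$feature_id])
  expect_gt(agree, 0.9) # stamped shapes classify as designed
  n <- length(truth)
  p_cocci_true <- mean(truth == "cocci")
  expect_lt(abs(p_cocci_true - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  p_cocci_rec <- mean(met2$morphology == "cocci")
  expect_lt(abs(p_cocci_rec - 0.4), 3 * sqrt(0.4 * 0.6 / n) + 0.05)
  # empty pattern -> empty mask
  mk0 <- make_feature_mask(cell_pattern(numeric(0), numeric(0), m$window))
  expect_equal(max(mk0$labels), 0)
})

test_that("community fixtures plant taxon-element correlations", {
  chem <- bulk_chem_table(list(
    A = c(Fe = 2, S = 8, Si = 30), B = c(Fe = 6, S = 1, Si = 28),
    C = c(Fe = 10, S = 4, Si = 25), D = c(Fe = 4, S = 12, Si = 27)))
  # rows sum to 1
  tb0 <- make_community_fixture(12, 20, chem, seed = 1)
  expect_equal(unname(rowSums(tb0$abundance)), rep(1, 12))
  # no links: correlations centred on zero across seeds
  cors <- vapply(1:15, function(s) {
    tb <- make_community_fixture(16, 10, chem, seed = s)
    stats::cor(tb$abundance[, "taxon1"], chem[tb$substrates, "S"])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.2)
  # planted link: strong positive correlation in most seeds
  hits <- vapply(1:10, function(s) {
    tb <- make_community_fixture(16, 10, chem,
                                 linked_taxa = list(taxon3 = list(element = "S",
                                                                  effect = 2)),
                                 seed = 50 + s)
    stats::cor(tb$abundance[, "taxon3"], chem[tb$substrates, "S"]) > 0.6
  }, logical(1))
  expect_gte(sum(hits), 8)
})
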