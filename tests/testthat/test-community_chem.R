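test_that("bulk chemistry is the element-wise scan mean", {
  s1 <- c(Fe = 10, S = 2); s2 <- c(Fe = 14, S = 4)
  expect_equal(bulk_chemistry(list(s1, s2)), c(Fe = 12, S = 3))
  expect_equal(bulk_chemistry(list(s1)), s1)
  eight <- rep(list(c(Si = 25, Fe = 8)), 8)
  expect_equal(bulk_chemistry(eight), c(Si = 25, Fe = 8))
  expect_error(bulk_chemistry(list(s1, c(Fe = 1, Ti = 2))), "element set")
})

test_that("taxa filtering applies the 1% / half-prevalence rule without renormalizing", {
  ab <- rbind(c(0.005, 0.02, 0.975), c(0.005, 0, 0.995),
              c(0.005, 0.03, 0.965), c(0.005, 0, 0.995))
  colnames(ab) <- c("rare", "patchy", "common")
  tb <- community_table(ab)
  filt <- filter_taxa(tb)
  # rare: 0.5% everywhere -> out; patchy: 2% in exactly half -> kept
  expect_equal(colnames(filt$abundance), c("patchy", "common"))
  expect_false(any(abs(rowSums(filt$abundance) - 1) < 1e-9)) # not renormalized
  # idempotent
  expect_identical(filter_taxa(filt)$abundance, filt$abundance)
  # empty in, empty out; all-fail warns
  tb0 <- community_table(matrix(numeric(0), 0, 0))
  expect_equal(ncol(filter_taxa(tb0)$abundance), 0)
  low <- community_table(rbind(c(0.004, 0.996), c(0.004, 0.996)))
  expect_warning(filter_taxa(low, min_abundance = 0.999, min_prevalence = 1),
                 "no taxa")
})

test_that("taxa-chemistry correlations match direct evaluation and flag undefined entries", {
  chem <- bulk_chem_table(list(A = c(Fe = 2, S = 1), B = c(Fe = 4, S = 1),
                               C = c(Fe = 6, S = 1), D = c(Fe = 8, S = 1)))
  ab <- cbind(prop = c(0.1, 0.2, 0.3, 0.4), const = rep(0.2, 4),
              other = c(0.7, 0.6, 0.5, 0.4))
  ab <- ab / rowSums(ab)
  colnames(ab) <- c("prop", "const", "other")
  tb <- community_table(ab, substrates = c("A", "B", "C", "D"),
                        check_rowsums = FALSE)
  cm <- taxa_chem_correlation(tb, chem)
  expect_equal(cm["prop", "Fe"], 1)
  expect_true(is.na(cm["const", "Fe"]))   # zero-variance taxon: undefined
  expect_true(all(is.na(cm[, "S"])))      # zero-variance element: undefined
  # brute-force Pearson oracle on a 4-sample hand dataset
  X <- chem[tb$substrates, ]
  for (tx in colnames(ab)) for (el in colnames(chem)) {
    xm <- ab[, tx] - mean(ab[, tx]); ym <- X[, el] - mean(X[, el])
    oracle <- if (sum(xm^2) == 0 || sum(ym^2) == 0) NA_real_
              else sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
    expect_equal(unname(cm[tx, el]), oracle, tolerance = 1e-12)
  }
  expect_error(taxa_chem_correlation(
    community_table(ab[1:2, ] / rowSums(ab[1:2, ]), substrates = c("A", "B")),
    chem), "at least 3")
})

test_that("Bray-Curtis has its closed-form values and permutation invariance", {
  tb <- community_table(rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0),
                              c = c(1, 0, 0), d = c(0, 0, 1)))
  d <- bray_curtis(tb)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["c", "d"], 1)         # disjoint supports
  expect_equal(d["b", "c"], 0.5)       # (0.5,0.5) vs (1,0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_true(all(d >= 0 & d <= 1))
  # permuting taxa leaves the matrix unchanged
  tb2 <- community_table(tb$abundance[, c(3, 1, 2)], check_rowsums = FALSE)
  expect_equal(unname(bray_curtis(tb2)), unname(d))
  expect_error(bray_curtis(community_table(rbind(c(0, 0), c(0.5, 0.5)),
                                           check_rowsums = FALSE)),
               "all-zero")
})

test_that("SIMPER contributions decompose the mean between-group dissimilarity", {
  ab <- rbind(g1a = c(0.7, 0.2, 0.1), g1b = c(0.6, 0.3, 0.1),
              g2a = c(0.1, 0.2, 0.7), g2b = c(0.2, 0.2, 0.6))
  colnames(ab) <- c("x", "y", "z")
  tb <- community_table(ab, groups = c("g1", "g1", "g2", "g2"))
  res <- simper_contributions(tb)
  # identity: contributions sum to the mean between-group Bray-Curtis
  d <- bray_curtis(tb)
  expect_equal(res$overall, mean(d[1:2, 3:4]), tolerance = 1e-12)
  # oracle: direct pairwise evaluation
  oracle <- bf_simper(ab, tb$groups, "g1", "g2")
  expect_equal(stats::setNames(res$contributions$average,
                               res$contributions$taxon),
               oracle[order(oracle, decreasing = TRUE)], tolerance = 1e-12)
  # 75% cutoff picks the smallest sufficient prefix
  cum <- res$contributions$cumulative_share
  k <- length(res$selected)
  expect_gte(cum[k], 0.75)
  if (k > 1) expect_lt(cum[k - 1], 0.75)
  # identical groups -> all contributions zero
  same <- community_table(rbind(ab[1, ], ab[1, ], ab[1, ], ab[1, ]),
                          groups = c("g1", "g1", "g2", "g2"))
  same_res <- simper_contributions(same)
  expect_equal(same_res$overall, 0)
  expect_equal(same_res$contributions$average, rep(0, 3))
  expect_error(simper_contributions(
    community_table(ab, groups = rep("g1", 4))), "two group")
})

test_that("SIMPER agrees with vegan and the identity holds on random tables", {
  for (seed in 1:20) {
    tb <- random_community(8, 12, seed,
                           groups = rep(c("rock", "control"), each = 4))
    res <- simper_contributions(tb)
    d <- bray_curtis(tb)
    expect_equal(res$overall, mean(d[tb$groups == "rock",
                                     tb$groups == "control"]),
                 tolerance = 1e-12)
    expect_true(all(res$contributions$average >= 0))
  }
  # independent cross-check against vegan::simper on one table
  tb <- random_community(10, 15, 99, groups = rep(c("a", "b"), each = 5))
  res <- simper_contributions(tb)
  vg <- vegan::simper(tb$abundance, tb$groups, permutations = 0)
  vavg <- vg[[1]]$average
  ours <- stats::setNames(res$contributions$average, res$contributions$taxon)
  expect_equal(ours[names(vavg)][order(names(vavg))],
               vavg[order(names(vavg))], tolerance = 1e-10)
})
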