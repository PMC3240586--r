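# Roughness statistics: additive model fit, local roughness, peaks, tree
# component.

test_that("an exactly additive landscape has zero residual", {
  ls <- additive_cube(4)
  fit <- fit_additive(ls)
  expect_lt(fit$ss_residual, 1e-20)
  expect_equal(unname(fit$fitted[main_peak(ls)]),
               max(ls$fitness))
  expect_equal(deviation_from_additivity(fit), 0, tolerance = 1e-12)
  expect_equal(variability_explained(fit), 1, tolerance = 1e-12)
})

test_that("2-site fit matches the normal-equations oracle", {
  ls <- landscape(c("11", "01", "10", "00"), c(1.0, 0.6, 0.5, 0.3))
  fit <- fit_additive(ls)
  # independent oracle: ordinary least squares via lm() on the same design
  x1 <- as.numeric(substr(ls$genotypes, 1, 1) == "0")
  x2 <- as.numeric(substr(ls$genotypes, 2, 2) == "0")
  y <- ls$fitness - 1.0
  ora <- stats::lm(y ~ 0 + x1 + x2)
  expect_equal(unname(fit$contributions["1:0"]),
               unname(stats::coef(ora)[["x1"]]), tolerance = 1e-10)
  expect_equal(unname(fit$contributions["2:0"]),
               unname(stats::coef(ora)[["x2"]]), tolerance = 1e-10)
  expect_equal(fit$ss_residual, sum(stats::resid(ora)^2), tolerance = 1e-10)
  # closed-form values of that least-squares system
  expect_equal(unname(fit$contributions[c("1:0", "2:0")]),
               c(-1 / 3, -13 / 30), tolerance = 1e-10)
})

test_that("star design (peak plus single mutants) is fitted exactly", {
  ls <- landscape(c("111", "011", "101", "110"), c(1, 0.7, 0.4, 0.9))
  fit <- fit_additive(ls)
  expect_lt(fit$ss_residual, 1e-20)
  expect_equal(unname(fit$contributions[c("1:0", "2:0", "3:0")]),
               c(-0.3, -0.6, -0.1), tolerance = 1e-10)
})

test_that("deviation and variability explained are exact complements", {
  set.seed(21)
  for (rep in 1:5) {
    ls <- random_landscape(4)
    fit <- fit_additive(ls)
    expect_equal(deviation_from_additivity(fit) + variability_explained(fit),
                 1, tolerance = 1e-12)
  }
  expect_error(deviation_from_additivity(cube_landscape(2, 0)), "all-zero")
})

test_that("deviation from additivity is invariant under relabelling", {
  set.seed(31)
  ls <- random_landscape(4, p_keep = 0.9)
  dev <- deviation_from_additivity(ls)
  # permute sites and swap the binary symbols
  perm <- c(3, 1, 4, 2)
  relab <- vapply(strsplit(ls$genotypes, ""), function(ch)
    paste(chartr("01", "10", ch[perm]), collapse = ""), character(1))
  ls2 <- landscape(relab, ls$fitness)
  expect_equal(deviation_from_additivity(ls2), dev, tolerance = 1e-10)
})

test_that("local roughness handles limiting cases and matches brute force", {
  expect_equal(local_roughness(cube_landscape(3, 1)), 0)
  expect_equal(local_roughness(landscape(c("0", "1"), c(0, 1))), 1.0)
  set.seed(41)
  ls <- cube_landscape(3, stats::runif(8))
  expect_equal(local_roughness(ls), bf_local_roughness(ls), tolerance = 1e-12)
  expect_error(local_roughness(landscape(c("00", "11"), c(1, 2))),
               "isolated")
})

test_that("find_peaks: additive has one, constant all, plateaus count", {
  expect_length(find_peaks(additive_cube(4)), 1L)
  expect_identical(find_peaks(cube_landscape(2, 1)),
                   c("00", "01", "10", "11"))
  ls <- landscape(c("00", "01", "10", "11"), c(0.1, 0.4, 0.4, 0.2))
  expect_identical(find_peaks(ls), c("01", "10"))
})

test_that("tree component matches definition and contains the peaks", {
  ls <- additive_cube(3)
  expect_identical(sort(tree_component(ls)),
                   sort(c("111", neighbors(ls, "111"))))
  expect_identical(tree_component(cube_landscape(2, 1)),
                   c("00", "01", "10", "11"))
  set.seed(51)
  for (rep in 1:5) {
    ls <- random_landscape(4, p_keep = 0.85)
    expect_identical(tree_component(ls), bf_tree_component(ls))
    expect_true(all(find_peaks(ls) %in% tree_component(ls)))
  }
})

test_that("mean tree distance: additive 3-cube gives 0.625", {
  ls <- additive_cube(3)
  # tree = peak + its 3 neighbours; remaining: 3 at distance 1, 1 at 2
  expect_equal(mean_tree_distance(ls), (4 * 0 + 3 * 1 + 1 * 2) / 8)
  d <- bf_bfs_distance(ls, tree_component(ls))
  expect_equal(mean_tree_distance(ls), mean(d))
  expect_equal(mean_tree_distance(cube_landscape(3, 1)), 0)
})

test_that("multi-component landscapes are handled by tree distances", {
  # every connected component contains its own fitness maximum, which has
  # no fitter neighbour and is therefore a tree node: distances stay finite
  ls <- landscape(c("0000", "1100", "1101", "1110", "1111"),
                  c(5, 0.1, 0.4, 0.3, 1))
  expect_silent(d <- mean_tree_distance(ls))
  expect_true(all(c("0000", "1111") %in% tree_component(ls)))
  expect_equal(d, 1 / 5)  # only "1100" (two fitter neighbours) is off-tree
})

test_that("roughness_report aggregates consistently", {
  set.seed(61)
  ls <- generate_noisy_additive(4, noise = noise_spec(nu = 1))
  rep <- roughness_report(ls, paths = TRUE)
  expect_equal(rep$peak_fraction, rep$n_peaks / rep$n)
  expect_equal(rep$deviation_from_additivity + rep$variability_explained, 1)
  expect_gte(rep$monotonic_path_fraction, 0)
  expect_lte(rep$monotonic_path_fraction, 1)
  expect_gte(rep$mean_path_divergence, 0)
})
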