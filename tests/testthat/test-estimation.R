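test_that("objective_r2 agrees with an independent lm-based oracle", {
  solv <- hansen_solvents()
  solv <- solv[!solv$name %in% c("water", "isopropanol"), ]
  sw <- c(hexane = 12, `diethyl ether` = 56, chloroform = 175,
          acetone = 49, `ethyl acetate` = 59)
  set.seed(5)
  cands <- rbind(c(19.7, 5.4, 2.5),
                 matrix(runif(15, 2.5, 40), ncol = 3))
  for (k in seq_len(nrow(cands))) {
    expect_equal(objective_r2(cands[k, ], sw, solv),
                 oracle_signed_r2(cands[k, ], unname(sw), solv),
                 tolerance = 1e-10)
  }
})

test_that("objective_r2 scores perfect negative linearity as 1 and rejects positive trends", {
  solv <- toy_solvents()
  truth <- c(18, 6, 4)
  ra <- vapply(1:3, function(i) {
    oracle_ra(truth, c(solv$delta_d[i], solv$delta_p[i], solv$delta_hb[i]))
  }, numeric(1))
  sw_neg <- stats::setNames(150 - 6 * ra, solv$name)
  expect_equal(suppressWarnings(objective_r2(truth, sw_neg, solv)), 1,
               tolerance = 1e-12)
  # flip the trend: same candidate must now score <= 0
  sw_pos <- stats::setNames(10 + 6 * ra, solv$name)
  expect_lte(suppressWarnings(objective_r2(truth, sw_pos, solv)), 0)
})

test_that("objective_r2 validates its inputs", {
  solv <- toy_solvents()
  expect_error(objective_r2(c(18, 6, 4), c(a = 1, b = 2), solv[1:2, ]),
               "at least 3")
  expect_warning(
    objective_r2(c(18, 6, 4), stats::setNames(c(10, 20, 30), solv$name), solv),
    "fewer than 5")
  expect_error(
    suppressWarnings(
      objective_r2(c(18, 6, 4), stats::setNames(c(10, 10, 10), solv$name),
                   solv)),
    "zero variance")
})

test_that("grid search equals an exhaustive brute-force oracle on a 3-solvent toy", {
  solv <- toy_solvents()
  ds <- make_dataset(solv$name, c(120, 60, 35))
  cfg <- estimation_config(lower = 2.5, upper = 20,
                           coarse_step = 0.5, refine_step = 0.1)
  fit <- suppressWarnings(estimate_hsp(ds, solv, cfg))
  oracle <- oracle_grid_search(c(120, 60, 35), solv, 2.5, 20, 0.1)
  expect_equal(fit$r_squared, oracle$score, tolerance = 1e-10)
  expect_equal(as.numeric(fit$hsp), oracle$hsp, tolerance = 1e-9)
})

test_that("noiseless synthetic data is recovered to within the refine step", {
  sim <- generate_dataset(synthetic_config(hsp(18, 6, 4), solvents = 8,
                                           noise_sd = 0, seed = 7))
  fit <- estimate_hsp(sim$dataset, sim$solvents)
  expect_lt(max(abs(as.numeric(fit$hsp) - c(18, 6, 4))), 0.05 + 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_identical(fit$slope_sign, "negative")
})

test_that("adding a constant to all swelling values leaves the fit unchanged", {
  sim <- generate_dataset(synthetic_config(hsp(19.7, 5.4, 2.5), solvents = 6,
                                           noise_sd = 5, seed = 21))
  fit1 <- estimate_hsp(sim$dataset, sim$solvents)
  shifted <- sim$dataset
  shifted$observations$percent_swelling <-
    shifted$observations$percent_swelling + 37
  fit2 <- estimate_hsp(shifted, sim$solvents)
  expect_identical(as.numeric(fit1$hsp), as.numeric(fit2$hsp))
  expect_equal(fit1$r_squared, fit2$r_squared, tolerance = 1e-12)
})

test_that("boundary solutions are flagged and the plateau covers near-ties", {
  solv <- toy_solvents()
  ds <- make_dataset(solv$name, c(120, 60, 35))
  cfg <- estimation_config(lower = 2.5, upper = 20, refine_step = 0.1,
                           plateau_tolerance = 1e-3)
  fit <- suppressWarnings(estimate_hsp(ds, solv, cfg))
  on_bound <- as.numeric(fit$hsp) %in% c(2.5, 20)
  expect_identical(unname(fit$boundary_flags), on_bound)
  expect_gte(nrow(fit$plateau), 1)
  # every plateau member is within tolerance of the optimum
  scores <- vapply(seq_len(nrow(fit$plateau)), function(i) {
    suppressWarnings(objective_r2(fit$plateau[i, ],
                                  stats::setNames(c(120, 60, 35), solv$name),
                                  solv))
  }, numeric(1))
  expect_true(all(scores >= fit$r_squared - 1e-3 - 1e-12))
})

test_that("estimation fails loudly when only positive correlations exist", {
  # solvents on the diagonal beyond the search box, swelling increasing with
  # distance from it: every candidate in the box sees a positive trend
  solv <- data.frame(name = c("near", "mid", "far"),
                     delta_d = c(45, 50, 55), delta_p = c(45, 50, 55),
                     delta_hb = c(45, 50, 55), source = "toy")
  ds <- make_dataset(solv$name, c(10, 50, 100))
  expect_error(suppressWarnings(estimate_hsp(ds, solv)),
               "positively correlated")
})

test_that("per-repetition fitting averages the fitted HSPs, not the data", {
  sim <- generate_dataset(synthetic_config(hsp(18, 6, 4), solvents = 7,
                                           noise_sd = 4, n_replicates = 2,
                                           seed = 13))
  res <- estimate_per_repetition(sim$dataset, sim$solvents)
  expect_length(res$fits, 2)
  manual <- colMeans(rbind(as.numeric(res$fits[[1]]$hsp),
                           as.numeric(res$fits[[2]]$hsp)))
  expect_equal(as.numeric(res$average), manual, tolerance = 1e-12)

  # identical repetitions: average equals the single fit
  one <- make_dataset(sim$solvents$name,
                      sim$dataset$observations$percent_swelling[
                        sim$dataset$observations$replicate == 1])
  both <- rbind(one$observations,
                transform(one$observations, replicate = 2))
  res2 <- estimate_per_repetition(swelling_dataset(both), sim$solvents)
  expect_identical(as.numeric(res2$average),
                   as.numeric(res2$fits[[1]]$hsp))
})

test_that("estimation is deterministic with lexicographic tie-breaking", {
  sim <- generate_dataset(synthetic_config(hsp(19, 5, 3), solvents = 5,
                                           noise_sd = 6, seed = 2))
  f1 <- estimate_hsp(sim$dataset, sim$solvents)
  f2 <- estimate_hsp(sim$dataset, sim$solvents)
  expect_identical(as.numeric(f1$hsp), as.numeric(f2$hsp))
  expect_identical(f1$r_squared, f2$r_squared)
})

test_that("optional multistart refinement never worsens the objective", {
  sim <- generate_dataset(synthetic_config(hsp(19.7, 5.4, 2.5), solvents = 8,
                                           noise_sd = 5, seed = 9))
  base <- estimate_hsp(sim$dataset, sim$solvents)
  cfg <- estimation_config(multistart_count = 3, seed = 4)
  refined <- estimate_hsp(sim$dataset, sim$solvents, cfg)
  expect_gte(refined$r_squared, base$r_squared - 1e-12)
})
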