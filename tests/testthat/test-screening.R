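cutin <- polymer_record("cutin", hsp(19.7, 5.4, 2.5),
                        ro_spec(reference_solvent = "hexane"))

test_that("Ro resolves from a reference solvent or passes through numerically", {
  ro <- resolve_ro(cutin$hsp, cutin$ro)
  expect_equal(ro, sqrt(127.57), tolerance = 1e-12)
  expect_equal(resolve_ro(cutin$hsp, ro_spec(value = 10.7)), 10.7)
  expect_error(resolve_ro(cutin$hsp, ro_spec(reference_solvent = "xylene")),
               "xylene")
  # degenerate: polymer coincides with the reference solvent
  expect_error(resolve_ro(hsp(14.9, 0, 0),
                          ro_spec(reference_solvent = "hexane")),
               "not positive")
})

test_that("summary-level screening reproduces the per-group Ra/RED geometry", {
  rep <- screen_polymer(cutin, food_group_summaries())
  expect_identical(rep$mode, "summary_level")
  rows <- rep$rows
  expect_equal(rows$red, rows$mean_ra / rep$ro_value, tolerance = 1e-12)

  fats <- rows[rows$group == "fats", ]
  expect_equal(fats$mean_ra, sqrt(66.13), tolerance = 1e-12)
  expect_equal(round(fats$red, 2), 0.72)
  expect_identical(fats$verdict, "compatible")

  carbs <- rows[rows$group == "carbohydrates", ]
  expect_equal(carbs$mean_ra, sqrt(491.98), tolerance = 1e-12)
  expect_equal(round(carbs$red, 2), 1.96)
  expect_identical(carbs$verdict, "incompatible")
})

test_that("component-level screening averages per-component Ra within groups", {
  comps <- read_components(hspcompat_example("components_illustrative.csv"))
  rep <- screen_polymer(cutin, comps)
  expect_identical(rep$mode, "component_level")
  # fats by hand: mean of the three per-component distances
  fats <- comps[comps$group == "fats", ]
  ra <- vapply(seq_len(nrow(fats)), function(i) {
    oracle_ra(c(19.7, 5.4, 2.5),
              c(fats$delta_d[i], fats$delta_p[i], fats$delta_hb[i]))
  }, numeric(1))
  row <- rep$rows[rep$rows$group == "fats", ]
  expect_equal(row$mean_ra, mean(ra), tolerance = 1e-12)
  expect_equal(row$sd_ra, sd(ra), tolerance = 1e-12)

  # a polymer identical to a single-component group has Ra = RED = 0
  solo <- data.frame(name = "self", group = "self",
                     delta_d = 19.7, delta_p = 5.4, delta_hb = 2.5)
  rep0 <- screen_polymer(cutin, solo)
  expect_equal(rep0$rows$mean_ra, 0)
  expect_equal(rep0$rows$red, 0)
  expect_identical(rep0$rows$verdict, "compatible")
})

test_that("delta-method sd matches a finite-difference gradient oracle", {
  g <- food_group_summaries()
  p <- as.numeric(cutin$hsp)
  for (i in seq_len(nrow(g))) {
    got <- propagate_uncertainty(g[i, ], cutin$hsp, method = "delta",
                                 ro = 11.29)$sd_ra
    mu <- c(g$mean_d[i], g$mean_p[i], g$mean_hb[i])
    sds <- c(g$sd_d[i], g$sd_p[i], g$sd_hb[i])
    h <- 1e-7
    grad <- vapply(1:3, function(k) {
      up <- mu; up[k] <- up[k] + h
      dn <- mu; dn[k] <- dn[k] - h
      (oracle_ra(p, up) - oracle_ra(p, dn)) / (2 * h)
    }, numeric(1))
    expect_equal(got, sqrt(sum((grad * sds)^2)), tolerance = 1e-6)
  }
  expect_equal(propagate_uncertainty(
    data.frame(mean_d = 16, mean_p = 4, mean_hb = 6,
               sd_d = 0, sd_p = 0, sd_hb = 0),
    cutin$hsp, method = "delta")$sd_ra, 0)
})

test_that("monte-carlo propagation is seeded, reproducible and sane", {
  g <- food_group_summaries()
  fats <- g[g$group == "fats", ]
  mc1 <- propagate_uncertainty(fats, cutin$hsp, method = "monte_carlo",
                               n_draws = 5000, seed = 31)
  mc2 <- propagate_uncertainty(fats, cutin$hsp, method = "monte_carlo",
                               n_draws = 5000, seed = 31)
  expect_identical(mc1$sd_ra, mc2$sd_ra)
  expect_error(propagate_uncertainty(fats, cutin$hsp, method = "monte_carlo",
                                     n_draws = 50), ">= 100")
  # agreement with the delta method at published sd magnitudes (sanity band)
  for (i in seq_len(nrow(g))) {
    de <- propagate_uncertainty(g[i, ], cutin$hsp, method = "delta")$sd_ra
    mc <- propagate_uncertainty(g[i, ], cutin$hsp, method = "monte_carlo",
                                n_draws = 20000, seed = 100 + i)$sd_ra
    expect_lt(abs(mc - de) / de, 0.3)
  }
})

test_that("RED columns scale as 1/Ro", {
  rep1 <- screen_polymer(cutin, food_group_summaries())
  ro2 <- ro_spec(value = 2 * rep1$ro_value)
  rep2 <- screen_polymer(cutin, food_group_summaries(), ro = ro2)
  expect_equal(rep2$rows$red, rep1$rows$red / 2,
               tolerance = 1e-12)
  expect_equal(rep2$rows$sd_red, rep1$rows$sd_red / 2, tolerance = 1e-12)
})

test_that("polymer comparison composes per-polymer screenings and ranks them", {
  pla <- polymer_record("PLA", hsp(17.9, 9.2, 5.9), ro_spec(value = 10.7))
  cmp <- compare_polymers(list(cutin, pla), food_group_summaries())
  expect_identical(names(cmp$reports), c("cutin", "PLA"))
  solo <- compare_polymers(list(cutin), food_group_summaries())
  expect_equal(solo$table$red_cutin,
               screen_polymer(cutin, food_group_summaries())$rows$red,
               tolerance = 1e-12)
  # column equals the polymer's own report
  expect_equal(cmp$table$red_PLA,
               screen_polymer(pla, food_group_summaries())$rows$red,
               tolerance = 1e-12)
  # identical polymers give identical columns
  twin <- polymer_record("twin", cutin$hsp, cutin$ro)
  cmp2 <- compare_polymers(list(cutin, twin), food_group_summaries())
  expect_equal(cmp2$table$red_cutin, cmp2$table$red_twin, tolerance = 1e-12)
  # per-group winner is the argmin of the RED columns
  mat <- cbind(cmp$table$red_cutin, cmp$table$red_PLA)
  expect_identical(cmp$table$lowest_red,
                   c("cutin", "PLA")[apply(mat, 1, which.min)])

  ph <- structure(list(name = "PHB"), class = "polymer_placeholder")
  expect_error(compare_polymers(list(cutin, ph), food_group_summaries()),
               "PHB")
  no_ro <- polymer_record("bare", hsp(17, 5, 5))
  expect_error(compare_polymers(list(cutin, no_ro), food_group_summaries()),
               "bare")
})
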