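test_that("exact bounds obey the closed forms at the boundaries", {
  ci <- exact_binomial_ci(0, 100, method = "clopper-pearson")
  expect_equal(ci[, "low"], c(low = 0))
  expect_equal(unname(ci[, "high"]), 1 - (0.025)^(1 / 100))
  ci <- exact_binomial_ci(100, 100, method = "clopper-pearson")
  expect_equal(unname(ci[, "high"]), 1)
  expect_equal(unname(ci[, "low"]), (0.025)^(1 / 100))
  # mid-p boundary closed forms
  ci <- exact_binomial_ci(0, 100, method = "midp")
  expect_equal(unname(ci[, "low"]), 0)
  expect_equal(unname(ci[, "high"]), 1 - (0.05)^(1 / 100))
  ci <- exact_binomial_ci(100, 100, method = "midp")
  expect_equal(unname(ci[, "low"]), (0.05)^(1 / 100))
  expect_equal(unname(ci[, "high"]), 1)
  expect_error(exact_binomial_ci(5, 4), "x <= n")
  expect_error(exact_binomial_ci(0, 0), "n >= 1")
})

test_that("Clopper-Pearson bounds equal brute-force tail inversion", {
  for (n in c(1, 3, 8)) for (x in 0:n) {
    o <- oracle_cp(x, n)
    ci <- exact_binomial_ci(x, n, method = "clopper-pearson")
    expect_equal(unname(ci[, "low"]), o[1], tolerance = 1e-8)
    expect_equal(unname(ci[, "high"]), o[2], tolerance = 1e-8)
  }
})

test_that("mid-p bounds solve their tail equations and nest inside CP", {
  set.seed(33)
  for (i in 1:60) {
    n <- sample(1:3000, 1); x <- sample(0:n, 1)
    mp <- exact_binomial_ci(x, n, method = "midp")
    cp <- exact_binomial_ci(x, n, method = "clopper-pearson")
    if (x > 0)  # defining equation at the lower bound
      expect_equal(unname(1 - pbinom(x - 1, n, mp[, "low"]) -
                            0.5 * dbinom(x, n, mp[, "low"])),
                   0.025, tolerance = 1e-8)
    if (x < n)
      expect_equal(unname(pbinom(x, n, mp[, "high"]) -
                            0.5 * dbinom(x, n, mp[, "high"])),
                   0.025, tolerance = 1e-8)
    expect_gte(mp[, "low"], cp[, "low"])
    expect_lte(mp[, "high"], cp[, "high"])
  }
})

test_that("published worked example reproduces to four decimals", {
  ci <- exact_binomial_ci(363, 1150)
  expect_equal(round(unname(ci[, "low"]), 4), 0.2893)
  expect_equal(round(unname(ci[, "high"]), 4), 0.3430)
})

test_that("mortality_rate scales, suppresses, and keeps computed values", {
  r <- mortality_rate(595, 745)
  expect_equal(round(r$rate, 1), 798.7)
  expect_false(r$suppressed)
  r0 <- mortality_rate(0, 1000)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)
  r3 <- mortality_rate(3, 1000)
  expect_true(r3$suppressed)
  expect_equal(r3$rate, 3)          # suppression masks display, not values
  expect_true(r3$ci_low <= r3$rate && r3$rate <= r3$ci_high)
})

test_that("rate invariants hold over random inputs (property)", {
  set.seed(9)
  for (i in 1:200) {
    n <- sample(1:5000, 1); x <- sample(0:n, 1)
    r <- mortality_rate(x, n)
    expect_gte(r$rate, 0); expect_lte(r$rate, 1000)
    expect_lte(r$ci_low, r$rate); expect_gte(r$ci_high, r$rate)
  }
})

test_that("crude rates use all registered deaths and survivor denominators", {
  plf <- make_min_plf(linked_ages = c(0, 3, 30, 100),
                      unlinked_ages = c(1, 200), n_births = 1000)
  cr <- crude_rates(plf)
  expect_equal(cr$deaths, c(6L, 3L, 3L))          # infant, neonatal, postneo
  expect_equal(cr$denominator, c(1000L, 1000L, 997L))
  expect_equal(cr$rate[1], 1000 * 6 / 1000)
  expect_equal(cr$rate[3], 1000 * 3 / 997)
  # all-neonatal cohort: post-neonatal rate 0
  plf2 <- make_min_plf(linked_ages = c(0, 1, 2), n_births = 500)
  expect_equal(crude_rates(plf2)$rate[3], 0)
  expect_error(crude_rates(make_min_plf(integer(0), integer(0), 0)),
               "denominator")
})

test_that("attribute-specific rates partition deaths and denominators", {
  run <- small_run()
  plf <- run$plf
  bw <- specific_rates(plf, "birthweight")
  # denominators sum to the live-birth denominator
  expect_equal(sum(bw$denominator), nrow(plf$denominator))
  # numerators sum to in-denominator live-birth links minus exclusions
  still_link <- plf$reclassified$death_id
  in_denom <- plf$linked$birth_id %in% plf$denominator$birth_id &
    !plf$linked$death_id %in% still_link
  expect_equal(sum(bw$deaths) + attr(bw, "excluded"), sum(in_denom))
  expect_true(all(bw$suppressed == (bw$deaths <= 5)))
  # unknown stratifier is a configuration error
  expect_error(specific_rates(plf, "shoe_size"), "stratifier")
})

test_that("restriction predicates and cumulative rows behave", {
  plf <- make_min_plf(linked_ages = c(0, 5), n_births = 100,
                      bw = c(450, rep(c(800, 3000), 49), 800),
                      ga = c(22, rep(c(26, 39), 49), 26))
  cum <- cumulative_rates(plf, "birthweight", c(500, 1000))
  expect_equal(cum$denominator, c(99L, 49L))      # >=500, >=1000
  expect_equal(cum$deaths[1], 1L)                 # the 800 g death
  sp <- specific_rates(plf, "birthweight", restrict = function(v) v >= 500)
  expect_equal(sum(sp$denominator), 99L)
})

test_that("empty bins are emitted as undefined rows, not errors", {
  plf <- make_min_plf(linked_ages = 0L, n_births = 10,
                      bw = rep(3200, 10), ga = rep(39, 10))
  sp <- specific_rates(plf, "birthweight")
  empty <- sp[sp$stratum == "<500", ]
  expect_equal(empty$denominator, 0L)
  expect_true(is.na(empty$rate))
})

test_that("mortality falls monotonically across gestational-age bins", {
  run <- small_run()
  ga <- specific_rates(run$plf, "gestational_age")
  ga <- ga[ga$stratum != "missing" & ga$denominator > 0, ]
  expect_true(all(diff(ga$rate) <= 0))
})

test_that("missing birth attributes are counted in an exclusion line", {
  run <- small_run()
  bw <- specific_rates(run$plf, "birthweight")
  expect_true(attr(bw, "excluded") >= 0)
  expect_true("missing" %in% bw$stratum || attr(bw, "excluded") == 0 ||
                sum(is.na(run$plf$denominator$birthweight_g)) == 0)
})
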