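rec_death <- function(dob = "2010-03-01", place = "H001", sex = "M",
                      postal = "K1H 8L1", id = "D1", enc = "E1") {
  data.frame(death_id = id, encoded_id = enc, dob = as.Date(dob),
             dod = as.Date(dob) + 10, place_of_death = place, sex = sex,
             postal_code = postal, icd10_cause = "P070", age_days = 10,
             stringsAsFactors = FALSE)
}
rec_birth <- function(dob = "2010-03-01", place = "H001", sex = "M",
                      postal = "K1H 8L1", id = "B1", enc = "E1") {
  data.frame(birth_id = id, encoded_id = enc, dob = as.Date(dob), sex = sex,
             place_code = place, postal_code = postal, birthweight_g = 3200,
             ga_weeks = 39, stillbirth_flag = FALSE, orphan_flag = FALSE,
             stringsAsFactors = FALSE)
}

test_that("comparison vectors assign the defined agreement levels", {
  v <- compare_records(rec_death(), rec_birth())
  expect_identical(unlist(v), c(dob = "exact", place = "agree",
                                sex = "agree", postal = "exact"))
  # postal differing after the FSA
  v <- compare_records(rec_death(postal = "K1H 8L1"),
                       rec_birth(postal = "K1H 8L9"))
  expect_identical(v$postal, "fsa")
  # postal differing inside the FSA
  v <- compare_records(rec_death(postal = "K1H 8L1"),
                       rec_birth(postal = "L1H 8L1"))
  expect_identical(v$postal, "disagree")
  # one-day date shift
  v <- compare_records(rec_death(dob = "2010-03-02"), rec_birth())
  expect_identical(v$dob, "pm1")
  v <- compare_records(rec_death(dob = "2010-03-05"), rec_birth())
  expect_identical(v$dob, "disagree")
  # missing is distinct from disagree
  v <- compare_records(rec_death(sex = "U", postal = NA), rec_birth())
  expect_identical(v$sex, "missing")
  expect_identical(v$postal, "missing")
})

test_that("deterministic pass links exact unique identifiers only", {
  deaths <- rbind(rec_death(id = "D1", enc = "E1"),
                  rec_death(id = "D2", enc = NA),
                  rec_death(id = "D3", enc = "E9"))
  ref <- rbind(rec_birth(id = "B1", enc = "E1"),
               rec_birth(id = "B2", enc = "E2"))
  out <- deterministic_link(deaths, ref)
  expect_identical(out$matches$death_id, "D1")
  expect_identical(out$matches$birth_id, "B1")
  expect_identical(out$matches$stage, "deterministic")
  expect_setequal(out$residual_deaths$death_id, c("D2", "D3"))
})

test_that("duplicate identifiers are demoted with a warning", {
  deaths <- rbind(rec_death(id = "D1", enc = "E1"),
                  rec_death(id = "D2", enc = "E1"))
  ref <- rec_birth(id = "B1", enc = "E1")
  expect_warning(out <- deterministic_link(deaths, ref), "duplicate")
  expect_identical(nrow(out$matches), 0L)
  expect_identical(nrow(out$residual_deaths), 2L)
  # ambiguous reference identifier
  deaths <- rec_death(id = "D1", enc = "E1")
  ref <- rbind(rec_birth(id = "B1", enc = "E1"),
               rec_birth(id = "B2", enc = "E1"))
  expect_warning(out <- deterministic_link(deaths, ref), "ambiguous")
  expect_identical(nrow(out$matches), 0L)
})

test_that("deterministic pass recovers the truth map on clean data", {
  run <- small_run()
  input <- corrupt_and_split(run$cohort, no_corruption(), seed = 4L)
  out <- deterministic_link(input$deaths, input$reference)
  tmap <- setNames(input$truth$birth_id, input$truth$death_id)
  expect_identical(nrow(out$residual_deaths), 0L)
  expect_true(all(out$matches$birth_id == tmap[out$matches$death_id]))
  expect_identical(nrow(out$matches), nrow(input$deaths))
})

test_that("blocking returns supersets containing the true record", {
  ref <- do.call(rbind, lapply(1:50, function(i)
    rec_birth(dob = as.character(as.Date("2010-01-01") + i %% 20),
              postal = sprintf("K1%s 8L%d", LETTERS[1 + i %% 6], i %% 10),
              id = sprintf("B%02d", i), enc = sprintf("E%02d", i))))
  d <- rec_death(dob = "2010-01-06", postal = "Z9Z 9Z9")  # corrupted postal
  # scheme none returns the whole file
  expect_identical(nrow(block_candidates(d, ref, "none")), nrow(ref))
  # exact dob + corrupted postal: truth still among dob-based candidates
  cand <- block_candidates(d, ref, "dob_pm1")
  expect_true("B05" %in% cand$birth_id)   # B05 born 2010-01-06
  expect_true(all(abs(as.integer(cand$dob - d$dob)) <= 1))
  # union blocking is never smaller than either single key
  cand_u <- block_candidates(rec_death(dob = "2010-01-06", postal = "K1B 8L3"),
                             ref, "dobyear_fsa")
  year_only <- sum(format(ref$dob, "%Y") == "2010")
  fsa_only <- sum(substr(gsub(" ", "", ref$postal_code), 1, 3) == "K1B")
  expect_gte(nrow(cand_u), max(year_only, fsa_only))
})

test_that("pair weights follow the closed form and the missing convention", {
  m <- list(dob = c(exact = 0.9, pm1 = 0.05, disagree = 0.05),
            place = c(agree = 0.9, disagree = 0.1),
            sex = c(agree = 0.9, disagree = 0.1),
            postal = c(exact = 0.9, fsa = 0.05, disagree = 0.05))
  u <- list(dob = c(exact = 0.1, pm1 = 0.2, disagree = 0.7),
            place = c(agree = 0.1, disagree = 0.9),
            sex = c(agree = 0.1, disagree = 0.9),
            postal = c(exact = 0.1, fsa = 0.2, disagree = 0.7))
  p <- fs_params(m, u, 0.01)
  all_agree <- data.frame(dob = "exact", place = "agree", sex = "agree",
                          postal = "exact")
  expect_equal(score_pairs(all_agree, p), 4 * log2(9))
  all_missing <- data.frame(dob = "missing", place = "missing",
                            sex = "missing", postal = "missing")
  expect_equal(score_pairs(all_missing, p), 0)
  # oracle equality on random vectors
  set.seed(2)
  lv <- list(dob = c("exact", "pm1", "disagree", "missing"),
             place = c("agree", "disagree", "missing"),
             sex = c("agree", "disagree", "missing"),
             postal = c("exact", "fsa", "disagree", "missing"))
  vec <- as.data.frame(lapply(lv, sample, size = 200, replace = TRUE),
                       stringsAsFactors = FALSE)
  w <- score_pairs(vec, p)
  for (i in sample(200, 25))
    expect_equal(w[i], oracle_weight(vec[i, ], p))
})

test_that("fs_params validates level sets, sums and lambda", {
  m <- list(dob = c(exact = 0.5, pm1 = 0.3, disagree = 0.3),  # sums to 1.1
            place = c(agree = 0.9, disagree = 0.1),
            sex = c(agree = 0.9, disagree = 0.1),
            postal = c(exact = 0.9, fsa = 0.05, disagree = 0.05))
  u <- lapply(m, function(v) v / sum(v))
  expect_error(fs_params(m, u, 0.5), "m\\$dob")
  m$dob <- c(exact = 0.5, pm1 = 0.3, disagree = 0.2)
  expect_error(fs_params(m, u, 1), "lambda")
})

test_that("EM log-likelihood is monotone and parameters are recoverable", {
  sim <- simulate_vectors(20000, TRUE_M, TRUE_U, 0.05, seed = 7L)
  fit <- estimate_fs_params(sim$vectors)
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) > -1e-7))
  expect_lt(abs(fit$lambda - 0.05), 0.01)
  expect_lt(abs(fit$m$dob[["exact"]] - TRUE_M$dob[["exact"]]), 0.03)
  expect_lt(abs(fit$u$postal[["disagree"]] - TRUE_U$postal[["disagree"]]), 0.03)
})

test_that("degenerate all-agree input clamps to the boundary with a warning", {
  vec <- data.frame(dob = rep("exact", 50), place = "agree", sex = "agree",
                    postal = "exact", stringsAsFactors = FALSE)
  expect_warning(fit <- estimate_fs_params(vec), "clamp")
  expect_gt(fit$lambda, 0)
  expect_lt(fit$lambda, 1)
})

test_that("classification thresholds and one-to-one assignment behave", {
  # single pair above the upper threshold links
  p1 <- data.frame(death_id = "D1", birth_id = "B1", weight = 15)
  expect_identical(classify_and_assign(p1, 10, 5)$decision, "link")
  # the higher-weight death wins a contested birth; the loser takes its
  # next candidate
  pairs <- data.frame(
    death_id = c("D1", "D2", "D2"),
    birth_id = c("B1", "B1", "B2"),
    weight = c(14, 12, 11), stringsAsFactors = FALSE)
  out <- classify_and_assign(pairs, 10, 5)
  expect_identical(out$decision[out$death_id == "D1" & out$birth_id == "B1"], "link")
  expect_identical(out$decision[out$death_id == "D2" & out$birth_id == "B1"], "possible")
  expect_identical(out$decision[out$death_id == "D2" & out$birth_id == "B2"], "link")
  # between-band pairs are possible, below-band non-links
  p2 <- data.frame(death_id = c("D1", "D2"), birth_id = c("B1", "B2"),
                   weight = c(7, 2))
  out2 <- classify_and_assign(p2, 10, 5)
  expect_identical(out2$decision, c("possible", "non-link"))
})

test_that("assignment never links a birth or death twice (property)", {
  set.seed(42)
  for (rep in 1:20) {
    nd <- sample(3:10, 1); nb <- sample(3:10, 1)
    pairs <- expand.grid(death_id = sprintf("D%d", 1:nd),
                         birth_id = sprintf("B%d", 1:nb),
                         stringsAsFactors = FALSE)
    pairs$weight <- round(rnorm(nrow(pairs), 8, 4), 2)
    out <- classify_and_assign(pairs, 9, 4)
    links <- out[out$decision == "link", ]
    expect_false(any(duplicated(links$death_id)))
    expect_false(any(duplicated(links$birth_id)))
  }
})

test_that("posterior weight thresholds invert the match posterior", {
  m <- TRUE_M; u <- TRUE_U
  p <- fs_params(m, u, 0.01)
  w <- weight_threshold(p, 0.9)
  post <- p$lambda * 2^w / (p$lambda * 2^w + 1 - p$lambda)
  expect_equal(post, 0.9, tolerance = 1e-12)
})

test_that("period linkage conserves deaths and stages do not conflict", {
  run <- small_run()
  plf <- run$plf
  n <- nrow(run$input$deaths)
  expect_identical(nrow(plf$linked) + nrow(plf$unlinked), n)
  expect_false(any(plf$unlinked$death_id %in% plf$linked$death_id))
  links <- plf$pairs[plf$pairs$decision == "link", ]
  expect_false(any(duplicated(links$death_id)))
  expect_false(any(duplicated(links$birth_id)))
  # deterministic links survive the probabilistic pass untouched
  det <- links$death_id[links$stage == "deterministic"]
  expect_true(all(det %in% plf$linked$death_id))
  # denominator excludes stillbirths and is restricted to the death window
  expect_false(any(plf$denominator$stillbirth_flag))
  yrs <- as.integer(format(plf$denominator$dob, "%Y"))
  expect_true(all(yrs >= 2010 & yrs <= 2011))
})

test_that("clean data link completely; edge inputs error or warn", {
  run <- small_run()
  input <- corrupt_and_split(run$cohort, no_corruption(), seed = 6L)
  plf <- run_period_linkage(input$deaths, input$reference,
                            death_years = run$config$death_years)
  expect_identical(nrow(plf$unlinked), 0L)
  expect_equal(plf$summary$prop_linked, 1)
  acc <- linkage_accuracy(plf, input$truth)
  expect_equal(acc$overall$precision, 1)
  expect_equal(acc$overall$recall, 1)
  # empty reference is a hard error
  expect_error(run_period_linkage(input$deaths, input$reference[0, ]),
               "empty reference")
  # deaths outside the period are excluded with a warning
  d2 <- input$deaths
  d2$dod[1] <- as.Date("2031-06-01")
  expect_warning(
    plf2 <- run_period_linkage(d2, input$reference,
                               death_years = run$config$death_years),
    "outside")
  expect_identical(nrow(plf2$linked) + nrow(plf2$unlinked),
                   nrow(input$deaths) - 1L)
})
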