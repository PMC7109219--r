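# Shared fixtures, built in code at test time.

# A small calibrated cohort run shared across tests (lazy, cached).
small_run <- local({
  cache <- NULL
  function(scale = 0.1, seed = 11L) {
    if (is.null(cache)) {
      cc <- default_cohort_config(scale = scale, seed = seed)
      cohort <- generate_cohort(cc)
      input <- corrupt_and_split(cohort, corruption_config(), seed = seed + 1L)
      plf <- suppressWarnings(run_period_linkage(
        input$deaths, input$reference, linkage_config(),
        death_years = cc$death_years))
      cache <<- list(config = cc, cohort = cohort, input = input, plf = plf)
    }
    cache
  }
})

# Minimal hand-built period_linked_file for rate arithmetic tests.
make_min_plf <- function(linked_ages, unlinked_ages = integer(0), n_births,
                         bw = NULL, ga = NULL) {
  nl <- length(linked_ages)
  linked <- data.frame(
    death_id = sprintf("D%03d", seq_len(nl)),
    birth_id = sprintf("B%03d", seq_len(nl)),
    age_days = linked_ages,
    icd10_cause = rep("P070", nl),
    stringsAsFactors = FALSE)
  nu <- length(unlinked_ages)
  unlinked <- data.frame(
    death_id = sprintf("U%03d", seq_len(nu)),
    age_days = unlinked_ages,
    icd10_cause = rep("R95", nu),
    stringsAsFactors = FALSE)
  denominator <- data.frame(
    birth_id = sprintf("B%03d", seq_len(n_births)),
    birthweight_g = if (is.null(bw)) rep(3200, n_births) else bw,
    ga_weeks = if (is.null(ga)) rep(39, n_births) else ga,
    stillbirth_flag = rep(FALSE, n_births), stringsAsFactors = FALSE)
  if (nl > 0) {
    linked$birthweight_g <- denominator$birthweight_g[seq_len(nl)]
    linked$ga_weeks <- denominator$ga_weeks[seq_len(nl)]
  }
  structure(list(
    pairs = data.frame(death_id = linked$death_id, birth_id = linked$birth_id,
                       weight = rep(NA_real_, nl),
                       stage = rep("deterministic", nl),
                       decision = rep("link", nl), stringsAsFactors = FALSE),
    linked = linked, unlinked = unlinked,
    reclassified = data.frame(death_id = character(0), birth_id = character(0)),
    denominator = denominator,
    summary = list(), meta = list(death_years = c(2010L, 2011L))),
    class = "period_linked_file")
}

# Brute-force oracles (independent of the implementation paths they check).
oracle_cp <- function(x, n, alpha = 0.05) {
  lo <- if (x == 0) 0 else
    stats::uniroot(function(p) sum(stats::dbinom(x:n, n, p)) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (x == n) 1 else
    stats::uniroot(function(p) sum(stats::dbinom(0:x, n, p)) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

oracle_U <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

oracle_weight <- function(vec_row, params) {
  w <- 0
  for (f in c("dob", "place", "sex", "postal")) {
    lv <- vec_row[[f]]
    if (lv != "missing")
      w <- w + log2(params$m[[f]][[lv]] / params$u[[f]][[lv]])
  }
  w
}

# Simulate comparison vectors from known Fellegi-Sunter parameters.
simulate_vectors <- function(n, m, u, lambda, seed) {
  set.seed(seed)
  z <- stats::runif(n) < lambda
  out <- list()
  for (f in names(m)) {
    lv <- names(m[[f]])
    v <- character(n)
    v[z] <- sample(lv, sum(z), replace = TRUE, prob = m[[f]])
    v[!z] <- sample(lv, sum(!z), replace = TRUE, prob = u[[f]])
    out[[f]] <- v
  }
  list(vectors = as.data.frame(out, stringsAsFactors = FALSE), z = z)
}

TRUE_M <- list(dob = c(exact = 0.95, pm1 = 0.04, disagree = 0.01),
               place = c(agree = 0.90, disagree = 0.10),
               sex = c(agree = 0.98, disagree = 0.02),
               postal = c(exact = 0.90, fsa = 0.05, disagree = 0.05))
TRUE_U <- list(dob = c(exact = 0.05, pm1 = 0.10, disagree = 0.85),
               place = c(agree = 0.02, disagree = 0.98),
               sex = c(agree = 0.50, disagree = 0.50),
               postal = c(exact = 0.01, fsa = 0.04, disagree = 0.95))
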