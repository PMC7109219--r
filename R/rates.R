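# Mortality-rate engine: crude, neonatal, post-neonatal, attribute-specific
# and stratified infant mortality rates with exact binomial confidence
# intervals and small-numerator suppression.

#' Exact binomial confidence intervals (mid-p and Clopper-Pearson)
#'
#' Two inversions of the exact binomial tails.  `"midp"` (the default, and
#' the variant that reproduces published provincial surveillance tables)
#' solves the mid-p tail equations: the lower bound satisfies
#' `P(X > x) + P(X = x)/2 = alpha/2` and the upper bound
#' `P(X < x) + P(X = x)/2 = alpha/2`, with closed forms `1 - alpha^(1/n)` /
#' `alpha^(1/n)` at the boundaries.  `"clopper-pearson"` is the conservative
#' Beta-quantile inversion: the lower bound is 0 when `x = 0` and otherwise
#' the `alpha/2` quantile of `Beta(x, n - x + 1)`; the upper bound is 1 when
#' `x = n` and otherwise the `1 - alpha/2` quantile of `Beta(x + 1, n - x)`.
#' The mid-p interval is strictly contained in the Clopper-Pearson interval.
#'
#' @param x number of events (vectorised).
#' @param n number of trials, `n >= 1`, `0 <= x <= n`.
#' @param alpha two-sided non-coverage probability (0.05 for a 95% CI).
#' @param method `"midp"` or `"clopper-pearson"`.
#' @return Two-column matrix `low`, `high` on the probability scale.
#' @export
exact_binomial_ci <- function(x, n, alpha = 0.05,
                              method = c("midp", "clopper-pearson")) {
  method <- match.arg(method)
  if (any(n < 1) || any(x < 0) || any(x > n) || any(x != floor(x)))
    stop("exact_binomial_ci: need integer 0 <= x <= n with n >= 1")
  check_prob(alpha, "alpha")
  if (method == "clopper-pearson") {
    low <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
    high <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
    return(cbind(low = low, high = high))
  }
  one <- function(xi, ni) {
    lo <- if (xi == 0) 0 else if (xi == ni) alpha^(1 / ni) else
      stats::uniroot(function(p)
        1 - stats::pbinom(xi - 1, ni, p) - 0.5 * stats::dbinom(xi, ni, p) -
          alpha / 2, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    hi <- if (xi == ni) 1 else if (xi == 0) 1 - alpha^(1 / ni) else
      stats::uniroot(function(p)
        stats::pbinom(xi, ni, p) - 0.5 * stats::dbinom(xi, ni, p) - alpha / 2,
        c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    c(lo, hi)
  }
  xx <- rep_len(x, max(length(x), length(n)))
  nn <- rep_len(n, length(xx))
  out <- t(vapply(seq_along(xx), function(i) one(xx[i], nn[i]), numeric(2)))
  colnames(out) <- c("low", "high")
  out
}

#' Mortality rate with exact CI and suppression flag
#'
#' @param x integer numerator (deaths); vectorised.
#' @param n integer denominator (live births or neonatal survivors).
#' @param scale reporting multiplier (1000 for per-1000 rates).
#' @param alpha CI non-coverage probability.
#' @param suppress_at numerators at or below this value are flagged
#'   suppressed (display masking; the computed values are retained for
#'   audit).  Use `NA` to disable.
#' @param method exact-interval variant, see [exact_binomial_ci()].
#' @return Data frame of class `rate_estimate` with columns `deaths`,
#'   `denominator`, `rate`, `ci_low`, `ci_high` (all on the `scale`
#'   multiplier) and `suppressed`.
#' @export
mortality_rate <- function(x, n, scale = 1000, alpha = 0.05, suppress_at = 5,
                           method = c("midp", "clopper-pearson")) {
  ci <- exact_binomial_ci(x, n, alpha, method = method)
  out <- data.frame(
    deaths = as.integer(x), denominator = as.integer(n),
    rate = scale * x / n,
    ci_low = scale * ci[, "low"], ci_high = scale * ci[, "high"],
    suppressed = if (is.na(suppress_at)) FALSE else x <= suppress_at
  )
  class(out) <- c("rate_estimate", class(out))
  attr(out, "scale") <- scale
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.rate_estimate <- function(x, digits = 1, ...) {
  scale <- attr(x, "scale") %||% 1000
  df <- as.data.frame(x)
  shown <- sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
                   df$rate, df$ci_low, df$ci_high)
  shown[df$suppressed] <- "suppressed"
  df$rate_ci <- shown
  keep <- c(setdiff(names(df), c("rate", "ci_low", "ci_high", "suppressed",
                                 "rate_ci")), "rate_ci")
  cat(sprintf("rates per %s (exact binomial %g%% CI)\n", format(scale),
              100 * (1 - (attr(x, "alpha") %||% 0.05))))
  print.data.frame(df[, keep, drop = FALSE], row.names = FALSE)
  invisible(x)
}

# Deaths counted for the crude numerators: every registered death, linked or
# not (linked-file attributes are only needed for attribute-specific tables).
all_registered_deaths <- function(plf) {
  rbind(plf$linked[, c("death_id", "age_days")],
        plf$unlinked[, c("death_id", "age_days")])
}

#' Crude infant, neonatal and post-neonatal mortality rates
#'
#' The infant numerator counts all registered deaths (linked and unlinked)
#' at 0-364 days; the neonatal numerator, deaths at 0-27 days; both per 1000
#' live births.  The post-neonatal numerator counts deaths at 28-364 days
#' per 1000 neonatal survivors (live births minus neonatal deaths).
#'
#' @param plf a `period_linked_file` from [run_period_linkage()].
#' @param scale reporting multiplier.
#' @param alpha CI non-coverage probability.
#' @return A `rate_estimate` data frame with rows `infant`, `neonatal`,
#'   `postneonatal`.
#' @export
crude_rates <- function(plf, scale = 1000, alpha = 0.05) {
  n_births <- nrow(plf$denominator)
  if (n_births == 0) stop("crude_rates: empty live-birth denominator")
  deaths <- all_registered_deaths(plf)
  x_inf <- nrow(deaths)
  x_neo <- sum(deaths$age_days <= 27)
  x_post <- sum(deaths$age_days >= 28)
  out <- mortality_rate(c(x_inf, x_neo, x_post),
                        c(n_births, n_births, n_births - x_neo),
                        scale = scale, alpha = alpha, suppress_at = NA)
  out <- cbind(measure = c("infant", "neonatal", "postneonatal"), out)
  class(out) <- c("rate_estimate", "data.frame")
  attr(out, "scale") <- scale; attr(out, "alpha") <- alpha
  out
}

#' Attribute-specific and stratified mortality rates
#'
#' One rate per stratum of a linked-birth attribute, using linked deaths in
#' the numerators (links onto stillbirth records are excluded) and the
#' period live-birth denominator.  Numeric stratifiers (`birthweight_g`,
#' `ga_weeks`) are binned with `bins`; categorical stratifiers use their
#' observed levels.  Records with a missing attribute form an explicit
#' `missing` stratum in the denominator; linked deaths with a missing
#' attribute are excluded from the binned numerators and reported in the
#' `excluded` attribute of the result.
#'
#' @param plf a `period_linked_file`.
#' @param by stratifier: one of `"birthweight"`, `"gestational_age"`,
#'   `"maternal_age"`, `"parity"`, `"sex"`, `"plurality"`,
#'   `"income_quintile"`, `"region"`, `"rurality"`.
#' @param bins bin data frame (`label`, `lo`, `hi`) for the numeric
#'   stratifiers; defaults to the shipped calibration bins.
#' @param restrict optional predicate on the attribute values (for example
#'   `function(bw) bw >= 500` for the >= 500 g restriction); applied to
#'   numerator and denominator alike, with missing values dropped.
#' @param scale,alpha,suppress_at as in [mortality_rate()].
#' @return A `rate_estimate` data frame with one row per stratum and
#'   attributes `excluded` (count of linked deaths left out for missing
#'   information) and `stratifier`.
#' @export
specific_rates <- function(plf, by, bins = NULL, restrict = NULL,
                           scale = 1000, alpha = 0.05, suppress_at = 5) {
  cols <- c(birthweight = "birthweight_g", gestational_age = "ga_weeks",
            maternal_age = "maternal_age", parity = "parity",
            sex = "sex", plurality = "plurality",
            income_quintile = "income_quintile", region = "region",
            rurality = "rural")
  if (!by %in% names(cols))
    fail_cfg("by", sprintf("unknown stratifier; use one of: %s",
                           paste(names(cols), collapse = ", ")))
  col <- cols[[by]]
  linked <- plf$linked
  linked <- linked[!linked$birth_id %in%
                     plf$reclassified$birth_id, , drop = FALSE]
  denom <- plf$denominator
  if (!col %in% names(denom))
    fail_cfg("by", sprintf("attribute `%s` absent from the linked file schema", col))
  # the linked death's attribute comes from its birth record; deaths linked
  # to out-of-period births fall outside the denominator and its strata
  linked <- linked[linked$birth_id %in% denom$birth_id, , drop = FALSE]
  num_col <- if (by == "sex" && "sex_birth" %in% names(linked)) "sex_birth" else col
  num_attr <- linked[[num_col]]
  den_attr <- denom[[col]]

  if (!is.null(restrict)) {
    keep_n <- !is.na(num_attr) & restrict(num_attr)
    keep_d <- !is.na(den_attr) & restrict(den_attr)
    linked <- linked[keep_n, , drop = FALSE]; num_attr <- num_attr[keep_n]
    denom <- denom[keep_d, , drop = FALSE]; den_attr <- den_attr[keep_d]
  }

  numeric_strat <- by %in% c("birthweight", "gestational_age")
  if (numeric_strat) {
    if (is.null(bins))
      bins <- if (by == "birthweight") default_bw_bins() else default_ga_bins()
    brk <- c(-Inf, bins$hi)
    cut_bin <- function(v) as.character(cut(v, breaks = brk, labels = bins$label,
                                            include.lowest = TRUE, right = TRUE))
    num_bin <- cut_bin(num_attr); den_bin <- cut_bin(den_attr)
    labels <- bins$label
  } else {
    num_bin <- as.character(num_attr); den_bin <- as.character(den_attr)
    labels <- sort(unique(stats::na.omit(den_bin)))
  }
  excluded <- sum(is.na(num_bin))
  if (any(is.na(den_bin))) labels <- c(labels, "missing")
  den_bin[is.na(den_bin)] <- "missing"
  num_bin[is.na(num_bin)] <- "missing"

  x <- as.integer(table(factor(num_bin, levels = labels)))
  n <- as.integer(table(factor(den_bin, levels = labels)))
  res <- data.frame(stratum = labels, deaths = x, denominator = n,
                    rate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    suppressed = FALSE)
  ok <- n > 0
  if (any(ok)) {
    mr <- mortality_rate(x[ok], n[ok], scale = scale, alpha = alpha,
                         suppress_at = suppress_at)
    res$rate[ok] <- mr$rate; res$ci_low[ok] <- mr$ci_low
    res$ci_high[ok] <- mr$ci_high; res$suppressed[ok] <- mr$suppressed
  }
  class(res) <- c("rate_estimate", "data.frame")
  attr(res, "scale") <- scale; attr(res, "alpha") <- alpha
  attr(res, "excluded") <- excluded
  attr(res, "stratifier") <- by
  res
}

#' Cumulative restricted rates (for example births >= 500 g)
#'
#' @param plf a `period_linked_file`.
#' @param by `"birthweight"` or `"gestational_age"`.
#' @param thresholds lower cutoffs; one row is produced per cutoff using all
#'   births at or above it.
#' @param scale,alpha,suppress_at as in [mortality_rate()].
#' @return A `rate_estimate` data frame, one row per threshold.
#' @export
cumulative_rates <- function(plf, by = "birthweight",
                             thresholds = c(500, 1000), scale = 1000,
                             alpha = 0.05, suppress_at = 5) {
  col <- if (by == "birthweight") "birthweight_g" else "ga_weeks"
  linked <- plf$linked[!plf$linked$birth_id %in%
                         plf$reclassified$birth_id, , drop = FALSE]
  linked <- linked[linked$birth_id %in% plf$denominator$birth_id, , drop = FALSE]
  xs <- vapply(thresholds, function(t)
    sum(linked[[col]] >= t, na.rm = TRUE), numeric(1))
  ns <- vapply(thresholds, function(t)
    sum(plf$denominator[[col]] >= t, na.rm = TRUE), numeric(1))
  out <- mortality_rate(xs, ns, scale = scale, alpha = alpha,
                        suppress_at = suppress_at)
  out <- cbind(stratum = sprintf(">=%g", thresholds), out)
  class(out) <- c("rate_estimate", "data.frame")
  attr(out, "scale") <- scale; attr(out, "alpha") <- alpha
  out
}

#' Default birthweight and gestational-age bins
#'
#' The bin edges of the shipped cohort calibration (grams / completed
#' weeks), used by [specific_rates()] when no bins are supplied.
#' @return Data frame with `label`, `lo`, `hi`.
#' @export
default_bw_bins <- function() {
  cfg <- default_cohort_config(scale = 0.001)
  cfg$bw_bins[, c("label", "lo", "hi")]
}

#' @rdname default_bw_bins
#' @export
default_ga_bins <- function() {
  cfg <- default_cohort_config(scale = 0.001)
  cfg$ga_bins[, c("label", "lo", "hi")]
}
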