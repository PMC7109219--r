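# Linked-vs-unlinked comparison: characteristic proportions, medians/IQRs,
# chi-square and Mann-Whitney tests.

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic `sum((O - E)^2 / E)` with expected counts from the
#' margins, `df = (r - 1)(c - 1)` and the upper-tail chi-square p-value; no
#' continuity correction.
#'
#' @param table integer matrix of counts, at least 2 x 2, non-negative,
#'   with no zero row or column margin.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("chi_square: need at least 2 rows and 2 columns")
  if (any(table < 0) || any(table != floor(table)))
    stop("chi_square: counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi_square: zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U statistic from midrank-tied rank sums (equivalently the count of pairs
#' `a_i > b_j` plus half the ties) and a two-sided p-value from the normal
#' approximation with tie-corrected variance.  When every value in both
#' samples is identical the test carries no information and `p = 1`.
#'
#' @param a,b non-empty numeric samples.
#' @return List with `U` and `p_value`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1L)
    return(list(U = length(a) * length(b) / 2, p_value = 1))
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = FALSE))
  p <- ht$p.value
  if (is.na(p)) p <- 1
  list(U = unname(ht$statistic), p_value = p)
}

fmt_p <- function(p) {
  ifelse(is.na(p), "-", ifelse(p < 0.001, "< 0.001", sprintf("%.2f", p)))
}

count_pct_rows <- function(char, lk, ul, values, labels = values) {
  out <- NULL
  for (i in seq_along(values)) {
    nl <- sum(lk == values[i], na.rm = TRUE)
    nu <- sum(ul == values[i], na.rm = TRUE)
    out <- rbind(out, data.frame(
      characteristic = char, level = labels[i],
      unlinked_n = nu,
      unlinked_pct = if (length(ul)) 100 * nu / length(ul) else NA_real_,
      linked_n = nl,
      linked_pct = if (length(lk)) 100 * nl / length(lk) else NA_real_))
  }
  out
}

#' Characteristics of linked versus unlinked death records
#'
#' Replicates the standard linkage-quality comparison: calendar year of
#' death, median (IQR) age at death, death within 24 hours, early neonatal
#' (0-6 days), neonatal (0-27 days), post-neonatal (28-364 days) and
#' location of death (hospital versus other), each with counts, column
#' percentages and a test p-value (chi-square for categorical rows,
#' Mann-Whitney for age at death).  Quartiles use linear interpolation on
#' the sorted values (`stats::quantile` type 7).  With an empty group the
#' table is still emitted, tests skipped, with a warning.
#'
#' @param linked,unlinked death registration data frames (need `dod`,
#'   `age_days`, `place_of_death`).
#' @return Data frame of class `characteristics_table`; each
#'   characteristic's first row carries its `p_value` (`NA` on further
#'   levels), with formatted display via `print()`.
#' @export
characteristics_table <- function(linked, unlinked) {
  skip_tests <- nrow(linked) == 0 || nrow(unlinked) == 0
  if (skip_tests)
    warning("empty linked or unlinked group; tests skipped")
  lk_year <- format(as.Date(linked$dod), "%Y")
  ul_year <- format(as.Date(unlinked$dod), "%Y")
  years <- sort(unique(c(lk_year, ul_year)))

  tab <- count_pct_rows("calendar_year", lk_year, ul_year, years)
  test_of <- function(lkv, ulv) {
    if (skip_tests) return(NA_real_)
    m <- rbind(table(factor(ulv, c(FALSE, TRUE))),
               table(factor(lkv, c(FALSE, TRUE))))
    if (any(colSums(m) == 0)) return(NA_real_)
    chi_square(m)$p_value
  }
  p_year <- if (skip_tests || length(years) < 2) NA_real_ else {
    chi_square(rbind(table(factor(ul_year, years)),
                     table(factor(lk_year, years))))$p_value
  }
  tab$p_value <- c(p_year, rep(NA_real_, nrow(tab) - 1))

  qs <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  lq <- if (nrow(linked)) qs(linked$age_days) else rep(NA_real_, 3)
  uq <- if (nrow(unlinked)) qs(unlinked$age_days) else rep(NA_real_, 3)
  p_age <- if (skip_tests) NA_real_ else
    mann_whitney(unlinked$age_days, linked$age_days)$p_value
  age_row <- data.frame(
    characteristic = "median_age_days", level = "median (IQR)",
    unlinked_n = uq[1], unlinked_pct = NA_real_,
    linked_n = lq[1], linked_pct = NA_real_, p_value = p_age)
  iqr_row <- data.frame(
    characteristic = "median_age_days", level = "IQR",
    unlinked_n = uq[2], unlinked_pct = uq[3],
    linked_n = lq[2], linked_pct = lq[3], p_value = NA_real_)

  timing <- list(
    death_within_24h = function(a) a < 1,
    early_neonatal_0_6 = function(a) a <= 6,
    neonatal_0_27 = function(a) a <= 27,
    postneonatal_28_364 = function(a) a >= 28)
  trows <- NULL
  for (nm in names(timing)) {
    lkv <- timing[[nm]](linked$age_days)
    ulv <- timing[[nm]](unlinked$age_days)
    r <- count_pct_rows(nm, lkv, ulv, c(FALSE, TRUE), c("no", "yes"))
    r$p_value <- c(test_of(lkv, ulv), NA_real_)
    trows <- rbind(trows, r)
  }

  lk_hosp <- linked$place_of_death != "OTH"
  ul_hosp <- unlinked$place_of_death != "OTH"
  loc <- count_pct_rows("location_of_death", lk_hosp, ul_hosp,
                        c(TRUE, FALSE), c("hospital", "other"))
  loc$p_value <- c(test_of(lk_hosp, ul_hosp), NA_real_)

  out <- rbind(tab, age_row, iqr_row, trows, loc)
  rownames(out) <- NULL
  class(out) <- c("characteristics_table", "data.frame")
  attr(out, "n_linked") <- nrow(linked)
  attr(out, "n_unlinked") <- nrow(unlinked)
  out
}

#' @export
print.characteristics_table <- function(x, ...) {
  cat(sprintf("Characteristics of unlinked (n = %d) and linked (n = %d) infant death records\n",
              attr(x, "n_unlinked"), attr(x, "n_linked")))
  df <- as.data.frame(x)
  df$p <- fmt_p(df$p_value); df$p_value <- NULL
  df$unlinked_pct <- ifelse(is.na(df$unlinked_pct), "",
                            sprintf("(%.1f)", df$unlinked_pct))
  df$linked_pct <- ifelse(is.na(df$linked_pct), "",
                          sprintf("(%.1f)", df$linked_pct))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
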