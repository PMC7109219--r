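# ICD-10 underlying-cause grouping (modified ICE groups) and cause-specific
# infant mortality rates over all registered deaths.

ICD10_PATTERN <- "^[A-Z][0-9]{2}[0-9A-Z]{0,2}$"

#' Cause-of-death grouping by ICD-10 code prefix
#'
#' An ordered list of (group label, ICD-10 code prefixes) with a fallback
#' group for valid codes matching no prefix.  Prefix sets must be pairwise
#' disjoint (no prefix may extend a prefix of another group), so every valid
#' code maps to exactly one group regardless of entry order.
#'
#' @param groups named list: group label -> character vector of prefixes.
#' @param fallback label for unmatched valid codes.
#' @return Object of class `ice_mapping`.
#' @export
ice_mapping <- function(groups, fallback = "other") {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  all_pref <- unlist(lapply(names(groups), function(g)
    stats::setNames(groups[[g]], rep(g, length(groups[[g]])))))
  for (i in seq_along(all_pref)) for (j in seq_along(all_pref)) {
    if (i != j && names(all_pref)[i] != names(all_pref)[j] &&
        startsWith(all_pref[[j]], all_pref[[i]]))
      fail_cfg("groups", sprintf(
        "prefixes not disjoint across groups: '%s' (%s) covers '%s' (%s)",
        all_pref[[i]], names(all_pref)[i], all_pref[[j]], names(all_pref)[j]))
  }
  structure(list(groups = groups, fallback = fallback), class = "ice_mapping")
}

#' Shipped modified-ICE cause grouping
#'
#' Loads the packaged approximation of the modified International
#' Collaborative Effort infant cause-of-death groups (immaturity-related,
#' congenital anomalies, asphyxia, infection, SIDS, external, other).  The
#' exact published code boundaries of surveillance programmes are not
#' public; this list is reference data and can be replaced via `path`.
#'
#' @param path optional path to an alternative YAML grouping.
#' @return An `ice_mapping`.
#' @export
default_ice_mapping <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ice_groups.yaml",
                                package = "vitalink", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  groups <- stats::setNames(
    lapply(y$groups, function(g) as.character(g$prefixes)),
    vapply(y$groups, `[[`, character(1), "label"))
  ice_mapping(groups, fallback = y$fallback %||% "other")
}

#' Assign ICD-10 codes to cause groups
#'
#' Longest-prefix match against the mapping; valid codes matching no prefix
#' fall into the fallback group; lexically malformed codes are labelled
#' `"unclassifiable"` with a message.
#'
#' @param icd10 character vector of ICD-10 codes (letter, two digits,
#'   optional subcode; dots are stripped).
#' @param mapping an [ice_mapping()].
#' @return Character vector of group labels.
#' @export
assign_cause_group <- function(icd10, mapping = default_ice_mapping()) {
  stopifnot(inherits(mapping, "ice_mapping"))
  code <- toupper(gsub("\\.", "", trimws(as.character(icd10))))
  bad <- is.na(code) | !grepl(ICD10_PATTERN, code)
  if (any(bad))
    message(sprintf("%d malformed ICD-10 code(s) marked unclassifiable", sum(bad)))
  out <- rep(mapping$fallback, length(code))
  best_len <- rep(0L, length(code))
  for (g in names(mapping$groups)) {
    for (p in mapping$groups[[g]]) {
      hit <- !bad & startsWith(code, p) & nchar(p) > best_len
      out[hit] <- g
      best_len[hit] <- nchar(p)
    }
  }
  out[bad] <- "unclassifiable"
  out
}

#' Cause-specific infant mortality rates
#'
#' One rate per cause group, per 1000 live births, computed over all
#' registered deaths (linked and unlinked); groups with numerators at or
#' below the suppression cutoff are flagged.
#'
#' @param deaths death registration data frame with an `icd10_cause`
#'   column, or a `period_linked_file` (all registered deaths are used).
#' @param denominator_n live-birth denominator count; taken from the period
#'   linked file when one is supplied.
#' @param mapping an [ice_mapping()].
#' @param scale,alpha,suppress_at as in [mortality_rate()].
#' @return A `rate_estimate` data frame, one row per group (groups with no
#'   deaths included with zero numerators).
#' @export
cause_specific_rates <- function(deaths, denominator_n = NULL,
                                 mapping = default_ice_mapping(),
                                 scale = 1000, alpha = 0.05, suppress_at = 5) {
  if (inherits(deaths, "period_linked_file")) {
    plf <- deaths
    if (is.null(denominator_n)) denominator_n <- nrow(plf$denominator)
    deaths <- rbind(plf$linked[, c("death_id", "icd10_cause")],
                    plf$unlinked[, c("death_id", "icd10_cause")])
  }
  if (is.null(denominator_n) || denominator_n < 1)
    stop("cause_specific_rates: live-birth denominator must be positive")
  grp <- assign_cause_group(deaths$icd10_cause, mapping)
  labels <- c(names(mapping$groups), mapping$fallback)
  if (any(grp == "unclassifiable")) labels <- c(labels, "unclassifiable")
  x <- as.integer(table(factor(grp, levels = labels)))
  out <- mortality_rate(x, rep(as.integer(denominator_n), length(x)),
                        scale = scale, alpha = alpha, suppress_at = suppress_at)
  out <- cbind(group = labels, out)
  out <- out[order(-out$rate, out$group), ]
  rownames(out) <- NULL
  class(out) <- c("rate_estimate", "data.frame")
  attr(out, "scale") <- scale; attr(out, "alpha") <- alpha
  out
}
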