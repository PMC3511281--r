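#' Tabulate response categories by group
#'
#' Builds the contingency table of response categories (`NONE`, `INCREASE`,
#' `DECREASE`, `COMBINATION`) by group (region or striatal cell class)
#' together with row percentages rounded half-up to one decimal, the format
#' used for population summaries.
#'
#' @param results data.frame with columns `group` and `category` (one row per
#'   analyzed unit; an optional `unit_id` column is checked for duplicates).
#' @return object of class `"cohort_summary"`: list with `table` (counts),
#'   `percentages` (row percentages, 1 decimal) and `n` (row totals).
#' @export
#' @examples
#' res <- data.frame(group = "GPe",
#'                   category = rep(c("NONE", "INCREASE"), c(78, 2)))
#' tabulate_responses(res)$percentages
tabulate_responses <- function(results) {
  stopifnot(is.data.frame(results), all(c("group", "category") %in% names(results)))
  if ("unit_id" %in% names(results) && anyDuplicated(results$unit_id)) {
    stop_invalid("duplicate unit ids in results")
  }
  cat <- factor(as.character(results$category), levels = response_levels())
  if (anyNA(cat)) stop_invalid("unknown response categories present")
  grp <- factor(results$group, levels = unique(results$group))
  tab <- table(group = grp, category = cat)
  n <- rowSums(tab)
  pct <- round_half_up(100 * sweep(unclass(tab), 1, pmax(n, 1), "/"), 1)
  structure(list(table = tab, percentages = pct, n = n),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  tb <- unclass(x$table)
  out <- matrix(sprintf("%d (%s)", tb, format(x$percentages, trim = TRUE)),
                nrow = nrow(tb), dimnames = dimnames(tb))
  print(out, quote = FALSE)
  invisible(x)
}

#' Histogram of responding units by distance to the injection site
#'
#' Counts units with a non-`NONE` response category per 1 mm distance bin
#' `[k, k+1)`, describing how far from the nearest viral injection site
#' light-responsive units are found.
#'
#' @param results data.frame with columns `category` and `distance_mm`.
#' @param bin_width_mm distance bin width, mm.
#' @return data.frame with `bin_lo`, `bin_hi` (mm) and `n_responders`; empty
#'   when there are no responders.
#' @export
responders_by_distance <- function(results, bin_width_mm = 1) {
  stopifnot(is.data.frame(results),
            all(c("category", "distance_mm") %in% names(results)))
  resp <- results[as.character(results$category) != "NONE", , drop = FALSE]
  if (anyNA(resp$distance_mm)) {
    warning(sum(is.na(resp$distance_mm)),
            " responding unit(s) without distance excluded", call. = FALSE)
    resp <- resp[!is.na(resp$distance_mm), , drop = FALSE]
  }
  if (!nrow(resp)) {
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      n_responders = integer()))
  }
  b <- floor(resp$distance_mm / bin_width_mm)
  bins <- seq(0, max(b))
  data.frame(bin_lo = bins * bin_width_mm, bin_hi = (bins + 1) * bin_width_mm,
             n_responders = as.integer(tabulate(b + 1, nbins = max(b) + 1)))
}

#' Mann-Whitney comparison of response magnitudes
#'
#' Two-sided Mann-Whitney U test comparing fold-change magnitudes between two
#' groups of units (e.g. regions). For combined sample sizes up to
#' `exact_max_n` the p-value is exact, computed by complete enumeration of all
#' group assignments of the pooled values (ties handled by mid-ranks); larger
#' samples use the tie-corrected normal approximation without continuity
#' correction.
#'
#' @param group_a,group_b numeric vectors of magnitudes (non-empty).
#' @param exact_max_n largest combined n for which the exact enumeration is
#'   used.
#' @return object of class `"group_comparison"`: list with `statistic` (U of
#'   `group_a`), `p_value`, `group_sizes`, `method`.
#' @export
#' @examples
#' compare_magnitudes(c(1, 2, 3), c(10, 20, 30))$p_value  # exact 0.1
compare_magnitudes <- function(group_a, group_b, exact_max_n = 20) {
  if (!length(group_a) || !length(group_b)) stop_invalid("both groups must be non-empty")
  n1 <- length(group_a)
  n2 <- length(group_b)
  N <- n1 + n2
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (N <= exact_max_n) {
    idx <- utils::combn(N, n1)
    Uall <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    tie <- table(r)
    s2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    p <- if (s2 <= 0) 1 else min(1, 2 * stats::pnorm(-abs((U - mu) / sqrt(s2))))
    method <- "normal approximation, tie-corrected"
  }
  structure(list(statistic = U, p_value = p, group_sizes = c(n1, n2),
                 method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Mann-Whitney U = %.4g, p = %.4g (%s; n = %d vs %d)\n",
              x$statistic, x$p_value, x$method, x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

#' Percentage from a count pair
#'
#' `100 * numerator / denominator`, rounded half-up at the requested
#' precision, for the simple count-to-percentage tabulations of cohort
#' reporting.
#'
#' @param numerator,denominator non-negative counts with
#'   `numerator <= denominator`, `denominator > 0`.
#' @param digits decimal places of the reported percentage (0 or 1 in common
#'   use).
#' @return the percentage as a numeric scalar.
#' @export
#' @examples
#' proportion_from_counts(39, 110)      # 35
#' proportion_from_counts(29, 92, 1)    # 31.5
proportion_from_counts <- function(numerator, denominator, digits = 0) {
  if (length(numerator) != 1 || length(denominator) != 1 ||
      is.na(numerator) || is.na(denominator) ||
      numerator < 0 || denominator <= 0 || numerator > denominator) {
    stop_invalid("need 0 <= numerator <= denominator with denominator > 0")
  }
  round_half_up(100 * numerator / denominator, digits)
}
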