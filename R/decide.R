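#' Classify assignment confidence
#'
#' An incursive is WELL_ASSIGNED iff all three criteria hold:
#' (i) its cluster assignment is consistent across the whole K range,
#' (ii) the cluster assignment at the top K equals the population with
#' the highest posterior probability, and (iii) the relative probability
#' strictly exceeds `rp_threshold`. Otherwise it is POORLY_ASSIGNED and
#' the failed criteria are listed.
#'
#' @param consistent Logical, from [consistency_across_k()].
#' @param dapc_assignment Final-K cluster assignment (population label
#'   or `NA`).
#' @param svm_assignment Population with the highest posterior.
#' @param relative_prob Relative probability (top / second posterior).
#' @param rp_threshold Strict lower bound for criterion (iii); default 2.
#' @return A list: `confidence` (`"WELL_ASSIGNED"` or
#'   `"POORLY_ASSIGNED"`) and `reasons` (character vector of failed
#'   criteria, empty when well-assigned).
#' @export
classify_confidence <- function(consistent, dapc_assignment,
                                svm_assignment, relative_prob,
                                rp_threshold = 2) {
  reasons <- character()
  if (!isTRUE(consistent)) {
    reasons <- c(reasons, "inconsistent_across_k")
  }
  agree <- !is.na(dapc_assignment) && !is.na(svm_assignment) &&
    dapc_assignment == svm_assignment
  if (!agree) reasons <- c(reasons, "methods_disagree")
  if (is.na(relative_prob) || !(relative_prob > rp_threshold)) {
    reasons <- c(reasons, "relative_probability_low")
  }
  list(
    confidence = if (length(reasons)) "POORLY_ASSIGNED" else
      "WELL_ASSIGNED",
    reasons = reasons
  )
}

#' Posterior-vs-missingness diagnostic regression
#'
#' Ordinary least squares of the top posterior probability on the
#' missing-data fraction, fit separately within each confidence group.
#' A strong negative slope among well-assigned incursives indicates that
#' their lower posteriors are driven by missing data; its absence in the
#' poorly-assigned group is the signature of unsampled source
#' populations.
#'
#' @param records A data frame with columns `posterior_top`,
#'   `missingness` and `confidence` (each group needs at least 3 rows).
#' @return A tibble per group: `confidence`, `n`, `slope`, `r_squared`,
#'   `f_statistic`, `df`, `p_value`.
#' @export
missingness_regression <- function(records) {
  records |>
    dplyr::group_by(.data$confidence) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) stop("fewer than 3 records in group ", key[[1]])
      if (stats::sd(d$missingness) == 0) {
        stop("constant missingness in group ", key[[1]])
      }
      fit <- stats::lm(posterior_top ~ missingness, data = d)
      s <- summary(fit)
      tibble::tibble(
        n = nrow(d),
        slope = unname(stats::coef(fit)[2]),
        r_squared = s$r.squared,
        f_statistic = unname(s$fstatistic[1]),
        df = unname(s$fstatistic[3]),
        p_value = stats::pf(s$fstatistic[1], s$fstatistic[2],
                            s$fstatistic[3], lower.tail = FALSE)
      )
    }) |>
    dplyr::ungroup()
}

#' Summarize an assignment report
#'
#' Counts and percentages by confidence class, by source population
#' (among all incursives and among well-assigned separately), and by
#' resistance class when present.
#'
#' @param report A tibble with columns `confidence`, `final_assignment`
#'   and optionally `resistance_class`.
#' @return A tibble: `section`, `category`, `n`, `pct` (percent of the
#'   section's denominator, 1 decimal).
#' @export
summarize_assignments <- function(report) {
  if (nrow(report) == 0) {
    return(tibble::tibble(section = character(), category = character(),
                          n = integer(), pct = numeric()))
  }
  pct <- function(n, d) round(100 * n / d, 1)
  section <- function(values, name, denom = length(values)) {
    tab <- table(values, useNA = "no")
    tibble::tibble(section = name, category = names(tab),
                   n = as.integer(tab), pct = pct(as.integer(tab), denom))
  }
  out <- list(section(report$confidence, "confidence"))
  well <- dplyr::filter(report, .data$confidence == "WELL_ASSIGNED")
  out <- c(out, list(
    section(report$final_assignment, "source_all", nrow(report)),
    section(well$final_assignment, "source_well_assigned", nrow(well))
  ))
  if ("resistance_class" %in% names(report)) {
    out <- c(out, list(section(report$resistance_class, "resistance")))
  }
  dplyr::bind_rows(out)
}
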