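#' Sample panel: reference samples plus incursives
#'
#' A `sample_panel` partitions the individuals of a genotype matrix into
#' labelled reference samples (collections from known locations, the raw
#' material of reference populations) and unlabelled incursives whose
#' source is to be inferred. Optional per-sample metadata (collection
#' location, date, terminal, a three-locus Vssc genotype string) travels
#' with it.
#'
#' @param reference A data frame with columns `id` and `label` (one row per
#'   reference individual), or a named list of character id vectors.
#' @param incursives Character vector of incursive sample ids.
#' @param metadata Optional tibble keyed by `id` with extra per-sample
#'   columns (e.g. `location`, `date`, `vssc`).
#'
#' @return An object of class `sample_panel` with elements `reference`
#'   (tibble id/label), `incursives` and `metadata`.
#' @export
sample_panel <- function(reference, incursives = character(),
                         metadata = NULL) {
  if (is.list(reference) && !is.data.frame(reference)) {
    reference <- tibble::tibble(
      label = rep(names(reference), lengths(reference)),
      id = unlist(reference, use.names = FALSE)
    )
  }
  reference <- tibble::as_tibble(reference)[, c("id", "label")]
  if (anyDuplicated(c(reference$id, incursives))) {
    stop("duplicate sample ids in panel")
  }
  if (any(is.na(reference$label) | reference$label == "")) {
    stop("every reference individual needs a non-empty population label")
  }
  if (is.null(metadata)) metadata <- tibble::tibble(id = character())
  structure(
    list(reference = reference, incursives = as.character(incursives),
         metadata = tibble::as_tibble(metadata)),
    class = "sample_panel"
  )
}

#' @export
print.sample_panel <- function(x, ...) {
  cat(sprintf(
    "<sample_panel> %d reference individuals in %d samples; %d incursives\n",
    nrow(x$reference), dplyr::n_distinct(x$reference$label),
    length(x$incursives)))
  invisible(x)
}

#' Reference labels of a panel
#' @param panel A `sample_panel`.
#' @return Character vector of distinct reference sample labels.
#' @export
panel_labels <- function(panel) unique(panel$reference$label)

#' Ids belonging to one reference sample
#' @param panel A `sample_panel`.
#' @param label A reference sample label.
#' @return Character vector of ids.
#' @export
panel_ids <- function(panel, label) {
  panel$reference$id[panel$reference$label == label]
}

#' Reference samples as a named list of id vectors
#' @param panel A `sample_panel`.
#' @return Named list, one character vector per reference label.
#' @export
panel_groups <- function(panel) {
  split(panel$reference$id, panel$reference$label)
}

#' Check a panel against a genotype matrix
#'
#' Warns about panel ids absent from the matrix and returns the panel
#' restricted to ids that are present.
#'
#' @param panel A `sample_panel`.
#' @param gm A `geno_matrix`.
#' @return The panel with unknown ids dropped (with a warning naming them).
#' @export
validate_panel <- function(panel, gm) {
  known <- sample_ids(gm)
  orphans <- setdiff(c(panel$reference$id, panel$incursives), known)
  if (length(orphans)) {
    warning("panel ids absent from genotype matrix: ",
            paste(orphans, collapse = ", "))
  }
  sample_panel(
    reference = dplyr::filter(panel$reference, .data$id %in% known),
    incursives = intersect(panel$incursives, known),
    metadata = panel$metadata
  )
}

#' Restrict a panel to a subset of ids
#' @param panel A `sample_panel`.
#' @param keep Ids to retain.
#' @return A `sample_panel`.
#' @export
panel_subset <- function(panel, keep) {
  sample_panel(
    reference = dplyr::filter(panel$reference, .data$id %in% keep),
    incursives = intersect(panel$incursives, keep),
    metadata = panel$metadata
  )
}
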