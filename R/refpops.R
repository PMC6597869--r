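#' Monte Carlo cross-validation of reference samples
#'
#' Repeatedly holds out a proportion of individuals from every reference
#' sample (`ceiling(proportion * n)` each, so at least one), trains the
#' SVM assignment model on the remainder, assigns the held-out
#' individuals, and accumulates sample-by-sample confusion counts.
#' Samples that cannot be told apart show up as off-diagonal mass.
#'
#' @param gm A [geno_matrix()] at the QC'd loci.
#' @param panel A [sample_panel()]; each sample needs enough individuals
#'   that holdout leaves at least 2 for training.
#' @param proportions Resampling proportions (default 0.1, 0.2, 0.3).
#' @param n_reps Replicates per proportion (default 200).
#' @param seed Integer seed.
#' @return An object of class `cv_result`: `counts` (confusion count
#'   matrix, rows true sample, columns assigned), `rates` (row-normalized;
#'   rows sum to 1), `proportions`, `n_reps`.
#' @export
mc_cross_validate <- function(gm, panel, proportions = c(0.1, 0.2, 0.3),
                              n_reps = 200, seed = 1) {
  stopifnot(all(proportions > 0), all(proportions < 1))
  groups <- panel_groups(panel)
  labels <- names(groups)
  for (lab in labels) {
    n_hold <- ceiling(max(proportions) * length(groups[[lab]]))
    if (length(groups[[lab]]) - n_hold < 2) {
      stop("sample '", lab, "' too small for holdout (",
           length(groups[[lab]]), " individuals)")
    }
  }
  counts <- matrix(0L, length(labels), length(labels),
                   dimnames = list(true = labels, assigned = labels))
  set.seed(seed)
  for (prop in proportions) {
    for (rep in seq_len(n_reps)) {
      held <- lapply(groups, function(ids) {
        sample(ids, ceiling(prop * length(ids)))
      })
      held_ids <- unlist(held, use.names = FALSE)
      train_panel <- sample_panel(
        reference = dplyr::filter(panel$reference,
                                  !.data$id %in% held_ids))
      model <- assign_train(gm, train_panel,
                            seed = sample.int(.Machine$integer.max, 1))
      res <- assign_posteriors(model, gm, held_ids)
      truth <- rep(labels, vapply(held, length, integer(1)))
      for (i in seq_along(held_ids)) {
        counts[truth[i], res$assigned[i]] <-
          counts[truth[i], res$assigned[i]] + 1L
      }
    }
  }
  structure(list(counts = counts,
                 rates = counts / rowSums(counts),
                 proportions = proportions, n_reps = n_reps),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  acc <- sum(diag(x$counts)) / sum(x$counts)
  cat(sprintf(
    "<cv_result> %d samples, %d assignments, overall accuracy %.1f%%\n",
    nrow(x$counts), sum(x$counts), 100 * acc))
  invisible(x)
}

#' Tidy cross-validation rates
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble: `true`, `assigned`, `n`, `rate`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::as_tibble(as.table(x$counts)) |>
    dplyr::mutate(rate = .data$n / rowSums(x$counts)[.data$true],
                  n = as.integer(.data$n))
}

#' @rdname tidy.cv_result
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$counts),
    n_assignments = sum(x$counts),
    accuracy = sum(diag(x$counts)) / sum(x$counts)
  )
}

#' Build a composite-population merge plan
#'
#' Flags every pair of reference samples whose cross-misassignment rate
#' (in either direction) reaches `merge_rate`, and merges the connected
#' components of the flagged-pair graph into composite populations whose
#' labels concatenate the member labels.
#'
#' @param cv A `cv_result`.
#' @param merge_rate Flagging threshold (default 0.05 — below the 7% and
#'   10% cross-assignment levels at which time-replicated or adjacent
#'   collections are typically merged).
#' @return An object of class `merge_plan`: tibble `plan` (columns
#'   `label`, `composite`), and `flagged_pairs`.
#' @export
build_merge_plan <- function(cv, merge_rate = 0.05) {
  labels <- rownames(cv$rates)
  n <- length(labels)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && (cv$rates[i, j] >= merge_rate ||
                     cv$rates[j, i] >= merge_rate)) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  # connected components by label propagation
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) {
      min(comp[c(i, which(adj[i, ]))])
    }, integer(1))
    if (identical(new, comp)) break
    comp <- new
  }
  composite <- vapply(comp, function(c) {
    paste(labels[comp == c], collapse = "+")
  }, character(1))
  flagged <- which(adj & upper.tri(adj), arr.ind = TRUE)
  structure(list(
    plan = tibble::tibble(label = labels, composite = composite),
    flagged_pairs = tibble::tibble(label1 = labels[flagged[, 1]],
                                   label2 = labels[flagged[, 2]]),
    merge_rate = merge_rate
  ), class = "merge_plan")
}

#' @export
print.merge_plan <- function(x, ...) {
  n_comp <- dplyr::n_distinct(x$plan$composite)
  cat(sprintf(
    "<merge_plan> %d samples -> %d populations (merge rate %.2f)\n",
    nrow(x$plan), n_comp, x$merge_rate))
  if (nrow(x$flagged_pairs)) print(x$flagged_pairs)
  invisible(x)
}

#' Apply a merge plan to a panel
#'
#' Relabels reference individuals to their composite population and caps
#' any composite exceeding `max_per_population` by dropping the
#' highest-missingness individuals (via [cap_population()]).
#'
#' @param panel A [sample_panel()].
#' @param plan A `merge_plan`.
#' @param missing_rates Named per-individual missingness (needed only if
#'   capping can trigger).
#' @param max_per_population Cap per composite population (default 18).
#' @return The merged (and possibly capped) `sample_panel`.
#' @export
apply_merge <- function(panel, plan, missing_rates = NULL,
                        max_per_population = 18) {
  map <- stats::setNames(plan$plan$composite, plan$plan$label)
  missing_labels <- setdiff(panel_labels(panel), names(map))
  if (length(missing_labels)) {
    stop("merge plan does not cover: ",
         paste(missing_labels, collapse = ", "))
  }
  ref <- dplyr::mutate(panel$reference,
                       label = unname(map[.data$label]))
  merged <- sample_panel(ref, panel$incursives, panel$metadata)
  keep <- unlist(lapply(panel_groups(merged), function(ids) {
    if (length(ids) <= max_per_population) return(ids)
    if (is.null(missing_rates)) {
      stop("capping required but no missing rates supplied")
    }
    cap_population(ids, missing_rates, max_per_population)
  }), use.names = FALSE)
  panel_subset(merged, c(keep, merged$incursives))
}
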