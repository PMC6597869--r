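#' Run the full incursion-tracing pipeline
#'
#' From a genotype matrix and a panel of labelled reference samples plus
#' incursives: (1) QC the references ([qc_reference()]); (2) optionally
#' delineate populations by Monte Carlo cross-validation and merge
#' indistinguishable samples into composites; (3) refilter loci with the
#' incursives included (call rate within every population and within the
#' incursive set, overall MAF); (4) assign every incursive by cluster
#' detection across the BIC/AIC K range and by the calibrated linear SVM;
#' (5) classify confidence and, when Vssc genotype strings are present in
#' the panel metadata, resistance phenotypes.
#'
#' @param gm A [geno_matrix()].
#' @param panel A [sample_panel()].
#' @param config A [filter_config()].
#' @param seed Integer seed governing every stochastic step.
#' @param delineate Run the cross-validation/merge stage (default `TRUE`
#'   when the panel has more than one reference sample).
#' @param cv_reps Replicates per resampling proportion for the
#'   delineation stage.
#' @param merge_rate Cross-misassignment rate at which samples merge.
#' @param n_components PCs for cluster detection (capped at rank).
#' @param n_start k-means restarts.
#' @param k_max Largest K scanned (default: populations + 2).
#' @return An object of class `incursion_result` with elements `report`
#'   (tibble, one row per incursive), `summary`, `kscan`, `cv`, `plan`,
#'   `qc_log`, `model`, `panel`, `gm` (final analysis matrix).
#' @export
run_incursion_trace <- function(gm, panel, config = filter_config(),
                                seed = 1, delineate = NULL, cv_reps = 50,
                                merge_rate = 0.05, n_components = 1000,
                                n_start = 10, k_max = NULL) {
  panel <- validate_panel(panel, gm)
  qc <- qc_reference(gm, panel, config)

  if (is.null(delineate)) {
    delineate <- length(panel_labels(qc$panel)) > 1
  }
  cv <- NULL
  plan <- NULL
  panel2 <- qc$panel
  if (delineate) {
    ref_panel <- sample_panel(qc$panel$reference,
                              metadata = qc$panel$metadata)
    cv <- mc_cross_validate(qc$gm, ref_panel, n_reps = cv_reps,
                            seed = seed)
    plan <- build_merge_plan(cv, merge_rate)
    miss <- sample_missingness(qc$gm)
    panel2 <- apply_merge(qc$panel, plan, miss,
                          config$max_per_population)
  }

  groups <- panel_groups(panel2)
  if (length(panel2$incursives)) {
    groups <- c(groups, list(.incursives = panel2$incursives))
  }
  gm_final <- filter_loci(qc$gm, groups, config)

  n_pops <- length(panel_labels(panel2))
  ref_ids <- panel2$reference$id
  if (is.null(k_max)) k_max <- min(n_pops + 2, length(ref_ids) - 1)
  pcs_ref <- fit_pca(gm_final, ref_ids, n_components)
  ks <- kscan(pcs_ref$scores, k_max = k_max, n_start = n_start,
              seed = seed + 1)
  # the top of the assignment range is the number of populations, where
  # every population sits in its own cluster
  k_range <- min(ks$k_lo, n_pops):n_pops

  model <- assign_train(gm_final, panel2, seed = seed + 2)
  report <- tibble::tibble()
  if (length(panel2$incursives)) {
    post <- assign_posteriors(model, gm_final, panel2$incursives)
    ref_only <- sample_panel(panel2$reference)
    dapc_rows <- purrr::map_dfr(seq_along(panel2$incursives),
                                function(i) {
      id <- panel2$incursives[i]
      ca <- assign_by_clusters(gm_final, ref_only, id, k_range,
                               n_components = n_components,
                               n_start = n_start, seed = seed + 10 + i)
      kcols <- stats::setNames(
        purrr::map_chr(ca$by_k$mates, paste, collapse = ";"),
        paste0("k", ca$by_k$k))
      dplyr::bind_cols(
        tibble::tibble(id = id,
                       final_assignment = ca$final_assignment,
                       consistent_across_k = consistency_across_k(ca)),
        tibble::as_tibble(as.list(kcols)))
    })
    report <- dplyr::left_join(dapc_rows, post, by = "id")
    conf <- purrr::map2(
      seq_len(nrow(report)), report$relative_probability,
      function(i, rp) {
        classify_confidence(report$consistent_across_k[i],
                            report$final_assignment[i],
                            report$assigned[i], rp)
      })
    report$methods_agree <- !is.na(report$final_assignment) &
      report$final_assignment == report$assigned
    report$confidence <- purrr::map_chr(conf, "confidence")
    report$reasons <- purrr::map_chr(
      conf, ~ paste(.x$reasons, collapse = ";"))
    if ("vssc" %in% names(panel2$metadata)) {
      vs <- panel2$metadata[, c("id", "vssc")]
      report <- dplyr::left_join(report, vs, by = "id")
      report <- dplyr::bind_cols(
        report,
        classify_resistance_cohort(report$vssc)[, -1])
    }
  }

  structure(list(
    report = report,
    summary = summarize_assignments(report),
    kscan = ks, k_range = k_range, cv = cv, plan = plan,
    qc_log = qc$log, model = model, panel = panel2, gm = gm_final
  ), class = "incursion_result")
}

#' @export
print.incursion_result <- function(x, ...) {
  cat(sprintf(
    "<incursion_result> %d populations, %d loci, %d incursives\n",
    length(x$model$levels), ncol(x$gm$calls), nrow(x$report)))
  if (nrow(x$report)) {
    n_w <- sum(x$report$confidence == "WELL_ASSIGNED")
    cat(sprintf("  well-assigned: %d (%.1f%%)\n", n_w,
                100 * n_w / nrow(x$report)))
  }
  invisible(x)
}

#' @method tidy incursion_result
#' @export
tidy.incursion_result <- function(x, ...) x$report

#' @method glance incursion_result
#' @export
glance.incursion_result <- function(x, ...) {
  n <- nrow(x$report)
  tibble::tibble(
    n_incursives = n,
    n_populations = length(x$model$levels),
    n_loci = ncol(x$gm$calls),
    k_lo = x$kscan$k_lo, k_hi = x$kscan$k_hi,
    pct_well_assigned = if (n) {
      round(100 * mean(x$report$confidence == "WELL_ASSIGNED"), 1)
    } else {
      NA_real_
    }
  )
}
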