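#' Scan the number of clusters K by BIC and AIC
#'
#' Runs best-of-`n_start` k-means on PC scores for each K from 1 to
#' `k_max` and scores each solution with the within-cluster sum of
#' squares (WSS) information criteria
#' `BIC(K) = n log(WSS_K / n) + K log(n)` and
#' `AIC(K) = n log(WSS_K / n) + 2 K` (spherical-cluster approximation,
#' the form used by PCA-based cluster detection in population genetics).
#' The selected K range runs from the BIC argmin (conservative) to the
#' AIC argmin (liberal); if the AIC argmin falls below the BIC argmin the
#' range spans the two with a warning.
#'
#' @param scores Numeric matrix of PC scores (individuals x components).
#' @param k_max Largest K scanned (must be < number of individuals).
#' @param n_start Random k-means restarts per K.
#' @param max_iter Iteration cap per k-means run.
#' @param seed Optional integer seed for the restarts.
#' @return An object of class `kscan`: tibble `scan` (k, wss, bic, aic),
#'   `k_lo`, `k_hi`, `n`.
#' @export
kscan <- function(scores, k_max = 15, n_start = 50, max_iter = 1000,
                  seed = NULL) {
  n <- nrow(scores)
  if (n <= k_max) stop("k_max must be below the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  wss <- vapply(seq_len(k_max), function(k) {
    if (k == 1) {
      sum(scale(scores, scale = FALSE)^2)
    } else {
      stats::kmeans(scores, centers = k, nstart = n_start,
                    iter.max = max_iter)$tot.withinss
    }
  }, numeric(1))
  wss <- cummin(wss)   # a coarser K can never fit better than a finer one
  bic <- n * log(wss / n) + seq_len(k_max) * log(n)
  aic <- n * log(wss / n) + 2 * seq_len(k_max)
  k_lo <- which.min(bic)
  k_hi <- which.min(aic)
  if (k_hi < k_lo) {
    warning("AIC argmin (", k_hi, ") below BIC argmin (", k_lo,
            "); spanning the two")
    rng <- range(k_lo, k_hi)
    k_lo <- rng[1]
    k_hi <- rng[2]
  }
  structure(list(
    scan = tibble::tibble(k = seq_len(k_max), wss = wss, bic = bic,
                          aic = aic),
    k_lo = k_lo, k_hi = k_hi, n = n
  ), class = "kscan")
}

#' @export
print.kscan <- function(x, ...) {
  cat(sprintf("<kscan> K range [%d, %d] (BIC..AIC argmin), n = %d\n",
              x$k_lo, x$k_hi, x$n))
  invisible(x)
}

#' @rdname kscan
#' @param x A `kscan`.
#' @param ... Unused.
#' @method tidy kscan
#' @export
tidy.kscan <- function(x, ...) x$scan

#' @rdname kscan
#' @method glance kscan
#' @export
glance.kscan <- function(x, ...) {
  tibble::tibble(k_lo = x$k_lo, k_hi = x$k_hi, n = x$n)
}

#' Assign one incursive by cluster detection across a K range
#'
#' Reproduces the leave-one-in design of cluster-based assignment: the
#' reference individuals plus a single incursive are decomposed by PCA,
#' then partitioned by k-means at each K in `k_range`. The incursive's
#' assignment at K is the set of reference-population labels of its
#' cluster mates; at the top of the range (normally K = number of
#' populations) the assignment is the majority population of its cluster,
#' or `NA` ("unresolved") if the incursive sits alone or the majority is
#' tied.
#'
#' @param gm A [geno_matrix()] holding references and the incursive at
#'   the analysis loci.
#' @param panel A [sample_panel()] whose reference labels are the
#'   (possibly composite) populations.
#' @param incursive_id The incursive to assign.
#' @param k_range Integer vector of K values (e.g. `k_lo:k_hi` from
#'   [kscan()]).
#' @param n_components PCs used for clustering (capped at rank).
#' @param n_start,max_iter k-means restarts and iteration cap.
#' @param seed Optional seed.
#' @return An object of class `cluster_assignment`: tibble `by_k` with
#'   columns `k`, `mates` (list of population labels sharing the
#'   incursive's cluster) and `alone`; `final_k`; `final_assignment`.
#' @export
assign_by_clusters <- function(gm, panel, incursive_id, k_range,
                               n_components = 1000, n_start = 10,
                               max_iter = 1000, seed = NULL) {
  stopifnot(incursive_id %in% sample_ids(gm))
  miss <- sample_missingness(gm, incursive_id)
  if (miss > 0.25) {
    warning("incursive ", incursive_id, " missing at ",
            round(100 * miss), "% of loci; assignment may be weak")
  }
  ref <- panel$reference
  ids <- c(ref$id, incursive_id)
  pcs <- fit_pca(gm, ids, n_components)
  if (!is.null(seed)) set.seed(seed)
  by_k <- purrr::map_dfr(sort(k_range), function(k) {
    part <- if (k == 1) {
      rep(1L, length(ids))
    } else {
      stats::kmeans(pcs$scores, centers = k, nstart = n_start,
                    iter.max = max_iter)$cluster
    }
    inc_cluster <- part[length(ids)]
    mates <- ref$label[part[seq_len(nrow(ref))] == inc_cluster]
    majority <- NA_character_
    if (length(mates)) {
      tab <- sort(table(mates), decreasing = TRUE)
      if (length(tab) == 1 || tab[1] > tab[2]) {
        majority <- names(tab)[1]
      }
    }
    tibble::tibble(k = k, mates = list(sort(unique(mates))),
                   alone = length(mates) == 0, majority = majority)
  })
  final_assignment <- by_k$majority[nrow(by_k)]
  structure(list(by_k = by_k, final_k = max(k_range),
                 final_assignment = final_assignment,
                 incursive_id = incursive_id,
                 missingness = unname(miss)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment> %s -> %s at K = %d (%.0f%% missing)\n",
    x$incursive_id,
    ifelse(is.na(x$final_assignment), "unresolved", x$final_assignment),
    x$final_k, 100 * x$missingness))
  invisible(x)
}

#' Does the final-K assignment hold at every smaller K?
#'
#' True iff the incursive's single-population assignment at the top of
#' the K range is contained in its cluster-mate population set at every
#' smaller K scanned (a range of length 1 is trivially consistent). An
#' unresolved final assignment is never consistent.
#'
#' @param ca A `cluster_assignment`.
#' @return Logical.
#' @export
consistency_across_k <- function(ca) {
  if (is.na(ca$final_assignment)) return(FALSE)
  all(purrr::map_lgl(ca$by_k$mates,
                     ~ ca$final_assignment %in% .x))
}

#' Re-assign within a geographic region with refiltered loci
#'
#' Restricts the panel to the populations of one region plus the
#' incursive, re-runs the locus filter on that subset (fewer group
#' call-rate constraints, so more SNPs survive) and repeats cluster
#' assignment there.
#'
#' @param gm The full [geno_matrix()] (pre final-stage filtering).
#' @param panel A [sample_panel()].
#' @param incursive_id Incursive to refine.
#' @param region_populations At least two population labels.
#' @param config A [filter_config()] for the re-filter.
#' @param k_range Optional K range; defaults to
#'   `2:length(region_populations)`.
#' @param ... Passed to [assign_by_clusters()].
#' @return A `cluster_assignment` with attribute `n_loci` (the regional
#'   locus count).
#' @export
regional_refinement <- function(gm, panel, incursive_id,
                                region_populations,
                                config = filter_config(),
                                k_range = NULL, ...) {
  if (length(region_populations) < 2) {
    stop("regional refinement needs at least 2 populations")
  }
  sub_panel <- sample_panel(
    reference = dplyr::filter(panel$reference,
                              .data$label %in% region_populations),
    incursives = incursive_id, metadata = panel$metadata)
  groups <- c(panel_groups(sub_panel), list(incursive = incursive_id))
  sub_gm <- gm[match(c(sub_panel$reference$id, incursive_id),
                     sample_ids(gm)), ]
  sub_gm <- filter_loci(sub_gm, groups, config)
  if (is.null(k_range)) k_range <- 2:length(region_populations)
  ca <- assign_by_clusters(sub_gm, sub_panel, incursive_id, k_range, ...)
  attr(ca, "n_loci") <- ncol(sub_gm$calls)
  ca
}
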