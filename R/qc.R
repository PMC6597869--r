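#' Filter configuration
#'
#' Thresholds of the genotype-level QC chain. Defaults follow common
#' RADseq assignment practice: loci must be called in at least 75% of the
#' individuals of every group and have overall minor allele frequency of
#' at least 0.05; loci out of Hardy-Weinberg equilibrium (exact test,
#' alpha 0.05) are removed; retained SNPs are at least 250 kbp apart;
#' individuals missing 30% or more of genotypes are dropped; pairs with
#' Loiselle kinship of 0.1875 or more (putative first-degree relatives)
#' are pruned; and reference samples are capped at 18 individuals.
#'
#' @param min_call_rate Per-group locus call-rate threshold (inclusive).
#' @param min_maf Overall minor-allele-frequency threshold (inclusive).
#' @param hwe_alpha Per-locus significance level of the exact
#'   Hardy-Weinberg test; `NULL` disables the filter.
#' @param hwe_mode `"per_sample"` (test within every reference sample,
#'   remove on any rejection) or `"pooled"`.
#' @param thin_window_bp Minimum distance between retained SNPs on a
#'   chromosome.
#' @param max_individual_missing Individuals with missingness at or above
#'   this fraction are removed (boundary exclusive retention).
#' @param kinship_threshold Loiselle kinship at or above which a pair is
#'   treated as first-degree related.
#' @param max_per_population Cap on individuals per reference sample or
#'   composite population.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_call_rate = 0.75, min_maf = 0.05,
                          hwe_alpha = 0.05, hwe_mode = "per_sample",
                          thin_window_bp = 250000,
                          max_individual_missing = 0.30,
                          kinship_threshold = 0.1875,
                          max_per_population = 18) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5,
            thin_window_bp >= 0,
            max_individual_missing > 0, max_individual_missing <= 1,
            kinship_threshold > 0, max_per_population >= 1)
  structure(as.list(environment()), class = "filter_config")
}

#' Locus filter: per-group call rate and overall MAF
#'
#' A locus is retained iff its call rate is at least `min_call_rate`
#' within EVERY group and its minor allele frequency, computed over all
#' non-missing calls across the groups, is at least `min_maf`. Both
#' boundaries are inclusive.
#'
#' @param gm A [geno_matrix()].
#' @param groups A list of sample-id vectors (e.g. [panel_groups()]; an
#'   incursive set may be one of the groups).
#' @param config A [filter_config()].
#' @return The filtered `geno_matrix`.
#' @export
filter_loci <- function(gm, groups, config = filter_config()) {
  if (ncol(gm$calls) == 0) stop("empty genotype matrix")
  stopifnot(length(groups) >= 1)
  cr_ok <- Reduce(`&`, lapply(groups, function(ids) {
    locus_call_rate(gm, ids) >= config$min_call_rate
  }))
  all_ids <- unlist(groups, use.names = FALSE)
  maf <- locus_maf(gm, all_ids)
  maf_ok <- !is.nan(maf) & maf >= config$min_maf
  gm[, which(cr_ok & maf_ok)]
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, the p-value is the sum of
#' the probabilities of all heterozygote counts whose configuration is no
#' more probable than the observed one (the standard genotype-count exact
#' test). Probabilities are computed by the stable ratio recurrence over
#' heterozygote counts.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total
#'   at least 1).
#' @return A p-value in (0, 1\].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25) # perfectly HWE counts -> 1
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("negative counts")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype required")
  n_a <- 2 * n_hom_ref + n_het          # rarer allele chosen below
  n_b <- 2 * n_hom_alt + n_het
  n_rare <- min(n_a, n_b)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # ratio recurrence: P(h+2)/P(h) = 4 * n_AA(h) * n_BB(h) / ((h+2)(h+1))
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    n_aa <- (n_rare - h) / 2
    n_bb <- (2 * n - n_rare - h) / 2
    probs[i] <- probs[i - 1] * 4 * n_aa * n_bb / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  # tiny relative slack so equal-probability configurations are included
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

#' Remove loci deviating from Hardy-Weinberg equilibrium
#'
#' @param gm A [geno_matrix()].
#' @param groups List of sample-id vectors (reference samples). Under
#'   `hwe_mode = "per_sample"` a locus is removed if the exact test
#'   rejects at `hwe_alpha` within any group; under `"pooled"` the groups
#'   are pooled first.
#' @param config A [filter_config()].
#' @return The filtered `geno_matrix`.
#' @export
hwe_filter <- function(gm, groups, config = filter_config()) {
  if (is.null(config$hwe_alpha)) return(gm)
  if (identical(config$hwe_mode, "pooled")) {
    groups <- list(unlist(groups, use.names = FALSE))
  }
  reject <- Reduce(`|`, lapply(groups, function(ids) {
    cnt <- locus_genotype_counts(gm, ids)
    p <- vapply(seq_len(nrow(cnt)), function(i) {
      tot <- cnt$n_hom_ref[i] + cnt$n_het[i] + cnt$n_hom_alt[i]
      if (tot < 1) return(1)
      hwe_exact_test(cnt$n_hom_ref[i], cnt$n_het[i], cnt$n_hom_alt[i])
    }, numeric(1))
    p < config$hwe_alpha
  }))
  gm[, which(!reject)]
}

#' Thin loci by physical distance
#'
#' Greedy left-to-right walk per chromosome: keep the first locus, then
#' drop any locus closer than `window_bp` to the last kept one. Loci on
#' different chromosomes never suppress each other.
#'
#' @param loci A data frame with columns `chrom` and `pos`.
#' @param window_bp Minimum distance (bp) between retained loci.
#' @return Integer indices (into the input row order) of retained loci.
#' @export
thin_by_distance <- function(loci, window_bp = 250000) {
  if (nrow(loci) == 0) return(integer())
  ord <- order(loci$chrom, loci$pos)
  keep <- logical(nrow(loci))
  last_chrom <- ""
  last_pos <- -Inf
  for (i in ord) {
    if (loci$chrom[i] != last_chrom || loci$pos[i] - last_pos >= window_bp) {
      keep[i] <- TRUE
      last_chrom <- loci$chrom[i]
      last_pos <- loci$pos[i]
    }
  }
  which(keep)
}

#' Remove individuals with excessive missing data
#'
#' @param gm A [geno_matrix()].
#' @param ids Candidate ids (default all).
#' @param threshold Individuals with missingness `>= threshold` are
#'   removed (so exactly 30% missing is out under the default 0.30).
#' @return Character vector of retained ids.
#' @export
filter_individuals_missing <- function(gm, ids = sample_ids(gm),
                                       threshold = 0.30) {
  stopifnot(threshold > 0, threshold <= 1)
  miss <- sample_missingness(gm, ids)
  ids[miss < threshold]
}

#' Loiselle multilocus kinship
#'
#' For biallelic loci with sample reference-allele frequency `p_l`
#' (computed from the individuals passed in) and half-dosages
#' `x_il in {0, 1/2, 1}`, the pairwise coefficient is
#' \deqn{k_{ij} = \frac{\sum_l \left[(x_{il}-p_l)(x_{jl}-p_l) +
#'   p_l(1-p_l)/(2 n_l-1)\right]}{\sum_l p_l(1-p_l)}}
#' with numerators and denominators summed over loci before dividing;
#' the `1/(2 n_l - 1)` term is the estimator's small-sample bias
#' correction, counting the `2 n_l` allele copies sampled at locus `l`
#' (`n_l` = individuals typed there).
#' With missing data, a pair's sums run over the loci where both are
#' typed. Expected values: ~0.25 for parent-offspring, ~0 for unrelated
#' pairs of the same population.
#'
#' @param gm A [geno_matrix()].
#' @param ids Individuals to compute kinship among (at least 2); allele
#'   frequencies are taken from this set, not globally.
#' @return A list of class `kinship_matrix`: `k` (symmetric matrix, `NA`
#'   on the diagonal and for pairs with no jointly typed loci — such
#'   pairs are flagged, not silently 0), and `n_shared` (jointly typed
#'   locus counts).
#' @export
loiselle_kinship <- function(gm, ids = sample_ids(gm)) {
  if (length(ids) < 2) stop("kinship needs at least 2 individuals")
  g <- gm$calls[ids, , drop = FALSE]
  typed <- !is.na(g)
  n_l <- colSums(typed)
  p <- 1 - colMeans(g, na.rm = TRUE) / 2   # reference-allele frequency
  v <- p * (1 - p)
  use <- v > 0 & n_l >= 2                  # MAF-0 loci excluded from sums
  g <- g[, use, drop = FALSE]
  typed <- typed[, use, drop = FALSE]
  n_l <- n_l[use]
  p <- p[use]
  v <- v[use]
  x <- (2 - g) / 2                          # reference-allele half-dosage
  z <- sweep(x, 2, p)
  z[!typed] <- 0
  m <- typed * 1
  bias <- v / (2 * n_l - 1)
  num <- z %*% t(z) + (m * rep(bias, each = nrow(m))) %*% t(m)
  den <- (m * rep(v, each = nrow(m))) %*% t(m)
  n_shared <- m %*% t(m)
  k <- num / den
  k[n_shared == 0] <- NA_real_
  diag(k) <- NA_real_
  dimnames(k) <- list(ids, ids)
  dimnames(n_shared) <- list(ids, ids)
  structure(list(k = k, n_shared = n_shared, ids = ids),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d individuals; max off-diagonal k = %.3f\n",
              length(x$ids), max(x$k, na.rm = TRUE)))
  invisible(x)
}

#' Tidy kinship to pairs
#' @param x A `kinship_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per unordered pair: `id1`, `id2`,
#'   `kinship`, `n_shared_loci`.
#' @method tidy kinship_matrix
#' @export
tidy.kinship_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$k), arr.ind = TRUE)
  tibble::tibble(
    id1 = x$ids[idx[, 1]], id2 = x$ids[idx[, 2]],
    kinship = x$k[idx], n_shared_loci = as.integer(x$n_shared[idx])
  )
}

#' Prune putative first-degree relatives
#'
#' Iteratively removes, among the individuals involved in any pair with
#' kinship at or above `threshold`, the one with the highest missingness
#' (ties: the one in more flagged pairs, then the lexicographically later
#' id), until all remaining pairs are below the threshold.
#'
#' @param kin A `kinship_matrix` from [loiselle_kinship()].
#' @param missing_rates Named missingness fractions covering all ids.
#' @param threshold Kinship threshold (default 0.1875, halfway between
#'   first- and second-degree expectations).
#' @return Character vector of removed ids (possibly empty).
#' @export
prune_related <- function(kin, missing_rates, threshold = 0.1875) {
  k <- kin$k
  ids <- kin$ids
  stopifnot(all(ids %in% names(missing_rates)))
  removed <- character()
  repeat {
    flagged <- !is.na(k) & k >= threshold
    if (!any(flagged)) break
    deg <- rowSums(flagged)
    cand <- ids[deg > 0]
    miss <- missing_rates[cand]
    # highest missingness first, then most flagged pairs, then the
    # lexicographically later id
    worst <- cand[order(miss, deg[match(cand, ids)], cand,
                        decreasing = TRUE)[1]]
    removed <- c(removed, worst)
    keep <- ids != worst
    k <- k[keep, keep, drop = FALSE]
    ids <- ids[keep]
  }
  removed
}

#' Cap a group at a maximum size by missingness
#'
#' If more than `max_n` ids are given, the highest-missingness
#' individuals are dropped until `max_n` remain; ties at the cut are
#' broken by dropping the lexicographically later id.
#'
#' @param ids Character ids.
#' @param missing_rates Named missingness fractions covering `ids`.
#' @param max_n Maximum group size (default 18).
#' @return Retained ids, in their input order.
#' @export
cap_population <- function(ids, missing_rates, max_n = 18) {
  stopifnot(max_n >= 1)
  if (length(ids) <= max_n) return(ids)
  miss <- missing_rates[ids]
  drop_order <- ids[order(miss, ids, decreasing = TRUE)]
  # sorts by missingness descending, lexicographically later id first
  drop <- drop_order[seq_len(length(ids) - max_n)]
  ids[!ids %in% drop]
}

#' Run the reference QC chain
#'
#' Applies, in order: per-sample call-rate/MAF locus filtering,
#' Hardy-Weinberg filtering, physical thinning, individual-missingness
#' removal, per-sample kinship pruning, and per-sample capping. Every
#' step's before/after counts are logged.
#'
#' @param gm A [geno_matrix()] (reference individuals are taken from
#'   `panel`).
#' @param panel A [sample_panel()].
#' @param config A [filter_config()].
#' @return A list of class `qc_result`: `gm` (filtered matrix restricted
#'   to retained reference individuals and incursives), `panel` (with
#'   removed individuals dropped), `log` (tibble of step/before/after),
#'   and `kinship` (the post-filter `kinship_matrix`).
#' @export
qc_reference <- function(gm, panel, config = filter_config()) {
  groups <- panel_groups(panel)
  log <- list()
  note <- function(step, unit, before, after) {
    tibble::tibble(step = step, unit = unit,
                   before = before, after = after)
  }

  n0 <- ncol(gm$calls)
  gm1 <- filter_loci(gm, groups, config)
  log$callrate <- note("call_rate_maf", "loci", n0, ncol(gm1$calls))

  gm2 <- hwe_filter(gm1, groups, config)
  log$hwe <- note("hwe", "loci", ncol(gm1$calls), ncol(gm2$calls))

  keep <- thin_by_distance(gm2$loci, config$thin_window_bp)
  gm3 <- gm2[, keep]
  log$thin <- note("thin_250kbp", "loci", ncol(gm2$calls), ncol(gm3$calls))

  ref_ids <- panel$reference$id
  kept_ids <- filter_individuals_missing(gm3, ref_ids,
                                         config$max_individual_missing)
  log$indmiss <- note("individual_missingness", "individuals",
                      length(ref_ids), length(kept_ids))

  miss <- sample_missingness(gm3, kept_ids)
  removed_rel <- character()
  kin_list <- list()
  for (lab in names(groups)) {
    ids <- intersect(groups[[lab]], kept_ids)
    if (length(ids) < 2) next
    kin <- loiselle_kinship(gm3, ids)
    kin_list[[lab]] <- kin
    removed_rel <- c(removed_rel,
                     prune_related(kin, miss, config$kinship_threshold))
  }
  kept_ids <- setdiff(kept_ids, removed_rel)
  log$kin <- note("kinship_pruning", "individuals",
                  length(kept_ids) + length(removed_rel), length(kept_ids))

  n_before <- length(kept_ids)
  capped <- unlist(lapply(names(groups), function(lab) {
    cap_population(intersect(groups[[lab]], kept_ids), miss,
                   config$max_per_population)
  }), use.names = FALSE)
  log$cap <- note("population_cap", "individuals", n_before,
                  length(capped))

  keep_all <- c(capped, intersect(panel$incursives, sample_ids(gm3)))
  structure(list(
    gm = gm3[match(keep_all, sample_ids(gm3)), ],
    panel = panel_subset(panel, keep_all),
    log = dplyr::bind_rows(log),
    kinship = kin_list
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$log)
  invisible(x)
}
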