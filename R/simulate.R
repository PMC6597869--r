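#' Simulation configuration
#'
#' Parameters of the Balding-Nichols structured-panel generator. Each
#' daughter population's allele frequency at a locus is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around an ancestral frequency `p`, so
#' `F` plays the role of the inter-population differentiation (F_ST) that
#' the assignment methods exploit. Genotypes are then binomial draws of
#' two allele copies, i.e. Hardy-Weinberg holds within each population.
#'
#' @param n_populations Number of reference populations.
#' @param fst Differentiation parameter F, strictly in (0, 1).
#' @param n_loci Number of unlinked biallelic loci.
#' @param n_per_population Diploid individuals per reference population
#'   (default 18, the size reference samples are capped at).
#' @param missing_rate Per-call missing probability in \[0, 0.5).
#' @param ancestral_maf_range Ancestral allele frequencies are drawn
#'   uniformly on this range (default \[0.1, 0.5\]), keeping the
#'   post-filter MAF spectrum realistic.
#' @param n_chrom Number of synthetic chromosomes loci are spread over.
#' @param spacing_bp Physical spacing between consecutive loci on a
#'   chromosome (default 50 kbp, so 250-kbp thinning has work to do).
#' @param seed Optional integer seed; all randomness of
#'   [simulate_panel()] flows from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 2, fst = 0.1, n_loci = 1000,
                       n_per_population = 18, missing_rate = 0,
                       ancestral_maf_range = c(0.1, 0.5), n_chrom = 3,
                       spacing_bp = 50000, seed = NULL) {
  stopifnot(n_populations >= 1, n_loci >= 1, n_per_population >= 1,
            fst > 0, fst < 1, missing_rate >= 0, missing_rate < 0.5,
            length(ancestral_maf_range) == 2)
  structure(as.list(environment()), class = "sim_config")
}

bn_pop_freqs <- function(p_anc, fst, n_populations) {
  shape <- (1 - fst) / fst
  vapply(seq_len(n_populations),
         function(i) stats::rbeta(length(p_anc), p_anc * shape,
                                  (1 - p_anc) * shape),
         numeric(length(p_anc)))
}

synthetic_loci <- function(n_loci, n_chrom, spacing_bp) {
  chrom <- paste0("chr", rep_len(seq_len(n_chrom), n_loci))
  chrom <- sort(chrom)
  pos <- unlist(lapply(table(chrom), function(k) seq_len(k) * spacing_bp),
                use.names = FALSE)
  tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "T")
}

draw_genotypes <- function(freqs, n_ind) {
  # freqs: one frequency per locus; returns n_ind x n_loci dosage matrix
  matrix(stats::rbinom(n_ind * length(freqs), 2,
                       rep(freqs, each = n_ind)),
         nrow = n_ind)
}

#' Simulate a structured reference panel with known truth
#'
#' Generates `n_populations` reference samples under the Balding-Nichols
#' model, places loci on synthetic chromosomes at fixed spacing, and
#' optionally blanks calls at `missing_rate`. Reproducible given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_panel` with elements `gm`
#'   ([geno_matrix()]), `panel` ([sample_panel()]) and `truth` (list with
#'   `individuals` and `loci` tibbles; `loci` carries the ancestral and
#'   per-population allele frequencies).
#' @export
simulate_panel <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  loci <- synthetic_loci(config$n_loci, config$n_chrom, config$spacing_bp)
  p_anc <- stats::runif(config$n_loci, config$ancestral_maf_range[1],
                        config$ancestral_maf_range[2])
  pf <- bn_pop_freqs(p_anc, config$fst, config$n_populations)
  labels <- if (config$n_populations <= 26) {
    paste0("pop", LETTERS[seq_len(config$n_populations)])
  } else {
    sprintf("pop%02d", seq_len(config$n_populations))
  }
  colnames(pf) <- labels
  calls <- do.call(rbind, lapply(seq_along(labels), function(i) {
    draw_genotypes(pf[, i], config$n_per_population)
  }))
  ids <- paste0(rep(labels, each = config$n_per_population), "_",
                rep(seq_len(config$n_per_population), length(labels)))
  rownames(calls) <- ids
  gm <- geno_matrix(calls, loci)
  if (config$missing_rate > 0) {
    gm <- inject_missingness(gm, config$missing_rate)
  }
  truth <- list(
    individuals = tibble::tibble(
      id = ids, population = rep(labels, each = config$n_per_population),
      role = "reference", relative_of = NA_character_),
    loci = dplyr::bind_cols(
      tibble::tibble(id = gm$loci$id, p_ancestral = p_anc),
      tibble::as_tibble(pf))
  )
  panel <- sample_panel(
    reference = tibble::tibble(id = ids,
                               label = truth$individuals$population))
  structure(list(gm = gm, panel = panel, truth = truth,
                 config = config), class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf(
    "<sim_panel> %d populations (F = %g), %d loci, %d individuals (%d incursive)\n",
    x$config$n_populations, x$config$fst, ncol(x$gm$calls),
    nrow(x$gm$calls), length(x$panel$incursives)))
  invisible(x)
}

#' Add simulated incursives drawn from known source populations
#'
#' Each incursive's genotypes are binomial draws from its source
#' population's (true, simulated) allele frequencies; the truth table
#' records the source.
#'
#' @param sim A `sim_panel` from [simulate_panel()].
#' @param sources Character vector of source population labels (recycled
#'   against `n`), or a vector of length `n` giving each incursive's
#'   source.
#' @param n Number of incursives to add per element of `sources`.
#' @param missing_rate Optional per-call missing probability applied to
#'   the new incursives only.
#' @return The updated `sim_panel`.
#' @export
simulate_incursives <- function(sim, sources, n = 1, missing_rate = 0) {
  labels <- unique(sim$truth$individuals$population)
  unknown <- setdiff(sources, labels)
  if (length(unknown)) {
    stop("unknown source population(s): ", paste(unknown, collapse = ", "))
  }
  src <- rep(sources, each = n)
  if (length(src) == 0) return(sim)
  pf <- sim$truth$loci
  n_existing <- sum(sim$truth$individuals$role == "incursive")
  ids <- paste0("inc_", n_existing + seq_along(src))
  calls <- do.call(rbind, lapply(src, function(s) {
    draw_genotypes(pf[[s]], 1)
  }))
  rownames(calls) <- ids
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(calls)) < missing_rate,
                   nrow = nrow(calls))
    calls[mask] <- NA_integer_
  }
  sim$gm <- geno_matrix(rbind(sim$gm$calls, calls), sim$gm$loci)
  sim$panel$incursives <- c(sim$panel$incursives, ids)
  sim$truth$individuals <- dplyr::bind_rows(
    sim$truth$individuals,
    tibble::tibble(id = ids, population = src, role = "incursive",
                   relative_of = NA_character_))
  sim
}

#' Add a simulated parent-offspring pair
#'
#' Appends one offspring of an existing member of `population`: at every
#' locus the child inherits one allele copy drawn from the parent's two
#' and one from the population's allele frequency. The expected Loiselle
#' kinship of the pair is about 0.25 over many loci. The pair is flagged
#' in the truth table.
#'
#' @param sim A `sim_panel`.
#' @param population Label of the population the parent belongs to.
#' @param parent_id Optional explicit parent id; defaults to the first
#'   member of the population.
#' @return The updated `sim_panel`.
#' @export
add_first_degree_pair <- function(sim, population, parent_id = NULL) {
  members <- sim$truth$individuals$id[
    sim$truth$individuals$population == population &
      sim$truth$individuals$role == "reference"]
  if (!length(members)) stop("population '", population, "' is empty")
  if (is.null(parent_id)) parent_id <- members[1]
  g_par <- sim$gm$calls[parent_id, ]
  p <- sim$truth$loci[[population]]
  # one allele from the parent's two copies, one from the population pool
  pr <- g_par / 2
  pr[is.na(pr)] <- 0
  from_parent <- stats::rbinom(length(g_par), 1, pr)
  from_pool <- stats::rbinom(length(p), 1, p)
  child <- from_parent + from_pool
  child[is.na(g_par)] <- NA_integer_
  n_kids <- sum(!is.na(sim$truth$individuals$relative_of))
  child_id <- paste0(population, "_child", n_kids + 1)
  calls <- rbind(sim$gm$calls, child)
  rownames(calls)[nrow(calls)] <- child_id
  sim$gm <- geno_matrix(calls, sim$gm$loci)
  sim$panel$reference <- dplyr::bind_rows(
    sim$panel$reference, tibble::tibble(id = child_id, label = population))
  sim$truth$individuals <- dplyr::bind_rows(
    sim$truth$individuals,
    tibble::tibble(id = child_id, population = population,
                   role = "reference", relative_of = parent_id))
  sim
}

#' Blank genotype calls at given per-individual rates
#'
#' @param gm A [geno_matrix()].
#' @param rates A single rate in \[0, 1) applied to everyone, or a named
#'   vector of per-individual rates (ids absent from it keep rate 0).
#' @return The `geno_matrix` with calls set missing; realized per-
#'   individual missingness is within binomial error of the request.
#' @export
inject_missingness <- function(gm, rates) {
  if (any(rates >= 1) || any(rates < 0)) {
    stop("missingness rates must be in [0, 1)")
  }
  ids <- sample_ids(gm)
  r <- if (is.null(names(rates))) {
    stats::setNames(rep(rates, length.out = length(ids)), ids)
  } else {
    out <- stats::setNames(numeric(length(ids)), ids)
    out[names(rates)] <- rates
    out
  }
  calls <- gm$calls
  for (id in ids[r[ids] > 0]) {
    mask <- stats::runif(ncol(calls)) < r[id]
    calls[id, mask] <- NA_integer_
  }
  geno_matrix(calls, gm$loci)
}

#' Simulate three-locus Vssc resistance genotypes
#'
#' Draws each individual's Vssc genotype string (e.g. `"GG/TT/CC"`) from
#' its population's distribution over genotype classes. Incursives draw
#' from their true source population's distribution.
#'
#' @param sim A `sim_panel`.
#' @param freqs Named list: population label -> named numeric vector of
#'   genotype-string frequencies summing to 1 (tolerance 1e-6).
#' @return The `sim_panel` with `panel$metadata` gaining a `vssc` column.
#' @export
simulate_vssc <- function(sim, freqs) {
  for (lab in names(freqs)) {
    if (abs(sum(freqs[[lab]]) - 1) > 1e-6) {
      stop("genotype frequencies for '", lab, "' do not sum to 1")
    }
  }
  ind <- sim$truth$individuals
  missing_pops <- setdiff(unique(ind$population), names(freqs))
  if (length(missing_pops)) {
    stop("no Vssc frequencies given for: ",
         paste(missing_pops, collapse = ", "))
  }
  gt <- vapply(seq_len(nrow(ind)), function(i) {
    f <- freqs[[ind$population[i]]]
    sample(names(f), 1, prob = f)
  }, character(1))
  meta <- tibble::tibble(id = ind$id, vssc = gt)
  sim$panel$metadata <- if (nrow(sim$panel$metadata)) {
    dplyr::rows_upsert(sim$panel$metadata, meta, by = "id")
  } else {
    meta
  }
  sim
}

#' Simulate the study-mirror reference panel
#'
#' Convenience configuration emulating the scale of the mosquito-incursion
#' study's final panel: 13 reference populations of 18 individuals at
#' F = 0.1, with enough loci at 50-kbp spacing (11,000) that roughly
#' 2,000 SNPs survive the full QC chain (call rate/MAF, per-population
#' Hardy-Weinberg exact test at alpha 0.05, 250-kbp thinning), and 5%
#' missing calls.
#'
#' @param seed Integer seed.
#' @param n_populations,n_loci,fst,missing_rate Overridable condition
#'   parameters.
#' @return A `sim_panel`.
#' @export
simulate_study_panel <- function(seed = NULL, n_populations = 13,
                                 n_loci = 11000, fst = 0.1,
                                 missing_rate = 0.05) {
  simulate_panel(sim_config(
    n_populations = n_populations, fst = fst, n_loci = n_loci,
    n_per_population = 18, missing_rate = missing_rate, seed = seed))
}
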