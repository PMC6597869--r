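#' Genotype matrix container
#'
#' A `geno_matrix` holds unphased biallelic genotypes as alt-allele dosages
#' (0, 1, 2, or `NA` for a missing call) for a set of individuals at a set
#' of loci, together with the physical coordinates of every locus. It is the
#' substrate of every filtering and assignment step in the package.
#'
#' @param calls Integer or numeric matrix, individuals in rows and loci in
#'   columns; entries must be 0, 1, 2 or `NA`.
#' @param loci A data frame with one row per locus and columns `chrom`,
#'   `pos` (1-based bp), `ref` and `alt` (single bases). Row order matches
#'   the column order of `calls`.
#' @param samples Character vector of sample ids; defaults to
#'   `rownames(calls)`.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   (the dosage matrix, dimnames set), and `loci` (a tibble).
#' @export
#' @examples
#' gm <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                          dimnames = list(c("a", "b"), NULL)),
#'                   loci = data.frame(chrom = "1", pos = c(100, 400000),
#'                                     ref = "A", alt = "T"))
#' sample_missingness(gm)
geno_matrix <- function(calls, loci, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(samples)) {
    samples <- paste0("ind_", seq_len(nrow(calls)))
  }
  stopifnot(length(samples) == nrow(calls))
  loci <- tibble::as_tibble(loci)
  required <- c("chrom", "pos")
  if (!all(required %in% names(loci))) {
    stop("`loci` must have columns 'chrom' and 'pos'")
  }
  if (!"ref" %in% names(loci)) loci$ref <- "A"
  if (!"alt" %in% names(loci)) loci$alt <- "T"
  if (nrow(loci) != ncol(calls)) {
    stop("number of loci (", nrow(loci), ") does not match number of call ",
         "columns (", ncol(calls), ")")
  }
  if (any(loci$pos < 1)) stop("locus positions must be >= 1")
  if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
  bad <- !(calls %in% c(0, 1, 2, NA))
  if (any(bad)) {
    stop("calls must be 0, 1, 2 or NA; found ",
         paste(unique(calls[bad]), collapse = ", "))
  }
  storage.mode(calls) <- "integer"
  rownames(calls) <- samples
  if (!"id" %in% names(loci)) {
    loci$id <- paste0(loci$chrom, ":", loci$pos)
  }
  colnames(calls) <- loci$id
  structure(list(calls = calls, loci = loci), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat(sprintf(
    "<geno_matrix> %d individuals x %d biallelic loci (%.1f%% missing)\n",
    nrow(x$calls), ncol(x$calls), 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Sample ids of a genotype matrix
#' @param x A `geno_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$calls)

#' Subset a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param i Sample ids (character) or indices to keep.
#' @param j Locus indices or locus ids to keep.
#' @param ... Unused.
#' @return A `geno_matrix` restricted to the requested samples and loci.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(j)) j <- match(j, x$loci$id)
  calls <- x$calls[i, j, drop = FALSE]
  geno_matrix(calls, x$loci[j, , drop = FALSE], samples = rownames(calls))
}

#' Per-sample missingness fraction
#' @param x A `geno_matrix`.
#' @param ids Optional subset of sample ids.
#' @return Named numeric vector in \[0, 1\].
#' @export
sample_missingness <- function(x, ids = sample_ids(x)) {
  rowMeans(is.na(x$calls[ids, , drop = FALSE]))
}

#' Per-locus call rate within a set of individuals
#' @param x A `geno_matrix`.
#' @param ids Sample ids over which to compute the rate.
#' @return Numeric vector, one value per locus.
#' @export
locus_call_rate <- function(x, ids = sample_ids(x)) {
  colMeans(!is.na(x$calls[ids, , drop = FALSE]))
}

#' Per-locus minor allele frequency
#'
#' Computed over all non-missing calls of the given individuals:
#' the alt-allele frequency folded onto \[0, 0.5\].
#'
#' @param x A `geno_matrix`.
#' @param ids Sample ids over which to compute the frequency.
#' @return Numeric vector, one value per locus; `NaN` where no calls.
#' @export
locus_maf <- function(x, ids = sample_ids(x)) {
  g <- x$calls[ids, , drop = FALSE]
  p <- colMeans(g, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-locus alternate allele frequency
#' @inheritParams locus_maf
#' @return Numeric vector of alt-allele frequencies.
#' @export
locus_alt_freq <- function(x, ids = sample_ids(x)) {
  colMeans(x$calls[ids, , drop = FALSE], na.rm = TRUE) / 2
}

#' Genotype counts at each locus
#'
#' @param x A `geno_matrix`.
#' @param ids Sample ids to count over.
#' @return A tibble with columns `id`, `n_hom_ref`, `n_het`, `n_hom_alt`.
#' @export
locus_genotype_counts <- function(x, ids = sample_ids(x)) {
  g <- x$calls[ids, , drop = FALSE]
  tibble::tibble(
    id        = x$loci$id,
    n_hom_ref = colSums(g == 0L, na.rm = TRUE),
    n_het     = colSums(g == 1L, na.rm = TRUE),
    n_hom_alt = colSums(g == 2L, na.rm = TRUE)
  )
}

#' Tidy a genotype matrix into long form
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `locus`, `chrom`, `pos`,
#'   `dosage`.
#' @method tidy geno_matrix
#' @export
tidy.geno_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$calls, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "locus",
                        values_to = "dosage")
  dplyr::left_join(
    long,
    dplyr::select(x$loci, locus = "id", "chrom", "pos"),
    by = "locus"
  )
}
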