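#' Principal components of a genotype matrix
#'
#' Centers dosages per locus (no scaling), imputes missing calls with the
#' per-locus mean dosage, and decomposes by SVD. The stored locus means
#' let new individuals (incursives) be imputed, centered and projected
#' into the same space.
#'
#' @param gm A [geno_matrix()].
#' @param ids Individuals the model is fit on (at least 2).
#' @param n_components Number of components requested; the number
#'   returned is capped at the matrix rank (`min(n_ids, n_loci) - 1`).
#' @return An object of class `pc_model`: `means` (per-locus mean
#'   dosage), `loadings` (loci x components), `eigenvalues` (covariance
#'   eigenvalues, non-increasing), `scores` (ids x components), `ids`,
#'   `loci_ids`.
#' @export
fit_pca <- function(gm, ids = sample_ids(gm), n_components = 1000) {
  if (length(ids) < 2) stop("PCA needs at least 2 individuals")
  x <- gm$calls[ids, , drop = FALSE]
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  if (anyNA(mu)) {
    stop("all-missing locus/loci in PCA input: ",
         paste(utils::head(gm$loci$id[is.na(mu)], 5), collapse = ", "))
  }
  idx <- which(is.na(x))
  if (length(idx)) x[idx] <- mu[(idx - 1) %/% nrow(x) + 1]
  xc <- sweep(x, 2, mu)
  rank_bound <- min(nrow(xc) - 1, ncol(xc))
  k <- min(n_components, rank_bound)
  if (k < n_components) {
    message("requested ", n_components, " components; rank allows ", k)
  }
  sv <- svd(xc, nu = k, nv = k)
  eig <- (sv$d^2) / (nrow(xc) - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- ids
  rownames(sv$v) <- gm$loci$id
  structure(list(means = mu, loadings = sv$v,
                 eigenvalues = eig[seq_len(k)], total_var = sum(eig),
                 scores = scores, ids = ids, loci_ids = gm$loci$id),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d individuals, %d loci, %d components\n",
              length(x$ids), length(x$means), ncol(x$loadings)))
  invisible(x)
}

#' Project individuals into a fitted PC space
#'
#' Missing calls are imputed with the model's (reference) locus means and
#' dosages centered with the same means before projection, so an
#' individual with no data lands at the origin.
#'
#' @param model A `pc_model`.
#' @param gm A [geno_matrix()] sharing the model's loci.
#' @param ids Individuals to project.
#' @return A scores matrix (ids x components).
#' @export
project_pca <- function(model, gm, ids) {
  stopifnot(identical(gm$loci$id, model$loci_ids))
  x <- gm$calls[ids, , drop = FALSE]
  storage.mode(x) <- "double"
  idx <- which(is.na(x))
  if (length(idx)) x[idx] <- model$means[(idx - 1) %/% nrow(x) + 1]
  sweep(x, 2, model$means) %*% model$loadings
}

#' Tidy PC scores
#' @param x A `pc_model`.
#' @param ... Unused.
#' @return A tibble with `id` and one column per component (`PC1`, ...).
#' @method tidy pc_model
#' @export
tidy.pc_model <- function(x, ...) {
  s <- x$scores
  colnames(s) <- paste0("PC", seq_len(ncol(s)))
  dplyr::bind_cols(tibble::tibble(id = x$ids), tibble::as_tibble(s))
}

#' One-line PCA summary
#' @param x A `pc_model`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_loci`, `n_components`,
#'   `var_explained` (fraction of total variance in retained components).
#' @method glance pc_model
#' @export
glance.pc_model <- function(x, ...) {
  tibble::tibble(
    n = length(x$ids), n_loci = length(x$means),
    n_components = ncol(x$loadings),
    var_explained = sum(x$eigenvalues) / x$total_var
  )
}
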