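#' Train the probabilistic assignment model
#'
#' Fits PCA on the reference individuals only, retains the components
#' whose covariance eigenvalues exceed 1 (the Kaiser rule; note the
#' eigenvalue scale of centered dosage data grows with locus count), and
#' trains a linear support vector machine with sigmoid-calibrated class
#' probabilities on the retained scores. Deterministic under `seed` (the
#' probability calibration uses internal cross-validation).
#'
#' @param gm A [geno_matrix()] at the analysis loci.
#' @param panel A [sample_panel()]; every reference population needs at
#'   least 2 individuals.
#' @param seed Integer seed.
#' @param scale_scores Scale retained PC scores to unit variance before
#'   classification (default `FALSE`).
#' @return An object of class `assignment_model`: `pca` (`pc_model`),
#'   `retained` (component indices with eigenvalue > 1), `svm`, `levels`
#'   (population label order), `scale_scores`.
#' @export
assign_train <- function(gm, panel, seed = 1, scale_scores = FALSE) {
  ref <- panel$reference
  sizes <- table(ref$label)
  if (length(sizes) < 2) stop("need at least 2 reference populations")
  if (any(sizes < 2)) {
    stop("population(s) with a single individual (probability ",
         "calibration impossible): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  pca <- fit_pca(gm, ref$id, n_components = min(1000, length(ref$id) - 1))
  retained <- which(pca$eigenvalues > 1)
  if (!length(retained)) {
    warning("no eigenvalue exceeds 1; retaining the first component")
    retained <- 1L
  }
  x <- pca$scores[, retained, drop = FALSE]
  sds <- rep(1, ncol(x))
  if (scale_scores) {
    sds <- apply(x, 2, stats::sd)
    x <- sweep(x, 2, sds, "/")
  }
  y <- factor(ref$label)
  set.seed(seed)
  fit <- e1071::svm(x = x, y = y, kernel = "linear", probability = TRUE,
                    scale = FALSE)
  structure(list(pca = pca, retained = retained, svm = fit,
                 levels = levels(y), scale_scores = scale_scores,
                 score_sds = sds, seed = seed),
            class = "assignment_model")
}

#' @export
print.assignment_model <- function(x, ...) {
  cat(sprintf(
    "<assignment_model> %d populations, %d Kaiser-retained PCs, %d loci\n",
    length(x$levels), length(x$retained), length(x$pca$means)))
  invisible(x)
}

#' Posterior membership probabilities for incursives
#'
#' Projects each incursive into the reference PC space (missing calls
#' imputed with reference locus means), classifies with the calibrated
#' linear SVM, and reports the full posterior vector, the top and second
#' populations and the relative probability (top / second posterior).
#'
#' @param model An `assignment_model`.
#' @param gm A [geno_matrix()] at the model's loci.
#' @param ids Incursive ids to assign.
#' @return A tibble: `id`, `assigned`, `posterior_top`, `second`,
#'   `posterior_second`, `relative_probability`, `missingness`, then one
#'   `post_<label>` column per population (summing to 1 per row).
#' @export
assign_posteriors <- function(model, gm, ids) {
  miss <- sample_missingness(gm, ids)
  if (any(miss >= 1)) {
    stop("individual(s) with no genotype data: ",
         paste(ids[miss >= 1], collapse = ", "))
  }
  sc <- project_pca(model$pca, gm, ids)[, model$retained, drop = FALSE]
  if (model$scale_scores) sc <- sweep(sc, 2, model$score_sds, "/")
  pred <- stats::predict(model$svm, sc, probability = TRUE)
  prob <- attr(pred, "probabilities")[, model$levels, drop = FALSE]
  out <- purrr::map_dfr(seq_along(ids), function(i) {
    p <- prob[i, ]
    ord <- order(p, decreasing = TRUE)
    tibble::tibble(
      id = ids[i],
      assigned = model$levels[ord[1]],
      posterior_top = unname(p[ord[1]]),
      second = model$levels[ord[2]],
      posterior_second = unname(p[ord[2]]),
      relative_probability = relative_probability(p),
      missingness = unname(miss[i])
    )
  })
  post <- tibble::as_tibble(prob)
  names(post) <- paste0("post_", model$levels)
  dplyr::bind_cols(out, post)
}

#' Relative probability of assignment
#'
#' Ratio of the highest to the second-highest posterior membership
#' probability; always at least 1 (exact ties give 1). A zero
#' second-best posterior yields `Inf` with a message. The conventional
#' confidence threshold is a strict `> 2`.
#'
#' @param posterior Numeric vector of membership probabilities over at
#'   least 2 populations.
#' @return A ratio >= 1.
#' @export
#' @examples
#' relative_probability(c(0.6, 0.2, 0.2)) # 3
relative_probability <- function(posterior) {
  stopifnot(length(posterior) >= 2)
  s <- sort(posterior, decreasing = TRUE)
  if (s[2] == 0) {
    message("second-best posterior is 0; relative probability infinite")
    return(Inf)
  }
  s[1] / s[2]
}

#' Tidy an assignment model
#' @param x An `assignment_model`.
#' @param ... Unused.
#' @return Tibble of retained components and eigenvalues.
#' @method tidy assignment_model
#' @export
tidy.assignment_model <- function(x, ...) {
  tibble::tibble(component = x$retained,
                 eigenvalue = x$pca$eigenvalues[x$retained])
}

#' @rdname tidy.assignment_model
#' @method glance assignment_model
#' @export
glance.assignment_model <- function(x, ...) {
  tibble::tibble(n_populations = length(x$levels),
                 n_components = length(x$retained),
                 n_reference = length(x$pca$ids),
                 n_loci = length(x$pca$means))
}
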