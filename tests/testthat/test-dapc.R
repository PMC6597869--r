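test_that("PCA scores match a dense eigendecomposition up to sign", {
  set.seed(51)
  calls <- matrix(sample(0:2, 200, replace = TRUE), nrow = 10,
                  dimnames = list(paste0("s", 1:10), NULL))
  gm <- geno_matrix(calls, data.frame(chrom = "c1", pos = 1:20))
  pcs <- fit_pca(gm, n_components = 5)
  xc <- scale(calls, center = TRUE, scale = FALSE)
  eg <- eigen(xc %*% t(xc) / (nrow(xc) - 1))
  oracle_scores <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0) *
                                              (nrow(xc) - 1)))
  for (j in 1:5) {
    expect_equal(abs(pcs$scores[, j]), abs(oracle_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_true(all(diff(pcs$eigenvalues) <= 1e-8))
})

test_that("PCA caps components at rank and handles constant loci", {
  set.seed(52)
  calls <- matrix(sample(0:2, 40, replace = TRUE), nrow = 4,
                  dimnames = list(paste0("s", 1:4), NULL))
  calls[, 1] <- 1L
  gm <- geno_matrix(calls, data.frame(chrom = "c1", pos = 1:10))
  expect_message(pcs <- fit_pca(gm, n_components = 1000), "rank")
  expect_equal(ncol(pcs$scores), 3)
  expect_true(all(abs(pcs$loadings[1, ]) < 1e-10))
  # all-missing locus errors
  calls[, 2] <- NA_integer_
  gm2 <- geno_matrix(calls, data.frame(chrom = "c1", pos = 1:10))
  expect_error(fit_pca(gm2), "all-missing")
})

test_that("missing calls are mean-imputed for fitting and projection", {
  set.seed(53)
  calls <- matrix(sample(0:2, 60, replace = TRUE), nrow = 6,
                  dimnames = list(paste0("s", 1:6), NULL))
  gm <- geno_matrix(calls, data.frame(chrom = "c1", pos = 1:10))
  pcs <- fit_pca(gm, ids = paste0("s", 1:5), n_components = 3)
  # an individual with no data projects to the origin
  calls_na <- rbind(calls, blank = rep(NA_integer_, 10))
  gm2 <- geno_matrix(calls_na, gm$loci)
  sc <- project_pca(pcs, gm2, "blank")
  expect_equal(max(abs(sc)), 0)
  # projecting the training individuals reproduces their scores
  sc_train <- project_pca(pcs, gm, paste0("s", 1:5))
  expect_equal(unname(sc_train), unname(pcs$scores), tolerance = 1e-8)
})

test_that("K scan finds three well-separated blobs and one blob", {
  set.seed(54)
  blobs <- make_blobs(n_per = 25, k = 3, d = 150, sep = 30)
  ks <- kscan(blobs$x, k_max = 8, n_start = 10, seed = 1)
  expect_equal(ks$k_lo, 3)
  expect_equal(ks$k_hi, 3)
  expect_true(all(diff(ks$scan$wss) <= 1e-8))
  one <- make_blobs(n_per = 50, k = 1, d = 30, sep = 0)
  ks1 <- kscan(one$x, k_max = 6, n_start = 10, seed = 1)
  expect_equal(ks1$k_lo, 1)
  expect_error(kscan(one$x[1:5, ], k_max = 6), "k_max")
})

test_that("cluster assignment recovers the source at K = n_pops", {
  sim <- simulate_panel(sim_config(n_populations = 3, fst = 0.15,
                                   n_loci = 800, n_per_population = 12,
                                   seed = 55))
  sim <- simulate_incursives(sim, c("popA", "popB", "popC"), n = 2)
  for (i in seq_along(sim$panel$incursives)) {
    id <- sim$panel$incursives[i]
    ca <- assign_by_clusters(sim$gm, sample_panel(sim$panel$reference),
                             id, k_range = 2:3, seed = 100 + i)
    truth <- sim$truth$individuals$population[
      sim$truth$individuals$id == id]
    expect_equal(ca$final_assignment, truth)
    expect_true(consistency_across_k(ca))
  }
})

test_that("assignment output is invariant to reference order", {
  sim <- simulate_panel(sim_config(n_populations = 2, fst = 0.2,
                                   n_loci = 500, n_per_population = 10,
                                   seed = 56))
  sim <- simulate_incursives(sim, "popB", n = 1)
  id <- sim$panel$incursives
  panel <- sample_panel(sim$panel$reference)
  perm <- sample_panel(sim$panel$reference[sample(20), ])
  ca1 <- assign_by_clusters(sim$gm, panel, id, 2, seed = 9)
  ca2 <- assign_by_clusters(sim$gm, perm, id, 2, seed = 9)
  expect_equal(ca1$final_assignment, ca2$final_assignment)
})

test_that("consistency logic follows nesting of cluster mates", {
  mk <- function(mates, final) {
    structure(list(
      by_k = tibble::tibble(k = seq_along(mates), mates = mates,
                            alone = lengths(mates) == 0,
                            majority = NA),
      final_k = length(mates), final_assignment = final,
      incursive_id = "x", missingness = 0), class = "cluster_assignment")
  }
  nested <- mk(list(c("A", "B", "C"), c("A", "B"), "A"), "A")
  expect_true(consistency_across_k(nested))
  broken <- mk(list(c("A", "B"), c("B", "C"), "A"), "A")
  expect_false(consistency_across_k(broken))
  single <- mk(list("A"), "A")
  expect_true(consistency_across_k(single))
  unresolved <- mk(list(character()), NA_character_)
  expect_false(consistency_across_k(unresolved))
})

test_that("leave-one-in clustering is stable against a single incursive", {
  sim <- simulate_panel(sim_config(n_populations = 3, fst = 0.2,
                                   n_loci = 600, n_per_population = 10,
                                   seed = 57))
  sim <- simulate_incursives(sim, "popA", n = 1)
  ref_ids <- sim$panel$reference$id
  # partition of references at K=3, with and without the incursive
  pcs_ref <- fit_pca(sim$gm, ref_ids, 20)
  set.seed(1)
  part_ref <- stats::kmeans(pcs_ref$scores, 3, nstart = 20)$cluster
  pcs_all <- fit_pca(sim$gm, c(ref_ids, sim$panel$incursives), 20)
  set.seed(1)
  part_all <- stats::kmeans(pcs_all$scores, 3, nstart = 20)$cluster
  # same partition of the references up to label permutation
  tab <- table(part_ref, part_all[seq_along(ref_ids)])
  expect_equal(sum(apply(tab, 1, max)), length(ref_ids))
})

test_that("regional refinement keeps more loci and needs 2+ populations", {
  sim <- simulate_panel(sim_config(n_populations = 4, fst = 0.1,
                                   n_loci = 1200, n_per_population = 10,
                                   seed = 58))
  # population-specific dropout: popD individuals miss a block of loci,
  # killing those loci's call rate only in the global analysis
  rates <- stats::setNames(rep(0.45, 10), panel_ids(sim$panel, "popD"))
  set.seed(58)
  sim$gm <- inject_missingness(sim$gm, rates)
  sim <- simulate_incursives(sim, "popA", n = 1)
  id <- sim$panel$incursives
  cfg <- filter_config()
  groups <- c(panel_groups(sim$panel), list(inc = id))
  global <- filter_loci(sim$gm, groups, cfg)
  ca <- regional_refinement(sim$gm, sim$panel, id,
                            c("popA", "popB", "popC"), cfg, k_range = 2:3,
                            seed = 3)
  expect_gte(attr(ca, "n_loci"), ncol(global$calls))
  expect_equal(ca$final_assignment, "popA")
  expect_error(regional_refinement(sim$gm, sim$panel, id, "popA"),
               "at least 2")
})
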