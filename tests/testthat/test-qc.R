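test_that("locus filter applies per-group call rate and overall MAF", {
  # 8 individuals in two groups of 4; locus call rate 3/4 in each group
  # sits exactly on the inclusive 0.75 boundary
  calls <- matrix(1L, nrow = 8, ncol = 3,
                  dimnames = list(paste0("s", 1:8), NULL))
  calls[1, 1] <- NA
  calls[5, 1] <- NA          # locus 1: call rate 0.75 in both groups
  calls[, 2] <- 0L           # locus 2: monomorphic, MAF 0
  calls[1:2, 3] <- NA
  calls[5, 3] <- NA          # locus 3: rate 0.5 in group 1
  gm <- geno_matrix(calls, data.frame(chrom = "c1",
                                      pos = c(1, 2, 3) * 1e6))
  groups <- list(g1 = paste0("s", 1:4), g2 = paste0("s", 5:8))
  kept <- filter_loci(gm, groups, filter_config())
  expect_equal(kept$loci$pos, 1e6)  # locus 2 fails MAF, locus 3 call rate
  # MAF boundary: 20 individuals, 2 alt copies -> 0.05 kept; 1 -> dropped
  calls2 <- matrix(0L, nrow = 20, ncol = 2,
                   dimnames = list(paste0("t", 1:20), NULL))
  calls2[1, 1] <- 2L
  calls2[1, 2] <- 1L
  gm2 <- geno_matrix(calls2, data.frame(chrom = "c1", pos = c(1e6, 2e6)))
  kept2 <- filter_loci(gm2, list(all = paste0("t", 1:20)),
                       filter_config())
  expect_equal(kept2$loci$pos, 1e6)
  expect_error(filter_loci(gm2[, integer(0)], list(a = "t1")), "empty")
})

test_that("locus filtering is idempotent", {
  sim <- simulate_panel(sim_config(n_populations = 2, fst = 0.1,
                                   n_loci = 500, n_per_population = 10,
                                   missing_rate = 0.2, seed = 31))
  groups <- panel_groups(sim$panel)
  once <- filter_loci(sim$gm, groups)
  twice <- filter_loci(once, groups)
  expect_identical(once$calls, twice$calls)
})

test_that("HWE exact test matches hand cases and the enumeration oracle", {
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-9)
  expect_equal(hwe_exact_test(2, 0, 2), hwe_oracle(2, 0, 2),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 0, 2), "negative")
  # spot grid; the exhaustive n <= 50 sweep lives in the acceptance suite
  set.seed(4)
  for (i in 1:200) {
    cnt <- as.vector(stats::rmultinom(1, sample(1:30, 1), c(1, 1, 1)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("distance thinning is a greedy left-to-right walk", {
  loci <- data.frame(chrom = "c1", pos = c(1, 100000, 300001))
  expect_equal(thin_by_distance(loci, 250000), c(1, 3))
  # chromosomes do not suppress each other
  loci2 <- data.frame(chrom = c("c1", "c2"), pos = c(1, 1))
  expect_equal(thin_by_distance(loci2, 250000), c(1, 2))
  expect_equal(thin_by_distance(loci2[0, ], 250000), integer())
  # unsorted input is sorted first
  loci3 <- data.frame(chrom = "c1", pos = c(300001, 1, 100000))
  expect_setequal(thin_by_distance(loci3, 250000), c(1, 2))
})

test_that("individual missingness boundary is exclusive at retention", {
  calls <- matrix(1L, nrow = 3, ncol = 10,
                  dimnames = list(c("a", "b", "c"), NULL))
  calls[1, 1:3] <- NA   # 0.30 exactly -> removed
  calls[2, 1:2] <- NA   # 0.20 -> kept (0.29-like case)
  calls[3, ] <- NA      # all missing -> removed
  gm <- geno_matrix(calls, data.frame(chrom = "c1", pos = 1:10))
  expect_equal(filter_individuals_missing(gm, threshold = 0.30), "b")
})

test_that("Loiselle kinship equals the brute-force oracle", {
  set.seed(8)
  calls <- matrix(sample(c(0:2, NA), 50, replace = TRUE,
                         prob = c(0.3, 0.3, 0.3, 0.1)),
                  nrow = 5, dimnames = list(paste0("s", 1:5), NULL))
  gm <- geno_matrix(calls, data.frame(chrom = "c1", pos = 1:10))
  kin <- loiselle_kinship(gm)
  oracle <- loiselle_oracle(gm, sample_ids(gm))
  expect_equal(kin$k, oracle, tolerance = 1e-12)
  expect_equal(kin$k, t(kin$k))
  expect_error(loiselle_kinship(gm, "s1"), "at least 2")
})

test_that("pairs with no jointly typed loci are flagged, not zero", {
  calls <- matrix(c(0L, 1L, NA, NA,
                    NA, NA, 1L, 2L,
                    0L, 1L, 2L, 1L), nrow = 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))
  gm <- geno_matrix(calls, data.frame(chrom = "c1", pos = 1:4))
  kin <- loiselle_kinship(gm)
  expect_true(is.na(kin$k["a", "b"]))
  expect_equal(kin$n_shared["a", "b"], 0)
  expect_false(is.na(kin$k["a", "c"]))
})

test_that("relatedness pruning removes by missingness and matches oracle", {
  # single flagged pair: the higher-missingness member goes
  k <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"),
                                       c("a", "b", "c")))
  k["a", "b"] <- k["b", "a"] <- 0.3
  diag(k) <- NA
  kin <- structure(list(k = k, n_shared = matrix(10, 3, 3),
                        ids = c("a", "b", "c")),
                   class = "kinship_matrix")
  miss <- c(a = 0.1, b = 0.2, c = 0.0)
  expect_equal(prune_related(kin, miss, 0.1875), "b")
  expect_equal(prune_related(kin, miss, 0.5), character())
  # triangle: two removals suffice; greedy result matches the oracle on
  # random fixtures
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    ids <- letters[seq_len(n)]
    km <- matrix(stats::runif(n * n, 0, 0.3), n, n,
                 dimnames = list(ids, ids))
    km[lower.tri(km)] <- t(km)[lower.tri(km)]
    diag(km) <- NA
    kin_r <- structure(list(k = km, n_shared = matrix(10, n, n),
                            ids = ids), class = "kinship_matrix")
    mr <- stats::setNames(round(stats::runif(n), 2), ids)
    got <- prune_related(kin_r, mr, 0.1875)
    expect_identical(got, prune_oracle(kin_r, mr, 0.1875))
    keep <- setdiff(ids, got)
    expect_true(all(km[keep, keep] < 0.1875, na.rm = TRUE))
  }
})

test_that("population capping drops the worst-missingness individuals", {
  ids <- sprintf("m%02d", 1:20)
  miss <- stats::setNames(seq(0, 0.19, by = 0.01), ids)
  kept <- cap_population(ids, miss, 18)
  expect_equal(kept, ids[1:18])
  expect_equal(cap_population(ids[1:18], miss, 18), ids[1:18])
  # tie at the cut: lexicographically later id dropped
  miss_tie <- stats::setNames(c(0, 0, 0.5, 0.5), c("a", "b", "c", "d"))
  expect_equal(cap_population(c("a", "b", "c", "d"), miss_tie, 3),
               c("a", "b", "c"))
})

test_that("reference QC leaves no related pair and caps samples", {
  sim <- simulate_panel(sim_config(n_populations = 2, fst = 0.15,
                                   n_loci = 3000, n_per_population = 20,
                                   missing_rate = 0.05, seed = 41))
  sim <- add_first_degree_pair(sim, "popA")
  qc <- qc_reference(sim$gm, sim$panel)
  groups <- panel_groups(qc$panel)
  expect_true(all(lengths(groups) <= 18))
  for (lab in names(groups)) {
    kin <- loiselle_kinship(qc$gm, groups[[lab]])
    expect_lt(max(kin$k, na.rm = TRUE), 0.1875)
  }
  expect_true(all(qc$log$after <= qc$log$before))
})
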