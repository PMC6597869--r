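# Independent oracles used across the suite. Each is written from the
# defining formula, deliberately unlike the package implementation.

# Exact Hardy-Weinberg test by direct log-factorial enumeration over all
# heterozygote counts compatible with the observed allele counts.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_ref + n_het
  n_b <- 2 * n_hom_alt + n_het
  n_rare <- min(n_a, n_b)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    n_aa <- (n_rare - h) / 2
    n_bb <- (2 * n - n_rare - h) / 2
    lfactorial(n) - lfactorial(n_aa) - lfactorial(h) - lfactorial(n_bb) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# Naive per-pair, per-locus Loiselle kinship with the allele-copy
# (2 n_l - 1) bias term.
loiselle_oracle <- function(gm, ids) {
  g <- gm$calls[ids, , drop = FALSE]
  n <- length(ids)
  k <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- 0
      den <- 0
      for (l in seq_len(ncol(g))) {
        col <- g[, l]
        typed <- which(!is.na(col))
        n_l <- length(typed)
        if (n_l < 2) next
        p <- mean((2 - col[typed]) / 2)
        v <- p * (1 - p)
        if (v <= 0) next
        if (is.na(col[i]) || is.na(col[j])) next
        x_i <- (2 - col[i]) / 2
        x_j <- (2 - col[j]) / 2
        num <- num + (x_i - p) * (x_j - p) + v / (2 * n_l - 1)
        den <- den + v
      }
      k[i, j] <- k[j, i] <- num / den
    }
  }
  k
}

# Weir-Cockerham two-level theta (F_ST) over loci, complete data.
wc_fst <- function(gm, groups) {
  r <- length(groups)
  a_sum <- b_sum <- c_sum <- 0
  for (l in seq_len(ncol(gm$calls))) {
    col <- gm$calls[, l]
    n_i <- vapply(groups, length, numeric(1))
    p_i <- vapply(groups, function(ids) mean(col[ids]) / 2, numeric(1))
    h_i <- vapply(groups, function(ids) mean(col[ids] == 1), numeric(1))
    n_bar <- mean(n_i)
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) /
         (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    a_sum <- a_sum + a
    b_sum <- b_sum + b
    c_sum <- c_sum + cc
  }
  a_sum / (a_sum + b_sum + c_sum)
}

# Naive re-statement of the greedy relatedness pruning rule, working on a
# tidy pair list instead of a matrix.
prune_oracle <- function(kin, missing_rates, threshold) {
  pairs <- tidy(kin)
  alive <- kin$ids
  removed <- character()
  repeat {
    bad <- pairs[!is.na(pairs$kinship) & pairs$kinship >= threshold &
                   pairs$id1 %in% alive & pairs$id2 %in% alive, ]
    if (nrow(bad) == 0) break
    cand <- unique(c(bad$id1, bad$id2))
    deg <- vapply(cand,
                  function(id) sum(bad$id1 == id | bad$id2 == id),
                  numeric(1))
    d <- data.frame(id = cand, miss = missing_rates[cand], deg = deg)
    d <- d[order(-d$miss, -d$deg, -rank(d$id)), ]
    removed <- c(removed, d$id[1])
    alive <- setdiff(alive, d$id[1])
  }
  removed
}

# Isotropic Gaussian blobs on axis-aligned centers.
make_blobs <- function(n_per, k, d, sep, sd = 1) {
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    center <- numeric(d)
    center[i] <- sep
    sweep(matrix(stats::rnorm(n_per * d, sd = sd), n_per, d), 2, -center)
  }))
  labels <- rep(seq_len(k), each = n_per)
  list(x = x, labels = labels)
}

# Closed-form simple-regression coefficients and R^2.
ols_oracle <- function(x, y) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  yhat <- b0 + b1 * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = b0, slope = b1, r_squared = r2)
}

# Small fully deterministic genotype fixture.
toy_gm <- function() {
  calls <- matrix(c(
    0L, 1L, 2L, 1L, 0L,
    2L, 1L, 0L, NA, 1L,
    1L, 1L, 1L, 2L, 0L,
    0L, NA, 2L, 2L, 1L
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("s", 1:4), NULL))
  geno_matrix(calls, loci = data.frame(
    chrom = c("c1", "c1", "c1", "c2", "c2"),
    pos = c(1, 100000, 300001, 5, 400000),
    ref = "A", alt = "T"))
}
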