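test_that("geno_matrix validates calls and locus metadata", {
  expect_error(geno_matrix(matrix(3L, 1, 1),
                           data.frame(chrom = "c1", pos = 1)),
               "calls must be")
  expect_error(geno_matrix(matrix(0L, 1, 1),
                           data.frame(chrom = "c1", pos = 0)),
               "positions")
  expect_error(geno_matrix(matrix(0L, 1, 1),
                           data.frame(chrom = "c1", pos = 1,
                                      ref = "A", alt = "A")),
               "differ")
  gm <- toy_gm()
  expect_equal(dim(gm), c(4L, 5L))
  expect_equal(unname(sample_missingness(gm)), c(0, 0.2, 0, 0.2))
})

test_that("VCF encoding: dosage, missing and phase conventions", {
  vcf <- file.path(tempdir(), "enc.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("c1", "100", ".", "A", "T", ".", "PASS", ".", "GT",
          "0/1", "1|1", sep = "\t"),
    paste("c1", "200", ".", "G", "C", ".", "PASS", ".", "GT",
          "./.", "0/0", sep = "\t")
  ), vcf)
  gm <- read_vcf(vcf)
  expect_equal(unname(gm$calls["s1", ]), c(1L, NA))
  expect_equal(unname(gm$calls["s2", ]), c(2L, 0L))
  expect_equal(gm$loci$pos, c(100, 200))
})

test_that("non-SNP and multiallelic records are skipped with a count", {
  vcf <- file.path(tempdir(), "tri.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("c1", "100", ".", "A", "T", ".", "PASS", ".", "GT", "0/1",
          sep = "\t"),
    paste("c1", "200", ".", "A", "T,G", ".", "PASS", ".", "GT", "1/2",
          sep = "\t"),
    paste("c1", "300", ".", "A", "C", ".", "PASS", ".", "GT", "1/1",
          sep = "\t")
  ), vcf)
  expect_message(gm <- read_vcf(vcf), "1 non-SNP")
  expect_equal(nrow(gm$loci), 2)
  expect_equal(gm$loci$pos, c(100, 300))
})

test_that("matrix -> VCF -> matrix round-trip is the identity", {
  gm <- toy_gm()
  path <- file.path(tempdir(), "rt.vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(unname(back$calls), unname(gm$calls))
  expect_equal(back$loci$pos, gm$loci$pos)
  expect_equal(back$loci$chrom, gm$loci$chrom)
  expect_equal(sample_ids(back), sample_ids(gm))
  # encoding conservation: non-missing call count invariant
  expect_equal(sum(!is.na(back$calls)), sum(!is.na(gm$calls)))
})

test_that("panel metadata parsing enforces labels and flags orphans", {
  path <- file.path(tempdir(), "panel.tsv")
  readr::write_tsv(tibble::tibble(
    id = c("s1", "s2", "s3", "inc1"),
    role = c("reference", "reference", "reference", "incursive"),
    population_label = c("Bali", "Bali", "Bali", NA)
  ), path)
  panel <- read_panel_metadata(path)
  expect_equal(panel_ids(panel, "Bali"), c("s1", "s2", "s3"))
  expect_equal(panel$incursives, "inc1")

  bad <- file.path(tempdir(), "bad.tsv")
  readr::write_tsv(tibble::tibble(
    id = "s1", role = "reference", population_label = ""), bad)
  expect_error(read_panel_metadata(bad), "lacking a population label")

  dup <- file.path(tempdir(), "dup.tsv")
  readr::write_tsv(tibble::tibble(
    id = c("s1", "s1"), role = "incursive", population_label = NA), dup)
  expect_error(read_panel_metadata(dup), "duplicate")

  orphan <- file.path(tempdir(), "orphan.tsv")
  readr::write_tsv(tibble::tibble(
    id = c("s1", "ghost"), role = "reference",
    population_label = "Bali"), orphan)
  gm <- toy_gm()
  expect_warning(p2 <- read_panel_metadata(orphan, gm), "ghost")
  expect_equal(p2$reference$id, "s1")
})

test_that("assignment report round-trips through TSV", {
  report <- tibble::tibble(
    id = c("inc1", "inc2"),
    final_assignment = c("A", "B"),
    posterior_top = c(0.812345678, 0.5),
    relative_probability = c(3.25, 1.0),
    missingness = c(0.1, 0.2),
    confidence = c("WELL_ASSIGNED", "POORLY_ASSIGNED"),
    post_A = c(0.812345678, 0.5),
    post_B = c(0.187654322, 0.5)
  )
  path <- file.path(tempdir(), "report.tsv")
  write_report(report, path)
  back <- read_report(path)
  expect_equal(nrow(back), 2)
  # posterior columns named by population, values kept to 6 decimals
  expect_true(all(c("post_A", "post_B") %in% names(back)))
  expect_equal(back$post_A, report$post_A, tolerance = 1e-6)
  expect_equal(back$confidence, report$confidence)
})

test_that("plain-table genotype dialect loads", {
  gdir <- tempdir()
  gpath <- file.path(gdir, "geno.tsv")
  lpath <- file.path(gdir, "loci.tsv")
  readr::write_tsv(tibble::tibble(id = c("a", "b"), l1 = c(0L, 2L),
                                  l2 = c(NA, 1L)), gpath)
  readr::write_tsv(tibble::tibble(id = c("l1", "l2"), chrom = "c1",
                                  pos = c(10, 300000)), lpath)
  gm <- read_geno_table(gpath, lpath)
  expect_equal(unname(gm$calls["b", ]), c(2L, 1L))
  expect_true(is.na(gm$calls["a", 2]))
})
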