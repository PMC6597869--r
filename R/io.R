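#' Read genotypes from a VCF file
#'
#' Parses GT fields into alt-allele dosages. Only biallelic SNP records are
#' kept; multiallelic or indel records are skipped with a message giving
#' the count. `./.` (or `.|.`) becomes a missing call; phase separators are
#' collapsed, so `0|1` and `0/1` are equivalent.
#'
#' @param path Path to a VCF (v4.x) file, plain or gzipped.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf))
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "."
  n_skip <- sum(!is_snp)
  if (n_skip > 0) {
    message(n_skip, " non-SNP or multiallelic record(s) skipped")
  }
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[is_snp, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dos[gt %in% c("0/0")] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt %in% c("1/1")] <- 2L
  fix <- fix[is_snp, , drop = FALSE]
  geno_matrix(
    t(dos),
    loci = tibble::tibble(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                          ref = fix$REF, alt = fix$ALT),
    samples = colnames(gt)
  )
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal plain-text VCF v4.2 with GT-only genotype fields, one
#' biallelic SNP per record, loci in their stored order. Round-trips
#' through [read_vcf()] exactly.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  g <- t(gm$calls)
  body <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  body[ok] <- gt_code[as.character(g[ok])]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=incursr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t"),
    paste(gm$loci$chrom, format(gm$loci$pos, scientific = FALSE,
                                trim = TRUE),
          gm$loci$id, gm$loci$ref, gm$loci$alt, ".", "PASS", ".", "GT",
          apply(body, 1, paste, collapse = "\t"),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain genotype table
#'
#' Alternative input dialect for small fixtures: a delimited table of
#' dosages with sample ids in the first column and one column per locus,
#' plus a locus sidecar table with columns `id`, `chrom`, `pos` (and
#' optionally `ref`, `alt`) in the same locus order.
#'
#' @param geno_path Path to the dosage table (TSV/CSV; missing cells empty
#'   or `NA`).
#' @param loci_path Path to the locus sidecar table.
#' @return A [geno_matrix()].
#' @export
read_geno_table <- function(geno_path, loci_path) {
  g <- readr::read_delim(geno_path, show_col_types = FALSE)
  loci <- readr::read_delim(loci_path, show_col_types = FALSE)
  ids <- as.character(g[[1]])
  m <- as.matrix(g[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  geno_matrix(m, loci = loci, samples = ids)
}

#' Read panel metadata
#'
#' Expects a delimited table with columns `id`, `role`
#' (`reference`/`incursive`) and `population_label` (required for
#' reference rows); any further columns (location, date, terminal, `vssc`)
#' are kept as metadata.
#'
#' @param path Path to a TSV or CSV file.
#' @param gm Optional [geno_matrix()]; if supplied, ids absent from it are
#'   reported with a warning and dropped.
#' @return A [sample_panel()].
#' @export
read_panel_metadata <- function(path, gm = NULL) {
  meta <- readr::read_delim(path, show_col_types = FALSE)
  need <- c("id", "role")
  if (!all(need %in% names(meta))) {
    stop("panel metadata must have columns 'id' and 'role'")
  }
  if (anyDuplicated(meta$id)) {
    stop("duplicate ids in panel metadata: ",
         paste(meta$id[duplicated(meta$id)], collapse = ", "))
  }
  is_ref <- meta$role == "reference"
  lab <- if ("population_label" %in% names(meta)) {
    meta$population_label
  } else {
    rep(NA_character_, nrow(meta))
  }
  if (any(is_ref & (is.na(lab) | lab == ""))) {
    stop("reference rows lacking a population label: ",
         paste(meta$id[is_ref & (is.na(lab) | lab == "")], collapse = ", "))
  }
  panel <- sample_panel(
    reference = tibble::tibble(id = meta$id[is_ref], label = lab[is_ref]),
    incursives = meta$id[meta$role == "incursive"],
    metadata = meta
  )
  if (!is.null(gm)) panel <- validate_panel(panel, gm)
  panel
}

#' Write an assignment report
#'
#' One row per incursive with the cluster assignment at each K, the final
#' assignment, the full posterior vector (one column per population,
#' named `post_<label>`), relative probability, missingness, confidence
#' class and Vssc resistance class. Deterministic column order;
#' round-trippable with [read_report()].
#'
#' @param report A tibble as produced by [run_incursion_trace()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  fixed <- intersect(
    c("id", "final_assignment", "posterior_top", "posterior_second",
      "relative_probability", "missingness", "consistent_across_k",
      "methods_agree", "confidence", "reasons", "vssc", "resistance_class"),
    names(report))
  post <- sort(grep("^post_", names(report), value = TRUE))
  kcols <- grep("^k[0-9]+$", names(report), value = TRUE)
  kcols <- kcols[order(as.integer(sub("^k", "", kcols)))]
  rest <- setdiff(names(report), c(fixed, post, kcols))
  out <- report[, c(fixed, post, kcols, rest)]
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.list), ~ purrr::map_chr(.x, paste, collapse = ";")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read back an assignment report
#' @param path Path written by [write_report()].
#' @return A tibble.
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
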