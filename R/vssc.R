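#' Parse a three-locus Vssc genotype string
#'
#' Genotypes at the three voltage-sensitive sodium channel (Vssc)
#' knockdown-resistance point mutations are written as three
#' slash-separated two-base fields in the fixed locus order
#' V1016G / F1534C / S989P, e.g. `"GG/TT/CC"`. Allowed bases are the
#' wild-type and mutant base of each locus (1016: T wild, G mutant;
#' 1534: T wild, G mutant; 989: T wild, C mutant). Heterozygotes are
#' order-normalized (wild base first).
#'
#' @param genotype_string A string like `"GG/TT/CC"`.
#' @return An object of class `vssc_genotype`: named character vector
#'   with elements `V1016G`, `F1534C`, `S989P`, each one of
#'   `"hom_wild"`, `"het"`, `"hom_mutant"`, plus attribute `bases` (the
#'   normalized string).
#' @export
#' @examples
#' parse_vssc("GG/TT/CC")
parse_vssc <- function(genotype_string) {
  loci <- c(V1016G = "G", F1534C = "G", S989P = "C")  # mutant bases
  wild <- c(V1016G = "T", F1534C = "T", S989P = "T")
  fields <- strsplit(genotype_string, "/", fixed = TRUE)[[1]]
  if (length(fields) != 3 || any(nchar(fields) != 2)) {
    stop("Vssc genotype must be three slash-separated two-base fields, ",
         "got '", genotype_string, "'")
  }
  states <- character(3)
  norm <- character(3)
  for (i in seq_len(3)) {
    b <- sort(strsplit(toupper(fields[i]), "")[[1]])
    allowed <- c(wild[i], loci[i])
    if (!all(b %in% allowed)) {
      stop("disallowed base(s) '", fields[i], "' at ", names(loci)[i],
           " (allowed: ", paste(allowed, collapse = "/"), ")")
    }
    n_mut <- sum(b == loci[i])
    states[i] <- c("hom_wild", "het", "hom_mutant")[n_mut + 1]
    norm[i] <- if (n_mut == 1) paste0(wild[i], loci[i]) else
      paste0(b, collapse = "")
  }
  out <- stats::setNames(states, names(loci))
  attr(out, "bases") <- paste(norm, collapse = "/")
  class(out) <- "vssc_genotype"
  out
}

#' @export
print.vssc_genotype <- function(x, ...) {
  cat("<vssc_genotype>", attr(x, "bases"), "\n")
  for (l in names(unclass(x))) cat(" ", l, ":", x[[l]], "\n")
  invisible(x)
}

#' Default resistance rule table
#'
#' Maps three-locus Vssc genotype states to pyrethroid-resistance
#' classes: homozygous mutant V1016G confers strong resistance to Type I
#' and Type II synthetic pyrethroids (homozygous S989P acts as a Type-II
#' synergist but has no effect alone); homozygous mutant F1534C with
#' wild-type 1016 confers strong Type I resistance; fully wild-type is
#' susceptible; heterozygous combinations are of intermediate or unknown
#' resistance status.
#'
#' @return A list with elements `classes` (documentation of the mapping)
#'   and `strong_type_I` rule. Users can pass an edited copy to
#'   [classify_resistance()].
#' @export
vssc_rules <- function() {
  list(
    type_I_and_II = "V1016G hom_mutant",
    type_I = "F1534C hom_mutant with V1016G hom_wild",
    susceptible = "all loci hom_wild",
    strong_type_I = "hom_mutant at V1016G or at F1534C"
  )
}

#' Classify pyrethroid-resistance phenotype
#'
#' @param g A `vssc_genotype` from [parse_vssc()] (or a genotype string,
#'   parsed on the fly).
#' @param rules Rule table (default [vssc_rules()]; present for users
#'   who want to refine the heterozygote classes).
#' @return A list: `class` — one of `"TYPE_I_AND_II_STRONG"`,
#'   `"TYPE_I_STRONG"`, `"SUSCEPTIBLE"`, `"INTERMEDIATE_OR_UNKNOWN"` —
#'   and `strong_type_I` (logical: homozygous mutant at 1016 or 1534).
#' @export
#' @examples
#' classify_resistance("GG/TT/CC")$class  # strong Type I + II
#' classify_resistance("TT/GG/TT")$class  # strong Type I
#' classify_resistance("TT/TT/TT")$class  # susceptible
classify_resistance <- function(g, rules = vssc_rules()) {
  if (is.character(g)) g <- parse_vssc(g)
  s <- unclass(g)
  cls <- if (s[["V1016G"]] == "hom_mutant") {
    "TYPE_I_AND_II_STRONG"
  } else if (s[["F1534C"]] == "hom_mutant" && s[["V1016G"]] == "hom_wild") {
    "TYPE_I_STRONG"
  } else if (all(s == "hom_wild")) {
    "SUSCEPTIBLE"
  } else {
    "INTERMEDIATE_OR_UNKNOWN"
  }
  list(class = cls,
       strong_type_I = s[["V1016G"]] == "hom_mutant" ||
         s[["F1534C"]] == "hom_mutant")
}

#' Apply the incursive-definition rule
#'
#' An individual is incursive iff (a) it was collected outside the
#' species' endemic region, or (b) it was collected inside the endemic
#' region but carries a resistance (mutant) allele not normally found in
#' local populations.
#'
#' @param region Region label of the collection location (e.g.
#'   `"Queensland"`); must not be `NA`.
#' @param g A `vssc_genotype` or genotype string.
#' @param endemic_region Character vector of region labels where the
#'   species is endemic.
#' @param local_alleles Mutant alleles normally present locally, a
#'   subset of `c("V1016G", "F1534C", "S989P")` (default none — local
#'   populations carry no resistance mutations).
#' @return Logical: is the individual an incursive?
#' @export
incursive_status <- function(region, g, endemic_region = "Queensland",
                             local_alleles = character()) {
  if (is.na(region) || !nzchar(region)) {
    stop("collection region must be labelled")
  }
  if (!region %in% endemic_region) return(TRUE)
  if (is.character(g)) g <- parse_vssc(g)
  s <- unclass(g)
  carried <- names(s)[s %in% c("het", "hom_mutant")]
  length(setdiff(carried, local_alleles)) > 0
}

#' Classify resistance for a cohort
#'
#' @param genotype_strings Character vector of Vssc genotype strings
#'   (`NA` allowed, reported as `NA` class).
#' @return A tibble: `vssc`, `resistance_class`, `strong_type_I`.
#' @export
classify_resistance_cohort <- function(genotype_strings) {
  purrr::map_dfr(genotype_strings, function(gs) {
    if (is.na(gs)) {
      return(tibble::tibble(vssc = NA_character_,
                            resistance_class = NA_character_,
                            strong_type_I = NA))
    }
    r <- classify_resistance(gs)
    tibble::tibble(vssc = gs, resistance_class = r$class,
                   strong_type_I = r$strong_type_I)
  })
}
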