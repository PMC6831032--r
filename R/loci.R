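#' Locus specification
#'
#' Describes one amplified locus: its name, genomic category and aligned
#' length, plus the per-locus singleton-collapse threshold used during clone
#' curation (the maximum number of differences at which a single-clone
#' sequence is absorbed into a better-supported allele).  Thresholds follow
#' the "<0.5% of the aligned length" rule, so `collapse_threshold / length`
#' must stay below 0.005.
#'
#' @param name Locus name, e.g. `"EF1a"`.
#' @param category `"nuclear"` or `"mito"`.
#' @param length Aligned length in sites (primer-binding regions excluded).
#' @param collapse_threshold Maximum Hamming differences for singleton
#'   absorption.
#' @param expected_alleles Alleles a normal individual is expected to carry:
#'   2 for a diploid nuclear locus; for mitochondrial loci 2 when the assay
#'   amplifies the doubly-uniparental male lineage alongside the female one,
#'   1 when it amplifies the female genome only.  Counts above this are the
#'   anomaly signature used by the lineage-detection stage.
#' @return An object of class `locus_spec`.
#' @examples
#' locus_spec("EF1a", "nuclear", 516, 2)
#' @export
locus_spec <- function(name, category = c("nuclear", "mito"), length,
                       collapse_threshold, expected_alleles = 2L) {
  category <- match.arg(category)
  stopifnot(length >= 1, collapse_threshold >= 0, expected_alleles >= 1)
  if (collapse_threshold / length >= 0.005) {
    warning("collapse_threshold/length >= 0.5% at locus ", name,
            "; inconsistent with the <0.5% singleton-collapse rule")
  }
  structure(
    list(name = name, category = category, length = as.integer(length),
         collapse_threshold = as.integer(collapse_threshold),
         expected_alleles = as.integer(expected_alleles)),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus %s: %s, %d aligned sites, collapse threshold %d>\n",
              x$name, x$category, x$length, x$collapse_threshold))
  invisible(x)
}

#' Default four-locus panel
#'
#' The two nuclear loci (elongation factor 1 alpha intron region, histone H4)
#' and two mitochondrial loci (control region, COI) used to genotype Mytilus
#' individuals.  Collapse thresholds are 2 differences for the nuclear loci
#' and 3 for mtCR; mtCOI is not assigned a published threshold and defaults
#' to the mtCR value (documented assumption).
#'
#' @return Named list of [locus_spec()] objects.
#' @export
default_loci <- function() {
  list(
    EF1a  = locus_spec("EF1a",  "nuclear", 516, 2),
    H4    = locus_spec("H4",    "nuclear", 444, 2),
    mtCR  = locus_spec("mtCR",  "mito",    720, 3),
    mtCOI = locus_spec("mtCOI", "mito",    660, 3, expected_alleles = 1)
  )
}

nuclear_loci <- function(loci) loci[vapply(loci, function(l) l$category == "nuclear", logical(1))]
mito_loci    <- function(loci) loci[vapply(loci, function(l) l$category == "mito", logical(1))]
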