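# Diagnostic-SNP (KASP) panel analysis.  Each locus yields two endpoint
# fluorescence values: x for the host allele and y for the cancer-source-
# species (M. trossulus) allele.  The transform y' = y/(x+y) maps them to a
# per-locus trossulus fraction; the compound multi-locus estimate is the
# mean of y' over the panel's loci.

#' KASP fluorescence transform
#'
#' `y' = y / (x + y)`: 0 when the host-allele fluorescence dominates, 1 when
#' the trossulus-allele fluorescence dominates.  Scale-invariant in (x, y).
#'
#' @param x Host-allele fluorescence (>= 0).
#' @param y Trossulus-allele fluorescence (>= 0).
#' @return y' in [0, 1]; `NA` for missing records (x + y = 0).
#' @export
kasp_transform <- function(x, y) {
  stopifnot(all(x >= 0, na.rm = TRUE), all(y >= 0, na.rm = TRUE))
  out <- y / (x + y)
  out[(x + y) == 0] <- NA_real_
  out
}

#' Compound multi-locus estimate per sample
#'
#' Computes y' per record and averages it over each sample's available loci
#' (missing records excluded from the mean and counted).
#'
#' @param records Data frame: sample, locus, x, y.
#' @return A `panel_result` data frame: sample, compound (mean y'),
#'   n_loci, n_missing, plus the per-locus y' in attribute `y_prime`
#'   (samples x loci matrix).
#' @export
compound_estimate <- function(records) {
  records$y_prime <- kasp_transform(records$x, records$y)
  samples <- unique(records$sample)
  loci <- unique(records$locus)
  yp <- matrix(NA_real_, length(samples), length(loci),
               dimnames = list(samples, loci))
  for (i in seq_len(nrow(records))) {
    yp[records$sample[i], records$locus[i]] <- records$y_prime[i]
  }
  ok_counts <- rowSums(!is.na(yp))
  if (any(ok_counts == 0)) {
    stop("sample(s) with no valid locus: ",
         paste(samples[ok_counts == 0], collapse = ", "))
  }
  out <- data.frame(sample = samples,
                    compound = rowMeans(yp, na.rm = TRUE),
                    n_loci = ok_counts,
                    n_missing = rowSums(is.na(yp)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "y_prime") <- yp
  class(out) <- c("panel_result", "data.frame")
  out
}

#' Classify samples from the diagnostic-SNP panel
#'
#' The signal count is the number of loci with `y' >= signal_threshold`.
#' Because incomplete lineage sorting and introgression let a non-hybrid
#' individual be heterozygous at one — very rarely two — diagnostic loci,
#' but never more, the classification is: `normal` for a signal count of at
#' most 1, `introgressed-normal` below `positive_min_loci`, and
#' `BTN-positive` at `positive_min_loci` (default 3) or more.
#'
#' @param result A [compound_estimate()] result.
#' @param signal_threshold y' at or above which a locus counts as signal
#'   (default 0.2, separating the host-homozygote cluster near 0 from the
#'   heterozygote cluster near 0.5).
#' @param positive_min_loci Minimum signal count for a BTN-positive call.
#' @return `result` with added `signal_count` and `classification` columns.
#' @export
classify_panel <- function(result, signal_threshold = 0.2,
                           positive_min_loci = 3) {
  yp <- attr(result, "y_prime")
  cnt <- rowSums(yp >= signal_threshold, na.rm = TRUE)
  result$signal_count <- as.integer(cnt[result$sample])
  result$classification <- ifelse(
    result$signal_count >= positive_min_loci, "BTN-positive",
    ifelse(result$signal_count <= 1, "normal", "introgressed-normal"))
  result
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("<SNP panel result: %d samples, %d loci%s>\n", nrow(x),
              ncol(attr(x, "y_prime")),
              if ("classification" %in% names(x))
                sprintf("; %d BTN-positive",
                        sum(x$classification == "BTN-positive")) else ""))
  print(utils::head(data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more samples\n")
  invisible(x)
}

#' Strip chart of per-locus and compound trossulus fractions
#'
#' @param x A classified `panel_result`.
#' @param ... Passed to [graphics::stripchart()].
#' @export
plot.panel_result <- function(x, ...) {
  yp <- attr(x, "y_prime")
  vals <- c(as.vector(yp), x$compound)
  grp <- factor(rep(c(colnames(yp), "compound"),
                    times = c(rep(nrow(yp), ncol(yp)), nrow(x))),
                levels = c(colnames(yp), "compound"))
  graphics::stripchart(vals ~ grp, vertical = TRUE, pch = 1,
                       method = "jitter", las = 2,
                       ylab = "trossulus fluorescence fraction y'", ...)
  graphics::abline(h = 0.2, lty = 2)
  invisible(x)
}
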