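# Allele-specific qPCR quantification: standard curves, Cq-to-copies
# inversion, cancer-allele fractions with the detection rules (10
# copies/reaction limit of detection for allele-specific reactions; samples
# discarded when any universal reaction yields < 5000 copies/reaction, an
# upper limit of detection of 10/5000 = 0.2%).

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10 copies over a serial dilution
#' (canonically 1e1..1e7 copies in triplicate).  Amplification efficiency is
#' derived as `10^(-1/slope) - 1` (1.0 at the perfect-doubling slope of
#' -log2(10) = -3.3219) and flagged when outside [0.6, 1.2].
#'
#' @param copies Vector of known standard copy numbers per reaction.
#' @param cq Measured Cq values (same length).
#' @return A `standard_curve`: slope, intercept, efficiency, dynamic range,
#'   flags.
#' @export
fit_standard_curve <- function(copies, cq) {
  stopifnot(length(copies) == length(cq))
  if (length(unique(copies)) < 3) stop("need at least 3 dilution points")
  fit <- stats::lm(cq ~ log10(copies))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) warning("standard-curve slope is non-negative")
  efficiency <- 10^(-1 / slope) - 1
  means <- tapply(cq, copies, mean)
  monotone <- all(diff(means[order(as.numeric(names(means)))]) < 0)
  if (!monotone) warning("mean Cq is not monotone decreasing in copy number")
  structure(
    list(slope = slope, intercept = intercept, efficiency = efficiency,
         efficiency_flag = efficiency < 0.6 || efficiency > 1.2,
         monotone = monotone, dynamic_range = range(copies),
         r_squared = suppressWarnings(summary(fit)$r.squared)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard curve: slope %.4f, intercept %.2f, efficiency %.1f%%%s>\n",
              x$slope, x$intercept, 100 * x$efficiency,
              if (x$efficiency_flag) " [FLAGGED]" else ""))
  invisible(x)
}

#' Convert Cq triplicates to mean copies/reaction
#'
#' Inverts the standard curve per replicate (`copies = 10^((Cq - intercept)
#' / slope)`) and averages.
#'
#' @param cq Vector of replicate Cq values.
#' @param curve A [fit_standard_curve()] object.
#' @return Mean copies, with attribute `extrapolated` when any replicate
#'   falls outside the curve's dynamic range.
#' @export
cq_to_copies <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  copies <- 10^((cq - curve$intercept) / curve$slope)
  extrapolated <- any(copies < curve$dynamic_range[1] |
                        copies > curve$dynamic_range[2])
  structure(mean(copies), extrapolated = extrapolated)
}

#' Cancer-allele fraction with detection rules
#'
#' The fraction is the mean allele-specific copies divided by the mean
#' universal copies.  Status logic (total — every record gets exactly one):
#' `sample_discarded` when the universal reaction yields fewer than
#' `universal_floor` copies/reaction; otherwise `undetectable` when the
#' allele-specific mean is below `lod` copies/reaction; otherwise
#' `over_unity` when the fraction exceeds 1 (the tandem-repeat signature);
#' otherwise `detected`.  Every undetectable record reports the upper limit
#' of detection `lod / universal_floor` (0.2% at the defaults).
#'
#' @param specific Mean allele-specific copies/reaction.
#' @param universal Mean universal copies/reaction.
#' @param lod Allele-specific limit of detection (copies/reaction).
#' @param universal_floor Minimum universal copies/reaction.
#' @return One-row data frame: specific, universal, fraction, status,
#'   upper_lod.
#' @export
allele_fraction <- function(specific, universal, lod = 10,
                            universal_floor = 5000) {
  fraction <- if (universal > 0) specific / universal else NA_real_
  status <- if (universal < universal_floor) {
    "sample_discarded"
  } else if (specific < lod) {
    "undetectable"
  } else if (fraction > 1) {
    "over_unity"
  } else {
    "detected"
  }
  data.frame(specific = specific, universal = universal, fraction = fraction,
             status = status, upper_lod = lod / universal_floor,
             stringsAsFactors = FALSE)
}

#' Per-sample allele fractions from a long plate table
#'
#' Accepts a plate in copies (columns sample, locus, target, replicate,
#' copies) — or in Cq plus a fitted standard curve per target — and
#' computes one [allele_fraction()] row per sample x locus x allele-specific
#' target.  The universal-floor rule is evaluated per locus but discards the
#' whole sample: if any universal reaction of a sample falls below the
#' floor, every record of that sample gets status `sample_discarded`.
#'
#' @param plate Long data frame; `target` is `"universal"` or an allele
#'   label.
#' @param curves Optional named list of [fit_standard_curve()] objects (by
#'   target) when the plate reports `cq` instead of `copies`.
#' @param lod,universal_floor Rule constants.
#' @return An `allele_fraction` data frame: sample, locus, allele, specific,
#'   universal, fraction, status, upper_lod.
#' @export
allele_fraction_table <- function(plate, curves = NULL, lod = 10,
                                  universal_floor = 5000) {
  if (!"copies" %in% names(plate)) {
    if (is.null(curves) || !"cq" %in% names(plate)) {
      stop("plate must have a 'copies' column, or 'cq' plus standard curves")
    }
    plate$copies <- NA_real_
    for (tg in unique(plate$target)) {
      cv <- curves[[tg]] %||% curves[[1]]
      idx <- plate$target == tg
      plate$copies[idx] <- 10^((plate$cq[idx] - cv$intercept) / cv$slope)
    }
  }
  agg <- stats::aggregate(copies ~ sample + locus + target, data = plate,
                          FUN = mean)
  rows <- list()
  for (sm in unique(agg$sample)) {
    sub <- agg[agg$sample == sm, ]
    uni <- sub[sub$target == "universal", ]
    discarded <- any(uni$copies < universal_floor)
    for (i in which(sub$target != "universal")) {
      lc <- sub$locus[i]
      u <- uni$copies[uni$locus == lc]
      if (length(u) == 0) u <- 0
      af <- allele_fraction(sub$copies[i], u[1], lod, universal_floor)
      if (discarded) af$status <- "sample_discarded"
      rows[[length(rows) + 1]] <- cbind(
        data.frame(sample = sm, locus = lc, allele = sub$target[i],
                   stringsAsFactors = FALSE), af)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("allele_fraction_table", "data.frame")
  out
}

#' Fraction heat-matrix with undetectable rendering
#'
#' Individuals x (locus:allele) matrix of fraction values rendered as
#' percent strings, with `"U"` for undetectable and `"X"` for discarded
#' samples, mirroring the tabular heat-map convention.
#'
#' @param fractions Output of [allele_fraction_table()].
#' @param digits Digits for the percent rendering.
#' @return Character matrix; the numeric fractions are attached as attribute
#'   `values`.
#' @export
fraction_matrix <- function(fractions, digits = 1) {
  cols <- unique(paste(fractions$locus, fractions$allele, sep = ":"))
  samples <- unique(fractions$sample)
  m <- matrix("", length(samples), length(cols),
              dimnames = list(samples, cols))
  v <- matrix(NA_real_, length(samples), length(cols),
              dimnames = list(samples, cols))
  for (i in seq_len(nrow(fractions))) {
    r <- fractions$sample[i]
    cc <- paste(fractions$locus[i], fractions$allele[i], sep = ":")
    m[r, cc] <- switch(fractions$status[i],
                       undetectable = "U",
                       sample_discarded = "X",
                       sprintf(paste0("%.", digits, "f%%"),
                               100 * fractions$fraction[i]))
    v[r, cc] <- fractions$fraction[i]
  }
  attr(m, "values") <- v
  m
}

#' Classify samples as lineage-negative from an all-undetectable profile
#'
#' A diseased sample in which every assayed cancer-associated allele is
#' undetectable at every locus carries none of the lineage's markers; with
#' a cancer diagnosis from histology this is non-lineage neoplasia.
#'
#' @param fractions Output of [allele_fraction_table()].
#' @param sheet Sample sheet data frame (id, diagnosis).
#' @return Data frame: sample, diagnosis, n_detected, classification.
#' @export
qpcr_classify <- function(fractions, sheet) {
  rows <- lapply(unique(fractions$sample), function(sm) {
    sub <- fractions[fractions$sample == sm, ]
    ndet <- sum(sub$status %in% c("detected", "over_unity"))
    dg <- sheet$diagnosis[match(sm, sheet$id)]
    cls <- if (all(sub$status == "sample_discarded")) {
      "sample_discarded"
    } else if (ndet > 0) {
      "lineage-positive"
    } else if (identical(dg, "cancer")) {
      "non-lineage neoplasia"
    } else {
      "negative"
    }
    data.frame(sample = sm, diagnosis = dg %||% NA_character_,
               n_detected = ndet, classification = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
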