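# Formats and the pipeline driver.  FASTA via Biostrings; tabular formats
# are plain TSV/CSV; configuration and truth are JSON.

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Records must be equal length (an alignment).  Labels following the
#' `<individual>-<alleleID>` convention are parsed into individual and
#' allele components; other labels are kept opaque.
#'
#' @param path FASTA path.
#' @param label_regex Regex with two capture groups (individual, allele).
#' @return An `allele_alignment`: named character vector `seqs` plus
#'   parallel `individual` and `allele` vectors.
#' @export
read_alignment <- function(path, label_regex = "^(.+)-([^-]+)$") {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  w <- nchar(seqs)
  if (length(unique(w)) != 1) {
    bad <- names(seqs)[w != stats::median(w)]
    stop("ragged alignment; offending record(s): ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate labels: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  m <- regmatches(names(seqs), regexec(label_regex, names(seqs)))
  ind <- vapply(m, function(g) if (length(g) == 3) g[2] else NA_character_,
                character(1))
  al <- vapply(m, function(g) if (length(g) == 3) g[3] else NA_character_,
               character(1))
  structure(list(seqs = seqs, individual = ind, allele = al),
            class = "allele_alignment")
}

#' @export
print.allele_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d sequences x %d sites>\n", length(x$seqs),
              nchar(x$seqs[1])))
  invisible(x)
}

#' Read a cohort sample sheet (TSV)
#'
#' Columns: id, species, site, diagnosis (normal | cancer | unknown).
#' IDs must be unique; diagnosis values are restricted.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "diagnosis")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("duplicate individual IDs in sample sheet")
  bad <- setdiff(unique(df$diagnosis), c("normal", "cancer", "unknown"))
  if (length(bad) > 0) stop("invalid diagnosis value(s): ", paste(bad, collapse = ", "))
  df
}

#' Run configuration
#'
#' Bundles the rule constants of the whole pipeline; serialized as JSON with
#' every run for reproducibility.
#'
#' @param loci Named list of [locus_spec()] objects.
#' @param near_match_radius Lineage near-match radius (differences).
#' @param lod qPCR allele-specific limit of detection (copies/reaction).
#' @param universal_floor qPCR universal-reaction floor (copies/reaction).
#' @param signal_threshold KASP y' signal threshold.
#' @param positive_min_loci KASP minimum signal loci for a positive call.
#' @param min_profile_loci Minimum loci with clone-based profile evidence
#'   for a lineage-positive call (multi-locus concordance).
#' @param seed Base seed recorded with the run.
#' @return A `btn_config` list.
#' @export
btn_config <- function(loci = default_loci(), near_match_radius = 1,
                       lod = 10, universal_floor = 5000,
                       signal_threshold = 0.2, positive_min_loci = 3,
                       min_profile_loci = 2, seed = NULL) {
  stopifnot(near_match_radius >= 0, lod > 0, universal_floor > 0,
            signal_threshold > 0, positive_min_loci > 0,
            min_profile_loci > 0)
  structure(list(loci = loci, near_match_radius = near_match_radius,
                 lod = lod, universal_floor = universal_floor,
                 signal_threshold = signal_threshold,
                 positive_min_loci = positive_min_loci,
                 min_profile_loci = min_profile_loci, seed = seed),
            class = "btn_config")
}

config_json <- function(config) {
  jsonlite::toJSON(list(
    loci = lapply(config$loci, unclass),
    near_match_radius = config$near_match_radius, lod = config$lod,
    universal_floor = config$universal_floor,
    signal_threshold = config$signal_threshold,
    positive_min_loci = config$positive_min_loci,
    min_profile_loci = config$min_profile_loci,
    seed = config$seed), auto_unbox = TRUE, digits = NA, null = "null")
}

# Assemble individual_genotype objects from curated calls and a sample sheet.
#' Build genotypes from curated allele calls
#'
#' @param calls_list List of `allele_calls` (each carrying individual and
#'   locus attributes, as returned by [call_alleles()]).
#' @param sheet Sample sheet data frame.
#' @return Named list of `individual_genotype` objects.
#' @export
build_genotypes <- function(calls_list, sheet) {
  ids <- vapply(calls_list, function(x) attr(x, "individual_id"), character(1))
  out <- list()
  for (id in unique(ids)) {
    row <- sheet[sheet$id == id, , drop = FALSE]
    if (nrow(row) == 0) stop("individual ", id, " missing from sample sheet")
    calls <- calls_list[ids == id]
    names(calls) <- vapply(calls, function(x) attr(x, "locus"), character(1))
    out[[id]] <- individual_genotype(
      id, row$species[1], row$site[1] %||% NA,
      diagnosis = if (row$diagnosis[1] == "cancer") "cancer" else "normal",
      calls = calls)
  }
  out
}

#' Run the full detection pipeline
#'
#' Executes clone curation, lineage detection, per-locus trees (optional),
#' mitochondrial breakpoint scanning (when parental references are given),
#' qPCR quantification (when a plate is given) and SNP-panel classification
#' (when KASP records are given), then reconciles all evidence streams into
#' one per-individual classification.  Stage failures are isolated: the
#' error is recorded and later stages still run on what is available.
#'
#' @param clone_sets List of `clone_set` objects (all individuals x loci).
#' @param sheet Sample sheet data frame.
#' @param config A [btn_config()].
#' @param qpcr_plate Optional long plate data frame (see
#'   [allele_fraction_table()]).
#' @param kasp_records Optional KASP data frame (sample, locus, x, y).
#' @param mito_parents Optional named list locus -> [parental_pair()].
#' @param build_trees Build per-locus NJ trees of the curated alleles.
#' @param verbose Log rule applications to stderr.
#' @return A `btn_run` object; see [print.btn_run()] and
#'   [summary.btn_run()].
#' @export
run_pipeline <- function(clone_sets, sheet, config = btn_config(),
                         qpcr_plate = NULL, kasp_records = NULL,
                         mito_parents = NULL, build_trees = FALSE,
                         verbose = FALSE) {
  log <- function(...) if (verbose) message("[mytBTN] ", sprintf(...))
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      log("stage %s failed: %s", name, conditionMessage(e))
      NULL
    })
  }

  calls_list <- run_stage("curation", {
    lapply(clone_sets, function(cs) {
      lc <- config$loci[[cs$locus]]
      if (is.null(lc)) stop("no locus spec for ", cs$locus)
      out <- call_alleles(cs, lc)
      log("curated %s x %s: %d clones -> %d alleles (%d chimera discarded)",
          cs$individual_id, cs$locus, length(cs$clones), nrow(out),
          length(attr(out, "discarded_chimeras")))
      out
    })
  })

  genotypes <- run_stage("genotypes", build_genotypes(calls_list, sheet))

  profile <- run_stage("lineage", {
    frags <- lapply(config$loci, function(lc) {
      find_shared_cancer_alleles(genotypes, lc, config$near_match_radius)
    })
    p <- lineage_profile(frags)
    merge_near_duplicates(p, config$near_match_radius)
  })

  trees <- NULL
  if (build_trees && !is.null(genotypes)) {
    trees <- run_stage("phylo", {
      out <- list()
      for (lc in names(config$loci)) {
        seqs <- unlist(lapply(genotypes, function(g) {
          if (!lc %in% names(g$calls)) return(NULL)
          stats::setNames(g$calls[[lc]]$sequence,
                          paste(g$individual_id, g$calls[[lc]]$label, sep = "-"))
        }))
        seqs <- seqs[!duplicated(seqs)]
        if (length(seqs) >= 3) {
          out[[lc]] <- midpoint_root(nj_tree(alignment_distances(seqs, "JC")))
        }
      }
      out
    })
  }

  breakpoints <- NULL
  if (!is.null(mito_parents) && !is.null(profile) && nrow(profile) > 0) {
    breakpoints <- run_stage("mitorec", {
      out <- list()
      for (lc in intersect(names(mito_parents), unique(profile$locus))) {
        sub <- profile[profile$locus == lc, ]
        for (j in seq_len(nrow(sub))) {
          bc <- find_breakpoint(sub$sequence[j], mito_parents[[lc]])
          out[[paste(lc, sub$label[j], sep = ":")]] <- bc
          log("breakpoint %s:%s -> %s", lc, sub$label[j], bc$verdict)
        }
      }
      out
    })
  }

  fractions <- NULL
  qpcr_class <- NULL
  if (!is.null(qpcr_plate)) {
    fractions <- run_stage("qpcr", {
      allele_fraction_table(qpcr_plate, lod = config$lod,
                            universal_floor = config$universal_floor)
    })
    if (!is.null(fractions)) {
      qpcr_class <- run_stage("qpcr_classify", qpcr_classify(fractions, sheet))
    }
  }

  panel <- NULL
  if (!is.null(kasp_records)) {
    panel <- run_stage("snppanel", {
      classify_panel(compound_estimate(kasp_records),
                     config$signal_threshold, config$positive_min_loci)
    })
  }

  classification <- run_stage("final", {
    base <- if (!is.null(genotypes) && !is.null(profile)) {
      classify_individuals(genotypes, profile, config$near_match_radius,
                           min_loci = min(config$min_profile_loci,
                                          length(config$loci)))
    } else {
      data.frame(id = sheet$id, species = sheet$species,
                 diagnosis = sheet$diagnosis, lineage_loci = 0L,
                 classification = ifelse(sheet$diagnosis == "cancer",
                                         "non-lineage neoplasia", "normal"),
                 stringsAsFactors = FALSE)
    }
    base$qpcr <- NA_character_
    base$kasp <- NA_character_
    if (!is.null(qpcr_class)) {
      base$qpcr <- qpcr_class$classification[match(base$id, qpcr_class$sample)]
    }
    if (!is.null(panel)) {
      base$kasp <- panel$classification[match(base$id, panel$sample)]
    }
    # reconcile: any positive evidence stream upgrades a diseased individual
    up <- base$diagnosis == "cancer" & base$classification != "lineage-positive" &
      (base$qpcr %in% "lineage-positive" | base$kasp %in% "BTN-positive")
    base$classification[up] <- "lineage-positive"
    base
  })

  structure(
    list(config = config, calls = calls_list, genotypes = genotypes,
         profile = profile, trees = trees, breakpoints = breakpoints,
         fractions = fractions, qpcr_class = qpcr_class, panel = panel,
         classification = classification, errors = errors,
         config_json = config_json(config)),
    class = "btn_run"
  )
}

#' @export
print.btn_run <- function(x, ...) {
  cat("Bivalve transmissible neoplasia detection run\n")
  if (!is.null(x$genotypes)) {
    cat(sprintf("  %d genotyped individuals\n", length(x$genotypes)))
  }
  if (!is.null(x$profile) && nrow(x$profile) > 0) {
    cat(sprintf("  lineage profile: %d cancer-associated alleles over %d loci\n",
                nrow(x$profile), length(unique(x$profile$locus))))
  } else {
    cat("  no cancer lineage detected\n")
  }
  if (!is.null(x$classification)) {
    tab <- table(x$classification$classification)
    cat("  classifications:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (length(x$errors) > 0) {
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.btn_run <- function(object, ...) {
  print(object)
  if (!is.null(object$profile) && nrow(object$profile) > 0) {
    print(object$profile)
  }
  if (!is.null(object$classification)) {
    print(object$classification, row.names = FALSE)
  }
  invisible(object)
}

#' Write the run's report bundle
#'
#' Emits the profile FASTA, classification TSV, fraction matrix TSV, panel
#' TSV and the serialized configuration.
#'
#' @param run A `btn_run`.
#' @param dir Output directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(run$profile) && nrow(run$profile) > 0) {
    write_fasta(stats::setNames(run$profile$sequence,
                                paste(run$profile$locus, run$profile$label,
                                      sep = "-")),
                file.path(dir, "lineage_profile.fasta"))
  }
  if (!is.null(run$classification)) {
    utils::write.table(run$classification,
                       file.path(dir, "classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$fractions)) {
    m <- fraction_matrix(run$fractions)
    utils::write.table(cbind(sample = rownames(m), as.data.frame(m)),
                       file.path(dir, "fraction_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$panel)) {
    utils::write.table(data.frame(run$panel),
                       file.path(dir, "snp_panel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$trees)) {
    for (lc in names(run$trees)) {
      ape::write.tree(run$trees[[lc]],
                      file.path(dir, sprintf("tree_%s.nwk", lc)))
    }
  }
  writeLines(run$config_json, file.path(dir, "config.json"))
  invisible(dir)
}
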