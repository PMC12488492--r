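#' Read a microbiome time-series study from five tab-delimited tables
#'
#' The study format follows the field convention of five TSV inputs:
#' \describe{
#'   \item{taxa}{one row per taxon: `id`, optional `sequence`, optional
#'     taxonomy columns among `kingdom, phylum, class, order, family, genus,
#'     species` (coarse to fine).}
#'   \item{counts}{column `id` (taxon) plus one column per sample id; cells
#'     are non-negative integer read counts.}
#'   \item{metadata}{columns `sampleID`, `subject`, `time` (days) mapping
#'     samples to subjects and timepoints.}
#'   \item{qpcr}{long format: `sampleID`, `replicate`, `value` (cfu/g);
#'     replicate counts may vary by sample and samples may be absent
#'     (reads-only fallback applies during inference).}
#'   \item{perturbations}{columns `name`, `start`, `end` (days), `subject`;
#'     a perturbation is active on [start, end).}
#' }
#'
#' @param taxa,counts,metadata,qpcr,perturbations file paths. `qpcr` and
#'   `perturbations` may be NULL (no qPCR / no perturbations).
#' @return a `glv_study` object: taxa table, subject ids, per-subject
#'   timepoint vectors, per-subject count matrices (taxa x timepoints),
#'   long-format qPCR table and the perturbation table.
#' @export
read_study <- function(taxa, counts, metadata, qpcr = NULL,
                       perturbations = NULL) {
  tx <- read_tsv_checked(taxa, "taxa", "id")
  ct <- read_tsv_checked(counts, "counts", "id")
  md <- read_tsv_checked(metadata, "metadata", c("sampleID", "subject", "time"))
  qp <- if (!is.null(qpcr)) {
    read_tsv_checked(qpcr, "qpcr", c("sampleID", "replicate", "value"))
  } else NULL
  pt <- if (!is.null(perturbations)) {
    read_tsv_checked(perturbations, "perturbations",
                     c("name", "start", "end", "subject"))
  } else NULL

  if (anyDuplicated(tx$id)) stop("taxa file: duplicated taxon ids")
  unknown <- setdiff(ct$id, tx$id)
  if (length(unknown)) {
    stop("counts file references unknown taxa: ",
         paste(unknown, collapse = ", "))
  }
  sample_ids <- setdiff(names(ct), "id")
  missing_md <- setdiff(sample_ids, md$sampleID)
  if (length(missing_md)) {
    stop("metadata file missing samples present in counts: ",
         paste(missing_md, collapse = ", "))
  }

  subjects <- unique(md$subject)
  times <- list()
  cmats <- list()
  for (s in subjects) {
    rows <- md[md$subject == s, , drop = FALSE]
    rows <- rows[order(rows$time), , drop = FALSE]
    if (any(diff(rows$time) <= 0)) {
      stop("non-monotone or duplicated timepoints for subject ", s)
    }
    times[[s]] <- rows$time
    m <- matrix(0, nrow(tx), nrow(rows),
                dimnames = list(tx$id, as.character(rows$time)))
    idx <- match(ct$id, tx$id)
    for (j in seq_len(nrow(rows))) {
      sid <- rows$sampleID[j]
      if (!sid %in% names(ct)) stop("counts file missing sample ", sid)
      m[idx, j] <- ct[[sid]]
    }
    if (any(m < 0) || any(m != round(m))) {
      stop("counts must be non-negative integers (subject ", s, ")")
    }
    cmats[[s]] <- m
  }

  qlong <- NULL
  if (!is.null(qp)) {
    mi <- match(qp$sampleID, md$sampleID)
    if (anyNA(mi)) stop("qpcr file references unknown samples")
    if (any(qp$value <= 0)) stop("qPCR concentrations must be positive")
    qlong <- data.frame(subject = md$subject[mi], time = md$time[mi],
                        replicate = qp$replicate, value = qp$value,
                        stringsAsFactors = FALSE)
  }

  if (!is.null(pt)) {
    if (any(pt$end <= pt$start)) {
      stop("perturbation windows must satisfy start < end")
    }
    bad <- setdiff(pt$subject, subjects)
    if (length(bad)) {
      stop("perturbation subjects not in study: ", paste(bad, collapse = ", "))
    }
  }

  new_glv_study(tx, subjects, times, cmats, qlong, pt)
}

read_tsv_checked <- function(path, label, required) {
  if (!file.exists(path)) stop(label, " file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(label, " file is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

new_glv_study <- function(taxa, subjects, times, counts, qpcr, perturbations) {
  structure(list(
    taxa = taxa, subjects = subjects, times = times, counts = counts,
    qpcr = qpcr, perturbations = perturbations
  ), class = "glv_study")
}

#' @export
print.glv_study <- function(x, ...) {
  nt <- vapply(x$times, length, integer(1))
  cat("glv_study:", nrow(x$taxa), "taxa,", length(x$subjects), "subjects,",
      sum(nt), "samples\n")
  cat("  timepoints per subject:", paste(nt, collapse = ", "), "\n")
  if (!is.null(x$perturbations)) {
    cat("  perturbations:",
        paste(unique(x$perturbations$name), collapse = ", "), "\n")
  }
  if (!is.null(x$qpcr)) cat("  qPCR samples:",
                            nrow(unique(x$qpcr[c("subject", "time")])), "\n")
  invisible(x)
}

#' Per-subject read depths (column sums of counts)
#' @param study a `glv_study`.
#' @return named list of numeric vectors.
#' @export
read_depth <- function(study) lapply(study$counts, colSums)

#' Per-subject relative abundance matrices
#' @param study a `glv_study`.
#' @return named list of matrices whose columns each sum to 1.
#' @export
relative_abundances <- function(study) {
  lapply(study$counts, function(m) sweep(m, 2, pmax(colSums(m), 1), "/"))
}

#' Write a study back to the five-table format
#'
#' Inverse of [read_study()]: emits taxa.tsv, counts.tsv, metadata.tsv,
#' qpcr.tsv and perturbations.tsv under `dir`. Sample ids are generated as
#' `<subject>_t<time>`.
#'
#' @param study a `glv_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(taxa = file.path(dir, "taxa.tsv"),
             counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             qpcr = file.path(dir, "qpcr.tsv"),
             perturbations = file.path(dir, "perturbations.tsv"))
  wr <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wr(study$taxa, paths["taxa"])
  md <- do.call(rbind, lapply(study$subjects, function(s) {
    data.frame(sampleID = paste0(s, "_t", study$times[[s]]),
               subject = s, time = study$times[[s]],
               stringsAsFactors = FALSE)
  }))
  wr(md, paths["metadata"])
  ct <- data.frame(id = study$taxa$id, stringsAsFactors = FALSE)
  for (s in study$subjects) {
    m <- study$counts[[s]]
    for (j in seq_len(ncol(m))) {
      ct[[paste0(s, "_t", study$times[[s]][j])]] <- m[, j]
    }
  }
  wr(ct, paths["counts"])
  if (!is.null(study$qpcr)) {
    qp <- data.frame(sampleID = paste0(study$qpcr$subject, "_t",
                                       study$qpcr$time),
                     replicate = study$qpcr$replicate,
                     value = study$qpcr$value, stringsAsFactors = FALSE)
    wr(qp, paths["qpcr"])
  } else paths <- paths[names(paths) != "qpcr"]
  if (!is.null(study$perturbations)) {
    wr(study$perturbations, paths["perturbations"])
  } else paths <- paths[names(paths) != "perturbations"]
  invisible(paths)
}

#' Remove samples at listed days from every subject
#'
#' Used to drop early low-biomass samples (e.g. days 0 and 0.5 after
#' colonization) before inference. Time gaps are re-derived from the
#' retained timepoints.
#'
#' @param study a `glv_study`.
#' @param times numeric vector of days to drop; values not observed anywhere
#'   trigger a warning.
#' @return the reduced `glv_study`.
#' @export
exclude_timepoints <- function(study, times) {
  if (length(times) == 0) return(study)
  observed <- unique(unlist(study$times, use.names = FALSE))
  unobserved <- setdiff(times, observed)
  if (length(unobserved)) {
    warning("times not observed in any subject: ",
            paste(unobserved, collapse = ", "))
  }
  for (s in study$subjects) {
    keep <- !(study$times[[s]] %in% times)
    if (!any(keep)) stop("excluding these times empties subject ", s)
    study$times[[s]] <- study$times[[s]][keep]
    study$counts[[s]] <- study$counts[[s]][, keep, drop = FALSE]
  }
  if (!is.null(study$qpcr)) {
    study$qpcr <- study$qpcr[!(study$qpcr$time %in% times), , drop = FALSE]
  }
  study
}

#' Abundance-based taxon filter
#'
#' Retains a taxon iff its relative abundance is at least `min_rel` at
#' `consecutive` or more consecutive timepoints in at least `min_subjects`
#' subjects (the standard pre-inference filter; defaults correspond to
#' 0.01\% relative abundance over seven consecutive timepoints in two
#' subjects). Counts and read depths are re-derived on the retained taxa.
#'
#' @param study a `glv_study`.
#' @param min_rel minimum relative abundance, in (0, 1).
#' @param consecutive required run length (>= 1).
#' @param min_subjects required number of subjects.
#' @return the filtered `glv_study`.
#' @export
filter_taxa <- function(study, min_rel = 1e-4, consecutive = 7,
                        min_subjects = 2) {
  if (!(min_rel > 0 && min_rel < 1)) stop("min_rel must be in (0, 1)")
  if (consecutive < 1) stop("consecutive must be >= 1")
  rel <- relative_abundances(study)
  n_ok <- rep(0L, nrow(study$taxa))
  for (s in study$subjects) {
    above <- rel[[s]] >= min_rel
    runs <- apply(above, 1, function(v) {
      r <- rle(v)
      mx <- r$lengths[r$values]
      if (length(mx)) max(mx) else 0L
    })
    n_ok <- n_ok + (runs >= consecutive)
  }
  keep <- n_ok >= min_subjects
  if (!any(keep)) stop("filter removed every taxon")
  study$taxa <- study$taxa[keep, , drop = FALSE]
  study$counts <- lapply(study$counts, function(m) m[keep, , drop = FALSE])
  study
}
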