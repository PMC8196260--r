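# Seed-based whole-volume connectivity maps, ROI temporal SNR, and
# motion-based subject exclusion.

#' Seed-based connectivity map
#'
#' For every voxel, the Pearson correlation of its time course with the
#' unweighted mean time course of the seed ROI, Fisher z-transformed.
#' Correlations are clipped to |r| <= 1 - 1e-7 before `atanh` so noiseless
#' data (r = +-1) stay finite. Zero-variance voxels (or a zero-variance
#' seed) yield z = 0 and are counted in the QC report rather than producing
#' NaN.
#'
#' @param series numeric matrix, time x voxel (a 4-D array is reshaped with
#'   time as the last dimension).
#' @param roi integer voxel indices (columns of `series`) or a logical mask.
#' @param subject,condition optional labels stored on the result.
#' @return object of class `seed_map`: list with `z` (voxel vector of
#'   Fisher-z values), `qc` (zero-variance counts), `subject`, `condition`.
#' @export
seed_map <- function(series, roi, subject = NA_character_,
                     condition = NA_character_) {
  if (is.array(series) && length(dim(series)) == 4L) {
    d <- dim(series)
    series <- t(matrix(series, prod(d[1:3]), d[4]))
  }
  if (is.logical(roi)) roi <- which(roi)
  if (length(roi) == 0L) stopf("roi is empty")
  if (nrow(series) < 3L) stopf("series must have >= 3 timepoints")
  if (max(roi) > ncol(series)) stopf("roi indices exceed voxel count")
  g <- rowMeans(series[, roi, drop = FALSE])
  seed_constant <- stats::sd(g) == 0
  if (seed_constant) {
    z <- numeric(ncol(series))
    nzv <- ncol(series)
  } else {
    r <- .col_cor(series, g)
    nzv <- attr(r, "n_zero_var")
    z <- fisher_z(as.vector(r))
  }
  structure(list(z = z, qc = list(n_zero_variance = nzv,
                                  seed_constant = seed_constant),
                 subject = subject, condition = condition),
            class = "seed_map")
}

#' Temporal signal-to-noise ratio of an ROI
#'
#' The ROI time course is the unweighted mean over ROI voxels; SNR is its
#' temporal mean divided by its temporal SD. A constant ROI course has no
#' defined SNR and is returned as an `Inf` record flagged for exclusion.
#'
#' @inheritParams seed_map
#' @param roi_label optional ROI name stored on the record.
#' @return object of class `roi_snr`: list with `snr`, `flagged` (TRUE when
#'   the ROI course is constant), `subject`, `roi_label`.
#' @export
roi_snr <- function(series, roi, subject = NA_character_,
                    roi_label = NA_character_) {
  if (is.array(series) && length(dim(series)) == 4L) {
    d <- dim(series)
    series <- t(matrix(series, prod(d[1:3]), d[4]))
  }
  if (is.logical(roi)) roi <- which(roi)
  if (length(roi) == 0L) stopf("roi is empty")
  g <- rowMeans(series[, roi, drop = FALSE])
  s <- stats::sd(g)
  if (s == 0) {
    warnf("ROI %s of subject %s has a constant mean course; flagged",
          roi_label, subject)
    return(structure(list(snr = Inf, flagged = TRUE, subject = subject,
                          roi_label = roi_label), class = "roi_snr"))
  }
  structure(list(snr = mean(g) / s, flagged = FALSE, subject = subject,
                 roi_label = roi_label), class = "roi_snr")
}

#' Exclude high-motion subjects by mean framewise displacement
#'
#' Subjects whose mean FD exceeds the threshold (default 0.5 mm) are
#' removed; the exclusion report lists their ids and values. Missing FD is
#' an error (no silent pass-through).
#'
#' @param cohort data.frame with a `mean_fd` column (mm) and a `subject`
#'   column.
#' @param threshold exclusion threshold in mm.
#' @return list with `cohort` (filtered data.frame) and `excluded`
#'   (data.frame of dropped ids and FD values).
#' @export
fd_filter <- function(cohort, threshold = 0.5) {
  if (!"mean_fd" %in% names(cohort))
    stopf("cohort has no mean_fd column")
  if (anyNA(cohort$mean_fd))
    stopf("mean_fd contains missing values for subjects: %s",
          paste(cohort$subject[is.na(cohort$mean_fd)], collapse = ", "))
  drop <- cohort$mean_fd > threshold
  list(cohort = cohort[!drop, , drop = FALSE],
       excluded = data.frame(subject = cohort$subject[drop],
                             mean_fd = cohort$mean_fd[drop]))
}

#' Stack seed-connectivity maps into the X block for PLS
#'
#' Computes one seed map per subject and condition (seed ROI) and stacks
#' the Fisher-z voxel vectors into a (subject, condition) x voxel matrix,
#' rows grouped by condition with identical subject order per condition.
#'
#' @param series list of time x voxel matrices, one per subject.
#' @param rois named list of seed voxel-index vectors (names become the
#'   condition labels, in order).
#' @param subjects optional subject ids (default `s001`, ...).
#' @return object of class `conn_stack`: list with `X` (matrix), `condition`
#'   (factor), `subject` (character), `qc` (total zero-variance count).
#' @export
conn_stack <- function(series, rois, subjects = NULL) {
  n <- length(series)
  if (is.null(subjects)) subjects <- sprintf("s%03d", seq_len(n))
  conds <- names(rois)
  if (is.null(conds)) stopf("rois must be a named list")
  rows <- list(); cond <- character(0); subj <- character(0); nzv <- 0L
  for (cc in conds) {
    for (i in seq_len(n)) {
      sm <- seed_map(series[[i]], rois[[cc]], subject = subjects[i],
                     condition = cc)
      rows[[length(rows) + 1L]] <- sm$z
      nzv <- nzv + sm$qc$n_zero_variance
      cond <- c(cond, cc); subj <- c(subj, subjects[i])
    }
  }
  structure(list(X = do.call(rbind, rows),
                 condition = factor(cond, levels = conds),
                 subject = subj, qc = list(n_zero_variance = nzv)),
            class = "conn_stack")
}
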