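#' Write one subject-session recording to tab-separated files
#'
#' The BOLD file has a header row of region labels and one row per volume;
#' the event file (task runs only) has columns onset_s, duration_s,
#' input_index, amplitude.
#'
#' @param recording a `session_recording`.
#' @param path_bold output path for the BOLD table.
#' @param path_events optional output path for the event table.
#' @param events optional event data frame to write.
#' @param region_labels optional labels for the header.
#' @return invisibly, the paths written.
#' @export
write_recording <- function(recording, path_bold, path_events = NULL,
                            events = NULL, region_labels = NULL) {
  bold <- recording$bold
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(ncol(bold)))
  df <- as.data.frame(bold)
  names(df) <- region_labels
  utils::write.table(df, path_bold, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(path_events) && !is.null(events)) {
    utils::write.table(events, path_events, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(c(path_bold, path_events))
}

#' Read a subject-session recording from tab-separated files
#'
#' Validates the dialect (header row present, rectangular numeric body,
#' events within the run, nonnegative durations) and reconstructs the
#' volume-resolution stimulus functions from the event table.
#'
#' @param path_bold path to the BOLD table (header = region labels).
#' @param path_events optional path to an event table.
#' @param TR repetition time in seconds.
#' @param n_inputs number of inputs to materialise (defaults to the largest
#'   input index in the event file, 0 without events).
#' @param subject_id,session_id identifiers stored in the recording.
#' @return a `session_recording`.
#' @export
read_recording <- function(path_bold, path_events = NULL, TR,
                           n_inputs = NULL, subject_id = 1L, session_id = 1L) {
  stopifnot(TR > 0)
  first <- readLines(path_bold, n = 1)
  if (!length(first)) stop("empty BOLD file: ", path_bold)
  if (!any(is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]]))))) {
    stop("BOLD file ", path_bold, " has no header row of region labels")
  }
  df <- utils::read.delim(path_bold, check.names = FALSE)
  bold <- as.matrix(df)
  if (!is.numeric(bold) || anyNA(bold)) {
    stop("non-numeric or missing values in BOLD file ", path_bold)
  }
  N <- nrow(bold)
  events <- NULL
  U <- matrix(0, N, 0)
  if (!is.null(path_events)) {
    events <- utils::read.delim(path_events)
    need <- c("onset_s", "duration_s", "input_index", "amplitude")
    if (!all(need %in% names(events))) {
      stop("event file ", path_events, " must have columns ",
           paste(need, collapse = ", "))
    }
    if (any(events$duration_s < 0)) {
      stop("negative duration at event file line ",
           which(events$duration_s < 0)[1] + 1)
    }
    run_s <- N * TR
    if (any(events$onset_s >= run_s)) {
      stop("event onset beyond run end at line ",
           which(events$onset_s >= run_s)[1] + 1)
    }
    if (is.null(n_inputs)) n_inputs <- max(events$input_index)
    U <- matrix(0, N, n_inputs)
    t0 <- (seq_len(N) - 1) * TR
    for (i in seq_len(nrow(events))) {
      k <- events$input_index[i]
      on <- events$onset_s[i]; off <- on + events$duration_s[i]
      U[t0 >= on & t0 < off, k] <- U[t0 >= on & t0 < off, k] +
        events$amplitude[i]
    }
  }
  structure(list(bold = bold, inputs = U, TR = TR, events = events,
                 subject_id = subject_id, session_id = as.integer(session_id)),
            class = "session_recording")
}

#' Write a whole cohort to disk in the package's file dialects
#'
#' One BOLD table (and, in task mode, one event table) per subject-session,
#' a JSON ground-truth file (matrices as nested arrays) and a JSON
#' provenance file (configuration and seeds).
#'
#' @param cohort a `cohort_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  for (s in seq_along(cohort$recordings)) {
    for (j in 1:2) {
      rec <- cohort$recordings[[s]][[j]]
      write_recording(
        rec,
        file.path(dir, sprintf("sub-%02d_ses-%d_bold.tsv", s, j)),
        if (cfg$mode == "task")
          file.path(dir, sprintf("sub-%02d_ses-%d_events.tsv", s, j)),
        events = cfg$event_schedule)
    }
  }
  truth <- cohort$truth
  jsonlite::write_json(
    list(group_A = truth$group$group_A, group_C = truth$group$group_C,
         sparsity_mask_A = truth$group$sparsity_mask_A,
         sparsity_mask_C = truth$group$sparsity_mask_C,
         subjects = lapply(truth$subjects, function(s)
           list(A = s$A, C = s$C))),
    file.path(dir, "truth.json"), digits = NA, matrix = "rowmajor")
  jsonlite::write_json(
    list(config = cfg[setdiff(names(cfg), c("hrf_params", "event_schedule"))],
         hrf_params = cfg$hrf_params,
         provenance = cohort$provenance),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}

#' Export an A (or C) matrix estimate as CSV
#'
#' Orientation convention: entry (r, j) is the connection from region j
#' (column) to region r (row) — rows are targets of afferent connections.
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @param row_labels,col_labels labels written with the matrix.
#' @return invisibly, the path.
#' @export
write_matrix_csv <- function(mat, path, row_labels = NULL, col_labels = NULL) {
  df <- as.data.frame(mat)
  if (!is.null(col_labels)) names(df) <- col_labels
  if (is.null(row_labels)) row_labels <- paste0("R", seq_len(nrow(mat)))
  utils::write.csv(cbind(target = row_labels, df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
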