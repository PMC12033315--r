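#' Write a spiral trace to CSV (+ JSON sidecar)
#'
#' Columns `t_s`, `x_cm`, `y_cm`; task/level/repeat/subject metadata go to a
#' `<path>.json` sidecar.
#'
#' @param trace a [spiral_trace()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_spiral_csv <- function(trace, path) {
  stopifnot(inherits(trace, "spiral_trace"))
  utils::write.csv(data.frame(t_s = trace$t, x_cm = trace$x, y_cm = trace$y),
                   path, row.names = FALSE)
  meta <- list(subject = trace$subject, task = trace$task,
               level = trace$level, rep = trace$rep)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a spiral trace from CSV
#'
#' Expects the header `t_s,x_cm,y_cm` (units are part of the contract);
#' non-monotone time stamps or missing values abort with the offending row
#' number. Metadata are taken from the `<path>.json` sidecar when present.
#'
#' @param path CSV file path.
#' @return a [spiral_trace()].
#' @export
read_spiral_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_s", "x_cm", "y_cm")
  if (!all(need %in% names(d)))
    stop("spiral CSV must have columns t_s, x_cm, y_cm")
  bad <- which(!stats::complete.cases(d[need]))
  if (length(bad))
    stop(sprintf("missing value in spiral CSV at row %d", bad[1L]))
  nonmono <- which(diff(d$t_s) <= 0)
  if (length(nonmono))
    stop(sprintf("non-increasing time stamp in spiral CSV at row %d",
                 nonmono[1L] + 1L))
  meta <- list(subject = "s01", task = "self_paced", level = 0L, rep = 1L)
  side <- paste0(path, ".json")
  if (file.exists(side))
    meta <- utils::modifyList(meta, jsonlite::read_json(side, simplifyVector = TRUE))
  spiral_trace(d$t_s, d$x_cm, d$y_cm, task = meta$task, level = meta$level,
               rep = meta$rep, subject = meta$subject)
}

#' Write / read a multichannel recording (CSV + JSON sidecar)
#'
#' Samples are rows, channels are columns (header = labels); the sidecar
#' `<path>.json` stores `fs_hz` and `space`.
#'
#' @param rec an [mc_recording()].
#' @param path CSV file path.
#' @return `path` (write) or an [mc_recording()] (read).
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "mc_recording"))
  d <- as.data.frame(t(rec$data))
  names(d) <- rec$labels
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = rec$fs_hz, space = rec$space),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  mc_recording(t(as.matrix(d)), meta$fs_hz, labels = names(d),
               space = meta$space)
}

#' Write / read a lead field as TSV
#'
#' Sensors are rows (row names = sensor labels), sources are columns.
#'
#' @param leadfield a `lead_field`.
#' @param path TSV file path.
#' @return `path` (write) or a `lead_field` (read).
#' @export
write_leadfield_tsv <- function(leadfield, path) {
  stopifnot(inherits(leadfield, "lead_field"))
  m <- leadfield$matrix
  dimnames(m) <- list(leadfield$sensor_labels, leadfield$source_labels)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_leadfield_tsv
#' @export
read_leadfield_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  lf <- structure(list(matrix = unname(m), source_labels = colnames(m),
                       sensor_labels = rownames(m)), class = "lead_field")
  if (qr(lf$matrix)$rank < ncol(lf$matrix))
    stop("lead field in file is rank-deficient")
  lf
}

# write a long-format table as TSV with a config-hash comment header
.write_tsv <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
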