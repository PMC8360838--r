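#' Write an electrogram record to a plain-text file
#'
#' Format: '#'-prefixed `key=value` header lines (`record_id`, `patient_id`,
#' `sampling_rate_hz`, `duration_s`, optionally `label` and `class_name`),
#' then tab-separated columns `t_ms`, `unipolar_mv`, `bipolar_mv`.
#'
#' @param record An `egm_record`.
#' @param path Output file path.
#' @param truth Optional `egm_truth`; when given, `label` and `class_name`
#'   header lines are written.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, truth = NULL) {
  hdr <- c(
    sprintf("# record_id=%s", record$record_id),
    sprintf("# patient_id=%s", record$patient_id),
    sprintf("# sampling_rate_hz=%g", record$sampling_rate),
    sprintf("# duration_s=%g", record$duration))
  if (!is.null(truth)) {
    hdr <- c(hdr,
             sprintf("# label=%d", as.integer(truth$is_fast)),
             sprintf("# class_name=%s", truth$class_name))
  }
  t_ms <- index_to_ms(seq_along(record$unipolar), record$sampling_rate)
  body <- sprintf("%.3f\t%.12g\t%.12g", t_ms, record$unipolar,
                  record$bipolar)
  writeLines(c(hdr, "t_ms\tunipolar_mv\tbipolar_mv", body), path)
  invisible(path)
}

#' Read an electrogram record written by [write_record()]
#'
#' @param path File path.
#' @return An `egm_record`; `label`/`class_name` headers, when present, are
#'   attached as attributes `label` and `class_name`.
#' @export
read_record <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0 || any(diff(hdr_idx) != 1)) {
    abort(sprintf("%s: header lines must be a leading '#' block.", path))
  }
  kv <- sub("^#\\s*", "", lines[hdr_idx])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  header <- setNames(vals, keys)
  for (k in c("record_id", "patient_id", "sampling_rate_hz", "duration_s")) {
    if (!k %in% keys) {
      abort(sprintf("%s: missing required header key '%s'.", path, k))
    }
  }
  col_line <- max(hdr_idx) + 1L
  if (lines[col_line] != "t_ms\tunipolar_mv\tbipolar_mv") {
    abort(sprintf("%s: line %d: expected column header.", path, col_line))
  }
  body <- lines[(col_line + 1L):length(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    abort(sprintf("%s: line %d: expected 3 tab-separated columns.",
                  path, col_line + bad[1]))
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
  if (anyNA(m)) {
    abort(sprintf("%s: non-numeric sample value.", path))
  }
  if (any(diff(m[, 1]) <= 0)) {
    abort(sprintf("%s: line %d: t_ms must be strictly increasing.",
                  path, col_line + which(diff(m[, 1]) <= 0)[1] + 1L))
  }
  rec <- structure(
    list(record_id = unname(header["record_id"]),
         patient_id = unname(header["patient_id"]),
         sampling_rate = as.numeric(header["sampling_rate_hz"]),
         duration = as.numeric(header["duration_s"]),
         unipolar = m[, 2], bipolar = m[, 3]),
    class = "egm_record")
  if ("label" %in% keys) {
    attr(rec, "label") <- as.integer(unname(header["label"]))
  }
  if ("class_name" %in% keys) {
    attr(rec, "class_name") <- unname(header["class_name"])
  }
  rec
}

#' Write / read a cohort manifest
#'
#' Tab-separated columns `record_path`, `patient_id`, `label`, `class_name`.
#'
#' @param manifest Tibble with those columns.
#' @param path File path.
#' @return `path` invisibly (write); manifest tibble (read).
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("record_path", "patient_id", "label", "class_name")
                %in% names(manifest)))
  utils::write.table(
    manifest[, c("record_path", "patient_id", "label", "class_name")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "integer", "character"))
  if (anyDuplicated(df$record_path)) {
    dup <- df$record_path[duplicated(df$record_path)][1]
    abort(sprintf("%s: duplicate record_path '%s'.", path, dup))
  }
  tibble::as_tibble(df)
}

#' Write a synthetic cohort to disk
#'
#' Writes one record file per record plus a manifest TSV, the on-disk layout
#' consumed by the command-line interface.
#'
#' @param cohort Result of [synth_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with `record_path` filled in), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$manifest$record_id, ".tsv"))
  for (i in seq_along(cohort$records)) {
    write_record(cohort$records[[i]], paths[i], cohort$truths[[i]])
  }
  manifest <- dplyr::mutate(cohort$manifest, record_path = paths,
                            .before = 1)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
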