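#' Read and write waveforms in the plain-text scan dialect
#'
#' Waveforms are stored as diffable plain text: a header of `# key: value`
#' metadata lines, a column-name line, then two tab-separated columns
#' `time_ps` and `amplitude_au`. Floats are written with 9 significant
#' digits and a `.` decimal separator, so identical waveforms always
#' serialize to identical bytes.
#'
#' Missing metadata keys get defaults on read: `role` defaults to
#' `"sample"`; a missing `thickness_mm` is only permitted for reference
#' scans, since the optics cannot run without it.
#'
#' @param path File path.
#' @return `read_waveform()` returns a [waveform()]; `write_waveform()`
#'   returns `path` invisibly.
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("waveform file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(lines, "#")
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta <- parse_meta_header(lines[seq_len(n_meta)], path)

  body <- lines[(n_meta + 1L):length(lines)]
  if (length(body) < 2L || !identical(body[1], "time_ps\tamplitude_au")) {
    abort(sprintf("%s: expected column header 'time_ps<TAB>amplitude_au' after metadata.", path))
  }
  data_lines <- body[-1L]
  data_lines <- data_lines[nzchar(data_lines)]
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(parts) == 2L
  if (!all(ncol_ok)) {
    bad <- which(!ncol_ok)[1]
    abort(sprintf("%s: line %d does not have two tab-separated fields.",
                  path, n_meta + 1L + bad))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    abort(sprintf(
      "%s: cannot parse numeric value on line %d ('%s'); the dialect uses '.' as decimal separator.",
      path, n_meta + 1L + bad, data_lines[bad]))
  }
  if (meta$role == "sample" && is.na(meta$thickness_mm)) {
    abort(sprintf("%s: sample scan is missing `thickness_mm` metadata.", path))
  }
  waveform(m[, 1], m[, 2], meta)
}

parse_meta_header <- function(meta_lines, path) {
  meta <- scan_meta()
  for (ln in meta_lines) {
    kv <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(kv) != 3) next
    key <- kv[2]; val <- kv[3]
    if (!key %in% names(meta)) next
    meta[[key]] <- if (identical(val, "NA")) {
      meta[[key]]
    } else {
      switch(key,
        sample_id = val,
        role = val,
        n_averages = as.integer(val),
        as.numeric(val)
      )
    }
  }
  validate_scan_meta(meta)
}

#' @rdname read_waveform
#' @param wf A [waveform()] to serialize.
#' @export
write_waveform <- function(wf, path) {
  stopifnot(inherits(wf, "thz_waveform"))
  if (!all(is.finite(wf$amplitude_au)) || !all(is.finite(wf$time_ps))) {
    abort("refusing to write waveform containing non-finite values.")
  }
  if (!dir.exists(dirname(path))) {
    abort(sprintf("parent directory does not exist: %s", dirname(path)))
  }
  m <- wf_meta(wf)
  hdr <- c(
    sprintf("# sample_id: %s", m$sample_id),
    sprintf("# role: %s", m$role),
    sprintf("# thickness_mm: %s", fmt_num(m$thickness_mm)),
    sprintf("# temperature_C: %s", fmt_num(m$temperature_C)),
    sprintf("# time_h: %s", fmt_num(m$time_h)),
    sprintf("# n_averages: %d", m$n_averages)
  )
  body <- sprintf("%s\t%s", fmt_num(wf$time_ps), fmt_num(wf$amplitude_au))
  con <- file(path, open = "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(c(hdr, "time_ps\tamplitude_au", body), con)
  invisible(path)
}

# fixed 9-significant-digit format; NA serializes as "NA"
fmt_num <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- "NA"
  out
}

MANIFEST_COLS <- c("file", "role", "sample_id", "temperature_C", "replicate",
                   "time_h", "thickness_mm", "x_amorphous", "x_beta",
                   "x_alpha", "seed")

#' Read or write a study manifest
#'
#' The manifest is the tab-separated index of a study tree: one row per
#' stored waveform with its role, acquisition coordinates and (for synthetic
#' studies) the ground-truth phase fractions. Rows are returned sorted by
#' `(temperature_C, replicate, time_h)`. The ground-truth columns
#' (`x_amorphous`, `x_beta`, `x_alpha`) are optional and come back as `NA`
#' when absent, as they are for real instrument data.
#'
#' @param path Manifest file path.
#' @return A tibble with the manifest schema.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing_core <- setdiff(c("file", "role", "sample_id", "time_h"), names(df))
  if (length(missing_core)) {
    abort(sprintf("manifest %s lacks required columns: %s",
                  path, paste(missing_core, collapse = ", ")))
  }
  for (col in setdiff(MANIFEST_COLS, names(df))) df[[col]] <- NA_real_
  df <- as_tibble(df[MANIFEST_COLS])
  samples <- dplyr::filter(df, .data$role == "sample")
  dup <- duplicated(samples[c("sample_id", "time_h")])
  if (any(dup)) {
    d <- samples[dup, ][1, ]
    abort(sprintf("manifest has duplicate (sample, time) rows: %s at %g h.",
                  d$sample_id, d$time_h))
  }
  dplyr::arrange(df, .data$temperature_C, .data$replicate, .data$time_h, .data$role)
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  man <- manifest
  for (col in intersect(names(man), c("temperature_C", "time_h", "thickness_mm",
                                      "x_amorphous", "x_beta", "x_alpha"))) {
    man[[col]] <- fmt_num(man[[col]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(man, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
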