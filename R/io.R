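# Shared TSV plumbing: plain tab-separated tables with '#'-prefixed
# `key=value` metadata lines above the header row.

write_tsv_with_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s=%s", nm, format(meta[[nm]], digits = 17)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_with_meta <- function(path, required = character()) {
  if (!file.exists(path)) abort_validation("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body))
    abort_validation("empty table (no header row) in %s", path)
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    abort_validation("%s is missing required column(s): %s", path,
                     paste(miss, collapse = ", "))
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(key)]] <- if (!is.na(num)) num else trimws(val)
    }
  }
  attr(df, "metadata") <- meta
  df
}

#' Read / write a mixture-motility dataset as TSV
#'
#' Columns: `k`, `velocity_um_s`, optional `uncertainty_um_s`,
#' `uncertainty_kind` (`ci95`|`sd`) and `n`; `#` comment lines carry
#' metadata.
#'
#' @param path file path.
#' @return [as_mixture_dataset()] result.
#' @examples
#' path <- system.file("extdata", "synthetic_mixture_wt_sk.tsv",
#'                     package = "myomech")
#' read_mixture_dataset(path)
#' @export
read_mixture_dataset <- function(path) {
  df <- read_tsv_with_meta(path, required = c("k", "velocity_um_s"))
  as_mixture_dataset(df, metadata = attr(df, "metadata"))
}

#' @rdname read_mixture_dataset
#' @param data a `mixture_dataset`.
#' @param meta named list written as `# key=value` lines.
#' @export
write_mixture_dataset <- function(data, path, meta = list()) {
  data <- as_mixture_dataset(data)
  md <- attr(data, "metadata")
  if (is.null(meta$seed) && !is.null(md$seed)) meta$seed <- md$seed
  write_tsv_with_meta(as.data.frame(data), path, meta)
}

#' Read / write a trap recording as TSV
#'
#' Columns `time_s`, `bead1_nm`, `bead2_nm`.  The sampling rate is inferred
#' from the time column, which must be uniform to 1 ppm (relative deviation
#' of any step from the median step); metadata (`# atp_uM=...`, `# seed=...`)
#' travels in `#` header lines.
#'
#' @param path file path.
#' @return a [trap_recording()].
#' @export
read_trap_recording <- function(path) {
  df <- read_tsv_with_meta(path, required = c("time_s", "bead1_nm", "bead2_nm"))
  if (nrow(df) < 2L) abort_validation("trap recording needs >= 2 samples")
  dt <- diff(df$time_s)
  dt0 <- stats::median(dt)
  if (dt0 <= 0 || any(abs(dt - dt0) > 1e-6 * dt0))
    abort_validation("column `time_s` is not uniform to 1 ppm")
  meta <- attr(df, "metadata") %||% list()
  trap_recording(df$bead1_nm, df$bead2_nm, sampling_rate = 1 / dt0,
                 atp = meta$atp_uM %||% NA_real_, metadata = meta)
}

#' @rdname read_trap_recording
#' @param rec a [trap_recording()].
#' @param meta extra metadata written as `# key=value` lines.
#' @export
write_trap_recording <- function(rec, path, meta = list()) {
  n <- length(rec$bead1)
  if (is.null(meta$atp_uM) && is.finite(rec$atp)) meta$atp_uM <- rec$atp
  if (is.null(meta$seed) && !is.null(rec$metadata$seed))
    meta$seed <- rec$metadata$seed
  if (is.null(meta$params) && !is.null(rec$metadata$params))
    meta$params <- as.character(jsonlite::toJSON(rec$metadata$params,
                                                 auto_unbox = TRUE, digits = NA))
  df <- data.frame(time_s = (0:(n - 1)) / rec$sampling_rate,
                   bead1_nm = rec$bead1, bead2_nm = rec$bead2)
  write_tsv_with_meta(df, path, meta)
}

#' Read / write an event set as TSV (`start_s`, `end_s`, `duration_s`)
#'
#' @param events an [event_set()].
#' @param path file path.
#' @param meta metadata lines.
#' @export
write_event_set <- function(events, path, meta = list()) {
  fs <- attr(events, "sampling_rate")
  df <- data.frame(start_s = events$start_index / fs,
                   end_s = events$end_index / fs,
                   duration_s = events$duration_s)
  meta$sampling_rate_hz <- fs
  write_tsv_with_meta(df, path, meta)
}

#' @rdname write_event_set
#' @export
read_event_set <- function(path) {
  df <- read_tsv_with_meta(path, required = c("start_s", "end_s", "duration_s"))
  fs <- (attr(df, "metadata") %||% list())$sampling_rate_hz
  if (is.null(fs)) abort_validation("event TSV lacks `# sampling_rate_hz=` metadata")
  event_set(round(df$start_s * fs), round(df$end_s * fs), fs)
}

#' Read / write per-filament gliding speeds as TSV
#'
#' Columns `speed_um_s`, `weight`, plus optional label columns `construct`,
#' `attachment`, `conc_ug_ml`, `temp_C`, `replicate`.
#'
#' @param path file path.
#' @return a [speed_sample()]; label columns are collapsed into the label.
#' @export
read_speed_sample <- function(path) {
  df <- read_tsv_with_meta(path, required = c("speed_um_s", "weight"))
  label_cols <- intersect(c("construct", "attachment", "conc_ug_ml", "temp_C"),
                          names(df))
  label <- if (length(label_cols))
    paste(unique(do.call(paste, df[label_cols])), collapse = "; ") else ""
  speed_sample(df$speed_um_s, df$weight, label = label,
               replicate = df$replicate)
}

#' @rdname read_speed_sample
#' @param sample a [speed_sample()].
#' @param labels optional named list of label columns to repeat on each row.
#' @param meta metadata lines.
#' @export
write_speed_sample <- function(sample, path, labels = list(), meta = list()) {
  df <- data.frame(speed_um_s = sample$speeds, weight = sample$weights)
  if (!is.null(sample$replicate)) df$replicate <- sample$replicate
  for (nm in names(labels)) df[[nm]] <- labels[[nm]]
  write_tsv_with_meta(df, path, meta)
}

#' Write an ensemble average as TSV
#' @param ens an [ensemble_average()].
#' @param path file path.
#' @param meta metadata lines.
#' @export
write_ensemble_average <- function(ens, path, meta = list()) {
  meta$mode <- ens$mode
  meta$n_events <- ens$n_events
  write_tsv_with_meta(data.frame(time_s = ens$times,
                                 mean_position_nm = ens$mean_position,
                                 n_events = ens$n_events_per_bin),
                      path, meta)
}

#' Write a JSON report
#'
#' Thin wrapper around `jsonlite::write_json(auto_unbox = TRUE, digits = NA)`
#' so scalar fields are emitted as bare JSON numbers at full precision.
#'
#' @param x a list.
#' @param path output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
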