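#' Single-lead ECG record container
#'
#' @param record_id identifier string.
#' @param samples numeric vector of sample values in mV.
#' @param fs sampling rate in Hz (> 0).
#' @param lead lead name (default `"MLII"`, the modified limb lead II).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, samples, fs, lead = "MLII") {
  if (fs <= 0) stop("fs must be > 0")
  if (length(samples) == 0) stop("samples must be non-empty")
  structure(list(record_id = as.character(record_id),
                 samples = as.numeric(samples), fs = fs, lead = lead),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d samples @ %g Hz (%.1f s), lead %s\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$lead))
  invisible(x)
}

# Published inter-patient partition of the 48 MIT-BIH Arrhythmia Database
# records; the four paced records are excluded following the AAMI
# recommendation.
MITDB_TRAIN <- c("101", "106", "108", "109", "112", "114", "115", "116",
                 "118", "119", "122", "124", "201", "203", "205", "207",
                 "208", "209", "215", "220", "223", "230")
MITDB_TEST <- c("100", "103", "105", "111", "113", "117", "121", "123",
                "200", "202", "210", "212", "213", "214", "219", "221",
                "222", "228", "231", "232", "233", "234")
MITDB_EXCLUDED <- c("102", "104", "107", "217")

#' Partition record ids into training, test, and excluded sets
#'
#' Applies the standard inter-patient split of the MIT-BIH Arrhythmia
#' Database: 22 training records, 22 test records, and the four
#' paced-rhythm records (102, 104, 107, 217) excluded. Custom id lists can
#' be supplied for synthetic data. Inter-patient splitting (no subject in
#' both sets) avoids the label leakage that record-level cross-validation
#' would cause, since one subject's beats are highly self-similar.
#'
#' @param available_ids character vector of record ids to partition.
#' @param train_records,test_records,excluded_records override lists; the
#'   defaults are the published MIT-BIH split.
#' @return A list with `train`, `test`, `excluded` character vectors.
#' @export
#' @examples
#' partition_records(c("100", "101", "107"))
partition_records <- function(available_ids,
                              train_records = MITDB_TRAIN,
                              test_records = MITDB_TEST,
                              excluded_records = MITDB_EXCLUDED) {
  available_ids <- as.character(available_ids)
  known <- c(train_records, test_records, excluded_records)
  bad <- setdiff(available_ids, known)
  if (length(bad) > 0)
    stop("record id(s) not in any partition: ", paste(bad, collapse = ", "))
  list(train = intersect(available_ids, train_records),
       test = intersect(available_ids, test_records),
       excluded = intersect(available_ids, excluded_records))
}

#' Default annotation-symbol-to-class mapping
#'
#' `'V'` maps to the PVC class. The normal class uses the AAMI N group --
#' normal ('N'), left/right bundle branch block ('L', 'R'), atrial escape
#' ('e') and junctional escape ('j') beats -- because the training split
#' contains records whose beats are exclusively bundle-branch-block and the
#' published beat totals are only reachable when those count as normal.
#' Every other symbol (other arrhythmias, paced beats, non-beat annotations)
#' is discarded.
#'
#' @return Named list with `pvc` and `normal` symbol vectors.
#' @export
default_label_map <- function() {
  list(pvc = "V", normal = c("N", "L", "R", "e", "j"))
}

#' Map an annotation symbol to a binary beat class
#'
#' @param symbol single-character annotation code (vectorised).
#' @param mapping list with `pvc` and `normal` symbol sets; see
#'   [default_label_map()].
#' @return Character vector in `{"pvc", "normal", "discard"}`.
#' @export
#' @examples
#' map_label(c("V", "N", "/", "L"))
map_label <- function(symbol, mapping = default_label_map()) {
  out <- rep("discard", length(symbol))
  out[symbol %in% mapping$pvc] <- "pvc"
  out[symbol %in% mapping$normal] <- "normal"
  out
}

#' Extract fixed-length R-peak-centred heartbeats
#'
#' Cuts a window of `window` samples around each annotated R peak so that
#' the R sample sits exactly at the window's centre (offset
#' `(window - 1) / 2`, i.e. position 216 of 0..432 for the default).
#' Annotations whose window would overrun either record edge are dropped,
#' as are annotations whose symbol maps to `discard`.
#'
#' @param record an [ecg_record()].
#' @param annotations data.frame with 0-based `sample_index` and `symbol`.
#' @param window odd window length in samples (default 433, i.e. ~1.2 s at
#'   360 Hz).
#' @param mapping label mapping passed to [map_label()].
#' @return A `heartbeat_set`: list with `samples` (n x window matrix),
#'   `label` (factor with levels normal/pvc), `r_index` (0-based),
#'   `record_id`, `window`.
#' @export
extract_beats <- function(record, annotations, window = 433,
                          mapping = default_label_map()) {
  stopifnot(inherits(record, "ecg_record"))
  if (window %% 2 == 0 || window <= 0) stop("window must be odd and positive")
  half <- (window - 1) / 2
  n <- length(record$samples)
  labels <- map_label(annotations$symbol, mapping)
  keep <- labels != "discard" &
    annotations$sample_index - half >= 0 &
    annotations$sample_index + half <= n - 1
  ann <- annotations[keep, , drop = FALSE]
  labels <- labels[keep]
  m <- nrow(ann)
  X <- matrix(0, nrow = m, ncol = window)
  for (i in seq_len(m)) {
    r <- ann$sample_index[i]  # 0-based
    X[i, ] <- record$samples[(r - half + 1):(r + half + 1)]
  }
  heartbeat_set(X, labels, r_index = ann$sample_index,
                record_id = record$record_id)
}

#' Construct a heartbeat set
#'
#' @param samples n x window numeric matrix, one beat per row.
#' @param label character/factor vector of classes (`normal`/`pvc`).
#' @param r_index optional 0-based R sample indices in the source record.
#' @param record_id optional source record id (scalar or vector).
#' @return Object of class `heartbeat_set`.
#' @export
heartbeat_set <- function(samples, label, r_index = NULL, record_id = NA) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(label))
    stop("label length must match number of beats")
  structure(list(samples = samples,
                 label = factor(label, levels = c("normal", "pvc")),
                 r_index = r_index,
                 record_id = record_id,
                 window = ncol(samples)),
            class = "heartbeat_set")
}

#' @export
print.heartbeat_set <- function(x, ...) {
  cat(sprintf("<heartbeat_set> %d beats x %d samples (%d normal, %d pvc)\n",
              nrow(x$samples), x$window,
              sum(x$label == "normal"), sum(x$label == "pvc")))
  invisible(x)
}

# Concatenate heartbeat sets (used when pooling beats across records).
#' @export
c.heartbeat_set <- function(...) {
  sets <- list(...)
  heartbeat_set(do.call(rbind, lapply(sets, `[[`, "samples")),
                unlist(lapply(sets, function(s) as.character(s$label))),
                r_index = unlist(lapply(sets, `[[`, "r_index")),
                record_id = unlist(lapply(sets, function(s)
                  rep_len(s$record_id, nrow(s$samples)))))
}

# ---- Minimal WFDB-compatible I/O (format 16) --------------------------------
# A record is stored as <id>.hea (text header) + <id>.dat (little-endian
# int16 ADC units); beat annotations as a plain-text CSV
# (sample_index,symbol). Only what this package writes is supported:
# single-signal format 16 with integer gain.

#' Write a record in WFDB-compatible format 16
#'
#' @param record an [ecg_record()].
#' @param dir output directory.
#' @param gain ADC units per mV.
#' @return Invisibly, the header path.
#' @export
write_wfdb_record <- function(record, dir, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- record$record_id
  adc <- as.integer(pmin(pmax(round(record$samples * gain), -32768), 32767))
  hea <- file.path(dir, paste0(id, ".hea"))
  dat <- file.path(dir, paste0(id, ".dat"))
  writeLines(c(
    sprintf("%s 1 %g %d", id, record$fs, length(adc)),
    sprintf("%s.dat 16 %d 16 0 %d 0 0 %s", id, gain, adc[1], record$lead)
  ), hea)
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2, endian = "little")
  invisible(hea)
}

#' Read a WFDB format-16 record
#'
#' @param header_path path to the `.hea` file.
#' @return An [ecg_record()] with samples converted back to mV.
#' @export
read_wfdb_record <- function(header_path) {
  lines <- readLines(header_path)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  id <- top[1]; nsig <- as.integer(top[2])
  fs <- as.numeric(top[3]); nsamp <- as.integer(top[4])
  if (nsig != 1) stop("only single-signal records are supported")
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (sig[2] != "16") stop("only format 16 is supported")
  gain <- as.numeric(sig[3])
  lead <- if (length(sig) >= 9) sig[9] else "MLII"
  dat <- file.path(dirname(header_path), sig[1])
  con <- file(dat, "rb")
  on.exit(close(con))
  adc <- readBin(con, "integer", n = nsamp, size = 2, endian = "little",
                 signed = TRUE)
  ecg_record(id, adc / gain, fs, lead)
}

#' Write beat annotations as a plain-text table
#'
#' @param annotations data.frame with `sample_index` (0-based) and `symbol`.
#' @param path output CSV path.
#' @export
write_beat_annotations <- function(annotations, path) {
  utils::write.csv(annotations[, c("sample_index", "symbol")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-text beat annotation table
#'
#' @param path CSV path with columns `sample_index`, `symbol`.
#' @return data.frame with integer `sample_index` and character `symbol`.
#' @export
read_beat_annotations <- function(path) {
  ann <- utils::read.csv(path, colClasses = c("integer", "character"))
  names(ann) <- c("sample_index", "symbol")
  ann
}
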