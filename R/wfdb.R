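# Minimal WFDB support: header (.hea) plus 16-bit little-endian interleaved
# signal (.dat, format 16) — the subset used by standard 12-lead archives.
# Reports and the machine RR interval round-trip through '#' comment lines.

#' Write an ECG record as a WFDB header + format-16 signal pair
#'
#' Amplitudes are quantized at `gain` ADU/mV. Reports and `rr_ms` are stored
#' as structured comment lines so fixtures round-trip losslessly apart from
#' quantization.
#'
#' @param record an [ecg_record].
#' @param dir output directory (created if missing).
#' @param gain integer ADU per millivolt (default 200).
#' @return the header path, invisibly.
#' @export
write_wfdb <- function(record, dir, gain = 200L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  name <- record$record_id
  n <- ncol(record$signal)
  adu <- round(record$signal * gain)
  stopifnot(all(abs(adu) < 32768))
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- paste0(name, ".dat")
  lines <- c(
    sprintf("%s 12 %g %d", name, record$fs, n),
    vapply(seq_len(12), function(l) {
      sprintf("%s 16 %d(0)/mV 16 0 %d 0 0 %s",
              dat, gain, as.integer(adu[l, 1]), record$lead_names[l])
    }, ""),
    sprintf("# patient_id: %s", record$patient_id),
    if (!is.na(record$rr_ms)) sprintf("# rr_ms: %g", record$rr_ms),
    vapply(record$reports, function(r) sprintf("# report: %s", r), ""))
  writeLines(lines, hea)
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(adu), con, size = 2L, endian = "little")
  invisible(hea)
}

#' Read a WFDB record and join patient metadata
#'
#' Parses the header, reads the format-16 signal (converted to millivolts via
#' the per-lead gain), recovers reports/rr_ms from comment lines, and joins
#' sex/age from a patient table keyed by `patient_id`; a failed join leaves
#' sex and age absent.
#'
#' @param path path to the `.hea` header (with or without extension).
#' @param patients optional data.frame with columns patient_id, sex, age.
#' @return an [ecg_record].
#' @export
read_record <- function(path, patients = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("missing header file: ", hea)
  lines <- readLines(hea, warn = FALSE)
  meta <- lines[grepl("^#", lines)]
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- top[1]; nsig <- as.integer(top[2])
  fs <- as.numeric(top[3]); nsamp <- as.integer(top[4])
  if (nsig != 12L)
    stop(sprintf("expected 12 channels, header declares %d", nsig))
  if (length(lines) < 1 + nsig) stop("corrupt header: missing signal lines")
  sig_lines <- lapply(lines[2:(1 + nsig)],
                      function(s) strsplit(trimws(s), "\\s+")[[1]])
  dat <- sig_lines[[1]][1]
  fmt <- sig_lines[[1]][2]
  if (fmt != "16") stop("unsupported WFDB format: ", fmt)
  gains <- vapply(sig_lines, function(tk) {
    as.numeric(sub("\\(.*$", "", sub("/.*$", "", tk[3])))
  }, 0)
  baselines <- vapply(sig_lines, function(tk) {
    b <- regmatches(tk[3], regexpr("\\(-?[0-9]+\\)", tk[3]))
    if (length(b)) as.numeric(gsub("[()]", "", b)) else 0
  }, 0)
  leads <- vapply(sig_lines, function(tk) tk[length(tk)], "")

  dpath <- file.path(dirname(hea), dat)
  if (!file.exists(dpath)) stop("missing signal file: ", dpath)
  raw <- readBin(dpath, "integer", n = nsig * nsamp, size = 2L,
                 endian = "little")
  if (length(raw) != nsig * nsamp)
    stop("corrupt signal file: expected ", nsig * nsamp, " samples, got ",
         length(raw))
  sig <- matrix(as.numeric(raw), nrow = nsig)
  sig <- (sig - baselines) / gains

  getm <- function(key) {
    m <- sub(paste0("^#\\s*", key, ":\\s*"), "",
             meta[grepl(paste0("^#\\s*", key, ":"), meta)])
    if (length(m)) m else NULL
  }
  pid <- getm("patient_id"); pid <- if (is.null(pid)) "unknown" else pid[1]
  rr <- getm("rr_ms"); rr <- if (is.null(rr)) NA_real_ else as.numeric(rr[1])
  reports <- getm("report"); if (is.null(reports)) reports <- character()

  sex <- NA_character_; age <- NA_real_
  if (!is.null(patients)) {
    hit <- match(pid, patients$patient_id)
    if (!is.na(hit)) {
      sex <- as.character(patients$sex[hit])
      age <- as.numeric(patients$age[hit])
    }
  }
  ecg_record(sig, fs = fs, record_id = name, patient_id = pid,
             reports = reports, rr_ms = rr, sex = sex, age = age,
             lead_names = leads)
}
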