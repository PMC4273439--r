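#' Write an ECG record as a self-describing CSV file
#'
#' Two columns (`time_s`, `voltage_mV`) preceded by comment lines carrying
#' the metadata needed to invert the write (`# fs=`, `# lead=`, `# t0=`).
#' [read_record()] restores the signal exactly (to the 12 significant
#' digits written).
#'
#' @param signal an `ecg_signal`.
#' @param path output file path (directory must exist).
#' @return `path`, invisibly.
#' @export
write_record <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", signal$fs),
               sprintf("# lead=%s", signal$lead),
               sprintf("# t0=%.10g", signal$t0),
               "time_s,voltage_mV"), con)
  writeLines(sprintf("%.10g,%.12g", sample_times(signal), signal$samples), con)
  invisible(path)
}

#' Write beat annotations as CSV
#'
#' Columns `beat`, `onset`, `qrs`, `offset`, `p`, `t` (1-based sample
#' indices; empty fields for absent fiducials).
#'
#' @param beats a `beat_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(beats, path) {
  stopifnot(inherits(beats, "beat_annotation"))
  df <- cbind(beat = seq_len(nrow(beats)), as.data.frame(beats))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read beat annotations written by [write_annotations()]
#'
#' @param path annotation CSV path.
#' @return a `beat_annotation`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("qrs")
  if (!all(need %in% names(df))) {
    stop("annotation file lacks a `qrs` column", call. = FALSE)
  }
  if (is.unsorted(df$qrs, strictly = TRUE)) {
    stop("annotation `qrs` indices must be strictly increasing", call. = FALSE)
  }
  grab <- function(col) if (col %in% names(df)) df[[col]] else NA_integer_
  beat_annotation(df$qrs, onset = grab("onset"), offset = grab("offset"),
                  p = grab("p"), t = grab("t"))
}

#' Read an ECG record from CSV or a WFDB (PhysioNet-style) record
#'
#' * `fmt = "csv"`: the dialect of [write_record()].  The sampling rate
#'   comes from the `# fs=` comment, or from the `fs` argument; a file
#'   without either is a configuration error.
#' * `fmt = "wfdb"`: `path` is the header file (`.hea`) or the record name;
#'   the binary signal file named in the header is read from the same
#'   directory.  Supports the common single-frequency header grammar and
#'   sample formats 16 (little-endian int16) and 212 (packed 12-bit),
#'   extracting one channel of possibly multi-channel records.  ADC units
#'   are converted to mV via the header's gain and baseline.
#'
#' @param path file path (see above).
#' @param fmt `"csv"` or `"wfdb"` (guessed from the extension by default).
#' @param fs sampling rate override, required for a CSV without metadata.
#' @param channel channel to extract from a multi-channel WFDB record
#'   (default 1).
#' @return an `ecg_signal`.
#' @export
read_record <- function(path, fmt = NULL, fs = NULL, channel = 1L) {
  if (is.null(fmt)) {
    fmt <- if (grepl("\\.hea$", path)) "wfdb" else "csv"
  }
  fmt <- match.arg(fmt, c("csv", "wfdb"))
  if (fmt == "csv") read_record_csv(path, fs) else read_record_wfdb(path, channel)
}

read_record_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  meta <- grep("^#", head_lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^#\\s*", key, "="), "", m[1])
  }
  fs_meta <- get_meta("fs")
  if (is.null(fs) && is.null(fs_meta)) {
    stop("CSV carries no `# fs=` metadata; pass `fs` explicitly",
         call. = FALSE)
  }
  fs <- if (!is.null(fs)) fs else as.numeric(fs_meta)
  lead <- get_meta("lead")
  t0 <- get_meta("t0")
  df <- utils::read.csv(path, comment.char = "#")
  vcol <- if ("voltage_mV" %in% names(df)) "voltage_mV" else names(df)[ncol(df)]
  ecg_signal(df[[vcol]], fs = fs,
             lead = if (is.null(lead)) "I" else lead,
             t0 = if (is.null(t0)) 0 else as.numeric(t0))
}

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3L) stop("malformed WFDB header record line", call. = FALSE)
  nsig <- as.integer(rec[2])
  fs <- as.numeric(sub("/.*", "", rec[3]))  # strip counter frequency
  nsamp <- if (length(rec) >= 4L) as.integer(rec[4]) else NA_integer_
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain_tok <- if (length(f) >= 3L) f[3] else "200"
    units <- if (grepl("/", gain_tok)) sub(".*/", "", gain_tok) else "mV"
    gain_tok <- sub("/.*", "", gain_tok)
    baseline <- 0
    if (grepl("\\(", gain_tok)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_tok))
      gain_tok <- sub("\\(.*", "", gain_tok)
    }
    gain <- as.numeric(gain_tok)
    if (!is.finite(gain) || gain == 0) gain <- 200
    list(file = f[1], fmt = sub("x.*|:.*|\\+.*", "", f[2]),
         gain = gain, baseline = baseline, units = units,
         desc = if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ")
                else paste0("ch", i))
  })
  list(record = rec[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_record_wfdb <- function(path, channel = 1L) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("no such header: ", hea_path, call. = FALSE)
  hdr <- parse_wfdb_header(hea_path)
  if (channel > hdr$nsig) {
    stop("record has only ", hdr$nsig, " channel(s)", call. = FALSE)
  }
  sig <- hdr$signals[[channel]]
  fmt <- hdr$signals[[1]]$fmt
  if (!fmt %in% c("16", "212")) {
    stop("unsupported WFDB sample format: ", fmt, call. = FALSE)
  }
  dat_path <- file.path(dirname(hea_path), sig$file)
  if (!file.exists(dat_path)) stop("no such signal file: ", dat_path, call. = FALSE)
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  adc <- if (fmt == "16") {
    readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
            signed = TRUE, endian = "little")
  } else {
    decode_fmt212(raw)
  }
  # channels are interleaved sample-by-sample
  adc <- adc[seq(channel, length(adc) - (hdr$nsig - channel), by = hdr$nsig)]
  if (!is.na(hdr$nsamp) && hdr$nsamp > 0 && length(adc) > hdr$nsamp) {
    adc <- adc[seq_len(hdr$nsamp)]
  }
  ecg_signal((adc - sig$baseline) / sig$gain, fs = hdr$fs, lead = sig$desc)
}

# WFDB format 212: pairs of 12-bit two's-complement samples packed into
# 3 bytes (low byte of s1; high nibbles of s2 and s1; low byte of s2)
decode_fmt212 <- function(raw) {
  n3 <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(n3)])
  b1 <- b[seq(1L, n3, by = 3L)]
  b2 <- b[seq(2L, n3, by = 3L)]
  b3 <- b[seq(3L, n3, by = 3L)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
  out <- numeric(2L * length(b1))
  out[c(TRUE, FALSE)] <- s1
  out[c(FALSE, TRUE)] <- s2
  out - 4096 * (out >= 2048)  # sign-extend 12-bit
}
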