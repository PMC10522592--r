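# Minimal single-channel EDF (European Data Format) I/O.
#
# EDF stores 16-bit integers with a linear physical/digital mapping declared
# in the header.  One signal per file, 1-second data records.  Recordings
# whose duration is not a whole number of seconds are zero-padded to the next
# record; the true sample count is kept in the reserved header field so the
# round trip is lossless in length.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param physical_range length-2 numeric, declared physical range in
#'   microvolts (default +-5000).  Samples outside the range are an error.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path, physical_range = c(-5000, 5000)) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sample rate", call. = FALSE)
  fs <- as.integer(round(fs))
  pmin <- physical_range[1]; pmax <- physical_range[2]
  if (pmax <= pmin) stop("invalid physical range", call. = FALSE)
  x <- rec$samples
  if (any(x < pmin | x > pmax))
    stop("samples exceed the declared physical range", call. = FALSE)
  dmin <- -32768; dmax <- 32767
  n <- length(x)
  nrec <- as.integer(ceiling(n / fs))
  dig <- as.integer(round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin))
  pad <- nrec * fs - n
  if (pad > 0L) {
    zero_dig <- as.integer(round((0 - pmin) / (pmax - pmin) * (dmax - dmin) + dmin))
    dig <- c(dig, rep(zero_dig, pad))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),                       # version
    edf_pad("X X X X", 80L),                # patient id
    edf_pad("Startdate X X X X", 80L),      # recording id
    edf_pad("01.01.00", 8L),                # start date
    edf_pad("00.00.00", 8L),                # start time
    edf_pad(256L + 256L, 8L),               # header bytes
    edf_pad(sprintf("n=%d;t0=%.9g", n, rec$t0), 44L),  # reserved
    edf_pad(nrec, 8L),
    edf_pad(1L, 8L),                        # record duration (s)
    edf_pad(1L, 4L))                        # number of signals
  sig <- paste0(
    edf_pad(rec$channel_name, 16L),
    edf_pad("", 80L),                       # transducer
    edf_pad("uV", 8L),
    edf_pad(format(pmin), 8L),
    edf_pad(format(pmax), 8L),
    edf_pad(dmin, 8L),
    edf_pad(dmax, 8L),
    edf_pad("", 80L),                       # prefiltering
    edf_pad(fs, 8L),                        # samples per record
    edf_pad("", 32L))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a single-channel EDF file
#'
#' @param path EDF file written by [write_edf()] or any single-channel EDF
#'   with 16-bit samples.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    s <- rawToChar(raw)
    Encoding(s) <- "latin1"  # header bytes may be arbitrary in corrupt files
    trimws(iconv(s, "latin1", "ASCII", sub = "?"))
  }
  version <- rd(8L)
  if (version != "0")
    stop(sprintf("not an EDF file: version field is '%s'", version), call. = FALSE)
  rd(80L); rd(80L); rd(8L); rd(8L)
  header_bytes <- as.integer(rd(8L))
  reserved <- rd(44L)
  nrec <- as.integer(rd(8L))
  recdur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L)
    stop("corrupt EDF header: bad number-of-signals field", call. = FALSE)
  if (ns != 1L)
    stop(sprintf("only single-channel EDF is supported (file has %d signals)", ns),
         call. = FALSE)
  label <- rd(16L); rd(80L); rd(8L)
  pmin <- as.numeric(rd(8L)); pmax <- as.numeric(rd(8L))
  dmin <- as.numeric(rd(8L)); dmax <- as.numeric(rd(8L))
  rd(80L)
  spr <- as.integer(rd(8L))
  rd(32L)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr, nrec, recdur)))
    stop("corrupt EDF header: non-numeric field", call. = FALSE)
  seek(con, header_bytes)
  dig <- readBin(con, "integer", n = nrec * spr, size = 2L,
                 signed = TRUE, endian = "little")
  x <- (dig - dmin) / (dmax - dmin) * (pmax - pmin) + pmin
  fs <- spr / recdur
  t0 <- 0
  n_true <- length(x)
  m <- regmatches(reserved, regexec("n=([0-9]+);t0=([-0-9.eE+]+)", reserved))[[1]]
  if (length(m) == 3L) {
    n_true <- min(as.integer(m[2]), length(x))
    t0 <- as.numeric(m[3])
  }
  eeg_recording(x[seq_len(n_true)], fs, t0 = t0, channel_name = label)
}
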