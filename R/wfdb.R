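# WFDB record and annotation input/output.
#
# Implements the subset of the WFDB spec needed here: header (.hea)
# parsing, signal formats 16 (16-bit little-endian) and 212 (paired
# 12-bit), and the MIT binary annotation stream (.atr), both directions.

# annotation code <-> mnemonic table (MIT annotation codes 1..41)
.ANN_CODES <- c(
  "N", "L", "R", "a", "V", "F", "J", "A", "S", "E",
  "j", "/", "Q", "~", "", "|", "", "s", "T", "*",
  "D", "\"", "=", "p", "B", "^", "t", "+", "u", "?",
  "!", "[", "]", "e", "n", "@", "x", "f", "(", ")", "r"
)

symbol_to_code <- function(symbol) {
  code <- match(symbol, .ANN_CODES)
  code[is.na(code)] <- 13L   # unknown -> Q (unclassifiable)
  code
}

#' Read a WFDB record
#'
#' Parses the `.hea` header, decodes the signal file (formats 16 and
#' 212), converts to physical units using gain and baseline, selects one
#' lead and, when an annotation file is present, attaches beat
#' annotations.
#'
#' @param path path to the record, with or without the `.hea` extension.
#' @param channel 1-based lead to extract (default 1).
#' @param annotator extension of the annotation file (default `"atr"`);
#'   `NULL` skips annotations.
#' @return A `raw_record`: list with `record_id`, `samples` (mV), `fs`,
#'   `lead_name`, and `annotations` (tibble: `sample_index` 0-based,
#'   `symbol`).
#' @export
read_record <- function(path, channel = 1L, annotator = "atr") {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea))
    rlang::abort(paste0("cannot read WFDB header: ", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- sub("/.*$", "", rec[1])
  nsig <- as.integer(rec[2])
  if (is.na(nsig) || nsig < 1L)
    rlang::abort(paste0("record has no signals: ", hea))
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*$", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_
  specs <- lapply(lines[2:(1 + nsig)], parse_signal_spec)
  if (channel < 1L || channel > nsig)
    rlang::abort("requested channel does not exist in the record.")
  fnames <- unique(vapply(specs, `[[`, character(1), "file"))
  if (length(fnames) != 1L)
    rlang::abort("multi-file signal groups are not supported.")
  dat <- file.path(dirname(hea), fnames[[1]])
  if (!file.exists(dat))
    rlang::abort(paste0("cannot read WFDB signal file: ", dat))
  fmt <- specs[[1]]$fmt
  digital <- read_signal_matrix(dat, fmt, nsig)
  if (!is.na(nsamp) && nrow(digital) > nsamp)
    digital <- digital[seq_len(nsamp), , drop = FALSE]
  sp <- specs[[channel]]
  samples <- (digital[, channel] - sp$baseline) / sp$gain
  ann <- empty_ann_tbl()
  if (!is.null(annotator)) {
    af <- file.path(dirname(hea),
                    paste0(sub("\\.hea$", "", basename(hea)), ".", annotator))
    if (file.exists(af)) ann <- read_annotations(af)
  }
  new_raw_record(record_id, samples, fs, sp$desc, ann)
}

parse_signal_spec <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  fmt <- as.integer(sub("[x:+].*$", "", f[2]))
  gain <- 200; baseline <- 0
  if (length(f) >= 3) {
    g <- f[3]
    if (grepl("\\(", g)) baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", g))
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", g)))
    if (is.na(gain) || gain == 0) gain <- 200
  }
  # adc resolution (f[4]) and adczero (f[5]) are not needed for decoding
  desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else "ECG"
  list(file = f[1], fmt = fmt, gain = gain, baseline = baseline, desc = desc)
}

read_signal_matrix <- function(dat, fmt, nsig) {
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  if (fmt == 16L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
    n <- length(v) %/% nsig
    matrix(v[seq_len(n * nsig)], ncol = nsig, byrow = TRUE)
  } else if (fmt == 212L) {
    b <- as.integer(raw)
    ntrip <- length(b) %/% 3L
    i <- 3L * (seq_len(ntrip) - 1L)
    s1 <- b[i + 1L] + bitwAnd(b[i + 2L], 0x0FL) * 256L
    s2 <- b[i + 3L] + bitwAnd(bitwShiftR(b[i + 2L], 4L), 0x0FL) * 256L
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
    n <- length(v) %/% nsig
    matrix(v[seq_len(n * nsig)], ncol = nsig, byrow = TRUE)
  } else {
    rlang::abort(paste0("unsupported WFDB signal format: ", fmt))
  }
}

#' Read a WFDB annotation file (MIT format)
#'
#' @param path path to the annotation file.
#' @return Tibble with `sample_index` (0-based) and `symbol`.
#' @export
read_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  words <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = FALSE, endian = "little")
  idx <- integer(0); sym <- character(0)
  t <- 0; i <- 1L; pend_skip <- 0
  while (i <= length(words)) {
    w <- words[i]
    code <- w %/% 1024L
    interval <- w %% 1024L
    if (code == 0L && interval == 0L) break
    if (code == 59L) {          # SKIP: next two words hold a long interval
      hi <- words[i + 1L]; lo <- words[i + 2L]
      v <- hi * 65536 + lo
      if (v >= 2^31) v <- v - 2^32
      pend_skip <- pend_skip + v
      i <- i + 3L
    } else if (code %in% c(60L, 61L, 62L)) {  # NUM/SUB/CHN modifiers
      i <- i + 1L
    } else if (code == 63L) {   # AUX: interval = byte count, padded to even
      i <- i + 1L + (interval + interval %% 2L) %/% 2L
    } else {
      t <- t + interval + pend_skip
      pend_skip <- 0
      idx <- c(idx, t)
      sym <- c(sym, if (code >= 1L && code <= length(.ANN_CODES))
                      .ANN_CODES[code] else "Q")
      i <- i + 1L
    }
  }
  tibble::tibble(sample_index = as.numeric(idx), symbol = sym)
}

#' Write a WFDB record (+ annotations)
#'
#' Writes a format-16 single- or multi-lead record: `.hea` header,
#' `.dat` signal file and, if annotations are present, a MIT-format
#' annotation file. Physical samples are quantised with the given gain,
#' so a read-back matches to within 1/(2 gain).
#'
#' @param record a `raw_record`.
#' @param dir output directory (created if needed).
#' @param gain ADC gain in units per mV (default 200).
#' @param annotator annotation extension (default `"atr"`).
#' @return The record path (without extension), invisibly.
#' @export
write_record <- function(record, dir, gain = 200, annotator = "atr") {
  stopifnot(inherits(record, "raw_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, record$record_id)
  digital <- as.integer(round(record$samples * gain))
  if (any(abs(digital) > 32767))
    rlang::abort("signal exceeds the 16-bit range at this gain.")
  writeLines(c(
    sprintf("%s 1 %g %d", record$record_id, record$fs, length(digital)),
    sprintf("%s.dat 16 %g 16 0 %d 0 0 %s", record$record_id, gain,
            digital[1], record$lead_name)
  ), paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(digital, con, size = 2L, endian = "little")
  close(con)
  if (nrow(record$annotations) > 0 && !is.null(annotator))
    write_annotations(record$annotations, paste0(base, ".", annotator))
  invisible(base)
}

#' Write a WFDB annotation file (MIT format)
#'
#' @param ann tibble with `sample_index` (0-based, sorted) and `symbol`.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(all(diff(ann$sample_index) >= 0))
  codes <- symbol_to_code(ann$symbol)
  deltas <- diff(c(0, ann$sample_index))
  words <- integer(0)
  for (k in seq_along(deltas)) {
    d <- deltas[k]
    if (d >= 1024) {   # emit SKIP with a 32-bit interval, then a zero-delta
      words <- c(words, 59L * 1024L, d %/% 65536, d %% 65536)
      d <- 0
    }
    words <- c(words, codes[k] * 1024L + d)
  }
  words <- c(words, 0L)   # EOF
  con <- file(path, "wb")
  writeBin(as.integer(words), con, size = 2L, endian = "little")
  close(con)
}

new_raw_record <- function(record_id, samples, fs, lead_name, annotations) {
  if (fs <= 0 || length(samples) == 0)
    rlang::abort("a record needs fs > 0 and a non-empty signal.")
  ann <- annotations[order(annotations$sample_index), , drop = FALSE]
  ann <- ann[ann$sample_index >= 0 & ann$sample_index < length(samples), ,
             drop = FALSE]
  structure(list(record_id = record_id, samples = as.numeric(samples),
                 fs = fs, lead_name = lead_name, annotations = ann),
            class = "raw_record")
}

empty_ann_tbl <- function() {
  tibble::tibble(sample_index = numeric(), symbol = character())
}

#' @export
print.raw_record <- function(x, ...) {
  cat(sprintf("<raw_record %s> %d samples @ %g Hz (%.1f s), lead %s, %d annotations\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$lead_name, nrow(x$annotations)))
  invisible(x)
}
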