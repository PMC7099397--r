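# Minimal WFDB support: header (.hea) parsing, signal formats 16 and 212,
# and the MIT annotation (.atr) byte format. Covers what is needed to read
# MIT-BIH-style records and to round-trip records written by this package;
# it is not a general WFDB implementation (no multi-segment records, no
# formats 80/24/32, no calibration files).

# WFDB annotation type codes -> display symbols (beat and non-beat).
.WFDB_CODE_SYMBOL <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r")
.WFDB_SYMBOL_CODE <- stats::setNames(as.integer(names(.WFDB_CODE_SYMBOL)),
                                     unname(.WFDB_CODE_SYMBOL))

parse_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) stopf("cannot read WFDB header '%s'", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  n_samp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sigs <- lapply(seq_len(n_sig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "[ \t]+")[[1]]
    gain_field <- f[3]
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field))
      as.integer(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    else if (length(f) >= 5) as.integer(f[5]) else 0L
    if (is.na(baseline)) baseline <- 0L
    list(file = f[1], format = as.integer(sub("x.*|:.*|\\+.*", "", f[2])),
         gain = gain, baseline = baseline,
         description = if (length(f) >= 9)
           paste(f[9:length(f)], collapse = " ") else sprintf("sig%d", i))
  })
  list(record = rec[1], n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sigs)
}

read_dat_16 <- function(path, n_sig, n_samp) {
  raw_n <- file.size(path) / 2L
  v <- readBin(path, "integer", n = raw_n, size = 2L, signed = TRUE,
               endian = "little")
  matrix(v, ncol = n_sig, byrow = TRUE)
}

read_dat_212 <- function(path, n_sig, n_samp) {
  b <- as.integer(readBin(path, "raw", n = file.size(path)))
  n_tri <- length(b) %/% 3L
  b1 <- b[seq(1, by = 3, length.out = n_tri)]
  b2 <- b[seq(2, by = 3, length.out = n_tri)]
  b3 <- b[seq(3, by = 3, length.out = n_tri)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0F), 8)      # low nibble of b2 = high bits
  s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4), 0x0F), 8)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  v <- as.vector(rbind(s1, s2))
  matrix(v[seq_len((length(v) %/% n_sig) * n_sig)], ncol = n_sig, byrow = TRUE)
}

read_record_wfdb <- function(path) {
  hdr <- parse_wfdb_header(paste0(path, ".hea"))
  dat_path <- file.path(dirname(paste0(path, ".hea")), hdr$signals[[1]]$file)
  if (!file.exists(dat_path)) stopf("cannot read WFDB signal file '%s'", dat_path)
  fmt <- hdr$signals[[1]]$format
  dig <- switch(as.character(fmt),
                "16" = read_dat_16(dat_path, hdr$n_sig, hdr$n_samp),
                "212" = read_dat_212(dat_path, hdr$n_sig, hdr$n_samp),
                stopf("unsupported WFDB signal format %s", fmt))
  if (!is.na(hdr$n_samp)) dig <- dig[seq_len(min(nrow(dig), hdr$n_samp)), ,
                                     drop = FALSE]
  s1 <- hdr$signals[[1]]
  mv <- (dig[, 1] - s1$baseline) / s1$gain
  record <- ecg_record(mv, hdr$fs, subject_id = hdr$record,
                       lead_label = s1$description)
  atr_path <- paste0(path, ".atr")
  n_skipped <- 0L
  if (file.exists(atr_path)) {
    ann_raw <- read_wfdb_annotations(atr_path)
    keep <- ann_raw$symbol %in% names(.AAMI_SYMBOL_MAP)
    n_skipped <- sum(!keep)
    ann_raw <- ann_raw[keep & ann_raw$sample_index < length(mv), , drop = FALSE]
    ann <- beat_annotations(ann_raw$sample_index, ann_raw$symbol,
                            signal_length = length(mv))
  } else {
    ann <- beat_annotations(integer(0), character(0))
  }
  attr(ann, "n_skipped_symbols") <- n_skipped
  list(record = record, annotations = ann)
}

read_wfdb_annotations <- function(atr_path) {
  b <- as.integer(readBin(atr_path, "raw", n = file.size(atr_path)))
  idx <- integer(0); sym <- character(0)
  t_cur <- 0; i <- 1L; n <- length(b)
  while (i + 1L <= n) {
    w <- b[i] + bitwShiftL(b[i + 1L], 8)
    i <- i + 2L
    code <- bitwShiftR(w, 10)
    tfield <- bitwAnd(w, 1023L)
    if (w == 0L) break                       # EOF
    if (code == 59L) {                       # SKIP: 4-byte interval follows
      if (i + 3L > n) break
      msw <- b[i] + bitwShiftL(b[i + 1L], 8)
      lsw <- b[i + 2L] + bitwShiftL(b[i + 3L], 8)
      i <- i + 4L
      t_cur <- t_cur + msw * 65536 + lsw
    } else if (code == 63L) {                # AUX: skip payload (even-padded)
      skip <- tfield + (tfield %% 2L)
      i <- i + skip
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN modifiers: no time advance, ignore value
    } else {
      t_cur <- t_cur + tfield
      s <- .WFDB_CODE_SYMBOL[[as.character(code)]] %||% NA_character_
      if (!is.na(s)) { idx <- c(idx, t_cur); sym <- c(sym, s) }
    }
  }
  data.frame(sample_index = as.integer(idx), symbol = sym,
             stringsAsFactors = FALSE)
}

# Write a single-signal record as format 16 with gain 200 adu/mV, plus an
# MIT-format annotation file. Quantization to the ADC grid loses < 2.5 uV.
write_record_wfdb <- function(record, annotations, path) {
  gain <- 200
  dig <- as.integer(round(record$signal * gain))
  dig <- pmax(pmin(dig, 32767L), -32768L)
  base <- basename(path)
  hea <- c(sprintf("%s 1 %g %d", base, record$sampling_rate,
                   length(dig)),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s", base, gain,
                   dig[1], 0L, gsub(" ", "_", record$lead_label)))
  writeLines(hea, paste0(path, ".hea"))
  writeBin(dig, paste0(path, ".dat"), size = 2L, endian = "little")
  write_wfdb_annotations(annotations, paste0(path, ".atr"))
  invisible(path)
}

write_wfdb_annotations <- function(annotations, atr_path) {
  con <- file(atr_path, "wb")
  on.exit(close(con))
  t_prev <- 0
  put_word <- function(w) writeBin(as.integer(c(bitwAnd(w, 255L),
                                                bitwShiftR(w, 8))),
                                   con, size = 1L)
  for (k in seq_len(nrow(annotations))) {
    code <- .WFDB_SYMBOL_CODE[[annotations$symbol[k]]] %||%
      stopf("symbol '%s' has no WFDB code", annotations$symbol[k])
    delta <- annotations$sample_index[k] - t_prev
    t_prev <- annotations$sample_index[k]
    if (delta >= 1024) {
      put_word(bitwShiftL(59L, 10))
      msw <- delta %/% 65536; lsw <- delta %% 65536
      writeBin(as.integer(c(bitwAnd(msw, 255L), bitwShiftR(msw, 8),
                            bitwAnd(lsw, 255L), bitwShiftR(lsw, 8))),
               con, size = 1L)
      delta <- 0L
    }
    put_word(bitwShiftL(code, 10) + delta)
  }
  put_word(0L)
  invisible(atr_path)
}
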