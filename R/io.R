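#' Derive a component seed from a master seed
#'
#' Hashes a master seed and a component label into a reproducible 31-bit
#' seed, so one `--seed` flag controls every randomized step without the
#' steps sharing a stream.
#'
#' @param master Integer master seed.
#' @param label Character tag naming the component.
#' @return An integer in `[0, 2^31)`.
#' @export
derive_seed <- function(master, label) {
  bytes <- utf8ToInt(paste0(label, ":"))
  h <- as.numeric(master) %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Write an annotated record to plain-text files
#'
#' `<prefix>_signal.csv` holds one sample per row (17 significant digits, so
#' a read round-trip is bit exact), `<prefix>_annotations.csv` the 1-based
#' fetal/maternal R-peak indices, and `<prefix>_meta.json` the sampling rate
#' and subject id. Clean components, when present, are stored alongside the
#' signal.
#'
#' @param rec An `aecg` record.
#' @param prefix Path prefix for the three files.
#' @return Invisibly, the three file paths.
#' @export
write_aecg <- function(rec, prefix) {
  sig <- data.frame(signal = rec$signal)
  if (!is.null(rec$fetal_clean)) sig$fetal_clean <- rec$fetal_clean
  if (!is.null(rec$maternal_clean)) sig$maternal_clean <- rec$maternal_clean
  f_sig <- paste0(prefix, "_signal.csv")
  f_ann <- paste0(prefix, "_annotations.csv")
  f_meta <- paste0(prefix, "_meta.json")
  old <- options(digits = 17)
  on.exit(options(old))
  utils::write.csv(format(sig, digits = 17, trim = TRUE), f_sig,
                   row.names = FALSE, quote = FALSE)
  ann <- rbind(
    data.frame(channel = "fetal", sample_index = rec$fetal_rpeaks),
    data.frame(channel = "maternal", sample_index = rec$maternal_rpeaks))
  utils::write.csv(ann, f_ann, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs, subject_id = rec$subject_id),
                       f_meta, auto_unbox = TRUE)
  invisible(c(f_sig, f_ann, f_meta))
}

#' Read a record written by [write_aecg()]
#'
#' @param prefix Path prefix used at write time.
#' @return An `aecg` record.
#' @export
read_aecg <- function(prefix) {
  sig <- utils::read.csv(paste0(prefix, "_signal.csv"))
  ann <- utils::read.csv(paste0(prefix, "_annotations.csv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))
  structure(list(
    signal = as.numeric(sig$signal), fs = meta$fs,
    fetal_rpeaks = as.integer(ann$sample_index[ann$channel == "fetal"]),
    maternal_rpeaks = as.integer(ann$sample_index[ann$channel == "maternal"]),
    fetal_clean = if ("fetal_clean" %in% names(sig)) as.numeric(sig$fetal_clean) else NULL,
    maternal_clean = if ("maternal_clean" %in% names(sig)) as.numeric(sig$maternal_clean) else NULL,
    subject_id = meta$subject_id
  ), class = "aecg")
}

#' Read a DaISy-style whitespace ASCII matrix
#'
#' The cutaneous-recordings matrix format: whitespace-delimited numbers,
#' first column the time axis, then eight signal columns, sampled at 250 Hz.
#'
#' @param path File path.
#' @param channel Signal channel 1--8 (column `channel + 1` of the matrix).
#' @param fs Sampling rate (default 250 Hz).
#' @return An `aecg` record without annotations.
#' @export
read_daisy_ascii <- function(path, channel, fs = 250) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.table(path),
                 warning = function(w) stop("parse error in ", path),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  mat <- suppressWarnings(as.matrix(data.frame(lapply(df, as.numeric))))
  if (anyNA(mat)) {
    bad_line <- which(rowSums(is.na(mat)) > 0)[1]
    stop(sprintf("parse error in %s: non-numeric content at line %d",
                 path, bad_line))
  }
  n_sig <- ncol(mat) - 1L
  if (channel < 1 || channel > n_sig)
    stop(sprintf("channel %d unavailable: file has %d signal columns",
                 channel, n_sig))
  structure(list(signal = as.numeric(mat[, channel + 1L]), fs = fs,
                 fetal_rpeaks = integer(0), maternal_rpeaks = integer(0),
                 subject_id = basename(path)), class = "aecg")
}

#' Read one channel of a WFDB record
#'
#' Minimal reader for MIT-format records: parses the `.hea` header and reads
#' the `.dat` samples for formats 16 (little-endian int16) and 212 (packed
#' 12-bit pairs). R-peak annotations are loaded from a `<record>_fqrs.csv`
#' sidecar (one 1-based `sample_index` per row) when present; binary
#' annotation files are out of scope.
#'
#' @param path Record path without extension.
#' @param channel 1-based channel index.
#' @return An `aecg` record.
#' @export
read_wfdb_record <- function(path, channel = 1) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(hdr[2])
  fs <- if (length(hdr) >= 3) as.numeric(hdr[3]) else 250
  n_samp <- if (length(hdr) >= 4) as.integer(hdr[4]) else NA_integer_
  if (channel < 1 || channel > n_sig) {
    descs <- vapply(lines[1 + seq_len(n_sig)], function(l) {
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      parts[length(parts)]
    }, character(1))
    stop(sprintf("channel %d unavailable; record has %d channel(s) in: %s",
                 channel, n_sig, paste(unique(descs), collapse = ", ")))
  }
  sig_line <- strsplit(trimws(lines[1 + channel]), "\\s+")[[1]]
  fmt <- as.integer(sub("x.*|:.*|\\+.*", "", sig_line[2]))
  dat <- file.path(dirname(path),
                   strsplit(trimws(lines[2]), "\\s+")[[1]][1])
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  if (fmt == 16) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                 endian = "little", signed = TRUE)
    m <- matrix(v[seq_len((length(v) %/% n_sig) * n_sig)], nrow = n_sig)
    sig <- as.numeric(m[channel, ])
  } else if (fmt == 212) {
    if (n_sig > 2) stop("format 212 supported for records with at most 2 channels")
    b <- as.integer(raw)
    n3 <- (length(b) %/% 3) * 3
    b1 <- b[seq(1, n3, 3)]; b2 <- b[seq(2, n3, 3)]; b3 <- b[seq(3, n3, 3)]
    s1 <- b1 + bitwAnd(b2, 15L) * 256L
    s2 <- b3 + bitwAnd(b2 %/% 16L, 15L) * 256L
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    pair <- rbind(s1, s2)
    sig <- if (n_sig == 1) as.numeric(pair) else as.numeric(pair[channel, ])
  } else stop("unsupported WFDB format: ", fmt)
  if (!is.na(n_samp) && n_samp > 0 && length(sig) > n_samp) sig <- sig[seq_len(n_samp)]
  ann_file <- paste0(path, "_fqrs.csv")
  fqrs <- if (file.exists(ann_file))
    as.integer(utils::read.csv(ann_file)$sample_index) else integer(0)
  structure(list(signal = sig, fs = fs, fetal_rpeaks = fqrs,
                 maternal_rpeaks = integer(0), subject_id = basename(path)),
            class = "aecg")
}
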