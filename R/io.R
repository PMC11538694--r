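#' Write a recording as columnar CSV
#'
#' Plain-text interchange format: metadata and montage as `#`-prefixed
#' header lines (key=value), then a `time, <channel...>` table in seconds
#' and microvolts.
#'
#' @param rec a [Recording-class].
#' @param path output file path.
#' @export
writeRecordingCSV <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", rec@fs), con)
  m <- rec@montage
  writeLines(sprintf("# regions=%s",
                     paste(sprintf("%s:%s", m@channels, m@regions[m@channels]),
                           collapse = ",")), con)
  if (length(m@excluded))
    writeLines(sprintf("# excluded=%s", paste(m@excluded, collapse = ",")), con)
  for (k in names(rec@meta)) {
    v <- rec@meta[[k]]
    if (length(v) == 1 && (is.character(v) || is.numeric(v)))
      writeLines(sprintf("# meta.%s=%s", k, v), con)
  }
  df <- data.frame(time = (seq_len(ncol(rec@samples)) - 1) / rec@fs,
                   t(rec@samples))
  colnames(df) <- c("time", m@channels)
  utils::write.csv(format(df, digits = 8, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
}

#' Read a recording from columnar CSV
#'
#' @param path a file written by [writeRecordingCSV].
#' @return a [Recording-class].
#' @export
readRecordingCSV <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    sub(sprintf("^# %s=", key), "", m[1])
  }
  fs <- as.numeric(getv("fs"))
  regPairs <- strsplit(strsplit(getv("regions"), ",")[[1]], ":")
  channels <- vapply(regPairs, `[`, "", 1)
  regions <- vapply(regPairs, `[`, "", 2)
  names(regions) <- channels
  excl <- getv("excluded")
  excluded <- if (is.null(excl)) character() else strsplit(excl, ",")[[1]]
  meta <- list()
  for (m in grep("^# meta\\.", hdr, value = TRUE)) {
    kv <- sub("^# meta\\.", "", m)
    key <- sub("=.*", "", kv)
    val <- sub("^[^=]*=", "", kv)
    nv <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(nv)) nv else val
  }
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  X <- t(as.matrix(df[, channels, drop = FALSE]))
  rownames(X) <- channels
  mont <- new("Montage", channels = channels, regions = regions,
              excluded = excluded)
  new("Recording", samples = X, fs = fs, montage = mont,
      validMask = rep(TRUE, ncol(X)), meta = meta)
}
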