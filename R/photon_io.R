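#' Read a time-tagged photon file
#'
#' Two dialects are defined. `"columnar_text"` is a plain-text format:
#' header lines of the form `#key=value` carrying the metadata
#' (`tick_s`, `tcspc_bin_s`, `sync_rate_hz`, `duration_s`), followed by three
#' tab-separated integer columns `macrotime_tick`, `nanotime_bin`,
#' `detector`. Integers are written in full decimal notation so the round
#' trip is bit-exact. `"photon_hdf5"` refers to the Photon-HDF5 layout
#' (photon_data group with timestamps/nanotimes/detectors plus a setup group);
#' reading it requires the `rhdf5` package.
#'
#' @param path file to read.
#' @param dialect `"columnar_text"` (default) or `"photon_hdf5"`.
#' @return a validated [photon_stream()] with metadata preserved verbatim.
#' @export
read_photon_file <- function(path, dialect = c("columnar_text", "photon_hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "photon_hdf5") {
    stop("read_photon_file: the photon_hdf5 dialect requires the 'rhdf5' package; ",
         "use dialect = 'columnar_text'")
  }
  if (!file.exists(path)) stop("read_photon_file: file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- sub("^#", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  required <- c("tick_s", "tcspc_bin_s", "sync_rate_hz", "duration_s")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("read_photon_file: missing metadata key(s): ", paste(missing, collapse = ", "))
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(body)]
  if (length(body)) {
    con <- textConnection(body)
    on.exit(close(con))
    tab <- utils::read.table(con, sep = "\t",
                             colClasses = c("numeric", "numeric", "integer"),
                             col.names = c("macrotime_tick", "nanotime_bin", "detector"))
  } else {
    tab <- data.frame(macrotime_tick = numeric(0), nanotime_bin = numeric(0),
                      detector = integer(0))
  }
  photon_stream(
    macrotimes = tab$macrotime_tick,
    nanotimes = tab$nanotime_bin,
    detectors = tab$detector,
    tick_s = as.numeric(meta$tick_s),
    tcspc_bin_s = as.numeric(meta$tcspc_bin_s),
    sync_rate_hz = as.numeric(meta$sync_rate_hz),
    duration_s = as.numeric(meta$duration_s)
  )
}

#' Write a time-tagged photon file
#'
#' Validates the stream, then writes the columnar-text dialect described in
#' [read_photon_file()]. The round trip through
#' `read_photon_file(write_photon_file(x))` is loss-free.
#'
#' @param stream a valid [photon_stream()].
#' @param path output file.
#' @param dialect see [read_photon_file()].
#' @return `path`, invisibly.
#' @export
write_photon_file <- function(stream, path,
                              dialect = c("columnar_text", "photon_hdf5")) {
  dialect <- match.arg(dialect)
  validate_photon_stream(stream)
  if (dialect == "photon_hdf5") {
    stop("write_photon_file: the photon_hdf5 dialect requires the 'rhdf5' package; ",
         "use dialect = 'columnar_text'")
  }
  hdr <- c(
    "#format=pieburst-photon-columnar-v1",
    sprintf("#tick_s=%.17g", stream$tick_s),
    sprintf("#tcspc_bin_s=%.17g", stream$tcspc_bin_s),
    sprintf("#sync_rate_hz=%.17g", stream$sync_rate_hz),
    sprintf("#duration_s=%.17g", stream$duration_s),
    sprintf("#n_photons=%d", n_photons(stream))
  )
  body <- if (n_photons(stream)) {
    paste(sprintf("%.0f", stream$macrotimes),
          sprintf("%.0f", stream$nanotimes),
          stream$detectors, sep = "\t")
  } else {
    character(0)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
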