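# Text-based, self-describing serialization shared by all stages: gridded
# fields as a JSON header line plus full-precision data rows, site tables as
# tab-delimited text with a JSON comment header. Round-trips are lossless
# (values are written with 17 significant digits, enough to reproduce any
# double exactly).

#' Provenance block for output files
#'
#' Every file the pipeline writes carries the package version, a stable hash
#' of the run configuration, and a creation stamp, so a result can be traced
#' to the config + seed that produced it.
#'
#' @param config Serializable configuration (list) or `NULL`.
#' @return Named list (`package`, `version`, `config_hash`, `created`).
#' @export
provenance_block <- function(config = NULL) {
  list(package = "windwue",
       version = as.character(utils::packageVersion("windwue")),
       config_hash = if (is.null(config)) NA_character_ else
         text_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

fmt_vals <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- "NA"
  out
}

#' Write a gridded field to a self-describing text file
#'
#' First line: a JSON header (`name`, `units`, `time`, `lat`, `lon`,
#' `provenance`). Then one whitespace-separated row of `%.17g` values per
#' time slice (pixels in column-major lat-lon order); missing cells are
#' `NA`. [read_gridded()] restores the field bit-exactly.
#'
#' @param field A [gridded_field()].
#' @param path Output path.
#' @param config Optional run configuration folded into the provenance hash.
#' @return `path`, invisibly.
#' @export
write_gridded <- function(field, path, config = NULL) {
  stopifnot(inherits(field, "gridded_field"))
  header <- jsonlite::toJSON(
    list(format = "windwue-gridded-1", name = field$name,
         units = field$units, time = field$time, lat = field$lat,
         lon = field$lon, provenance = provenance_block(config)),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  m <- pixel_matrix(field)
  for (t in seq_len(nrow(m))) {
    writeLines(paste(fmt_vals(m[t, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a gridded field written by [write_gridded()]
#'
#' Rejects files whose header lacks a units attribute instead of guessing.
#'
#' @param path Input path.
#' @return A [gridded_field()]; the file's provenance block is attached as
#'   attribute `provenance`.
#' @export
read_gridded <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$format, "windwue-gridded-1")) {
    stop("not a windwue gridded file: ", path, call. = FALSE)
  }
  if (is.null(header$units) || !nzchar(header$units)) {
    stop("gridded file has no units attribute: ", path, call. = FALSE)
  }
  ntime <- length(header$time)
  nlat <- length(header$lat)
  nlon <- length(header$lon)
  vals <- matrix(NA_real_, ntime, nlat * nlon)
  for (t in seq_len(ntime)) {
    vals[t, ] <- scan(text = lines[t + 1L], quiet = TRUE, na.strings = "NA")
  }
  out <- gridded_field(array(vals, c(ntime, nlat, nlon)), header$time,
                       header$lat, header$lon, header$name, header$units)
  attr(out, "provenance") <- header$provenance
  out
}

#' Write a site (or any) table as annotated tab-delimited text
#'
#' Plain TSV preceded by `#`-prefixed JSON lines carrying the provenance
#' block, readable back with [read_site_table()] or any TSV reader that
#' skips comments.
#'
#' @param table Data frame.
#' @param path Output path.
#' @param config Optional configuration for the provenance hash.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path, config = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(provenance_block(config),
                                           auto_unbox = TRUE, digits = NA)),
             con)
  utils::write.table(table, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a table written by [write_site_table()]
#'
#' @param path Input path.
#' @return Data frame; provenance attached as attribute `provenance`.
#' @export
read_site_table <- function(path) {
  lines <- readLines(path, n = 1L)
  prov <- if (startsWith(lines[1], "# ")) {
    jsonlite::fromJSON(sub("^# ", "", lines[1]))
  } else NULL
  out <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if ("date" %in% names(out)) out$date <- as.Date(out$date)
  attr(out, "provenance") <- prov
  out
}
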