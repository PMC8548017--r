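# DTOF container file format: a documented JSON schema holding an
# instrument configuration block and a list of DTOF records (counts are
# integer-exact, so write-then-read round trips losslessly).

CONTAINER_FORMAT <- "tdnirs-dtof-container"
CONTAINER_VERSION <- "1.0"

#' Write a DTOF container file
#'
#' JSON layout: `format`, `version`, optional `config` block, and
#' `records`, each with `counts` (integers), `bin_width`,
#' `channel_wavelength`, `rho`, `acquisition_time`, `background_level`
#' and `role` (`"measurement"` or `"irf"`). All records must share the
#' number of bins and the bin width.
#'
#' @param records list of [dtof()]s.
#' @param path output path.
#' @param config optional [instrument_config()] stored alongside.
#' @return `path`, invisibly.
#' @export
write_dtof_container <- function(records, path, config = NULL) {
  if (!length(records) || !all(vapply(records, inherits, logical(1),
                                      "dtof")))
    stop("write_dtof_container: records must be a non-empty list of dtof")
  nb <- vapply(records, function(d) length(d$counts), integer(1))
  bw <- vapply(records, `[[`, numeric(1), "bin_width")
  if (length(unique(nb)) != 1L || length(unique(bw)) != 1L)
    stop("write_dtof_container: records have mixed bin counts or widths")
  payload <- list(
    format = CONTAINER_FORMAT, version = CONTAINER_VERSION,
    config = if (is.null(config)) NULL else unclass(config),
    records = lapply(records, function(d) {
      list(counts = as.integer(round(d$counts)), bin_width = d$bin_width,
           channel_wavelength = d$channel_wavelength, rho = d$rho,
           acquisition_time = d$acquisition_time,
           background_level = d$background_level, role = d$role)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a DTOF container file
#'
#' @param path file written by [write_dtof_container()].
#' @param require_irf error unless at least one record has role `"irf"`.
#' @return list with `records` (list of [dtof()]s) and `config` (plain
#'   list or `NULL`).
#' @export
read_dtof_container <- function(path, require_irf = FALSE) {
  if (!file.exists(path)) stop("read_dtof_container: no such file: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$format) || x$format != CONTAINER_FORMAT)
    stop("read_dtof_container: not a DTOF container")
  if (is.null(x$version) || x$version != CONTAINER_VERSION)
    stop("read_dtof_container: unsupported container version: ",
         x$version)
  if (!length(x$records)) stop("read_dtof_container: empty container")
  as_num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  records <- lapply(x$records, function(r) {
    dtof(vapply(r$counts, as.numeric, numeric(1)),
         bin_width = as.numeric(r$bin_width),
         channel_wavelength = as_num(r$channel_wavelength),
         rho = as_num(r$rho), acquisition_time = as_num(r$acquisition_time),
         background_level = as_num(r$background_level),
         role = if (is.null(r$role)) "measurement" else r$role)
  })
  nb <- vapply(records, function(d) length(d$counts), integer(1))
  bw <- vapply(records, `[[`, numeric(1), "bin_width")
  if (length(unique(nb)) != 1L || length(unique(bw)) != 1L)
    stop("read_dtof_container: records have mixed bin counts or widths")
  if (require_irf &&
      !any(vapply(records, function(d) identical(d$role, "irf"),
                  logical(1))))
    stop("read_dtof_container: container has no IRF record")
  list(records = records, config = x$config)
}
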