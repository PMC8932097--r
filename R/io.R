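#' CSV readers and writers
#'
#' All tables are UTF-8, comma-separated, header row mandatory; years
#' are integers and prevalences are on the 0-100 percent scale.
#' Readers validate the schema and report offending rows by line
#' number (header = line 1).
#'
#' @name csv_io
NULL

.read_checked <- function(path, need) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  x
}

.row_stop <- function(bad, what) {
  # +1 for the header line
  stop(what, " at line(s): ", paste(which(bad) + 1L, collapse = ", "))
}

#' @rdname csv_io
#' @param path file path.
#' @export
read_climate_csv <- function(path) {
  x <- .read_checked(path, c("region_id", "year", "month", "tmean_c", "precip_mm"))
  if (any(bad <- !(x$month %in% 1:12))) .row_stop(bad, "month outside 1..12")
  if (any(bad <- !is.na(x$precip_mm) & x$precip_mm < 0)) {
    .row_stop(bad, "negative precipitation")
  }
  .check_climate(x, need_precip = TRUE)
  x
}

#' @rdname csv_io
#' @export
read_responses_csv <- function(path) {
  x <- .read_checked(path, c("region_id", "year", "weight", paste0("q", 1:8)))
  if (any(bad <- !is.na(x$weight) & x$weight <= 0)) {
    .row_stop(bad, "non-positive survey weight")
  }
  q <- as.matrix(x[, paste0("q", 1:8)])
  if (any(bad <- apply(q, 1L, function(r) any(!is.na(r) & !(r %in% 0:1))))) {
    .row_stop(bad, "non-binary item answer")
  }
  x
}

#' @rdname csv_io
#' @export
read_panel_csv <- function(path) {
  x <- .read_checked(path, c("region_id", "year", "anomaly", "shdi_scaled",
                             "drought", "msfi", "sfi"))
  for (cl in c("msfi", "sfi")) {
    if (any(bad <- !is.na(x[[cl]]) & (x[[cl]] < 0 | x[[cl]] > 100))) {
      .row_stop(bad, paste0(cl, " outside [0, 100]"))
    }
  }
  if (anyDuplicated(paste(x$region_id, x$year))) {
    stop("duplicated (region, year) keys in ", path)
  }
  x
}

#' @rdname csv_io
#' @param x table to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
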