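# canonical panel CSV dialect:
# header date,ha_count,pm25,pm10,pmc,so2,no2,co,o3,aqi,tem,rh;
# ISO-8601 dates; empty field = missing cell

panel_header <- function() c("date", "ha_count", env_variables())

#' Write a daily panel to CSV
#'
#' @param panel An \code{ha_panel}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  out <- panel[panel_header()]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a daily panel from CSV
#'
#' Parses the canonical dialect with strict validation: the header must
#' match, dates must parse, be strictly increasing by one day and gap-free,
#' and counts must be non-negative integers with no missing values.
#' \code{write_panel_csv(load_panel_csv(p))} is byte-identical for
#' canonical files.
#'
#' @param path CSV file path.
#' @return An \code{ha_panel}.
#' @export
load_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(date = "character"))
  if (!identical(names(df), panel_header()))
    stop(sprintf("malformed header: expected '%s'",
                 paste(panel_header(), collapse = ",")), call. = FALSE)
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop(sprintf("unparseable date at row %d", which(is.na(dates))[1]),
         call. = FALSE)
  if (nrow(df) > 1 && any(diff(dates) != 1))
    stop(sprintf("dates not consecutive at row %d",
                 which(diff(dates) != 1)[1] + 1L), call. = FALSE)
  if (anyNA(df$ha_count))
    stop(sprintf("missing ha_count at row %d",
                 which(is.na(df$ha_count))[1]), call. = FALSE)
  if (any(df$ha_count < 0 | df$ha_count != round(df$ha_count)))
    stop(sprintf("ha_count not a non-negative integer at row %d",
                 which(df$ha_count < 0 | df$ha_count != round(df$ha_count))[1]),
         call. = FALSE)
  df$date <- dates
  df$ha_count <- as.integer(df$ha_count)
  class(df) <- c("ha_panel", "data.frame")
  df
}
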