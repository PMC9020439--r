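#' Build a validated count-survey table
#'
#' The central data container: one record per (site, year) with a
#' non-negative integer count, plus one coordinate row per site. Validation
#' enforces unique (site, year) keys, integer counts, and coordinates for
#' every recorded site.
#'
#' @param records data.frame with columns `site_id`, `year`, `count` (and
#'   optionally `t` if already centered).
#' @param sites data.frame with columns `site_id`, `lon`, `lat` (and
#'   optionally projected `x`, `y` in meters).
#' @param center Centering year already applied to `records$t`, or `NA`.
#' @param crs CRS parameter list of `x`/`y`, or `NULL` if unprojected.
#' @return An object of class `survey_table`.
#' @export
survey_table <- function(records, sites, center = NA, crs = NULL) {
  need_r <- c("site_id", "year", "count")
  if (!all(need_r %in% names(records))) {
    stop_arg("`records` lacks column(s): %s",
             paste(setdiff(need_r, names(records)), collapse = ", "))
  }
  need_s <- c("site_id", "lon", "lat")
  if (!all(need_s %in% names(sites))) {
    stop_arg("`sites` lacks column(s): %s",
             paste(setdiff(need_s, names(sites)), collapse = ", "))
  }
  records$site_id <- as.character(records$site_id)
  sites$site_id <- as.character(sites$site_id)
  key <- paste(records$site_id, records$year, sep = "/")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (site, year) record(s): %s",
                 paste(unique(key[duplicated(key)]), collapse = ", ")),
         call. = FALSE)
  }
  cnt <- records$count
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop_arg("counts must be non-negative integers")
  }
  records$count <- as.integer(round(cnt))
  records$year <- as.integer(records$year)
  if (anyDuplicated(sites$site_id)) stop_arg("duplicated site_id in `sites`")
  orphan <- setdiff(records$site_id, sites$site_id)
  if (length(orphan)) {
    stop_arg("record site(s) without coordinates: %s",
             paste(utils::head(orphan, 5), collapse = ", "))
  }
  sites <- sites[sites$site_id %in% records$site_id, , drop = FALSE]
  rownames(records) <- rownames(sites) <- NULL
  if (!is.na(center)) records$t <- records$year - center
  structure(list(records = records, sites = sites,
                 center = center, crs = crs),
            class = "survey_table")
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("<survey_table> %d records, %d sites, years %d-%d%s%s\n",
              nrow(x$records), nrow(x$sites),
              min(x$records$year), max(x$records$year),
              if (!is.na(x$center)) sprintf(", t centered at %d", x$center) else "",
              if (!is.null(x$crs)) sprintf(", projected (%s)", x$crs$name) else ""))
  invisible(x)
}

#' Read a count-survey CSV
#'
#' Reads a flat CSV with one row per (site, year) and per-row coordinates,
#' validating the result. Column names are remapped through `dialect`.
#'
#' @param path CSV file path.
#' @param dialect Named list mapping the canonical names `site_id`, `year`,
#'   `count`, `lon`, `lat` to the file's column names.
#' @return A [survey_table()].
#' @export
read_counts <- function(path,
                        dialect = list(site_id = "site_id", year = "year",
                                       count = "count", lon = "lon", lat = "lat")) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  def <- list(site_id = "site_id", year = "year", count = "count",
              lon = "lon", lat = "lat")
  def[names(dialect)] <- dialect
  miss <- setdiff(unlist(def), names(raw))
  if (length(miss)) {
    stop_arg("input lacks mapped column(s): %s", paste(miss, collapse = ", "))
  }
  records <- data.frame(site_id = raw[[def$site_id]],
                        year = raw[[def$year]],
                        count = raw[[def$count]],
                        stringsAsFactors = FALSE)
  sites <- unique(data.frame(site_id = as.character(raw[[def$site_id]]),
                             lon = raw[[def$lon]], lat = raw[[def$lat]],
                             stringsAsFactors = FALSE))
  if (anyDuplicated(sites$site_id)) {
    bad <- unique(sites$site_id[duplicated(sites$site_id)])
    stop_arg("inconsistent coordinates for site(s): %s",
             paste(utils::head(bad, 5), collapse = ", "))
  }
  survey_table(records, sites)
}

#' Write a survey table to CSV
#'
#' Inverse of [read_counts()] under the default dialect: columns `site_id`,
#' `year`, `count`, `lon`, `lat`.
#'
#' @param table A [survey_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "survey_table"))
  m <- match(table$records$site_id, table$sites$site_id)
  out <- data.frame(site_id = table$records$site_id,
                    year = table$records$year,
                    count = table$records$count,
                    lon = table$sites$lon[m], lat = table$sites$lat[m])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Retain sites with sufficient survey coverage
#'
#' Keeps only sites surveyed in at least `min_years` distinct years — the
#' standard retention rule for estimating a per-site trend from a short
#' window (e.g. at least 7 of 11 years, a 60% coverage rule). Record order is
#' preserved and the operation is idempotent.
#'
#' @param table A [survey_table()].
#' @param min_years Minimum number of distinct surveyed years (>= 1).
#' @return The filtered [survey_table()].
#' @export
filter_by_coverage <- function(table, min_years = 7) {
  stopifnot(inherits(table, "survey_table"))
  min_years <- check_number(min_years, "min_years", lower = 1)
  ny <- tapply(table$records$year, table$records$site_id,
               function(y) length(unique(y)))
  keep <- names(ny)[ny >= min_years]
  records <- table$records[table$records$site_id %in% keep, , drop = FALSE]
  sites <- table$sites[table$sites$site_id %in% keep, , drop = FALSE]
  rownames(records) <- rownames(sites) <- NULL
  out <- table
  out$records <- records
  out$sites <- sites
  out
}

#' Center calendar years
#'
#' Stores `t = year - center` on every record. Centering at the middle of the
#' study window decorrelates intercepts and slopes in the trend fit.
#'
#' @param table A [survey_table()].
#' @param center Calendar year at which `t = 0`.
#' @return The table with `t` set and `center` recorded.
#' @export
center_years <- function(table, center = 2007) {
  stopifnot(inherits(table, "survey_table"))
  center <- check_number(center, "center")
  table$records$t <- table$records$year - center
  table$center <- center
  table
}

#' Attach projected site coordinates
#'
#' Projects site longitude/latitude to planar meters with the equal-area
#' projection given by `crs`, as required for metric gridding.
#'
#' @param table A [survey_table()].
#' @param crs CRS name or parameter list, see [crs_params()].
#' @return The table with `x`, `y` columns on `$sites` and `$crs` set.
#' @export
project_coordinates <- function(table, crs = "ETRS89-LAEA") {
  stopifnot(inherits(table, "survey_table"))
  crs <- crs_params(crs)
  if (nrow(table$sites)) {
    xy <- laea_project(table$sites$lon, table$sites$lat, crs)
    table$sites$x <- xy$x
    table$sites$y <- xy$y
  } else {
    table$sites$x <- numeric(0)
    table$sites$y <- numeric(0)
  }
  table$crs <- crs
  table
}
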