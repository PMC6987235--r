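# Tucson decadal .rwl reading/writing and assembly of ring series, metadata,
# climate and soil tables into a validated dataset.
#
# Dialects: classic 0.01 mm files end each series with the stop marker 999;
# 0.001 mm files use -9999. Zero ring values encode locally absent rings and
# are decoded as NA (they are bridged only for BAI radius accumulation, never
# used in ratio indices).

#' Construct a single tree's ring series
#'
#' @param tree_id,site_id,species,genus character identifiers.
#' @param group `"angiosperm"` or `"gymnosperm"`.
#' @param status `"surviving"` or `"now-dead"`.
#' @param years integer vector of strictly consecutive calendar years.
#' @param trw ring widths (mm, positive; NA marks a locally absent ring).
#' @param dbh_cm diameter at breast height at sampling (cm).
#' @return object of class `ring_series`; `last_year` is `max(years)` (the
#'   death year for now-dead trees).
#' @export
ring_series <- function(tree_id, years, trw, site_id = NA_character_,
                        species = NA_character_, genus = NA_character_,
                        group = NA_character_, status = NA_character_,
                        dbh_cm = NA_real_) {
  years <- as.integer(years)
  if (length(years) != length(trw)) stop(tree_id, ": years and trw lengths differ")
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop(tree_id, ": years must be strictly consecutive")
  }
  if (any(trw <= 0, na.rm = TRUE)) stop(tree_id, ": non-positive ring width")
  structure(list(tree_id = tree_id, years = years, trw = as.numeric(trw),
                 site_id = site_id, species = species, genus = genus,
                 group = group, status = status, dbh_cm = dbh_cm,
                 last_year = max(years)),
            class = "ring_series")
}

#' @exportS3Method base::print
print.ring_series <- function(x, ...) {
  cat("<ring_series>", x$tree_id, "site", x$site_id, "|", x$status, x$group,
      "|", length(x$years), "rings", min(x$years), "-", x$last_year, "\n")
  invisible(x)
}

rwl_dialects <- c("0.01" = 0.01, "0.001" = 0.001)
rwl_stop <- c("0.01" = 999L, "0.001" = -9999L)

detect_dialect <- function(tokens) {
  if (any(tokens == "-9999")) return("0.001")
  if (any(tokens == "999")) return("0.01")
  stop("cannot auto-detect rwl dialect (no stop marker found); ",
       "pass units_dialect explicitly")
}

#' Read a Tucson decadal ring-width file
#'
#' @param path path to the `.rwl` file.
#' @param units_dialect `"0.01"` (hundredths of mm, stop marker 999),
#'   `"0.001"` (thousandths of mm, stop marker -9999) or `"auto"`.
#' @return list of `ring_series` with widths converted to mm and only the
#'   identity fields available from the file itself (no status metadata).
#' @export
read_rwl <- function(path, units_dialect = c("auto", "0.01", "0.001")) {
  units_dialect <- match.arg(units_dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  tok <- strsplit(trimws(lines), "\\s+")
  if (units_dialect == "auto") units_dialect <- detect_dialect(unlist(tok))
  stopm <- rwl_stop[[units_dialect]]
  unit <- rwl_dialects[[units_dialect]]

  out <- list()
  cur_id <- NULL; cur_years <- integer(); cur_vals <- numeric(); open <- FALSE
  flush <- function() {
    if (is.null(cur_id)) return()
    if (cur_id %in% names(out)) stop("duplicate series id: ", cur_id)
    out[[cur_id]] <<- ring_series(cur_id, cur_years, cur_vals)
  }
  for (ln in seq_along(tok)) {
    t <- tok[[ln]]
    if (length(t) < 2) stop("unparseable line ", ln, " in ", path)
    id <- t[1]
    yr <- suppressWarnings(as.integer(t[2]))
    if (is.na(yr)) stop("unparseable decade year on line ", ln, " in ", path)
    vals <- suppressWarnings(as.integer(t[-(1:2)]))
    if (any(is.na(vals))) stop("unparseable value on line ", ln, " in ", path)
    if (!identical(id, cur_id)) {
      if (open) stop("series ", cur_id, " not terminated before line ", ln)
      flush()
      cur_id <- id; cur_years <- integer(); cur_vals <- numeric(); open <- TRUE
    } else if (!open) {
      stop("duplicate series id: ", id, " (line ", ln, ")")
    } else if (yr != cur_years[length(cur_years)] + 1L) {
      stop("non-consecutive decades for ", id, " at line ", ln)
    }
    for (v in vals) {
      if (v == stopm) { open <- FALSE; break }
      cur_vals <- c(cur_vals, if (v == 0) NA_real_ else v * unit)
      cur_years <- c(cur_years, if (length(cur_years)) cur_years[length(cur_years)] + 1L else yr)
    }
  }
  if (open) stop("series ", cur_id, " missing stop marker at end of file")
  flush()
  out
}

#' Write ring series to a Tucson decadal file
#'
#' @param series list of `ring_series`.
#' @param path output path.
#' @param units_dialect `"0.01"` or `"0.001"`; widths are rounded to the
#'   dialect resolution and terminated with the dialect's stop marker.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path, units_dialect = c("0.01", "0.001")) {
  units_dialect <- match.arg(units_dialect)
  unit <- rwl_dialects[[units_dialect]]
  stopm <- rwl_stop[[units_dialect]]
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    vals <- ifelse(is.na(s$trw), 0L, as.integer(round(s$trw / unit)))
    if (any(vals > 99999 | vals < -9998)) {
      stop(s$tree_id, ": width exceeds ", units_dialect, " mm field width")
    }
    vals <- c(vals, stopm)
    yrs <- c(s$years, s$last_year + 1L)
    decade <- yrs %/% 10L
    for (d in unique(decade)) {
      sel <- decade == d
      writeLines(sprintf("%-8s %4d%s", substr(s$tree_id, 1, 8), min(yrs[sel]),
                         paste(sprintf("%6d", vals[sel]), collapse = "")), con)
    }
  }
  invisible(path)
}

#' Assemble ring series, metadata, climate and soil into a validated dataset
#'
#' Joins `.rwl` series with per-tree metadata and per-site climate and soil
#' tables, checking that every metadata row resolves to a series, that no
#' series is orphaned, and that each site's climate covers its series span.
#' Sites lacking one of the two tree statuses are flagged (`both_statuses` is
#' FALSE): the study design is a matched-pairs case-control, so such sites are
#' excluded from status models but kept for chronology building.
#'
#' @param rwl_paths character vector of `.rwl` files.
#' @param metadata_csv CSV with columns `tree_id`, `site`, `species`, `genus`,
#'   `group`, `status`, `dbh_cm`, `last_year` and optionally `hemisphere`.
#' @param climate_csv CSV with columns `site`, `year`, `month`, `prcp_mm`,
#'   `pet_mm`.
#' @param soil_csv CSV with a `site` column plus the ten soil characteristics.
#' @param units_dialect passed to [read_rwl()].
#' @return object of class `ring_dataset`: list with `series` (named list of
#'   `ring_series`), `sites` (data frame: `site_id`, `hemisphere`,
#'   `both_statuses`), `climate`, `soil`.
#' @export
assemble_dataset <- function(rwl_paths, metadata_csv, climate_csv, soil_csv,
                             units_dialect = "auto") {
  raw <- list()
  for (p in rwl_paths) raw <- c(raw, read_rwl(p, units_dialect))
  if (anyDuplicated(names(raw))) {
    stop("duplicate series ids across files: ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  }
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  climate <- utils::read.csv(climate_csv, stringsAsFactors = FALSE)
  soil <- utils::read.csv(soil_csv, stringsAsFactors = FALSE)

  missing_series <- setdiff(meta$tree_id, names(raw))
  if (length(missing_series)) {
    stop("metadata rows without series: ", paste(missing_series, collapse = ", "))
  }
  orphans <- setdiff(names(raw), meta$tree_id)
  if (length(orphans)) {
    stop("series without metadata: ", paste(orphans, collapse = ", "))
  }
  if (!"hemisphere" %in% names(meta)) meta$hemisphere <- "N"

  series <- list()
  for (i in seq_len(nrow(meta))) {
    r <- raw[[meta$tree_id[i]]]
    series[[meta$tree_id[i]]] <- ring_series(
      meta$tree_id[i], r$years, r$trw, site_id = meta$site[i],
      species = meta$species[i], genus = meta$genus[i], group = meta$group[i],
      status = meta$status[i], dbh_cm = meta$dbh_cm[i])
  }

  site_ids <- sort(unique(meta$site))
  both <- vapply(site_ids, function(sid) {
    st <- unique(meta$status[meta$site == sid])
    all(c("surviving", "now-dead") %in% st)
  }, logical(1))
  hemi <- vapply(site_ids, function(sid) meta$hemisphere[meta$site == sid][1],
                 character(1))
  for (sid in site_ids) {
    cl <- climate[climate$site == sid, ]
    if (nrow(cl) == 0) stop("no climate for site ", sid)
    span <- range(unlist(lapply(series[meta$tree_id[meta$site == sid]],
                                function(s) range(s$years))))
    if (min(cl$year) > span[1] || max(cl$year) < span[2]) {
      stop("climate for site ", sid, " does not cover series span ",
           span[1], "-", span[2])
    }
  }
  structure(list(series = series,
                 sites = data.frame(site_id = site_ids, hemisphere = hemi,
                                    both_statuses = both,
                                    stringsAsFactors = FALSE, row.names = NULL),
                 climate = climate, soil = soil),
            class = "ring_dataset")
}

#' @exportS3Method base::print
print.ring_dataset <- function(x, ...) {
  cat("<ring_dataset>", length(x$series), "trees over", nrow(x$sites),
      "sites;", sum(x$sites$both_statuses), "sites with both statuses\n")
  invisible(x)
}

#' Monthly climate slice for one site
#'
#' @param dataset a `ring_dataset`.
#' @param site_id site identifier.
#' @return data frame of that site's monthly climate, ordered by year, month.
#' @export
site_climate <- function(dataset, site_id) {
  cl <- dataset$climate[dataset$climate$site == site_id, ]
  if (nrow(cl) == 0) stop("no climate for site ", site_id)
  cl[order(cl$year, cl$month), ]
}
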