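#' Read demand or supply sites from CSV or GeoJSON
#'
#' CSV needs columns `site_id,x,y,population[,zone_id]` (demand) or
#' `site_id,x,y,area,score` (supply; `supply_scale`/`weight` also accepted).
#' GeoJSON needs Point features with the same fields as properties; the
#' coordinates supply `x`/`y`. Both encodings parse to identical records.
#'
#' @param path File path; `.geojson`/`.json` is parsed as GeoJSON, anything
#'   else as CSV.
#' @param role `"demand"` or `"supply"`.
#' @return A [demand_sites()] or [supply_sites()] table.
#' @export
read_sites <- function(path, role = c("demand", "supply")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    geojson_points_to_df(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (role == "demand") demand_sites(df) else supply_sites(df)
}

geojson_points_to_df <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  rows <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      stop("expected Point features", call. = FALSE)
    }
    props <- f$properties
    c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
      props)
  })
  nm <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(lapply(stats::setNames(nm, nm), function(cn) {
    vapply(rows, function(r) {
      v <- r[[cn]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  }), stringsAsFactors = FALSE)
  for (cn in setdiff(nm, c("site_id", "zone_id"))) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  df
}

#' Write sites to CSV
#'
#' Supply tables are written with the `area`/`score` column names used by
#' [read_sites()]. Floats carry 12 significant digits so written files are
#' reproducible golden files.
#'
#' @param sites A `demand_sites` or `supply_sites` table.
#' @param path Output CSV path.
#' @export
write_sites <- function(sites, path) {
  df <- as.data.frame(sites)
  if (inherits(sites, "supply_sites")) {
    names(df)[names(df) == "supply_scale"] <- "area"
    names(df)[names(df) == "weight"] <- "score"
  }
  write_csv12(df, path)
}

#' Read per-mode travel-cost matrices from long-format CSV
#'
#' Expects columns `origin_id, dest_id, mode, minutes`. One dense matrix per
#' mode present in the file is returned; an origin-destination pair absent
#' for a mode is unreachable (`Inf`), never zero.
#'
#' @param path CSV path.
#' @param demand_ids,supply_ids Expected row/column ids. When given, ids in
#'   the file outside these sets raise an error; when omitted, the id sets
#'   are inferred from the file.
#' @return Named list of [cost_matrix()] objects keyed by mode.
#' @export
read_od <- function(path, demand_ids = NULL, supply_ids = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("origin_id", "dest_id", "mode", "minutes"), "OD")
  df$origin_id <- as.character(df$origin_id)
  df$dest_id <- as.character(df$dest_id)
  if (anyNA(df$minutes) || any(df$minutes < 0)) {
    bad <- which(is.na(df$minutes) | df$minutes < 0)[1]
    stop(sprintf("OD row %d: minutes must be nonnegative", bad), call. = FALSE)
  }
  if (is.null(demand_ids)) demand_ids <- sort(unique(df$origin_id))
  if (is.null(supply_ids)) supply_ids <- sort(unique(df$dest_id))
  demand_ids <- sort(as.character(demand_ids))
  supply_ids <- sort(as.character(supply_ids))
  bad <- setdiff(df$origin_id, demand_ids)
  if (length(bad)) {
    stop(sprintf("OD file has unknown origin id(s): %s", bad[1]), call. = FALSE)
  }
  bad <- setdiff(df$dest_id, supply_ids)
  if (length(bad)) {
    stop(sprintf("OD file has unknown destination id(s): %s", bad[1]),
         call. = FALSE)
  }
  out <- list()
  for (m in sort(unique(df$mode))) {
    sub <- df[df$mode == m, ]
    key <- paste(sub$origin_id, sub$dest_id)
    if (anyDuplicated(key)) {
      stop(sprintf("OD file has duplicate pair for mode %s", m), call. = FALSE)
    }
    mat <- matrix(Inf, length(demand_ids), length(supply_ids),
                  dimnames = list(demand_ids, supply_ids))
    mat[cbind(match(sub$origin_id, demand_ids),
              match(sub$dest_id, supply_ids))] <- sub$minutes
    out[[m]] <- cost_matrix(mat, mode = m, metric = "time")
  }
  out
}

#' Write per-mode cost matrices to long-format CSV
#'
#' Only finite entries are written; unreachable (`Inf`) pairs are simply
#' absent and become `Inf` again on read, so write/read round-trips are
#' lossless.
#'
#' @param costs A [cost_matrix()] or named list of them.
#' @param path Output CSV path.
#' @export
write_od <- function(costs, path) {
  if (inherits(costs, "cost_matrix")) costs <- list(costs)
  rows <- lapply(costs, function(cm) {
    m <- unclass(cm)
    idx <- which(is.finite(m), arr.ind = TRUE)
    data.frame(origin_id = rownames(m)[idx[, 1]],
               dest_id = colnames(m)[idx[, 2]],
               mode = attr(cm, "mode"),
               minutes = m[idx], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$mode, df$origin_id, df$dest_id), ]
  write_csv12(df, path)
}

#' Write accessibility fields to long CSV
#'
#' @param fields Named list of `accessibility_field`s (typically per-mode plus
#'   `combined`), or a single field.
#' @param path Output CSV path with columns `site_id, mode, A`.
#' @export
write_field <- function(fields, path) {
  if (inherits(fields, "accessibility_field")) fields <- list(fields)
  df <- do.call(rbind, lapply(fields, function(f) {
    data.frame(site_id = names(f$values), mode = f$mode,
               A = unname(f$values), stringsAsFactors = FALSE)
  }))
  df <- df[order(df$mode, df$site_id), ]
  write_csv12(df, path)
}

#' Write per-park supply-demand ratios to long CSV
#'
#' @param result Output of [run_scm_g2sfca()].
#' @param path Output CSV path with columns `park_id, mode, R`.
#' @export
write_ratios <- function(result, path) {
  df <- do.call(rbind, lapply(result$per_mode, function(f) {
    data.frame(park_id = names(f$ratios), mode = f$mode,
               R = unname(f$ratios), stringsAsFactors = FALSE)
  }))
  df <- df[order(df$mode, df$park_id), ]
  write_csv12(df, path)
}

#' Write zone rectangles as GeoJSON polygons
#'
#' @param zones Zone data frame from [generate_city()].
#' @param path Output `.geojson` path.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(seq_len(nrow(zones)), function(i) {
    z <- zones[i, ]
    ring <- list(c(z$xmin, z$ymin), c(z$xmax, z$ymin), c(z$xmax, z$ymax),
                 c(z$xmin, z$ymax), c(z$xmin, z$ymin))
    list(type = "Feature",
         properties = list(zone_id = z$zone_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write sites as GeoJSON points
#'
#' @param sites A `demand_sites` or `supply_sites` table.
#' @param path Output `.geojson` path.
#' @export
write_sites_geojson <- function(sites, path) {
  df <- as.data.frame(sites)
  if (inherits(sites, "supply_sites")) {
    names(df)[names(df) == "supply_scale"] <- "area"
    names(df)[names(df) == "weight"] <- "score"
  }
  # match the CSV writers' 12-significant-digit precision
  for (cn in names(df)) if (is.double(df[[cn]])) df[[cn]] <- signif(df[[cn]], 12)
  propcols <- setdiff(names(df), c("x", "y"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, propcols, drop = FALSE])
    props <- props[!vapply(props, function(v) is.na(v), logical(1))]
    list(type = "Feature", properties = props,
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

# CSV writer with floats at 12 significant digits (reproducible outputs).
write_csv12 <- function(df, path) {
  for (cn in names(df)) {
    if (is.double(df[[cn]])) {
      df[[cn]] <- formatC(df[[cn]], digits = 12, format = "g")
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a flat key=value configuration file
#'
#' Lines of `key = value`; `#` starts a comment. Values parse to numeric or
#' logical where possible; comma-separated values become vectors.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop(sprintf("bad config line: %s", ln), call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(tolower(parts) %in% c("true", "false"))) {
        tolower(parts) == "true"
      } else parts
  }
  out
}

#' Write a flat key=value configuration file
#'
#' @param config Named list of scalars/vectors.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    vtxt <- if (is.double(v)) formatC(v, digits = 12, format = "g") else
      as.character(v)
    sprintf("%s = %s", k, paste(vtxt, collapse = ", "))
  }, character(1))
  writeLines(lines, path)
}
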