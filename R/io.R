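#' aiidval: spatial validation of acoustic individual identification
#'
#' Validates acoustic individual-identification (AIID) predictions without
#' ground-truth labels, using the spatial footprint of localized
#' vocalizations. Two complementary routes are provided: locality-assumption
#' metrics (consistency and specificity, with a label-corruption simulation
#' that calibrates how well they track true accuracy) and agreement with
#' known home ranges (kernel density rasters, rank power-law diversity,
#' normalised mutual information, permutation tests). Supporting stages
#' cover TDOA multilateration, spatial/temporal plausibility filters, and a
#' synthetic territorial-population generator.
#'
#' @section Call tables:
#' The central data container is a plain `data.frame` of call records, one
#' row per localized vocalization, with columns `call_id`, `x`, `y` (planar
#' metres in a projected CRS), `day` (integer day index), `predicted_id`
#' (class label), and optionally `confidence` in \[0, 1\] and `in_hull`.
#' All coordinates are planar; the package never performs geodesic math.
#'
#' @keywords internal
"_PACKAGE"

# ---- call tables -----------------------------------------------------------

#' Read a table of localized call predictions
#'
#' Reads a CSV of localized, ID-predicted vocalizations into a call table
#' (one `CallRecord` row per line). Rows whose coordinates cannot be parsed
#' as finite numbers are dropped and reported in the `"rejections"`
#' attribute; file order is preserved for the retained rows. Unknown extra
#' columns are carried through untouched.
#'
#' @param path path to a CSV file with a header row.
#' @param column_map named character vector mapping the canonical field
#'   names (`call_id`, `x`, `y`, `day`, `predicted_id`, `confidence`,
#'   `in_hull`) to the column names used in the file. Fields absent from the
#'   map default to their canonical names; `day`, `confidence` and `in_hull`
#'   are optional in the file.
#' @return a `data.frame` with canonical columns first, extra columns after;
#'   attribute `"rejections"` holds a `data.frame` of dropped row indices and
#'   reasons. `confidence` defaults to 1 when absent. A `day` column given as
#'   dates or timestamps is floored to integer days.
#' @seealso [write_call_table()], [read_homeranges()], [read_stations()]
#' @export
read_call_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty call table: ", path)

  map <- c(call_id = "call_id", x = "x", y = "y", day = "day",
           predicted_id = "predicted_id", confidence = "confidence",
           in_hull = "in_hull")
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  required <- c("call_id", "x", "y", "predicted_id")
  missing_cols <- setdiff(map[required], names(raw))
  if (length(missing_cols) > 0L)
    stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "))

  xs <- suppressWarnings(as.numeric(raw[[map[["x"]]]]))
  ys <- suppressWarnings(as.numeric(raw[[map[["y"]]]]))
  bad <- !is.finite(xs) | !is.finite(ys)
  rejections <- data.frame(row = which(bad),
                           reason = rep("non-numeric or non-finite coordinate",
                                        sum(bad)))

  calls <- data.frame(call_id = as.character(raw[[map[["call_id"]]]]),
                      x = xs, y = ys,
                      predicted_id = as.character(raw[[map[["predicted_id"]]]]),
                      stringsAsFactors = FALSE)
  calls$day <- if (map[["day"]] %in% names(raw))
    floor_to_day(raw[[map[["day"]]]]) else NA_integer_
  calls$confidence <- if (map[["confidence"]] %in% names(raw))
    suppressWarnings(as.numeric(raw[[map[["confidence"]]]])) else 1
  if (map[["in_hull"]] %in% names(raw))
    calls$in_hull <- as.logical(raw[[map[["in_hull"]]]])

  extra <- setdiff(names(raw), map[map %in% names(raw)])
  for (col in extra) calls[[col]] <- raw[[col]]

  calls <- calls[!bad, , drop = FALSE]
  rownames(calls) <- NULL
  if (any(!is.na(calls$confidence) &
          (calls$confidence < 0 | calls$confidence > 1)))
    stop("confidence values outside [0, 1]")
  attr(calls, "rejections") <- rejections
  calls
}

#' Write a call table to CSV
#'
#' @param calls call-table `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE)
  invisible(path)
}

# Floor a day column to integer day indices. Numeric input is floored;
# character input is parsed as dates or datetimes first.
floor_to_day <- function(day) {
  if (is.numeric(day)) return(as.integer(floor(day)))
  d <- suppressWarnings(as.Date(as.character(day)))
  if (any(is.na(d) & !is.na(day)))
    stop("day column is neither numeric nor parseable as dates")
  as.integer(d)
}

# ---- home ranges -----------------------------------------------------------

#' Read home-range polygons from GeoJSON
#'
#' Reads a GeoJSON `FeatureCollection` of polygon features into a list of
#' home-range polygons. Each feature must carry a `range_id` property and a
#' `Polygon` geometry; the closing vertex of the GeoJSON ring is dropped so
#' each polygon is stored as an open ring of distinct vertices in file order.
#'
#' @param path path to a GeoJSON file.
#' @return an object of class `aiid_homeranges`: a named list with one
#'   element per feature, each a list with `range_id` and a two-column
#'   `vertices` matrix (x, y in metres).
#' @export
read_homeranges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else stop("expected a GeoJSON FeatureCollection")
  polys <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("non-polygon geometry in feature")
    id <- f$properties$range_id
    if (is.null(id)) stop("feature lacks a range_id property")
    ring <- f$geometry$coordinates[[1]]
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # GeoJSON rings repeat the first vertex at the end
    if (nrow(v) >= 2L && all(v[1, ] == v[nrow(v), ]))
      v <- v[-nrow(v), , drop = FALSE]
    homerange_polygon(as.character(id), v)
  })
  names(polys) <- vapply(polys, `[[`, character(1), "range_id")
  if (anyDuplicated(names(polys))) stop("duplicate range_id in feature collection")
  structure(polys, class = "aiid_homeranges")
}

#' Construct a home-range polygon
#'
#' @param range_id identifier string.
#' @param vertices two-column matrix of planar coordinates (metres), an open
#'   ring of at least 3 vertices describing a simple polygon.
#' @return a list with `range_id` and `vertices`, class `homerange_polygon`.
#' @export
homerange_polygon <- function(range_id, vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  if (nrow(vertices) < 3L) stop("polygon needs at least 3 vertices")
  if (!all(is.finite(vertices))) stop("non-finite polygon vertex")
  if (abs(polygon_area(vertices)) <= 0) stop("polygon has zero area")
  if (polygon_self_intersects(vertices)) stop("self-intersecting polygon")
  structure(list(range_id = as.character(range_id), vertices = vertices),
            class = "homerange_polygon")
}

#' Write home-range polygons to GeoJSON
#'
#' @param polygons an `aiid_homeranges` list (or plain list of
#'   `homerange_polygon` objects).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homeranges <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    ring <- rbind(p$vertices, p$vertices[1, ])
    list(type = "Feature",
         properties = list(range_id = p$range_id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  gj <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- stations --------------------------------------------------------------

#' Read recorder station coordinates
#'
#' @param path CSV with columns `station_id`, `x`, `y` (metres).
#' @return `data.frame` with character `station_id` and numeric coordinates.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "x", "y")
  if (!all(need %in% names(st)))
    stop("stations file must have columns station_id, x, y")
  st$station_id <- as.character(st$station_id)
  if (anyDuplicated(st$station_id)) stop("duplicate station_id")
  if (!all(is.finite(st$x)) || !all(is.finite(st$y)))
    stop("non-finite station coordinate")
  st[, c("station_id", "x", "y")]
}

#' Write recorder station coordinates
#' @param stations `data.frame` with `station_id`, `x`, `y`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stations <- function(stations, path) {
  utils::write.csv(stations[, c("station_id", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

# ---- planar geometry -------------------------------------------------------

# Signed area of an open-ring polygon (shoelace).
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# Do two closed segments [p1,p2] and [p3,p4] properly intersect?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

# Any pair of non-adjacent edges crossing?
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (segments_cross(v[i, ], v[i %% n + 1L, ], v[j, ], v[j %% n + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Test points against a polygon (boundary inclusive)
#'
#' Crossing-number point-in-polygon test on a simple polygon given as an
#' open ring. Points lying exactly on an edge or vertex count as inside.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param vertices two-column vertex matrix (open ring).
#' @return logical vector, `TRUE` for points inside or on the boundary.
#' @export
point_in_polygon <- function(px, py, vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  xs <- v[, 1]; ys <- v[, 2]
  xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
  m <- length(px)
  crossings <- integer(m)
  on_edge <- logical(m)
  for (e in seq_len(n)) {          # vectorized over points, edge by edge
    dx <- xe[e] - xs[e]; dy <- ye[e] - ys[e]
    cr <- dx * (py - ys[e]) - dy * (px - xs[e])
    on_edge <- on_edge |
      (abs(cr) <= 1e-9 * max(1, abs(dx), abs(dy)) &
         px >= min(xs[e], xe[e]) - 1e-12 & px <= max(xs[e], xe[e]) + 1e-12 &
         py >= min(ys[e], ye[e]) - 1e-12 & py <= max(ys[e], ye[e]) + 1e-12)
    crosses <- (ys[e] > py) != (ye[e] > py)
    if (any(crosses)) {            # half-open rule avoids double counts
      xint <- xs[e] + (py - ys[e]) / (ye[e] - ys[e]) * dx
      crossings <- crossings + as.integer(crosses & xint > px)
    }
  }
  on_edge | (crossings %% 2L == 1L)
}
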