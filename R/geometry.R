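# Convex-hull geometry for the RSF availability domain.

#' Minimum convex polygon with an outward buffer
#'
#' Computes the convex hull (MCP) of a point set and dilates it outward by
#' `buffer` km (Minkowski sum with a disc). Because the hull is convex the
#' dilation is closed-form: its area is
#' `area(hull) + perimeter(hull) * buffer + pi * buffer^2`, and a point lies
#' inside it iff its distance to the hull is at most `buffer`. Used to build
#' the used-available sampling domain around the rub-object array (the field
#' default buffer, 2.4 km, is an average daily bear movement).
#'
#' @param points Data frame with `x`, `y` (km); at least 3 non-collinear
#'   points.
#' @param buffer Outward buffer in km (`>= 0`).
#' @param arc_points Vertices used to trace each corner arc in the returned
#'   boundary polygon (the area is exact regardless).
#' @return An object of class `mcp` with elements `hull` (tibble of hull
#'   vertices, counter-clockwise), `buffer`, `area` (km^2), `hull_area`,
#'   `perimeter`, and `boundary` (tibble tracing the buffered outline).
#' @export
mcp_buffer <- function(points, buffer = 2.4, arc_points = 16) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (buffer < 0) abort("`buffer` must be >= 0")
  pts <- dplyr::distinct(tibble::as_tibble(points[c("x", "y")]))
  if (nrow(pts) < 3) abort("MCP needs at least 3 distinct points")
  idx <- grDevices::chull(pts$x, pts$y)  # clockwise
  hull <- pts[rev(idx), ]                # counter-clockwise
  ha <- polygon_area(hull$x, hull$y)
  if (ha <= 1e-12) abort("points are collinear; MCP is degenerate")
  per <- sum(sqrt(diff(c(hull$x, hull$x[1]))^2 + diff(c(hull$y, hull$y[1]))^2))
  structure(
    list(
      hull = hull, buffer = buffer,
      hull_area = ha, perimeter = per,
      area = ha + per * buffer + pi * buffer^2,
      boundary = buffered_outline(hull, buffer, arc_points)
    ),
    class = "mcp"
  )
}

# Shoelace area of a simple polygon (vertices in order, not closed).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Trace the outline of hull (+) disc of radius b: offset edges joined by
# corner arcs. Hull must be counter-clockwise.
buffered_outline <- function(hull, b, arc_points) {
  n <- nrow(hull)
  if (b == 0) return(tibble::as_tibble(hull))
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(n)) {
    p <- c(hull$x[i], hull$y[i])
    nxt <- c(hull$x[i %% n + 1], hull$y[i %% n + 1])
    prv <- c(hull$x[(i - 2) %% n + 1], hull$y[(i - 2) %% n + 1])
    # Outward normals of incoming and outgoing edges (CCW polygon).
    n_in <- c(p[2] - prv[2], prv[1] - p[1]); n_in <- n_in / sqrt(sum(n_in^2))
    n_out <- c(nxt[2] - p[2], p[1] - nxt[1]); n_out <- n_out / sqrt(sum(n_out^2))
    a0 <- atan2(n_in[2], n_in[1]); a1 <- atan2(n_out[2], n_out[1])
    if (a1 < a0) a1 <- a1 + 2 * pi  # normals rotate CCW around a CCW hull
    ang <- seq(a0, a1, length.out = max(2, arc_points))
    out_x <- c(out_x, p[1] + b * cos(ang))
    out_y <- c(out_y, p[2] + b * sin(ang))
  }
  tibble::tibble(x = out_x, y = out_y)
}

#' Test whether points fall inside a buffered MCP
#'
#' @param poly An `mcp` object.
#' @param x,y Point coordinates (km).
#' @return Logical vector: distance from the point to the hull is at most
#'   the buffer (points inside the hull have distance 0).
#' @export
in_mcp <- function(poly, x, y) {
  stopifnot(inherits(poly, "mcp"))
  dist_to_hull(poly$hull, x, y) <= poly$buffer + 1e-12
}

# Distance from points to a convex hull (0 if inside).
dist_to_hull <- function(hull, x, y) {
  n <- nrow(hull)
  inside <- rep(TRUE, length(x))
  dmin <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    p <- c(hull$x[i], hull$y[i])
    q <- c(hull$x[i %% n + 1], hull$y[i %% n + 1])
    e <- q - p
    # CCW polygon: interior is to the left; cross <= 0 means outside this edge.
    cross <- e[1] * (y - p[2]) - e[2] * (x - p[1])
    inside <- inside & (cross >= -1e-12)
    len2 <- sum(e^2)
    t <- pmin(1, pmax(0, ((x - p[1]) * e[1] + (y - p[2]) * e[2]) / len2))
    dmin <- pmin(dmin, sqrt((x - (p[1] + t * e[1]))^2 + (y - (p[2] + t * e[2]))^2))
  }
  ifelse(inside, 0, dmin)
}
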