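# Contiguity-based neighborhood dictionaries.
#
# Geometries are represented as a named list (one entry per region) of
# polygons; a polygon is a list of rings and a ring is a 2-column numeric
# matrix of vertices (closed or open; edges wrap around). This covers
# Polygon and MultiPolygon GeoJSON geometries.

#' Build a neighborhood dictionary from region polygons
#'
#' Two regions are neighbors when their boundaries touch: under the queen
#' rule any shared boundary point counts (corner contact included); under
#' the rook rule they must share a boundary segment of positive length.
#' Boundaries are considered touching when their distance is at most `tol`
#' in the layer's coordinate units, absorbing coordinate precision noise.
#'
#' @param geoms Named list of polygon geometries (see [read_geojson()] or
#'   [grid_polygons()]); names are the region ids.
#' @param rule Contiguity rule, `"queen"` (default) or `"rook"`.
#' @param tol Geometric tolerance, default `1e-9`.
#' @return An object of class `nb_dict`: list with `neighbors` (named list,
#'   region id -> sorted character vector of neighbor ids; isolated regions
#'   map to `character(0)`) and `rule`.
#' @export
build_adjacency <- function(geoms, rule = c("queen", "rook"), tol = 1e-9) {
  rule <- match.arg(rule)
  if (length(geoms) == 0) stop("empty geometry set", call. = FALSE)
  ids <- names(geoms)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("geometries must be a named list keyed by region id", call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate region id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)

  edges <- lapply(geoms, polygon_edges)
  bbox <- t(vapply(edges, function(e)
    c(min(e[, 1], e[, 3]), min(e[, 2], e[, 4]),
      max(e[, 1], e[, 3]), max(e[, 2], e[, 4])), numeric(4)))

  nb <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) {
      for (k in (i + 1):length(ids)) {
        # bounding boxes must come within tol for boundaries to touch
        if (bbox[i, 1] > bbox[k, 3] + tol || bbox[k, 1] > bbox[i, 3] + tol ||
            bbox[i, 2] > bbox[k, 4] + tol || bbox[k, 2] > bbox[i, 4] + tol)
          next
        touch <- if (rule == "queen")
          edges_touch(edges[[i]], edges[[k]], tol)
        else
          edges_share_segment(edges[[i]], edges[[k]], tol)
        if (touch) {
          nb[[i]] <- c(nb[[i]], ids[k])
          nb[[k]] <- c(nb[[k]], ids[i])
        }
      }
    }
  }
  structure(list(neighbors = lapply(nb, sort), rule = rule),
            class = "nb_dict")
}

#' @export
print.nb_dict <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("nb_dict (%s): %d regions, mean degree %.2f, %d island(s)\n",
              x$rule, length(deg), mean(deg), sum(deg == 0)))
  invisible(x)
}

# Flatten a polygon (list of ring matrices) into an edge matrix with
# columns x1, y1, x2, y2.
polygon_edges <- function(poly) {
  if (is.matrix(poly)) poly <- list(poly)
  out <- lapply(poly, function(ring) {
    ring <- as.matrix(ring)
    if (nrow(ring) < 3) stop("ring with fewer than 3 vertices", call. = FALSE)
    # drop an explicit closing vertex, then wrap
    if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
    nxt <- c(2:nrow(ring), 1)
    cbind(ring[, 1], ring[, 2], ring[nxt, 1], ring[nxt, 2])
  })
  do.call(rbind, out)
}

# Distance from points (px, py) to segments (x1,y1)-(x2,y2), recycling
# elementwise over points and segments.
point_seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 == 0, 0,
              pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) /
                                pmax(len2, .Machine$double.xmin))))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# TRUE when any segment of A comes within tol of any segment of B.
# Endpoint-to-segment distances cover touching and crossing configurations
# up to the tolerance used here (a strict proper crossing without close
# endpoints does not occur between boundaries of non-overlapping polygons).
edges_touch <- function(A, B, tol) {
  for (r in seq_len(nrow(A))) {
    d <- pmin(
      point_seg_dist(B[, 1], B[, 2], A[r, 1], A[r, 2], A[r, 3], A[r, 4]),
      point_seg_dist(B[, 3], B[, 4], A[r, 1], A[r, 2], A[r, 3], A[r, 4]),
      point_seg_dist(A[r, 1], A[r, 2], B[, 1], B[, 2], B[, 3], B[, 4]),
      point_seg_dist(A[r, 3], A[r, 4], B[, 1], B[, 2], B[, 3], B[, 4])
    )
    if (any(d <= tol)) return(TRUE)
  }
  FALSE
}

# TRUE when A and B share collinear overlap of total length > tol.
edges_share_segment <- function(A, B, tol) {
  for (r in seq_len(nrow(A))) {
    ax <- A[r, 3] - A[r, 1]; ay <- A[r, 4] - A[r, 2]
    alen <- sqrt(ax * ax + ay * ay)
    if (alen == 0) next
    ux <- ax / alen; uy <- ay / alen
    # perpendicular distance of both B endpoints from the line through A
    d1 <- abs(-uy * (B[, 1] - A[r, 1]) + ux * (B[, 2] - A[r, 2]))
    d2 <- abs(-uy * (B[, 3] - A[r, 1]) + ux * (B[, 4] - A[r, 2]))
    cand <- which(d1 <= tol & d2 <= tol)
    if (length(cand) == 0) next
    # scalar projections onto A's direction
    s1 <- ux * (B[cand, 1] - A[r, 1]) + uy * (B[cand, 2] - A[r, 2])
    s2 <- ux * (B[cand, 3] - A[r, 1]) + uy * (B[cand, 4] - A[r, 2])
    lo <- pmax(pmin(s1, s2), 0)
    hi <- pmin(pmax(s1, s2), alen)
    if (any(hi - lo > tol)) return(TRUE)
  }
  FALSE
}

validate_nb <- function(neighbors, rule) {
  ids <- names(neighbors)
  if (is.null(ids) || anyDuplicated(ids))
    stop("neighborhood dictionary keys must be unique region ids",
         call. = FALSE)
  for (i in ids) {
    nbi <- neighbors[[i]]
    if (i %in% nbi)
      stop(sprintf("self-loop %s", i), call. = FALSE)
    unknown <- setdiff(nbi, ids)
    if (length(unknown) > 0)
      stop(sprintf("neighbor id(s) of %s not in the region universe: %s",
                   i, paste(unknown, collapse = ", ")), call. = FALSE)
    for (k in nbi)
      if (!(i %in% neighbors[[k]]))
        stop(sprintf("asymmetric pair (%s,%s)", i, k), call. = FALSE)
  }
  structure(list(neighbors = lapply(neighbors, function(x) sort(as.character(x))),
                 rule = rule),
            class = "nb_dict")
}

#' Save a neighborhood dictionary as JSON
#'
#' The file is a JSON object mapping each region id to its sorted neighbor
#' list, plus a `"_rule"` entry recording the contiguity rule, so it can be
#' re-used across analyses of the same layer.
#'
#' @param nd An `nb_dict`.
#' @param path Output file path.
#' @export
save_adjacency <- function(nd, path) {
  stopifnot(inherits(nd, "nb_dict"))
  obj <- c(nd$neighbors, list(`_rule` = nd$rule))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Load and validate a neighborhood dictionary from JSON
#'
#' Entries must be symmetric and self-loop free; violations raise an error
#' naming the offending pair.
#'
#' @param path Path written by [save_adjacency()] (or hand-authored in the
#'   same format).
#' @return An `nb_dict`.
#' @export
load_adjacency <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rule <- "queen"
  if ("_rule" %in% names(obj)) {
    rule <- as.character(obj[["_rule"]])
    if (!rule %in% c("queen", "rook"))
      stop(sprintf("%s: unknown contiguity rule '%s'", path, rule),
           call. = FALSE)
    obj <- obj[names(obj) != "_rule"]
  }
  neighbors <- lapply(obj, function(x)
    if (length(x) == 0) character(0) else as.character(x))
  validate_nb(neighbors, rule)
}

#' Read region polygons from a GeoJSON file
#'
#' Supports FeatureCollections of Polygon and MultiPolygon features; the
#' region id is taken from the named property field.
#'
#' @param path GeoJSON file path.
#' @param id_field Feature property holding the region id (default
#'   `"GEOID"`).
#' @return Named list of polygon geometries usable by [build_adjacency()].
#' @export
read_geojson <- function(path, id_field = "GEOID") {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop(sprintf("%s: expected a GeoJSON FeatureCollection", path),
         call. = FALSE)
  feats <- gj$features
  if (length(feats) == 0) stop(sprintf("%s: no features", path), call. = FALSE)
  ring_mat <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  out <- list()
  for (f in feats) {
    id <- f$properties[[id_field]]
    if (is.null(id))
      stop(sprintf("%s: feature without property '%s'", path, id_field),
           call. = FALSE)
    g <- f$geometry
    rings <- switch(g$type,
      Polygon = lapply(g$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(g$coordinates, function(part)
        lapply(part, ring_mat)), recursive = FALSE),
      stop(sprintf("%s: unsupported geometry type '%s'", path, g$type),
           call. = FALSE))
    out[[as.character(id)]] <- rings
  }
  if (anyDuplicated(names(out)))
    stop(sprintf("%s: duplicate region id(s) in '%s'", path, id_field),
         call. = FALSE)
  out
}

#' Unit-square grid polygons for an R x C lattice
#'
#' Convenience generator of a rectangular tessellation (row-major ids
#' `"r<row>c<col>"` by default), used by the simulation harness and test
#' fixtures.
#'
#' @param nrow,ncol Grid dimensions.
#' @param ids Optional character vector of region ids, row-major, length
#'   `nrow * ncol`.
#' @return Named list of single-ring polygons.
#' @export
grid_polygons <- function(nrow, ncol, ids = NULL) {
  stopifnot(nrow >= 1, ncol >= 1)
  if (is.null(ids))
    ids <- paste0("r", rep(seq_len(nrow), each = ncol),
                  "c", rep(seq_len(ncol), times = nrow))
  stopifnot(length(ids) == nrow * ncol)
  out <- vector("list", nrow * ncol)
  k <- 0
  for (r in seq_len(nrow)) {
    for (cc in seq_len(ncol)) {
      k <- k + 1
      x0 <- cc - 1; y0 <- nrow - r   # row 1 on top, map-style
      out[[k]] <- list(cbind(c(x0, x0 + 1, x0 + 1, x0),
                             c(y0, y0, y0 + 1, y0 + 1)))
    }
  }
  stats::setNames(out, ids)
}
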