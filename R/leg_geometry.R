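#' Leg cross-section contour
#'
#' A closed planar polyline sampled around one leg cross-section at height
#' `z`. Points are stored counter-clockwise (reoriented on construction if
#' supplied clockwise) without repeating the first vertex.
#'
#' @param x,y vertex coordinates (m), at least 16 vertices.
#' @param z section height along the leg axis (m).
#' @param label optional measurement-position label: `"B"` (ankle), `"B1"`,
#'   `"C"` (calf) or `"D"` (below knee).
#' @param check if `TRUE` (default) verify the polyline is simple
#'   (non-self-intersecting).
#' @return an object of class `"cross_section"`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' cs <- cross_section(0.04 * cos(th), 0.04 * sin(th), z = 0, label = "B")
#' girth(cs)  # ~ 2 pi 0.04
#' @export
cross_section <- function(x, y, z = 0, label = NA_character_, check = TRUE) {
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  if (length(x) < 16L) stop("a cross-section needs at least 16 points")
  if (anyNA(x) || anyNA(y)) stop("coordinates contain NA")
  if (!is.na(label)) label <- match.arg(label, c("B", "B1", "C", "D"))
  # drop a repeated closing vertex if present
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  if (polygon_area(x, y) < 0) { x <- rev(x); y <- rev(y) }  # enforce CCW
  if (check && !is_simple_polygon(x, y))
    stop("cross-section polyline is self-intersecting")
  structure(list(x = x, y = y, z = z, label = label),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("Cross-section%s at z = %.3f m: %d points, girth %.2f cm\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$z, length(x$x), girth(x) * 100))
  invisible(x)
}

# signed area (shoelace); > 0 for counter-clockwise orientation
polygon_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# vectorised all-pairs proper-intersection test for a closed polyline
is_simple_polygon <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  i <- rep.int(seq_len(n), n); j <- rep(seq_len(n), each = n)
  keep <- i < j & j - i > 1L & !(i == 1L & j == n)  # skip adjacent edges
  i <- i[keep]; j <- j[keep]
  d <- function(ax, ay, bx, by, px, py) (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  o1 <- d(x[i], y[i], x2[i], y2[i], x[j], y[j])
  o2 <- d(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
  o3 <- d(x[j], y[j], x2[j], y2[j], x[i], y[i])
  o4 <- d(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
  !any(o1 * o2 < 0 & o3 * o4 < 0)
}

#' Leg model from stacked cross-sections
#'
#' @param sections list of [cross_section()] objects ordered by strictly
#'   increasing `z`.
#' @param rigidity `"soft"` or `"rigid"` (printed mannequin).
#' @param tissue a [tissue_model()] (required for soft legs).
#' @return an object of class `"leg_model"`.
#' @export
leg_model <- function(sections, rigidity = c("soft", "rigid"), tissue = NULL) {
  rigidity <- match.arg(rigidity)
  stopifnot(is.list(sections), length(sections) >= 1L)
  if (!all(vapply(sections, inherits, TRUE, "cross_section")))
    stop("all sections must be cross_section objects")
  z <- vapply(sections, `[[`, 0, "z")
  if (is.unsorted(z, strictly = TRUE)) stop("section heights z must be strictly increasing")
  labs <- vapply(sections, `[[`, "", "label")
  if (!all(c("B", "D") %in% labs))
    warning("leg has no labelled B (ankle) and D (below-knee) sections")
  if (rigidity == "soft") {
    if (is.null(tissue)) stop("soft legs require a tissue_model")
    stopifnot(inherits(tissue, "tissue_model"))
  }
  structure(list(sections = sections, rigidity = rigidity, tissue = tissue),
            class = "leg_model")
}

#' @export
print.leg_model <- function(x, ...) {
  g <- leg_girths(x)
  cat(sprintf("Leg model (%s), %d sections, height span %.1f cm\n",
              x$rigidity, length(x$sections),
              diff(range(vapply(x$sections, `[[`, 0, "z"))) * 100))
  for (i in seq_along(x$sections)) {
    s <- x$sections[[i]]
    cat(sprintf("  %-3s z = %5.1f cm  girth = %5.2f cm\n",
                ifelse(is.na(s$label), "-", s$label), s$z * 100, g[i] * 100))
  }
  if (!is.null(x$tissue)) print(x$tissue)
  invisible(x)
}

#' Girths of all sections of a leg
#'
#' @param leg a [leg_model()].
#' @return numeric vector of girths (m), named by position label where set.
#' @export
leg_girths <- function(leg) {
  stopifnot(inherits(leg, "leg_model"))
  g <- vapply(leg$sections, girth, 0)
  names(g) <- vapply(leg$sections, `[[`, "", "label")
  g
}

#' Retrieve a labelled section from a leg
#'
#' @param leg a [leg_model()].
#' @param label position label (`"B"`, `"B1"`, `"C"`, `"D"`).
#' @return the matching [cross_section()].
#' @export
leg_section <- function(leg, label) {
  labs <- vapply(leg$sections, `[[`, "", "label")
  i <- match(label, labs)
  if (is.na(i)) stop("leg has no section labelled '", label, "'")
  leg$sections[[i]]
}

#' Perimeter (girth) of a cross-section
#'
#' Sum of the segment lengths of the closed polyline; this is the body girth
#' C entering Laplace's law.
#'
#' @param section a [cross_section()] (or any list with `x`, `y`).
#' @return girth (m).
#' @export
girth <- function(section) {
  x <- section$x; y <- section$y
  if (length(x) < 3L) stop("girth needs at least 3 points")
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# circumradius of triangles through consecutive vertex triples, per vertex
vertex_radii <- function(x, y, clip = c(1e-4, 10)) {
  n <- length(x)
  ip <- c(n, seq_len(n - 1L)); inx <- c(seq_len(n)[-1], 1L)
  ax <- x[ip]; ay <- y[ip]; bx <- x; by <- y; cx <- x[inx]; cy <- y[inx]
  la <- sqrt((bx - cx)^2 + (by - cy)^2)
  lb <- sqrt((ax - cx)^2 + (ay - cy)^2)
  lc <- sqrt((ax - bx)^2 + (ay - by)^2)
  area2 <- abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))  # 2*area
  r <- ifelse(area2 < .Machine$double.eps * la * lb, clip[2],
              la * lb * lc / (2 * area2))
  pmin(pmax(r, clip[1]), clip[2])
}

#' Local radius of curvature along a section boundary
#'
#' Radius of the circle through three consecutive boundary samples nearest to
#' the requested arc position; this is the local 1/curvature feeding the
#' per-point Laplace pressure. Radii are clipped to [1e-4, 10] m so that
#' locally flat (collinear) scan segments give a finite pressure rather than
#' zero curvature.
#'
#' @param section a [cross_section()].
#' @param arc_position normalised arc-length position(s) in [0, 1), measured
#'   from the first vertex; vectorised.
#' @param clip radius clipping bounds (m).
#' @return local radius (m).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 181)[-181]
#' circ <- cross_section(0.04 * cos(th), 0.04 * sin(th))
#' local_radius(circ, c(0, 0.25, 0.5))  # 0.04 everywhere
#' @export
local_radius <- function(section, arc_position, clip = c(1e-4, 10)) {
  x <- section$x; y <- section$y
  if (length(x) < 3L) stop("local_radius needs at least 3 points")
  if (any(arc_position < 0 | arc_position >= 1))
    stop("arc_position must lie in [0, 1)")
  seg <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  cum <- c(0, cumsum(seg))                 # arc length at each vertex, 0..L
  L <- cum[length(cum)]
  r <- vertex_radii(x, y, clip)
  idx <- vapply(arc_position * L, function(s) which.min(abs(cum - s)), 0L)
  idx[idx > length(x)] <- 1L               # wrap the closing point
  r[idx]
}

#' Displace a section boundary inward along its normals
#'
#' Moves every vertex inward by `w` along the local (vertex) normal,
#' modelling a uniform radial indentation of the limb surface. For a circular
#' section this reduces the girth by exactly 2 pi w.
#'
#' @param section a [cross_section()].
#' @param w inward normal displacement (m), >= 0 and small enough that the
#'   displaced boundary remains simple.
#' @return the displaced [cross_section()].
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' cs <- cross_section(0.05 * cos(th), 0.05 * sin(th))
#' girth(cs) - girth(apply_radial_displacement(cs, 0.00361))  # ~2.27 cm
#' @export
apply_radial_displacement <- function(section, w) {
  stopifnot(inherits(section, "cross_section"))
  if (w < 0) stop("displacement w must be >= 0")
  if (w == 0) return(section)
  x <- section$x; y <- section$y; n <- length(x)
  if (w >= min(vertex_radii(x, y, clip = c(0, Inf))))
    stop("displacement w exceeds the local radius: section would self-intersect")
  ip <- c(n, seq_len(n - 1L)); inx <- c(seq_len(n)[-1], 1L)
  tx <- x[inx] - x[ip]; ty <- y[inx] - y[ip]   # central-difference tangent
  len <- sqrt(tx^2 + ty^2)
  nx <- -ty / len; ny <- tx / len              # inward normal for CCW rings
  out <- tryCatch(
    cross_section(x + w * nx, y + w * ny, z = section$z, label = section$label),
    error = function(e) stop("displacement w too large: ", conditionMessage(e)))
  out
}

#' Girth change implied by a uniform radial displacement
#'
#' For a (near-)circular section, a uniform inward radial displacement w
#' shortens the circumference by exactly 2 pi w; this identity links reported
#' surface displacements to circumference changes.
#'
#' @param w inward radial displacement (m), >= 0; vectorised.
#' @return circumference reduction (m).
#' @examples
#' girth_change_from_displacement(c(0.00361, 0.01106)) * 100  # 2.27, 6.95 cm
#' @export
girth_change_from_displacement <- function(w) {
  if (any(w < 0)) stop("w must be >= 0")
  2 * pi * w
}

#' Read / write a leg model as a contour CSV
#'
#' The CSV has one row per vertex with columns
#' `z_m,point_index,x_m,y_m,label`; each section's ring is closed by
#' repeating its first vertex as the last row. `read_leg_csv` checks that
#' sections are sorted by `z`, rings are closed, and rows parse, reporting
#' the offending row number otherwise.
#'
#' @param path file path.
#' @param leg a [leg_model()] (for writing).
#' @param rigidity,tissue passed to [leg_model()] on read.
#' @return `read_leg_csv` returns a [leg_model()]; `write_leg_csv` returns
#'   `path` invisibly.
#' @export
read_leg_csv <- function(path, rigidity = "rigid", tissue = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("z_m", "point_index", "x_m", "y_m")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("leg CSV missing columns: ", paste(miss, collapse = ", "))
  has_label <- "label" %in% names(df)
  if (!has_label) {
    warning("leg CSV has no 'label' column; position labels left unset")
    df$label <- NA_character_
  }
  for (cn in req) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed leg CSV row ", bad[1] + 1L,
           " (counting the header): non-numeric '", cn, "'")
    df[[cn]] <- v
  }
  zs <- unique(df$z_m)
  if (is.unsorted(zs, strictly = TRUE))
    stop("leg CSV sections are not sorted by strictly increasing z_m")
  sections <- lapply(zs, function(z) {
    s <- df[df$z_m == z, ]
    s <- s[order(s$point_index), ]
    n <- nrow(s)
    row0 <- which(df$z_m == z)[1] + 1L
    if (abs(s$x_m[1] - s$x_m[n]) > 1e-12 || abs(s$y_m[1] - s$y_m[n]) > 1e-12)
      stop("open polyline for section at z = ", z,
           " (rows starting at ", row0, "): first and last vertex differ")
    lab <- s$label[1]
    if (is.null(lab) || is.na(lab) || lab == "") lab <- NA_character_
    cross_section(s$x_m[-n], s$y_m[-n], z = z, label = lab)
  })
  leg_model(sections, rigidity = rigidity, tissue = tissue)
}

#' @rdname read_leg_csv
#' @export
write_leg_csv <- function(leg, path) {
  stopifnot(inherits(leg, "leg_model"))
  rows <- lapply(leg$sections, function(s) {
    n <- length(s$x)
    data.frame(z_m = s$z, point_index = seq_len(n + 1L),
               x_m = c(s$x, s$x[1]), y_m = c(s$y, s$y[1]),
               label = ifelse(is.na(s$label), "", s$label))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a leg section stack as a Wavefront OBJ surface
#'
#' Triangulated side walls between consecutive sections (no end caps), for
#' external 3-D viewers. Sections must share a common point count.
#'
#' @param leg a [leg_model()].
#' @param path output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_leg_obj <- function(leg, path) {
  stopifnot(inherits(leg, "leg_model"))
  ns <- vapply(leg$sections, function(s) length(s$x), 0L)
  if (length(unique(ns)) != 1L)
    stop("OBJ export needs a common point count across sections")
  n <- ns[1]
  con <- file(path, "w"); on.exit(close(con))
  for (s in leg$sections)
    writeLines(sprintf("v %.9f %.9f %.9f", s$x, s$y, rep(s$z, n)), con)
  for (k in seq_len(length(leg$sections) - 1L)) {
    b0 <- (k - 1L) * n; t0 <- k * n
    i <- seq_len(n); j <- c(seq_len(n)[-1], 1L)
    writeLines(sprintf("f %d %d %d", b0 + i, b0 + j, t0 + j), con)
    writeLines(sprintf("f %d %d %d", b0 + i, t0 + j, t0 + i), con)
  }
  invisible(path)
}
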