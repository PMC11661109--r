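#' Construct a 2D contour
#'
#' Ordered point list tracing a cortical section outline. Closed contours
#' are stored without repeating the first point; the closing segment is
#' implicit.
#'
#' @param points Two-column numeric matrix (x, y), >= 3 points, no two
#'   consecutive points identical.
#' @param closed Logical, default TRUE.
#' @return An object of class `contour_points`.
#' @export
contour_points <- function(points, closed = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have two columns", call. = FALSE)
  if (anyNA(points)) stop("points must be finite", call. = FALSE)
  if (closed && nrow(points) > 1 &&
      all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 3) stop("a contour needs >= 3 points", call. = FALSE)
  d <- diff(points)
  if (any(rowSums(d^2) == 0))
    stop("consecutive duplicate points in contour", call. = FALSE)
  structure(list(points = unname(points), closed = closed),
            class = "contour_points")
}

#' Arc length of a contour
#'
#' Sum of Euclidean segment lengths, including the closing segment for
#' closed contours.
#' @param c A [contour_points()].
#' @return Total length (coordinate units).
#' @examples
#' sq <- contour_points(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' contour_length(sq)  # 4
#' @export
contour_length <- function(c) {
  stopifnot(inherits(c, "contour_points"))
  p <- c$points
  if (c$closed) p <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Smooth enclosing outline of a contour
#'
#' The outer boundary that "smoothly encloses" a cortical section is taken
#' to be the convex hull of the contour points, returned as a closed
#' contour. Every input point lies inside or on the hull.
#'
#' @param c A closed [contour_points()].
#' @return A closed `contour_points` of hull vertices.
#' @export
enclosing_outline <- function(c) {
  stopifnot(inherits(c, "contour_points"))
  if (!c$closed) stop("enclosing outline requires a closed contour",
                      call. = FALSE)
  idx <- grDevices::chull(c$points[, 1], c$points[, 2])
  if (length(idx) < 3)
    stop("contour is degenerate (collinear points); no enclosing outline",
         call. = FALSE)
  contour_points(c$points[idx, , drop = FALSE], closed = TRUE)
}

#' Gyrification index of a closed contour
#'
#' Ratio of the contour's arc length (the folded inner surface in section)
#' to the arc length of its smooth enclosing outline. A smooth
#' (lissencephalic) section gives GI = 1; folding raises it.
#'
#' @param c A closed [contour_points()].
#' @return List of class `gyrification_result`: `gi`, `inner_length`,
#'   `outer_length`, `outline`.
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 361)[-361]
#' circle <- contour_points(cbind(cos(theta), sin(theta)))
#' gyrification_index(circle)$gi  # ~1
#' @export
gyrification_index <- function(c) {
  outline <- enclosing_outline(c)
  inner <- contour_length(c)
  outer <- contour_length(outline)
  structure(list(gi = inner / outer, inner_length = inner,
                 outer_length = outer, outline = outline,
                 window_results = NULL),
            class = "gyrification_result")
}

#' @export
print.gyrification_result <- function(x, ...) {
  cat(sprintf("GI = %.4f (inner %.4g / outer %.4g)\n", x$gi,
              x$inner_length, x$outer_length))
  if (!is.null(x$window_results))
    cat("  local GI over", nrow(x$window_results), "windows: max",
        sprintf("%.4f", max(x$window_results$local_gi)), "\n")
  invisible(x)
}

# Arc-length position on a closed polyline of the point nearest to p.
# outline_p: vertex matrix (closed, first vertex not repeated);
# cum: cumulative arc length at segment starts; returns position in
# [0, total).
nearest_arc_position <- function(p, outline_p, cum, seg_vec, seg_len2) {
  rel_x <- p[1] - outline_p[, 1]
  rel_y <- p[2] - outline_p[, 2]
  t <- (rel_x * seg_vec[, 1] + rel_y * seg_vec[, 2]) / seg_len2
  t <- pmin(pmax(t, 0), 1)
  dx <- rel_x - t * seg_vec[, 1]
  dy <- rel_y - t * seg_vec[, 2]
  i <- which.min(dx^2 + dy^2)
  cum[i] + t[i] * sqrt(seg_len2[i])
}

# Length of the overlap between arc intervals [a1, a2] and [b1, b2] on a
# circle of circumference total. An interval wraps when its end is
# numerically before its start (a2 < a1) or runs past total (b2 > total).
arc_overlap <- function(a1, a2, b1, b2, total) {
  split_arc <- function(x1, x2) {
    if (x2 > total) list(c(x1, total), c(0, x2 - total))
    else if (x2 < x1) list(c(x1, total), c(0, x2))
    else list(c(x1, x2))
  }
  ov <- 0
  for (p in split_arc(a1, a2))
    for (w in split_arc(b1, b2))
      ov <- ov + max(0, min(p[2], w[2]) - max(p[1], w[1]))
  ov
}

#' Local gyrification index along the enclosing outline
#'
#' Slides a window of outer arc length `window_arc` along the enclosing
#' outline in steps of `step_arc`. Each inner contour segment is mapped to
#' the outer outline by nearest-point correspondence of its endpoints and
#' its length is spread proportionally over the corresponding outer arc
#' interval; the local GI of a window is the inner length mapped into the
#' window divided by the window's outer arc length. Windows wrap around
#' the closed outline. On a convex contour the correspondence is the
#' identity, so every local GI is 1.
#'
#' @param c A closed [contour_points()].
#' @param window_arc Window length along the outer outline (required; the
#'   appropriate scale depends on the section size).
#' @param step_arc Step between window starts (default `window_arc / 2`).
#' @return A `gyrification_result` whose `window_results` data frame holds
#'   `start_arc`, `end_arc` and `local_gi` per window.
#' @export
local_gi <- function(c, window_arc, step_arc = window_arc / 2) {
  res <- gyrification_index(c)
  outer_total <- res$outer_length
  if (window_arc >= outer_total)
    stop("window_arc must be smaller than the outline length (",
         signif(outer_total, 6), ")", call. = FALSE)
  if (step_arc <= 0) stop("step_arc must be > 0", call. = FALSE)
  op <- res$outline$points
  op_closed <- rbind(op, op[1, ])
  seg_vec <- diff(op_closed)
  seg_len <- sqrt(rowSums(seg_vec^2))
  seg_len2 <- rowSums(seg_vec^2)
  cum <- c(0, cumsum(seg_len))[seq_len(nrow(op))]

  ip <- c$points
  ip_closed <- rbind(ip, ip[1, ])
  ilen <- sqrt(rowSums(diff(ip_closed)^2))
  pos <- vapply(seq_len(nrow(ip)), function(i)
    nearest_arc_position(ip[i, ], op, cum, seg_vec, seg_len2),
    numeric(1))
  # arc interval of inner segment i: endpoint positions, taking the
  # shorter way around the outline
  p1 <- pos
  p2 <- pos[c(seq_len(nrow(ip))[-1], 1)]
  fw <- (p2 - p1) %% outer_total        # forward arc from p1 to p2
  use_fw <- fw <= outer_total / 2
  a1 <- ifelse(use_fw, p1, p2)
  a2 <- ifelse(use_fw, p2, p1)
  span <- ifelse(use_fw, fw, (p1 - p2) %% outer_total)

  starts <- seq(0, outer_total - 1e-9, by = step_arc)
  win <- lapply(starts, function(s) {
    e_raw <- s + window_arc
    inner_sum <- 0
    for (i in seq_along(ilen)) {
      if (span[i] < 1e-12) {
        # segment collapses onto one outer point: all-or-nothing
        inside <- if (e_raw <= outer_total) {
          a1[i] >= s && a1[i] < e_raw
        } else {
          a1[i] >= s || a1[i] < e_raw - outer_total
        }
        if (inside) inner_sum <- inner_sum + ilen[i]
      } else {
        ov <- arc_overlap(a1[i], a2[i], s, e_raw, outer_total)
        inner_sum <- inner_sum + ilen[i] * ov / span[i]
      }
    }
    data.frame(start_arc = s, end_arc = e_raw %% outer_total,
               local_gi = inner_sum / window_arc)
  })
  res$window_results <- do.call(rbind, win)
  res
}
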