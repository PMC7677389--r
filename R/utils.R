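# Internal helpers shared across modules: seeded RNG scoping, polygon
# geometry primitives, and small validation utilities.

#' Evaluate an expression with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package never disturb the caller's RNG stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible sub-seed from a master seed and a step label.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, label) {
  chars <- utf8ToInt(as.character(label))
  acc <- as.double(seed) %% 2147483647
  for (ch in chars) acc <- (acc * 31 + ch) %% 2147483647
  as.integer(acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# --- polygon primitives -----------------------------------------------------
# Polygons are n x 2 numeric matrices of vertices, implicitly closed
# (last vertex connects back to the first), coordinates in micrometres.

as_polygon <- function(p, what = "polygon") {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L || !all(is.finite(p))) {
    stopf("%s must be an n x 2 finite matrix with n >= 3", what)
  }
  storage.mode(p) <- "double"
  # drop a duplicated closing vertex
  if (isTRUE(all.equal(p[1L, ], p[nrow(p), ], check.attributes = FALSE))) {
    p <- p[-nrow(p), , drop = FALSE]
  }
  p
}

# Signed area by the shoelace formula; positive for counter-clockwise order.
polygon_area_signed <- function(p) {
  n <- nrow(p)
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area <- function(p) abs(polygon_area_signed(p))

polygon_perimeter <- function(p) {
  q <- rbind(p, p[1L, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

# Orient counter-clockwise.
polygon_ccw <- function(p) {
  if (polygon_area_signed(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# Proper segment-crossing test for simplicity checking (shared endpoints of
# adjacent edges are not crossings).
polygon_is_simple <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) break
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

polygon_is_convex <- function(p) {
  p <- polygon_ccw(p)
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  nx2 <- nxt[nxt]
  v1 <- p[nxt, , drop = FALSE] - p
  v2 <- p[nx2, , drop = FALSE] - p[nxt, , drop = FALSE]
  z <- v1[, 1L] * v2[, 2L] - v1[, 2L] * v2[, 1L]
  all(z >= -1e-9 * max(abs(z), 1))
}

# Vectorised even-odd (ray casting) point-in-polygon. Boundary points count
# as inside (within a small tolerance handled by strict/non-strict mix).
points_in_polygon <- function(x, y, p) {
  n <- nrow(p)
  px <- p[, 1L]; py <- p[, 2L]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    yi <- py[i]; yj <- py[j]; xi <- px[i]; xj <- px[j]
    hit <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

# Minimum distance from points to a polygon's boundary (vectorised over points).
points_to_polygon_boundary <- function(x, y, p) {
  n <- nrow(p)
  d2 <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- p[j, 1L]; ay <- p[j, 2L]
    bx <- p[i, 1L]; by <- p[i, 2L]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(x)) else ((x - ax) * vx + (y - ay) * vy) / len2
    t <- pmin(1, pmax(0, t))
    dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

# Outward Minkowski offset of a CONVEX polygon by radius r, with the corner
# arcs polygonalised at angular resolution arc_step (radians). r = 0 returns
# the polygon itself. Used for exact-area ring computations.
offset_convex_polygon <- function(p, r, arc_step = 2 * pi / 20000) {
  p <- polygon_ccw(p)
  if (r <= 0) return(p)
  n <- nrow(p)
  prv <- c(n, seq_len(n - 1L))
  nxt <- c(2:n, 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    e_in <- p[i, ] - p[prv[i], ]
    e_out <- p[nxt[i], ] - p[i, ]
    # outward unit normals (CCW polygon: normal is (dy, -dx) rotated -> (y, -x))
    n_in <- c(e_in[2L], -e_in[1L]); n_in <- n_in / sqrt(sum(n_in^2))
    n_out <- c(e_out[2L], -e_out[1L]); n_out <- n_out / sqrt(sum(n_out^2))
    a0 <- atan2(n_in[2L], n_in[1L])
    a1 <- atan2(n_out[2L], n_out[1L])
    da <- (a1 - a0) %% (2 * pi)
    k <- max(1L, ceiling(da / arc_step))
    ang <- a0 + da * (0:k) / k
    out[[i]] <- cbind(p[i, 1L] + r * cos(ang), p[i, 2L] + r * sin(ang))
  }
  do.call(rbind, out)
}

# Sutherland-Hodgman clip of a polygon to an axis-aligned rectangle
# bounds = c(x0, y0, x1, y1). Returns a polygon matrix (possibly 0 rows).
clip_polygon_rect <- function(p, bounds) {
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    keep <- inside(pts)
    out <- vector("list", 2L * n)
    m <- 0L
    j <- n
    for (i in seq_len(n)) {
      cur_in <- keep[i]; prev_in <- keep[j]
      if (cur_in) {
        if (!prev_in) {
          m <- m + 1L; out[[m]] <- intersect(pts[j, ], pts[i, ])
        }
        m <- m + 1L; out[[m]] <- pts[i, ]
      } else if (prev_in) {
        m <- m + 1L; out[[m]] <- intersect(pts[j, ], pts[i, ])
      }
      j <- i
    }
    if (m == 0L) return(pts[0L, , drop = FALSE])
    do.call(rbind, out[seq_len(m)])
  }
  x0 <- bounds[1L]; y0 <- bounds[2L]; x1 <- bounds[3L]; y1 <- bounds[4L]
  lerp <- function(a, b, t) a + t * (b - a)
  p <- clip_half(p, function(q) q[, 1L] >= x0,
                 function(a, b) { t <- (x0 - a[1L]) / (b[1L] - a[1L]); c(x0, lerp(a[2L], b[2L], t)) })
  p <- clip_half(p, function(q) q[, 1L] <= x1,
                 function(a, b) { t <- (x1 - a[1L]) / (b[1L] - a[1L]); c(x1, lerp(a[2L], b[2L], t)) })
  p <- clip_half(p, function(q) q[, 2L] >= y0,
                 function(a, b) { t <- (y0 - a[2L]) / (b[2L] - a[2L]); c(lerp(a[1L], b[1L], t), y0) })
  p <- clip_half(p, function(q) q[, 2L] <= y1,
                 function(a, b) { t <- (y1 - a[2L]) / (b[2L] - a[2L]); c(lerp(a[1L], b[1L], t), y1) })
  p
}
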