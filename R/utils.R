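# Internal geometry and RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under an explicit, locally scoped RNG seed. Generators must not
# touch the caller's random stream.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Ray casting with an explicit boundary check. Points exactly on a polygon
# edge or vertex count as inside (the package-wide boundary convention).
# px, py: polygon vertices (not closed); x, y: query points (vectorized).
pointsInPolygon <- function(x, y, px, py) {
  n <- length(px)
  stopifnot(n >= 3L, length(py) == n, length(x) == length(y))
  inside <- logical(length(x))
  onb <- logical(length(x))
  scale <- max(abs(px), abs(py), 1)
  tol <- 1e-9 * scale
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    onseg <- abs(cross) <= tol * max(abs(xj - xi) + abs(yj - yi), 1) &
      x >= pmin(xi, xj) - tol & x <= pmax(xi, xj) + tol &
      y >= pmin(yi, yj) - tol & y <= pmax(yi, yj) + tol
    onb <- onb | onseg
    crosses <- ((yi > y) != (yj > y))
    if (any(crosses)) {
      xint <- xi + (xj - xi) * (y - yi) / (yj - yi)
      inside <- xor(inside, crosses & x < xint)
    }
    j <- i
  }
  inside | onb
}

# Shoelace; positive for counter-clockwise vertex order.
polygonSignedArea <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  sum(px[j] * py - px * py[j]) / 2
}

polygonArea <- function(px, py) abs(polygonSignedArea(px, py))

# O(n^2) simplicity test: no two non-adjacent edges intersect.
polygonIsSimple <- function(px, py) {
  n <- length(px)
  if (n < 3L) return(FALSE)
  seg <- cbind(px, py, px[c(2:n, 1L)], py[c(2:n, 1L)])
  segIntersect <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (k in seq.int(i + 2L, n)) {
      if (i == 1L && k == n) next  # adjacent through closure
      if (segIntersect(seg[i, ], seg[k, ])) return(FALSE)
    }
  }
  TRUE
}

# Minimum distance from points to the polygon boundary (any edge).
distToPolygonBoundary <- function(x, y, px, py) {
  n <- length(px)
  d2 <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- px[j]; ay <- py[j]; bx <- px[i]; by <- py[i]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 > 0) pmin(pmax(((x - ax) * vx + (y - ay) * vy) / len2, 0), 1) else 0
    dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

# 8-connected labeling of a logical/binary matrix. EBImage::bwlabel is
# 4-connected, and adhesion segmentation is specified with 8-connectivity,
# so components are taken over the 8-neighbour pixel graph.
labelComponents8 <- function(mask) {
  stopifnot(is.matrix(mask))
  fg <- which(mask != 0)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(fg) == 0L) return(lab)
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_along(fg)
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    r2 <- rr + s[1L]; c2 <- cc + s[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- idx[cbind(r2[ok], c2[ok])]
    has <- nb > 0L
    if (any(has)) {
      edges[[length(edges) + 1L]] <-
        cbind(idx[cbind(rr[ok], cc[ok])][has], nb[has])
    }
  }
  if (length(edges) > 0L) {
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(fg)
  }
  # renumber labels in first-pixel (column-major) order for determinism
  comp <- match(comp, unique(comp))
  lab[fg] <- comp
  lab
}
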