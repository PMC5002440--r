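# Planar Delaunay triangulation (Bowyer-Watson) and barycentric evaluation.
# Small point sets only (probe sites, n <= a few hundred).  Exactly co-circular
# site layouts (regular grids) are disambiguated with a deterministic
# sub-nanometre perturbation; site values are still attached to the unperturbed
# coordinates, so interpolation stays exact at sites and keeps linear precision
# to well below interpolation tolerances.

.delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("cannot triangulate: need at least 3 points")
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  # deterministic tie-break jitter, ~1e-9 of the span
  jit <- ((seq_len(n) * 2654435761) %% 9973) / 9973 - 0.5
  p <- pts + span * 1e-9 * cbind(jit, rev(jit))
  # super-triangle enclosing everything
  cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2])); r <- 20 * span
  p <- rbind(p, c(cx - 2 * r, cy - r), c(cx + 2 * r, cy - r), c(cx, cy + 2 * r))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3)
  circum <- function(tri) {
    a <- p[tri[1], ]; b <- p[tri[2], ]; c2 <- p[tri[3], ]
    d <- 2 * (a[1] * (b[2] - c2[2]) + b[1] * (c2[2] - a[2]) + c2[1] * (a[2] - b[2]))
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - c2[2]) + (b[1]^2 + b[2]^2) * (c2[2] - a[2]) +
           (c2[1]^2 + c2[2]^2) * (a[2] - b[2])) / d
    uy <- ((a[1]^2 + a[2]^2) * (c2[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c2[1]) +
           (c2[1]^2 + c2[2]^2) * (b[1] - a[1])) / d
    c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
  }
  cc <- matrix(circum(tris[1, ]), ncol = 3)
  for (i in seq_len(n)) {
    px <- p[i, 1]; py <- p[i, 2]
    bad <- (px - cc[, 1])^2 + (py - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12)
    if (!any(bad)) stop("triangulation failure at point ", i)  # nocov
    hole <- tris[bad, , drop = FALSE]
    edges <- rbind(hole[, c(1, 2)], hole[, c(2, 3)], hole[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    newt <- cbind(boundary, i)
    tris <- rbind(tris, newt)
    cc <- rbind(cc, t(apply(newt, 1, circum)))
  }
  keep <- apply(tris, 1, function(tr) all(tr <= n))
  tris <- tris[keep, , drop = FALSE]
  if (!nrow(tris)) stop("cannot triangulate: points are collinear")
  list(points = pts, triangles = tris)
}

# Evaluate piecewise-linear interpolant defined by (triangulation, values) at
# query points (m x 2).  Returns NA outside the convex hull.
.tri_interp <- function(tri, values, query) {
  out <- rep(NA_real_, nrow(query))
  pts <- tri$points
  eps <- -1e-9 * max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  for (k in seq_len(nrow(tri$triangles))) {
    tr <- tri$triangles[k, ]
    a <- pts[tr[1], ]; b <- pts[tr[2], ]; c2 <- pts[tr[3], ]
    det <- (b[2] - c2[2]) * (a[1] - c2[1]) + (c2[1] - b[1]) * (a[2] - c2[2])
    if (abs(det) < 1e-12) next
    idx <- which(is.na(out))
    if (!length(idx)) break
    qx <- query[idx, 1]; qy <- query[idx, 2]
    l1 <- ((b[2] - c2[2]) * (qx - c2[1]) + (c2[1] - b[1]) * (qy - c2[2])) / det
    l2 <- ((c2[2] - a[2]) * (qx - c2[1]) + (a[1] - c2[1]) * (qy - c2[2])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= eps & l2 >= eps & l3 >= eps
    if (any(inside)) {
      sel <- idx[inside]
      out[sel] <- l1[inside] * values[tr[1]] + l2[inside] * values[tr[2]] +
        l3[inside] * values[tr[3]]
    }
  }
  out
}
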