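# Iso-surface triangulation of a binary occupancy grid by marching
# tetrahedra. Each grid cell is split into 6 tetrahedra; within a
# tetrahedron the 0.5 level set of the linearly interpolated field is a
# triangle or a quad, so no case table beyond the 16 tetrahedral sign
# patterns is needed (the patterns are derived programmatically below).
# The binary grid is first replaced by its 3x3x3 box-averaged occupancy:
# triangulating the raw 0/1 field puts every vertex on an edge midpoint and
# inflates the area of curved objects by ~27%, while the averaged field
# recovers digital-sphere areas to ~1% by r = 20 voxels.

# tetrahedral edge list and per-sign-pattern triangles (edge indices)
.mt <- local({
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  tris <- vector("list", 16L)
  eid <- function(u, v) which(edges[, 1] == min(u, v) & edges[, 2] == max(u, v))
  for (cfg in 0:15) {
    inside <- which(bitwAnd(cfg, c(1L, 2L, 4L, 8L)) > 0L)
    k <- length(inside)
    if (k == 0L || k == 4L) { tris[[cfg + 1L]] <- matrix(0L, 0, 3); next }
    crossing <- which(xor(edges[, 1] %in% inside, edges[, 2] %in% inside))
    if (k == 1L || k == 3L) {
      tris[[cfg + 1L]] <- matrix(crossing, 1, 3)
    } else {
      a <- inside[1]; b <- inside[2]; out <- setdiff(1:4, inside)
      quad <- c(eid(a, out[1]), eid(a, out[2]), eid(b, out[2]), eid(b, out[1]))
      tris[[cfg + 1L]] <- rbind(quad[c(1, 2, 3)], quad[c(1, 3, 4)])
    }
  }
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  list(edges = edges, tris = tris, corner = corner, tets = tets)
})

# 3x3x3 box mean with zero padding
box_mean3 <- function(g) {
  d <- dim(g)
  out <- array(0, d)
  p <- array(0, d + 2L)
  p[1:d[1] + 1L, 1:d[2] + 1L, 1:d[3] + 1L] <- g
  for (di in 0:2) for (dj in 0:2) for (dk in 0:2)
    out <- out + p[di + 1:d[1], dj + 1:d[2], dk + 1:d[3]]
  out / 27
}

# Total area (mm^2) of the 0.5 iso-surface of the box-averaged occupancy.
iso_surface_area <- function(grid, spacing, presmooth = TRUE) {
  d0 <- dim(grid)
  g <- array(0, d0 + 4L)
  g[1:d0[1] + 2L, 1:d0[2] + 2L, 1:d0[3] + 2L] <- grid
  if (presmooth) g <- box_mean3(g)
  d <- dim(g)
  nx <- d[1] - 1L; ny <- d[2] - 1L; nz <- d[3] - 1L
  ii <- rep.int(seq_len(nx), ny * nz)
  jj <- rep.int(rep(seq_len(ny), each = nx), nz)
  kk <- rep(seq_len(nz), each = nx * ny)
  corner_vals <- lapply(1:8, function(c) {
    co <- .mt$corner[c, ]
    g[(kk - 1L + co[3]) * d[1] * d[2] + (jj - 1L + co[2]) * d[1] + ii + co[1]]
  })
  total <- 0
  for (t in 1:6) {
    v <- .mt$tets[t, ]
    b <- lapply(1:4, function(m) as.integer(corner_vals[[v[m]]] > 0.5))
    cfg <- b[[1]] + 2L * b[[2]] + 4L * b[[3]] + 8L * b[[4]]
    act <- which(cfg != 0L & cfg != 15L)
    if (!length(act)) next
    P <- lapply(1:4, function(m) {
      co <- .mt$corner[v[m], ]
      cbind((ii[act] + co[1]) * spacing[1],
            (jj[act] + co[2]) * spacing[2],
            (kk[act] + co[3]) * spacing[3])
    })
    V <- lapply(1:4, function(m) corner_vals[[v[m]]][act])
    M <- lapply(1:6, function(e) {
      v1 <- V[[.mt$edges[e, 1]]]; v2 <- V[[.mt$edges[e, 2]]]
      tt <- ifelse(abs(v2 - v1) < 1e-12, 0.5, (0.5 - v1) / (v2 - v1))
      tt <- pmin(pmax(tt, 0), 1)
      P[[.mt$edges[e, 1]]] + tt * (P[[.mt$edges[e, 2]]] - P[[.mt$edges[e, 1]]])
    })
    cfga <- cfg[act]
    for (c in 1:14) {
      sel <- which(cfga == c)
      if (!length(sel)) next
      tr <- .mt$tris[[c + 1L]]
      for (r in seq_len(nrow(tr))) {
        A <- M[[tr[r, 1]]][sel, , drop = FALSE]
        B <- M[[tr[r, 2]]][sel, , drop = FALSE]
        C <- M[[tr[r, 3]]][sel, , drop = FALSE]
        u <- B - A; w <- C - A
        cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                    u[, 3] * w[, 1] - u[, 1] * w[, 3],
                    u[, 1] * w[, 2] - u[, 2] * w[, 1])
        total <- total + sum(sqrt(rowSums(cr^2))) / 2
      }
    }
  }
  total
}
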