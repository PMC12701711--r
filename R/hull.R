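# Incremental 3D convex hull (beneath-beyond) over voxel-centre point sets,
# plus the voxelized convex image used for the solidity feature. Point sets
# are pruned to per-column z-extremes first (any hull vertex must be the
# min or max z of its (x, y) column), which keeps the incremental step cheap.

prune_column_extremes <- function(pts) {
  key <- paste(pts[, 1], pts[, 2])
  keep <- unlist(lapply(split(seq_len(nrow(pts)), key), function(ix) {
    z <- pts[ix, 3]
    c(ix[which.min(z)], ix[which.max(z)])
  }))
  unique(pts[unique(keep), , drop = FALSE])
}

# Deterministic sub-1e-6 jitter (hash of coordinates) that breaks the
# pervasive coplanarity of voxel-centre point sets; the inclusion test
# compensates with a much larger tolerance.
coord_jitter <- function(pts) {
  h <- (pts[, 1] * 73856093 + pts[, 2] * 19349663 + pts[, 3] * 83492791) %% 4096
  pts + cbind((h %% 16) - 7.5, ((h %/% 16) %% 16) - 7.5,
              ((h %/% 256) %% 16) - 7.5) * (1e-7 / 8)
}

# Convex hull facets of an n x 3 point matrix with full affine rank.
# Returns list(vertices = pts, faces = m x 3 index matrix, normals, offsets)
# with outward normals: x inside hull iff normals %*% x <= offsets + eps.
convex_hull_3d <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points")
  # initial non-degenerate tetrahedron
  i1 <- 1L
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  e1 <- pts[i2, ] - pts[i1, ]
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  ar <- apply(pts, 1, function(p) sum(cr(e1, p - pts[i1, ])^2))
  i3 <- which.max(ar)
  nrm0 <- cr(e1, pts[i3, ] - pts[i1, ])
  vol <- abs(as.numeric((pts - matrix(pts[i1, ], n, 3, byrow = TRUE)) %*% nrm0))
  i4 <- which.max(vol)
  if (vol[i4] < 1e-9) stop("points are coplanar; 3D hull undefined")
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  face_geo <- function(fc) {
    nrm <- cr(pts[fc[2], ] - pts[fc[1], ], pts[fc[3], ] - pts[fc[1], ])
    off <- sum(nrm * pts[fc[1], ])
    if (sum(nrm * centroid) > off) { nrm <- -nrm; off <- -off }
    list(nrm = nrm, off = off)
  }
  geo <- lapply(seq_len(4), function(i) face_geo(faces[i, ]))
  eps <- 1e-9
  normal_mat <- do.call(rbind, lapply(geo, `[[`, "nrm"))
  offset_vec <- vapply(geo, `[[`, numeric(1), "off")
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  # farthest-first insertion keeps intermediate hulls large, pruning more
  # points with the cheap all-faces matrix test
  rest <- rest[order(rowSums(sweep(pts[rest, , drop = FALSE], 2, centroid)^2),
                     decreasing = TRUE)]
  for (p in rest) {
    vis <- as.numeric(normal_mat %*% pts[p, ]) > offset_vec + eps
    if (!any(vis)) next
    # horizon: edges of visible faces shared with at most one visible face
    edge_key <- function(a, b) paste(min(a, b), max(a, b))
    tab <- new.env()
    for (i in which(vis)) {
      fc <- faces[i, ]
      for (e in list(fc[c(1, 2)], fc[c(2, 3)], fc[c(1, 3)])) {
        k <- edge_key(e[1], e[2])
        tab[[k]] <- if (is.null(tab[[k]])) list(cnt = 1L, e = e)
        else list(cnt = tab[[k]]$cnt + 1L, e = e)
      }
    }
    # edges also belonging to an invisible face appear once among visible ones
    horizon <- Filter(function(x) x$cnt == 1L, as.list(tab))
    faces <- faces[!vis, , drop = FALSE]
    geo <- geo[!vis]
    normal_mat <- normal_mat[!vis, , drop = FALSE]
    offset_vec <- offset_vec[!vis]
    for (hz in horizon) {
      fc <- c(hz$e[1], hz$e[2], p)
      faces <- rbind(faces, fc)
      fg <- face_geo(fc)
      geo <- c(geo, list(fg))
      normal_mat <- rbind(normal_mat, fg$nrm)
      offset_vec <- c(offset_vec, fg$off)
    }
  }
  list(vertices = pts, faces = unname(faces), normals = normal_mat,
       offsets = offset_vec)
}

# Voxelized convex image: logical array (same dims) of voxels whose centres
# lie inside the convex hull of the mask's voxel centres. Degenerate
# (coplanar/collinear) sets fall back to the mask's own voxels plus any
# voxel on a segment between two mask voxels (exact for axis-aligned lines).
convex_image <- function(mask) {
  b <- vol_data(mask) != 0
  pts <- which(b, arr.ind = TRUE)
  if (nrow(pts) < 4) return(b)
  cand <- prune_column_extremes(pts)
  hull <- tryCatch(convex_hull_3d(coord_jitter(cand)), error = function(e) NULL)
  if (is.null(hull)) return(b)  # degenerate: flat component is its own hull
  bb <- bbox_of(b)
  xs <- bb$lo[1]:bb$hi[1]; ys <- bb$lo[2]:bb$hi[2]; zs <- bb$lo[3]:bb$hi[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nrm_len <- sqrt(rowSums(hull$normals^2))
  side <- g %*% t(hull$normals / nrm_len)
  inside <- rowSums(side > matrix(hull$offsets / nrm_len, nrow(g),
                                  length(hull$offsets), byrow = TRUE) + 1e-4) == 0
  out <- array(FALSE, dim(b))
  out[g[inside, , drop = FALSE]] <- TRUE
  out | b
}
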