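# 3D binary morphology (ball structuring elements) and connected components.
# Dilation/erosion use shift-and-combine over the ball's integer offsets;
# connected-component labelling delegates the union-find to igraph.

ball_offsets <- function(r) {
  r <- as.integer(r)
  if (r < 0) stop("radius must be >= 0")
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
}

# Shift a 3D logical array by integer offset, padding with `fill`.
shift_3d <- function(b, off, fill = FALSE) {
  d <- dim(b)
  out <- array(fill, d)
  sx <- max(1, 1 - off[1]):min(d[1], d[1] - off[1])
  sy <- max(1, 1 - off[2]):min(d[2], d[2] - off[2])
  sz <- max(1, 1 - off[3]):min(d[3], d[3] - off[3])
  if (length(sx) < 1 || length(sy) < 1 || length(sz) < 1) return(out)
  out[sx + off[1], sy + off[2], sz + off[3]] <- b[sx, sy, sz]
  out
}

#' Binary dilation by a Euclidean ball
#'
#' @param mask logical or 0/1 3D array.
#' @param r ball radius in voxels (0 returns the input binarized).
#' @return logical 3D array.
#' @export
dilate_ball <- function(mask, r) {
  b <- vol_data(mask) != 0
  if (r == 0) return(b)
  offs <- ball_offsets(r)
  out <- array(FALSE, dim(b))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_3d(b, c(offs$dx[i], offs$dy[i], offs$dz[i]))
  out
}

#' Binary erosion by a Euclidean ball
#'
#' Voxels outside the grid count as background.
#' @inheritParams dilate_ball
#' @return logical 3D array.
#' @export
erode_ball <- function(mask, r) {
  b <- vol_data(mask) != 0
  if (r == 0) return(b)
  offs <- ball_offsets(r)
  out <- array(TRUE, dim(b))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_3d(b, c(offs$dx[i], offs$dy[i], offs$dz[i]), fill = FALSE)
  out
}

#' Binary morphological closing by a Euclidean ball
#'
#' @inheritParams dilate_ball
#' @return logical 3D array.
#' @export
close_ball <- function(mask, r) {
  if (r == 0) return(vol_data(mask) != 0)
  erode_ball(dilate_ball(mask, r), r)
}

#' Label connected components of a 3D binary mask
#'
#' @param mask logical or 0/1 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer 3D array of component labels (0 = background), with the
#'   number of components as attribute `n`.
#' @export
label_components <- function(mask, connectivity = 26) {
  b <- vol_data(mask) != 0
  d <- dim(b)
  n_fg <- sum(b)
  lab <- array(0L, d)
  attr(lab, "n") <- 0L
  if (n_fg == 0) return(lab)
  id <- array(0L, d)
  id[b] <- seq_len(n_fg)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (connectivity == 26) {
    g <- as.matrix(ball_offsets(2))  # superset; filter to Chebyshev <= 1
    g <- g[apply(abs(g), 1, max) == 1, , drop = FALSE]
    g[g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
        (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0), , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- shift_3d(b, -offs[i, ])               # neighbour exists at +off
    both <- b & nb
    if (!any(both)) next
    from <- id[both]
    idn <- shift_3d(id, -offs[i, ], fill = 0L)  # neighbour's id pulled back
    edges[[i]] <- cbind(from, idn[both])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n_fg, directed = FALSE)
  if (!is.null(el) && nrow(el) > 0)
    g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)
  lab[b] <- comp$membership
  attr(lab, "n") <- comp$no
  lab
}

# Drop components smaller than min_voxels; returns logical array.
filter_small_components <- function(mask, min_voxels, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (attr(lab, "n") == 0L) return(lab != 0)
  sizes <- tabulate(lab[lab > 0], nbins = attr(lab, "n"))
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(lab))
}
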