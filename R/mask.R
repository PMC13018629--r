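#' Measure projected area and length from a binary segmentation mask
#'
#' Area is the number of foreground pixels times the pixel area. Length is
#' the longest side of the minimum-area bounding rectangle of the foreground
#' pixels (rotating calipers over the convex hull of pixel centres, padded
#' by one pixel so that an axis-aligned n-pixel run measures n pixels), in
#' micrometres. The minimum-area rectangle makes the length estimate
#' invariant to mask orientation up to rasterisation error.
#'
#' @param mask logical or 0/1 matrix; nonzero marks the cell. Must contain a
#'   single 8-connected component.
#' @param pixel_area_um2 area of one pixel in square micrometres.
#' @return list with `projected_area_um2` and `length_um`.
#' @export
measure_mask <- function(mask, pixel_area_um2 = 0.005) {
  stopifnot(is.matrix(mask), pixel_area_um2 > 0)
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty mask: no foreground pixels")
  if (count_components(mask) > 1)
    stop("mask has multiple connected components; split it upstream")
  px <- sqrt(pixel_area_um2)
  list(
    projected_area_um2 = nrow(fg) * pixel_area_um2,
    length_um = (min_area_rect_sides(fg)[2] + 1) * px
  )
}

# Number of 8-connected foreground components, by iterative flood fill.
count_components <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  comps <- 0L
  idx <- which(m)
  for (start in idx) {
    r0 <- (start - 1L) %% nr + 1L
    c0 <- (start - 1L) %/% nr + 1L
    if (seen[r0, c0]) next
    comps <- comps + 1L
    stack_r <- r0; stack_c <- c0
    seen[r0, c0] <- TRUE
    while (length(stack_r)) {
      r <- stack_r[length(stack_r)]; c <- stack_c[length(stack_c)]
      stack_r <- stack_r[-length(stack_r)]
      stack_c <- stack_c[-length(stack_c)]
      rr <- pmax(1L, r - 1L):pmin(nr, r + 1L)
      cc <- pmax(1L, c - 1L):pmin(nc, c + 1L)
      for (r2 in rr) for (c2 in cc) {
        if (m[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          stack_r <- c(stack_r, r2)
          stack_c <- c(stack_c, c2)
        }
      }
    }
  }
  comps
}

# Sides (sorted, short then long, in pixel units) of the minimum-area
# rectangle enclosing the given points (n x 2 matrix of coordinates).
# Rotating calipers: the optimal rectangle has a side collinear with a
# convex-hull edge.
min_area_rect_sides <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  if (nrow(pts) == 1) return(c(0, 0))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  if (n == 2) {
    d <- sqrt(sum((hull[1, ] - hull[2, ])^2))
    return(c(0, d))
  }
  best <- c(Inf, Inf, Inf)  # area, side1, side2
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len            # edge direction
    v <- c(-u[2], u[1])     # normal
    pu <- hull %*% u
    pv <- hull %*% v
    s1 <- max(pu) - min(pu)
    s2 <- max(pv) - min(pv)
    if (s1 * s2 < best[1]) best <- c(s1 * s2, s1, s2)
  }
  sort(best[2:3])
}

#' Read a binary mask from a PNG file
#'
#' Any pixel with a nonzero first channel is foreground. Requires the
#' `png` package.
#'
#' @param path path to a PNG file.
#' @return a logical matrix.
#' @export
read_mask_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG masks requires the 'png' package")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' Build a cell table from a set of masks
#'
#' Convenience wrapper applying [measure_mask()] to a list of masks and
#' assembling the per-cell measurement table consumed by
#' [derive_dimensions()].
#'
#' @param masks list of binary matrices.
#' @param time_h,condition labels recycled across masks.
#' @param pixel_area_um2 pixel area in square micrometres.
#' @return data.frame with `cell_id`, `condition`, `time_h`,
#'   `projected_area_um2`, `length_um`.
#' @export
cells_from_masks <- function(masks, time_h = 0, condition = "sim",
                             pixel_area_um2 = 0.005) {
  stopifnot(is.list(masks))
  meas <- lapply(masks, measure_mask, pixel_area_um2 = pixel_area_um2)
  data.frame(
    cell_id = sprintf("mask_%03d", seq_along(masks)),
    condition = rep_len(condition, length(masks)),
    time_h = rep_len(time_h, length(masks)),
    projected_area_um2 = vapply(meas, `[[`, numeric(1), "projected_area_um2"),
    length_um = vapply(meas, `[[`, numeric(1), "length_um")
  )
}
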