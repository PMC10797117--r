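#' @name correspondence
#' @title Spatial correspondence between T1 and perfusion maps
#' @description
#' Two routes relate maps acquired on different grids / respiratory states:
#' (a) applying externally produced deformation fields (pull-back
#' resampling; the registration that produces them is upstream of this
#' package, an identity field is always available), and (b) a
#' registration-free scheme that subdivides each lung into 10 vertical
#' strips of equal voxel count, each split horizontally into 10 blocks of
#' equal count - 100 areas per lung that correspond across grids because
#' they tile the same cumulative volume fractions.
NULL

#' Intensity-based region growing segmentation
#'
#' Grows a connected region from seed voxels, accepting a 4-neighbour
#' whenever its intensity lies within `tolerance` of the running region
#' mean, then fills interior holes. A grown region that leaks to the image
#' border (more than `border_frac` of its voxels on the border) is treated
#' as a failed segmentation, which catches seeds placed in the background.
#'
#' @param image numeric matrix.
#' @param seeds integer matrix with one `(x, y)` voxel index per row.
#' @param tolerance maximum absolute deviation from the running mean.
#' @param border_frac leak-detection threshold.
#' @return logical mask.
#' @export
region_grow_segment <- function(image, seeds, tolerance, border_frac = 0.05) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  seeds <- matrix(as.integer(seeds), ncol = 2L)
  nx <- nrow(image); ny <- ncol(image)
  if (any(seeds[, 1] < 1L | seeds[, 1] > nx | seeds[, 2] < 1L | seeds[, 2] > ny))
    stop("seeds must lie inside the image")
  mask <- matrix(FALSE, nx, ny)
  for (s in seq_len(nrow(seeds))) {
    idx0 <- seeds[s, 1] + (seeds[s, 2] - 1L) * nx
    if (mask[idx0]) next
    queue <- idx0
    in_q <- matrix(FALSE, nx, ny)
    in_q[idx0] <- TRUE
    region <- logical(nx * ny)
    rsum <- 0; rn <- 0L
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      val <- image[v]
      if (rn > 0L && abs(val - rsum / rn) > tolerance) next
      region[v] <- TRUE
      rsum <- rsum + val; rn <- rn + 1L
      x <- ((v - 1L) %% nx) + 1L
      y <- ((v - 1L) %/% nx) + 1L
      for (nb in c(if (x > 1L) v - 1L, if (x < nx) v + 1L,
                   if (y > 1L) v - nx, if (y < ny) v + nx)) {
        if (!in_q[nb]) { in_q[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
    reg <- matrix(region, nx, ny)
    on_border <- reg
    on_border[2:(nx - 1L), 2:(ny - 1L)] <- FALSE
    if (sum(reg) == 0L || sum(on_border) / sum(reg) > border_frac)
      stop("region growing failed: region empty or leaked to the image border")
    mask <- mask | reg
  }
  fill_holes(mask)
}

# interior holes = background components not reachable from the border
fill_holes <- function(mask) {
  lab <- EBImage::bwlabel(!mask)
  nx <- nrow(mask); ny <- ncol(mask)
  border_labels <- unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny]))
  border_labels <- border_labels[border_labels > 0]
  mask | (lab > 0 & !(lab %in% border_labels))
}

#' Split a lung mask into left and right lungs
#'
#' The two largest connected components are labelled by the horizontal
#' position of their centroids (1 = left, 2 = right). A single-component
#' mask is split at the vertical midline with a warning.
#'
#' @param mask logical matrix.
#' @return integer matrix (0 background, 1 left, 2 right).
#' @export
split_left_right <- function(mask) {
  if (!any(mask)) stop("empty mask")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(sizes) == 1L) {
    warning("single connected component: splitting at the vertical midline")
    xs <- row(mask)[mask]
    mid <- stats::median(xs)
    out[mask & row(mask) <= mid] <- 1L
    out[mask & row(mask) > mid] <- 2L
    return(out)
  }
  top2 <- order(sizes, decreasing = TRUE)[1:2]
  cx <- vapply(top2, function(l) mean(row(lab)[lab == l]), numeric(1))
  left <- top2[which.min(cx)]
  right <- top2[which.max(cx)]
  out[lab == left] <- 1L
  out[lab == right] <- 2L
  out
}

#' Equal-volume subdivision of a single lung
#'
#' Lung voxels are ordered by vertical coordinate (ties broken by
#' horizontal coordinate, i.e. a total raster order) and cut into
#' `n_strips` strips of equal cumulative count; within each strip the same
#' rule along the horizontal axis yields `n_blocks` blocks. The resulting
#' areas partition the mask exactly, with counts differing by at most one
#' voxel, and are deterministic for any voxel enumeration order.
#'
#' @param mask logical matrix of one lung.
#' @param n_strips,n_blocks subdivision counts (default 10 x 10).
#' @return a `subdivision_map`: list with `area` (integer matrix,
#'   `(strip - 1) * n_blocks + block`, `NA` outside), `strip`, `block`,
#'   `n_strips`, `n_blocks`.
#' @export
subdivide_lung <- function(mask, n_strips = 10L, n_blocks = 10L) {
  idx <- which(mask)
  n <- length(idx)
  if (n < n_strips * n_blocks)
    stop(sprintf("lung has %d voxels; need at least %d", n, n_strips * n_blocks))
  x <- ((idx - 1L) %% nrow(mask)) + 1L
  y <- ((idx - 1L) %/% nrow(mask)) + 1L
  ord <- order(y, x)
  strip_of <- integer(n)
  strip_of[ord] <- ceiling(seq_len(n) * n_strips / n)
  block_of <- integer(n)
  for (k in seq_len(n_strips)) {
    inb <- which(strip_of == k)
    ordb <- inb[order(x[inb], y[inb])]
    block_of[ordb] <- ceiling(seq_along(ordb) * n_blocks / length(inb))
  }
  area <- strip <- block <- matrix(NA_integer_, nrow(mask), ncol(mask))
  strip[idx] <- strip_of
  block[idx] <- block_of
  area[idx] <- (strip_of - 1L) * n_blocks + block_of
  structure(list(area = area, strip = strip, block = block,
                 n_strips = n_strips, n_blocks = n_blocks),
            class = "subdivision_map")
}

#' Matched area pairs between two subdivision maps
#'
#' Areas correspond by (strip, block) index; both maps must use the same
#' scheme. The pairing is the identity on indices - the point of the
#' equal-volume construction is that equal indices cover the same physical
#' volume on either grid.
#'
#' @param sub_a,sub_b `subdivision_map`s.
#' @return data.frame with columns `strip`, `block`, `area`.
#' @export
corresponding_areas <- function(sub_a, sub_b) {
  stopifnot(inherits(sub_a, "subdivision_map"), inherits(sub_b, "subdivision_map"))
  if (sub_a$n_strips != sub_b$n_strips || sub_a$n_blocks != sub_b$n_blocks)
    stop("subdivision schemes differ")
  g <- expand.grid(block = seq_len(sub_a$n_blocks),
                   strip = seq_len(sub_a$n_strips))
  data.frame(strip = g$strip, block = g$block,
             area = (g$strip - 1L) * sub_a$n_blocks + g$block)
}

#' Per-area summary of a voxel map
#'
#' @param values numeric matrix on the subdivision grid.
#' @param sub a `subdivision_map`.
#' @param fun summary function (default median); `NA` values are dropped
#'   first, areas with no finite voxel give `NA`.
#' @return numeric vector indexed by area label.
#' @export
area_summary <- function(values, sub, fun = stats::median) {
  vapply(seq_len(sub$n_strips * sub$n_blocks), function(a) {
    v <- values[!is.na(sub$area) & sub$area == a]
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else fun(v)
  }, numeric(1))
}

#' Apply a deformation field by pull-back resampling
#'
#' Output voxel `v` takes the input value at `v + displacement(v)`
#' (displacements in voxel units): bilinear interpolation for continuous
#' maps, nearest neighbour for label maps (which therefore never invents
#' labels). Samples falling outside the input domain become `NA`.
#'
#' @param map numeric matrix.
#' @param field list with matrices `dx`, `dy` matching `map`.
#' @param mode `"linear"` or `"nearest"`.
#' @return matrix of warped values.
#' @export
apply_deformation <- function(map, field, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (!all(is.finite(field$dx)) || !all(is.finite(field$dy)))
    stop("deformation field contains non-finite displacements")
  if (!all(dim(field$dx) == dim(map)) || !all(dim(field$dy) == dim(map)))
    stop("field shape does not match the map")
  nx <- nrow(map); ny <- ncol(map)
  xs <- row(map) + field$dx
  ys <- col(map) + field$dy
  out <- matrix(NA_real_, nx, ny)
  if (mode == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
    out[ok] <- map[cbind(xi[ok], yi[ok])]
  } else {
    ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
    # clamp the interpolation cell so exact upper-edge hits stay in-domain
    x0 <- pmin(pmax(floor(xs), 1), nx - 1)
    y0 <- pmin(pmax(floor(ys), 1), ny - 1)
    fx <- xs - x0; fy <- ys - y0
    i <- which(ok)
    v00 <- map[cbind(x0[i], y0[i])]
    v10 <- map[cbind(x0[i] + 1, y0[i])]
    v01 <- map[cbind(x0[i], y0[i] + 1)]
    v11 <- map[cbind(x0[i] + 1, y0[i] + 1)]
    out[i] <- v00 * (1 - fx[i]) * (1 - fy[i]) + v10 * fx[i] * (1 - fy[i]) +
      v01 * (1 - fx[i]) * fy[i] + v11 * fx[i] * fy[i]
  }
  out
}

#' Identity deformation field
#' @param shape voxel counts `(nx, ny)`.
#' @export
identity_field <- function(shape) {
  list(dx = matrix(0, shape[1], shape[2]), dy = matrix(0, shape[1], shape[2]))
}

#' Smooth analytic deformation field for testing
#'
#' A sinusoidal displacement pattern with known amplitude (voxels) and
#' wavelength (voxels), the kind of smooth field a deformable registration
#' would produce.
#'
#' @param shape voxel counts. @param amplitude peak displacement (voxels).
#' @param wavelength spatial period (voxels).
#' @export
sinusoidal_field <- function(shape, amplitude = 2, wavelength = 24) {
  xs <- row(matrix(0, shape[1], shape[2]))
  ys <- col(matrix(0, shape[1], shape[2]))
  list(dx = amplitude * sin(2 * pi * ys / wavelength),
       dy = amplitude * cos(2 * pi * xs / wavelength))
}
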