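#' Image grid geometry
#'
#' A lightweight container describing the sampling geometry of a 2D image:
#' voxel counts, voxel spacing in mm and the physical position (mm) of the
#' first voxel centre. All phantom geometry is defined in physical
#' coordinates so the same anatomy can be rasterised at any resolution.
#'
#' @param shape integer vector of voxel counts, length 2 (x = horizontal,
#'   y = vertical on a coronal slice).
#' @param spacing voxel spacing in mm per axis; a scalar is recycled.
#' @param origin physical coordinate (mm) of the centre of voxel (1, 1).
#'   Defaults to centring the field of view on 0.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("shape must be two positive voxel counts")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (any(spacing <= 0)) stop("spacing must be > 0 on every axis")
  if (is.null(origin)) origin <- -(shape - 1L) * spacing / 2
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d, spacing %.3g x %.3g mm>\n",
              x$shape[1], x$shape[2], x$spacing[1], x$spacing[2]))
  invisible(x)
}

#' Physical coordinates of every voxel centre
#'
#' @param grid an `image_grid`.
#' @return list with matrices `x` and `y` (mm), each of dim `grid$shape`.
#' @keywords internal
grid_coords <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1L) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1L) * grid$spacing[2]
  list(x = matrix(xs, grid$shape[1], grid$shape[2]),
       y = matrix(ys, grid$shape[1], grid$shape[2], byrow = TRUE))
}

grids_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_grid_mismatch <- function(a, b, what = "inputs") {
  stop(sprintf("grid mismatch between %s: %s vs %s", what,
               paste(a$shape, collapse = "x"),
               paste(b$shape, collapse = "x")), call. = FALSE)
}

# Evaluate and restore the RNG state around seeded simulation so that
# generators are reproducible without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
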