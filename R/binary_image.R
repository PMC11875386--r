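#' Binary 3D pore-space image
#'
#' Wraps a 3D array of `{0, 1}` voxel tags into a `pore_image` object.
#' Following the usual micro-CT convention, voxels tagged 0 are pore (void,
#' water-filled under saturation) and voxels tagged 1 are solid. The array is
#' indexed `[x, y, z]`; voxel indices are 0-based in all coordinate output.
#'
#' @param values 3D numeric/integer array (or a vector together with `dims`)
#'   whose entries are all 0 or 1.
#' @param dims integer vector `(nx, ny, nz)`; defaults to `dim(values)`.
#' @param voxel_edge physical edge length of one voxel (any consistent unit;
#'   default 1 voxel unit). Only used by [physical_volume()].
#' @return an object of class `pore_image` with fields `values`, `dims`,
#'   `voxel_edge`.
#' @examples
#' img <- pore_image(array(0L, c(3, 3, 3)))
#' porosity(img)
#' @export
pore_image <- function(values, dims = dim(values), voxel_edge = 1) {
  if (is.null(dims) || length(dims) != 3L)
    stop("a pore image needs three dimensions (nx, ny, nz)")
  dims <- as.integer(dims)
  if (any(dims <= 0L)) stop("image dimensions must be positive")
  if (length(values) != prod(dims))
    stop("length of `values` (", length(values),
         ") does not match prod(dims) = ", prod(dims))
  bad <- which(values != 0 & values != 1)
  if (length(bad) > 0L)
    stop("non-binary voxel value ", format(values[bad[1L]]),
         " at linear index ", bad[1L], "; pore images must contain only 0/1")
  structure(
    list(values = array(as.integer(values), dim = dims),
         dims = dims, voxel_edge = voxel_edge),
    class = "pore_image"
  )
}

#' @export
print.pore_image <- function(x, ...) {
  cat("pore_image: ", paste(x$dims, collapse = " x "),
      " voxels, porosity ", signif(porosity(x), 4),
      ", voxel edge ", format(x$voxel_edge), "\n", sep = "")
  invisible(x)
}

#' Porosity of a binary image
#'
#' Fraction of voxels tagged 0 (pore).
#'
#' @param image a [pore_image()].
#' @return scalar in \[0, 1\].
#' @export
porosity <- function(image) {
  stopifnot(inherits(image, "pore_image"))
  mean(image$values == 0L)
}

#' Physical volume of an imaged sample
#'
#' `prod(dims) * voxel_edge^3`, in the cube of whatever unit `voxel_edge`
#' carries. For a 512^3 image at a 24 um (= 24e-4 cm) voxel edge this gives
#' the familiar ~1.855 cm^3 sample volume.
#'
#' @param dims integer vector `(nx, ny, nz)` or a [pore_image()].
#' @param voxel_edge voxel edge length; taken from the image when `dims` is a
#'   `pore_image` and `voxel_edge` is missing.
#' @return scalar volume.
#' @examples
#' physical_volume(c(512, 512, 512), 24e-4)  # cm^3
#' @export
physical_volume <- function(dims, voxel_edge = NULL) {
  if (inherits(dims, "pore_image")) {
    if (is.null(voxel_edge)) voxel_edge <- dims$voxel_edge
    dims <- dims$dims
  }
  if (is.null(voxel_edge)) voxel_edge <- 1
  prod(as.numeric(dims)) * voxel_edge^3
}

#' All-pore chain image (1D validation geometry)
#'
#' An `L x 1 x 1` image whose voxel graph is the path graph on `L` nodes,
#' with Laplacian eigenvalues `2 - 2*cos(k*pi/L)`, `k = 0..L-1` — handy as an
#' analytically solvable diffusion test case.
#'
#' @param length integer >= 2.
#' @return a [pore_image()].
#' @export
chain_image <- function(length) {
  length <- as.integer(length)
  if (length < 2L) stop("chain length must be at least 2")
  pore_image(array(0L, c(length, 1L, 1L)))
}

#' All-pore cubic image
#'
#' @param dims integer vector `(nx, ny, nz)` (a scalar is recycled).
#' @return a [pore_image()] with every voxel pore.
#' @export
full_pore_image <- function(dims) {
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  pore_image(array(0L, as.integer(dims)))
}

#' Pore slab image
#'
#' All voxels solid except `thickness` consecutive layers of pore along the
#' chosen axis (layers `0..thickness-1`).
#'
#' @param dims integer vector `(nx, ny, nz)`.
#' @param thickness number of pore layers (default 2).
#' @param axis one of `"x"`, `"y"`, `"z"` (default `"z"`).
#' @return a [pore_image()].
#' @export
slab_image <- function(dims, thickness = 2L, axis = "z") {
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  dims <- as.integer(dims)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  if (thickness < 1L || thickness > dims[ax])
    stop("slab thickness must be in 1..", dims[ax])
  vals <- array(1L, dims)
  idx <- list(seq_len(dims[1L]), seq_len(dims[2L]), seq_len(dims[3L]))
  idx[[ax]] <- seq_len(thickness)
  vals[idx[[1L]], idx[[2L]], idx[[3L]]] <- 0L
  pore_image(vals)
}
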