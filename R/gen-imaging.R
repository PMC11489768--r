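#' Simulate a 3D fluorescence stack with Gaussian spots
#'
#' Builds a voxel stack (array indexed \[y, x, z\]) as background +
#' anisotropic 3D Gaussian spots + white noise, emulating confocal stacks
#' of presynaptic boutons (default voxel size 0.05 x 0.05 um laterally,
#' 0.2 um axially). Spot centroids and amplitudes are recorded as ground
#' truth for recovery tests.
#'
#' @param shape_vox Integer vector (ny, nx, nz).
#' @param voxel_size_um Numeric vector (dy, dx, dz) in um (default
#'   `c(0.05, 0.05, 0.2)`).
#' @param spots Data frame with columns `y_um`, `x_um`, `z_um` (centroids,
#'   inside the stack), `amplitude`, and either `sigma_um` (isotropic) or
#'   `sigma_y_um`, `sigma_x_um`, `sigma_z_um`.
#' @param background Constant background intensity (default 10).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed RNG seed.
#' @return A `voxel_stack`: list with `data` (3D array), `voxel_size_um`.
#'   Carries [ground_truth()] with the spot table.
#' @export
gen_bouton_stack <- function(shape_vox, voxel_size_um = c(0.05, 0.05, 0.2),
                             spots, background = 10, noise_sd = 0, seed = 1) {
  stopifnot(length(shape_vox) == 3, length(voxel_size_um) == 3)
  if (nrow(spots) > 0) {
    if (is.null(spots$sigma_y_um)) {
      if (is.null(spots$sigma_um)) {
        stop("spots need sigma_um or per-axis sigmas", call. = FALSE)
      }
      spots$sigma_y_um <- spots$sigma_um
      spots$sigma_x_um <- spots$sigma_um
      spots$sigma_z_um <- spots$sigma_um
    }
    if (any(spots$sigma_y_um <= 0 | spots$sigma_x_um <= 0 |
            spots$sigma_z_um <= 0)) {
      stop("spot sigmas must be positive", call. = FALSE)
    }
    ext <- shape_vox * voxel_size_um
    if (any(spots$y_um < 0 | spots$y_um > ext[1] |
            spots$x_um < 0 | spots$x_um > ext[2] |
            spots$z_um < 0 | spots$z_um > ext[3])) {
      stop("spot centroids must lie inside the stack", call. = FALSE)
    }
    if (anyDuplicated(spots[, c("y_um", "x_um", "z_um")])) {
      stop("duplicate spot centroids", call. = FALSE)
    }
  }

  a <- array(background, dim = shape_vox)
  # voxel-center coordinates in um
  yy <- (seq_len(shape_vox[1]) - 0.5) * voxel_size_um[1]
  xx <- (seq_len(shape_vox[2]) - 0.5) * voxel_size_um[2]
  zz <- (seq_len(shape_vox[3]) - 0.5) * voxel_size_um[3]
  for (i in seq_len(nrow(spots))) {
    s <- spots[i, ]
    gy <- exp(-(yy - s$y_um)^2 / (2 * s$sigma_y_um^2))
    gx <- exp(-(xx - s$x_um)^2 / (2 * s$sigma_x_um^2))
    gz <- exp(-(zz - s$z_um)^2 / (2 * s$sigma_z_um^2))
    a <- a + s$amplitude * (gy %o% gx %o% gz)
  }
  if (noise_sd > 0) {
    a <- with_seed(seed, a + array(stats::rnorm(length(a), sd = noise_sd),
                                   dim = shape_vox))
    a <- pmax(a, 0)
  }
  stack <- structure(
    list(data = a, voxel_size_um = voxel_size_um),
    class = "voxel_stack"
  )
  attr(stack, "ground_truth") <- new_ground_truth(
    "bouton_stack",
    list(spots = spots, background = background, noise_sd = noise_sd),
    seed
  )
  stack
}

#' Write / read a voxel stack as multi-page TIFF
#'
#' Stacks are stored as 16-bit multi-page TIFFs (one page per z plane),
#' scaled by `scale` so intensities fit \[0, 65535\].
#'
#' @param stack A `voxel_stack`.
#' @param path Output file path.
#' @param scale Intensity units per grey level (default 1).
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns a `voxel_stack`.
#' @export
write_stack_tiff <- function(stack, path, scale = 1) {
  pages <- lapply(seq_len(dim(stack$data)[3]), function(z) {
    pmin(pmax(stack$data[, , z] / (scale * 65535), 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param voxel_size_um Voxel size to attach on read.
#' @export
read_stack_tiff <- function(path, voxel_size_um = c(0.05, 0.05, 0.2),
                            scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) a[, , z] <- pages[[z]] * 65535 * scale
  structure(list(data = a, voxel_size_um = voxel_size_um),
            class = "voxel_stack")
}
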