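#' Specification for a synthetic FLAIR-like phantom
#'
#' Describes a parametric brain phantom built from two nested ellipsoids:
#' an outer "brain" ellipsoid defining the intracranial volume (ICV) and an
#' inner white-matter (WM) ellipsoid. WM voxel intensities follow a
#' two-component Gaussian mixture: a dominant normal-appearing-WM mode plus a
#' smaller partial-volume component. Optional spherical lesions are planted
#' inside the WM with their own intensity Gaussian, emulating hyperintense
#' lesions on FLAIR. Geometry is deliberately non-anatomical: only the
#' intensity statistics matter to the downstream histogram analysis.
#'
#' @param grid_dims integer(3), volume dimensions in voxels.
#' @param voxel_size numeric(3), voxel edge lengths in mm.
#' @param brain_semiaxes numeric(3), semi-axes (voxels) of the ICV ellipsoid,
#'   centred in the grid.
#' @param wm_semiaxes numeric(3), semi-axes (voxels) of the WM ellipsoid,
#'   nested inside the brain ellipsoid.
#' @param dominant list(mu, sigma): mean and SD (intensity a.u.) of the
#'   dominant normal-appearing-WM Gaussian.
#' @param secondary list(weight, mu, sigma): mixing weight in `[0, 1)` and
#'   moments of the secondary (partial-volume) component. The dominant weight
#'   is `1 - weight` and must exceed 0.5.
#' @param lesions list of lesions, each `list(center = c(x, y, z), radius, mu,
#'   sigma)` in voxel units; every lesion sphere must lie inside the WM
#'   ellipsoid.
#' @param frontal_plane integer, coronal (second-axis) cut index; WM voxels
#'   with a second coordinate strictly greater than it form the "frontal"
#'   submask.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(96L, 112L, 72L),
                         voxel_size = c(1, 1, 1),
                         brain_semiaxes = c(44, 52, 33),
                         wm_semiaxes = c(38, 45, 28),
                         dominant = list(mu = 100, sigma = 10),
                         secondary = list(weight = 0.1, mu = 140, sigma = 15),
                         lesions = list(),
                         frontal_plane = 76L,
                         seed = 1L) {
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 4),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(brain_semiaxes) == 3L, all(brain_semiaxes > 0),
            length(wm_semiaxes) == 3L, all(wm_semiaxes > 0),
            all(wm_semiaxes <= brain_semiaxes))
  stop_if_not_scalar_pos(dominant$sigma, "dominant$sigma")
  if (secondary$weight < 0 || secondary$weight >= 0.5)
    stop("secondary weight must lie in [0, 0.5) so the dominant component stays dominant",
         call. = FALSE)
  if (secondary$weight > 0) stop_if_not_scalar_pos(secondary$sigma, "secondary$sigma")
  for (les in lesions) {
    stopifnot(length(les$center) == 3L)
    stop_if_not_scalar_pos(les$radius, "lesion radius")
    stop_if_not_scalar_pos(les$sigma, "lesion sigma")
  }
  structure(list(grid_dims = as.integer(grid_dims), voxel_size = voxel_size,
                 brain_semiaxes = brain_semiaxes, wm_semiaxes = wm_semiaxes,
                 dominant = dominant, secondary = secondary, lesions = lesions,
                 frontal_plane = as.integer(frontal_plane), seed = as.integer(seed)),
            class = "phantom_spec")
}

# logical array marking voxels inside an ellipsoid centred at `center`
ellipsoid_mask <- function(dims, center, semiaxes) {
  dx <- (seq_len(dims[1]) - center[1]) / semiaxes[1]
  dy <- (seq_len(dims[2]) - center[2]) / semiaxes[2]
  dz <- (seq_len(dims[3]) - center[3]) / semiaxes[3]
  d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  array(d2 <= 1, dims)
}

sphere_mask <- function(dims, center, radius) {
  dx <- seq_len(dims[1]) - center[1]
  dy <- seq_len(dims[2]) - center[2]
  dz <- seq_len(dims[3]) - center[3]
  d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  array(d2 <= radius^2, dims)
}

#' Generate a synthetic FLAIR-like phantom volume
#'
#' Realizes a [phantom_spec()]: WM voxels outside lesions are drawn from the
#' two-component Gaussian mixture, lesion voxels from their own Gaussian,
#' brain voxels outside the WM get a constant grey-matter-like intensity
#' (0.7 of the dominant mean; they are excluded by the WM mask downstream),
#' and voxels outside the brain ellipsoid are zero. The intracranial volume
#' is the brain-ellipsoid voxel count times the voxel volume.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `flair_phantom`: a list with `intensity`
#'   (numeric 3D array), logical masks `brain_mask`, `wm_mask`,
#'   `frontal_mask` (WM restricted anterior to the cut plane), `icv_mm3`,
#'   `voxel_size`, and `truth` (lesion mask, lesion voxel count, planted
#'   lesion volume in mm^3, and the generating mixture parameters).
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_dims = c(32, 36, 24),
#'   brain_semiaxes = c(14, 16, 10), wm_semiaxes = c(11, 13, 8),
#'   frontal_plane = 18, seed = 7))
#' sum(ph$wm_mask)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_dims
  center <- (dims + 1) / 2
  brain <- ellipsoid_mask(dims, center, spec$brain_semiaxes)
  wm <- ellipsoid_mask(dims, center, spec$wm_semiaxes)

  lesion_mask <- array(FALSE, dims)
  lesion_of <- vector("list", length(spec$lesions))
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    sm <- sphere_mask(dims, les$center, les$radius)
    if (any(sm & !wm))
      stop(sprintf("lesion %d (center %s, radius %g) extends outside the WM ellipsoid",
                   i, paste(les$center, collapse = ","), les$radius), call. = FALSE)
    lesion_of[[i]] <- sm
    lesion_mask <- lesion_mask | sm
  }

  intensity <- array(0, dims)
  gm_value <- 0.7 * spec$dominant$mu
  intensity[brain & !wm] <- gm_value

  wm_clean <- wm & !lesion_mask
  n_wm <- sum(wm_clean)
  with_seed(spec$seed, {
    if (n_wm > 0) {
      from_secondary <- stats::runif(n_wm) < spec$secondary$weight
      vals <- numeric(n_wm)
      n2 <- sum(from_secondary)
      vals[!from_secondary] <- stats::rnorm(n_wm - n2, spec$dominant$mu, spec$dominant$sigma)
      if (n2 > 0) vals[from_secondary] <- stats::rnorm(n2, spec$secondary$mu, spec$secondary$sigma)
      intensity[wm_clean] <- vals
    }
    for (i in seq_along(spec$lesions)) {
      les <- spec$lesions[[i]]
      idx <- which(lesion_of[[i]])
      intensity[idx] <- stats::rnorm(length(idx), les$mu, les$sigma)
    }
  })

  frontal <- wm
  coords2 <- slice.index(frontal, 2)
  frontal <- frontal & (coords2 > spec$frontal_plane)

  vv <- voxel_volume(spec$voxel_size)
  structure(list(
    intensity = intensity, brain_mask = brain, wm_mask = wm,
    frontal_mask = frontal, icv_mm3 = sum(brain) * vv,
    voxel_size = spec$voxel_size,
    truth = list(lesion_mask = lesion_mask,
                 lesion_voxels = sum(lesion_mask),
                 lesion_volume_mm3 = sum(lesion_mask) * vv,
                 dominant = spec$dominant, secondary = spec$secondary),
    spec = spec), class = "flair_phantom")
}

#' @export
print.flair_phantom <- function(x, ...) {
  cat("<flair_phantom> ", paste(dim(x$intensity), collapse = "x"),
      " voxels; WM ", sum(x$wm_mask),
      "; ICV ", format(x$icv_mm3, big.mark = ","), " mm^3; planted lesions ",
      x$truth$lesion_voxels, " voxels\n", sep = "")
  invisible(x)
}
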