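#' Sampling grid description
#'
#' @param dim integer length-3 voxel counts.
#' @param spacing voxel size per axis, mm.
#' @param origin physical position of the first voxel centre, mm; default
#'   centres the grid on the world origin.
#' @return list with `dim`, `spacing`, `origin`.
#' @export
grid3 <- function(dim, spacing, origin = NULL) {
  dim <- as.integer(dim)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  stopifnot(length(dim) == 3L, all(dim >= 1L), all(spacing > 0))
  if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
  list(dim = dim, spacing = spacing, origin = as.numeric(origin))
}

## --- geometric primitives ---------------------------------------------

#' Phantom shape primitives
#'
#' Shapes are painted in list order (later shapes overwrite earlier ones
#' where they overlap), each carrying an activity concentration (MBq/mL)
#' and a CT number (HU).
#'
#' `shape_cylinder` is a z-axis-aligned circular cylinder;
#' `shape_ellipsoid` an axis-aligned ellipsoid; `shape_shell` the region
#' between two concentric ellipsoids (a kidney-cortex-like rind);
#' `shape_spheres` a union of spheres (heterogeneous tumour blob).
#'
#' @param center length-3 centre in mm.
#' @param radius_mm,height_mm cylinder radius and full height (mm).
#' @param semiaxes_mm,outer_mm,inner_mm length-3 ellipsoid semi-axes (mm).
#' @param centers_mm n-by-3 matrix of sphere centres; `radii_mm` length-n.
#' @param activity_MBq_per_mL activity concentration (>= 0).
#' @param hu CT number in HU, between -1000 (air) and 3000.
#' @return A `phantom_shape` object.
#' @name phantom_shapes
NULL

new_shape <- function(type, activity_MBq_per_mL, hu, ...) {
  if (activity_MBq_per_mL < 0) {
    stop("activity concentration must be >= 0", call. = FALSE)
  }
  if (hu < -1000 || hu > 3000) {
    stop("HU must lie in [-1000, 3000]", call. = FALSE)
  }
  structure(list(type = type, activity_MBq_per_mL = activity_MBq_per_mL,
                 hu = hu, ...), class = "phantom_shape")
}

#' @rdname phantom_shapes
#' @export
shape_cylinder <- function(center = c(0, 0, 0), radius_mm, height_mm,
                           activity_MBq_per_mL = 0, hu = 0) {
  new_shape("cylinder", activity_MBq_per_mL, hu, center = center,
            radius_mm = radius_mm, height_mm = height_mm)
}

#' @rdname phantom_shapes
#' @export
shape_ellipsoid <- function(center = c(0, 0, 0), semiaxes_mm,
                            activity_MBq_per_mL = 0, hu = 0) {
  new_shape("ellipsoid", activity_MBq_per_mL, hu, center = center,
            semiaxes_mm = rep(semiaxes_mm, length.out = 3L))
}

#' @rdname phantom_shapes
#' @export
shape_shell <- function(center = c(0, 0, 0), outer_mm, inner_mm,
                        activity_MBq_per_mL = 0, hu = 0) {
  outer_mm <- rep(outer_mm, length.out = 3L)
  inner_mm <- rep(inner_mm, length.out = 3L)
  if (any(inner_mm >= outer_mm)) {
    stop("shell inner semi-axes must be smaller than outer", call. = FALSE)
  }
  new_shape("shell", activity_MBq_per_mL, hu, center = center,
            outer_mm = outer_mm, inner_mm = inner_mm)
}

#' @rdname phantom_shapes
#' @export
shape_spheres <- function(centers_mm, radii_mm, activity_MBq_per_mL = 0,
                          hu = 0) {
  centers_mm <- matrix(centers_mm, ncol = 3L)
  if (nrow(centers_mm) != length(radii_mm)) {
    stop("need one radius per sphere centre", call. = FALSE)
  }
  new_shape("spheres", activity_MBq_per_mL, hu, centers_mm = centers_mm,
            radii_mm = as.numeric(radii_mm))
}

shape_bbox <- function(s) {
  switch(s$type,
    cylinder = rbind(s$center - c(s$radius_mm, s$radius_mm, s$height_mm / 2),
                     s$center + c(s$radius_mm, s$radius_mm, s$height_mm / 2)),
    ellipsoid = rbind(s$center - s$semiaxes_mm, s$center + s$semiaxes_mm),
    shell = rbind(s$center - s$outer_mm, s$center + s$outer_mm),
    spheres = rbind(apply(s$centers_mm - s$radii_mm, 2, min),
                    apply(s$centers_mm + s$radii_mm, 2, max)))
}

## logical support of a shape sampled at voxel centres X, Y, Z (arrays)
shape_support <- function(s, X, Y, Z) {
  switch(s$type,
    cylinder = {
      ((X - s$center[1L])^2 + (Y - s$center[2L])^2 <= s$radius_mm^2) &
        (abs(Z - s$center[3L]) <= s$height_mm / 2)
    },
    ellipsoid = {
      ((X - s$center[1L]) / s$semiaxes_mm[1L])^2 +
        ((Y - s$center[2L]) / s$semiaxes_mm[2L])^2 +
        ((Z - s$center[3L]) / s$semiaxes_mm[3L])^2 <= 1
    },
    shell = {
      outer <- ((X - s$center[1L]) / s$outer_mm[1L])^2 +
        ((Y - s$center[2L]) / s$outer_mm[2L])^2 +
        ((Z - s$center[3L]) / s$outer_mm[3L])^2 <= 1
      inner <- ((X - s$center[1L]) / s$inner_mm[1L])^2 +
        ((Y - s$center[2L]) / s$inner_mm[2L])^2 +
        ((Z - s$center[3L]) / s$inner_mm[3L])^2 <= 1
      outer & !inner
    },
    spheres = {
      acc <- array(FALSE, dim = dim(X))
      for (i in seq_along(s$radii_mm)) {
        acc <- acc | ((X - s$centers_mm[i, 1L])^2 +
                        (Y - s$centers_mm[i, 2L])^2 +
                        (Z - s$centers_mm[i, 3L])^2 <= s$radii_mm[i]^2)
      }
      acc
    })
}

#' Ground-truth phantom description
#'
#' @param shapes list of [phantom_shapes] primitives, painted in order.
#' @param spect_grid,ct_grid [grid3()] descriptions of the SPECT (default
#'   0.6 mm voxels) and CT (default 0.4 mm voxels) sampling.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shapes, spect_grid, ct_grid = NULL) {
  stopifnot(is.list(shapes),
            all(vapply(shapes, inherits, TRUE, "phantom_shape")))
  if (is.null(ct_grid)) {
    extent <- spect_grid$dim * spect_grid$spacing
    ct_grid <- grid3(ceiling(extent / 0.4), 0.4)
  }
  structure(list(shapes = shapes, spect_grid = spect_grid,
                 ct_grid = ct_grid),
            class = "phantom_spec")
}

coord_arrays <- function(g) {
  x <- g$origin[1L] + (seq_len(g$dim[1L]) - 1) * g$spacing[1L]
  y <- g$origin[2L] + (seq_len(g$dim[2L]) - 1) * g$spacing[2L]
  z <- g$origin[3L] + (seq_len(g$dim[3L]) - 1) * g$spacing[3L]
  list(
    X = array(rep(x, times = g$dim[2L] * g$dim[3L]), dim = g$dim),
    Y = array(rep(rep(y, each = g$dim[1L]), times = g$dim[3L]), dim = g$dim),
    Z = array(rep(z, each = g$dim[1L] * g$dim[2L]), dim = g$dim))
}

grid_extent <- function(g) {
  rbind(g$origin - g$spacing / 2, g$origin + (g$dim - 0.5) * g$spacing)
}

#' Rasterize a phantom onto its SPECT and CT grids
#'
#' Paints the shapes in order (later shapes overwrite earlier ones where
#' they overlap) at voxel centres. The activity image lives on the SPECT
#' grid, the CT image on the CT grid (background -1000 HU). Per-shape
#' ground truth is reported: the exact voxelized support (on the SPECT
#' grid) and the total activity in MBq actually painted for that shape
#' (concentration times owned-voxel volume).
#'
#' @param spec a [phantom_spec()].
#' @return list with `activity` (MBq/mL, SPECT grid), `ct` (HU, CT grid),
#'   `truth_masks` (list of [voi_mask()], provenance `"phantom-truth"`),
#'   `true_activity_MBq` (per shape) and `total_activity_MBq`.
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  for (g in list(spec$spect_grid, spec$ct_grid)) {
    ext <- grid_extent(g)
    for (i in seq_along(spec$shapes)) {
      bb <- shape_bbox(spec$shapes[[i]])
      if (any(bb[1L, ] < ext[1L, ]) || any(bb[2L, ] > ext[2L, ])) {
        stop(sprintf("shape %d extends outside the grid", i), call. = FALSE)
      }
    }
  }
  sg <- spec$spect_grid
  cg <- spec$ct_grid

  co <- coord_arrays(sg)
  act <- array(0, dim = sg$dim)
  owner <- array(0L, dim = sg$dim)
  truth_masks <- vector("list", length(spec$shapes))
  for (i in seq_along(spec$shapes)) {
    s <- spec$shapes[[i]]
    sup <- shape_support(s, co$X, co$Y, co$Z)
    act[sup] <- s$activity_MBq_per_mL
    owner[sup] <- i
    truth_masks[[i]] <- voi_mask(sup, sg$spacing, sg$origin, "phantom-truth")
  }
  voxvol <- prod(sg$spacing) / 1000
  true_act <- vapply(seq_along(spec$shapes), function(i) {
    spec$shapes[[i]]$activity_MBq_per_mL * sum(owner == i) * voxvol
  }, numeric(1))

  cc <- coord_arrays(cg)
  hu <- array(-1000, dim = cg$dim)
  for (i in seq_along(spec$shapes)) {
    s <- spec$shapes[[i]]
    hu[shape_support(s, cc$X, cc$Y, cc$Z)] <- s$hu
  }

  list(activity = scalar_image(act, sg$spacing, sg$origin, "MBq_per_mL"),
       ct = scalar_image(hu, cg$spacing, cg$origin, "HU"),
       truth_masks = truth_masks,
       true_activity_MBq = true_act,
       total_activity_MBq = sum(act) * voxvol)
}

## --- study phantoms ----------------------------------------------------

auto_grids <- function(extent_mm, spect_spacing = 0.6, ct_spacing = 0.4) {
  list(spect = grid3(ceiling(extent_mm / spect_spacing), spect_spacing),
       ct = grid3(ceiling(extent_mm / ct_spacing), ct_spacing))
}

## Rescale all shape concentrations so the painted (voxelized) total
## activity equals the requested one exactly; keeps ground truth and
## nominal activity identical despite voxelization of the supports.
normalize_phantom_activity <- function(spec, target_MBq) {
  total <- rasterize_phantom(spec)$total_activity_MBq
  scale <- target_MBq / total
  spec$shapes <- lapply(spec$shapes, function(s) {
    s$activity_MBq_per_mL <- s$activity_MBq_per_mL * scale
    s
  })
  spec
}

#' Standard study phantoms
#'
#' Ready-made [phantom_spec()]s mirroring the acquisitions the pipeline
#' is exercised on:
#'
#' * `phantom_tube()`: a saline tube (default 500 uL, water-equivalent
#'   HU 0) in air, holding a given total activity.
#' * `phantom_uniform_cylinder()`: a uniform water cylinder of given
#'   diameter (rat-sized by default), used for calibration and for the
#'   dual-peak weighting check.
#' * `phantom_container()`: an activity blob centred in a water-filled
#'   container tube (ex vivo organ-in-tube geometry).
#' * `phantom_kidney()`: a kidney-like ellipsoid with a hot cortex shell
#'   (about 0.7 mL) and low-activity interior, embedded in a soft-tissue
#'   cylinder.
#' * `phantom_tumor()`: a heterogeneous union-of-spheres blob in a
#'   soft-tissue ellipsoid.
#'
#' @param activity_MBq total activity of the hot structure, MBq.
#' @param volume_uL tube fill volume in uL.
#' @param radius_mm tube inner radius.
#' @param diameter_mm,height_mm cylinder dimensions.
#' @param volume_mL cylinder or container fill volume in mL.
#' @param blob_radius_mm radius of the contained activity sphere.
#' @param margin_mm air margin added around the object.
#' @param spect_spacing,ct_spacing grid voxel sizes in mm.
#' @return A [phantom_spec()].
#' @name study_phantoms
NULL

#' @rdname study_phantoms
#' @export
phantom_tube <- function(activity_MBq, volume_uL = 500, radius_mm = 4.9,
                         margin_mm = 6, spect_spacing = 0.6,
                         ct_spacing = 0.4) {
  height <- volume_uL / (pi * radius_mm^2)
  conc <- activity_MBq / (volume_uL / 1000)
  g <- auto_grids(c(2 * radius_mm, 2 * radius_mm, height) + 2 * margin_mm,
                  spect_spacing, ct_spacing)
  spec <- phantom_spec(
    list(shape_cylinder(radius_mm = radius_mm, height_mm = height,
                        activity_MBq_per_mL = conc, hu = 0)),
    g$spect, g$ct)
  normalize_phantom_activity(spec, activity_MBq)
}

#' @rdname study_phantoms
#' @export
phantom_uniform_cylinder <- function(activity_MBq = NULL, volume_mL = NULL,
                                     diameter_mm = 40, height_mm = NULL,
                                     margin_mm = 6, spect_spacing = 0.6,
                                     ct_spacing = 0.4) {
  r <- diameter_mm / 2
  if (is.null(height_mm)) {
    stopifnot(!is.null(volume_mL))
    height_mm <- volume_mL * 1000 / (pi * r^2)
  }
  vol_mL <- pi * r^2 * height_mm / 1000
  conc <- if (is.null(activity_MBq)) 0 else activity_MBq / vol_mL
  g <- auto_grids(c(diameter_mm, diameter_mm, height_mm) + 2 * margin_mm,
                  spect_spacing, ct_spacing)
  phantom_spec(
    list(shape_cylinder(radius_mm = r, height_mm = height_mm,
                        activity_MBq_per_mL = conc, hu = 0)),
    g$spect, g$ct)
}

#' @rdname study_phantoms
#' @export
phantom_container <- function(activity_MBq, volume_mL = 2,
                              blob_radius_mm = 4, margin_mm = 6,
                              spect_spacing = 0.6, ct_spacing = 0.4) {
  r <- 6.3
  height <- volume_mL * 1000 / (pi * r^2)
  blob_mL <- 4 / 3 * pi * blob_radius_mm^3 / 1000
  g <- auto_grids(c(2 * r, 2 * r, height) + 2 * margin_mm,
                  spect_spacing, ct_spacing)
  spec <- phantom_spec(
    list(
      shape_cylinder(radius_mm = r, height_mm = height,
                     activity_MBq_per_mL = 0, hu = 0),
      shape_ellipsoid(semiaxes_mm = rep(blob_radius_mm, 3L),
                      activity_MBq_per_mL = activity_MBq / blob_mL,
                      hu = 40)),
    g$spect, g$ct)
  normalize_phantom_activity(spec, activity_MBq)
}

#' @rdname study_phantoms
#' @export
phantom_kidney <- function(activity_MBq, margin_mm = 6,
                           spect_spacing = 0.6, ct_spacing = 0.4) {
  outer <- c(9, 6, 5)
  inner <- 0.7 * outer
  cortex_mL <- 4 / 3 * pi * (prod(outer) - prod(inner)) / 1000
  body_r <- 16
  body_h <- 24
  g <- auto_grids(c(2 * body_r, 2 * body_r, body_h) + 2 * margin_mm,
                  spect_spacing, ct_spacing)
  conc <- activity_MBq / cortex_mL
  spec <- phantom_spec(
    list(
      shape_cylinder(radius_mm = body_r, height_mm = body_h,
                     activity_MBq_per_mL = 0, hu = 20),
      shape_shell(center = c(4, 0, 0), outer_mm = outer, inner_mm = inner,
                  activity_MBq_per_mL = conc, hu = 40),
      shape_ellipsoid(center = c(4, 0, 0), semiaxes_mm = inner,
                      activity_MBq_per_mL = 0.1 * conc, hu = 35)),
    g$spect, g$ct)
  normalize_phantom_activity(spec, activity_MBq)
}

#' @rdname study_phantoms
#' @export
phantom_tumor <- function(activity_MBq, margin_mm = 6,
                          spect_spacing = 0.6, ct_spacing = 0.4) {
  body <- c(14, 12, 9)
  g <- auto_grids(2 * body + 2 * margin_mm, spect_spacing, ct_spacing)
  centers <- rbind(c(0, 0, 0), c(4.5, 2, 0), c(-3, 3.5, 1.5))
  radii <- c(5, 3.5, 3)
  ## heterogeneous: overlapping spheres at 1x / 1.8x / 0.6x of a base
  ## concentration; normalise so the painted total equals activity_MBq
  base <- 1
  spheres <- list(
    shape_spheres(centers[1L, , drop = FALSE], radii[1L],
                  activity_MBq_per_mL = base, hu = 45),
    shape_spheres(centers[2L, , drop = FALSE], radii[2L],
                  activity_MBq_per_mL = 1.8 * base, hu = 45),
    shape_spheres(centers[3L, , drop = FALSE], radii[3L],
                  activity_MBq_per_mL = 0.6 * base, hu = 45))
  spec0 <- phantom_spec(
    c(list(shape_ellipsoid(semiaxes_mm = body, activity_MBq_per_mL = 0,
                           hu = 30)), spheres),
    g$spect, g$ct)
  normalize_phantom_activity(spec0, activity_MBq)
}

#' @rdname study_phantoms
#' @export
phantom_calibration <- function(volume_mL = 5,
                                c_vol_kBq_per_mL = 0.72,
                                spect_spacing = 0.6, ct_spacing = 0.4) {
  r <- 8.4
  height <- volume_mL * 1000 / (pi * r^2)
  g <- auto_grids(c(2 * r, 2 * r, height) + 12, spect_spacing, ct_spacing)
  phantom_spec(
    list(shape_cylinder(radius_mm = r, height_mm = height,
                        activity_MBq_per_mL = c_vol_kBq_per_mL / 1000,
                        hu = 0)),
    g$spect, g$ct)
}
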