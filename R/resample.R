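#' Resample an image onto the grid of a reference image
#'
#' Samples `source` at the voxel centres of `reference`, with trilinear or
#' nearest-neighbour interpolation. Points outside the physical extent of
#' `source` receive `fill` (default: -1000 for HU images, i.e. air, and 0
#' for everything else). This implements the CT-to-SPECT grid matching
#' used throughout the pipeline; registration is assumed given (identity
#' world transform).
#'
#' @param source a [scalar_image()] to resample.
#' @param reference a [scalar_image()] or [voi_mask()] defining the target
#'   grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill value used outside the source extent.
#' @return A [scalar_image()] on the reference grid, unit of `source`.
#' @export
resample_to_grid <- function(source, reference,
                             interpolation = c("linear", "nearest"),
                             fill = NULL) {
  interpolation <- match.arg(interpolation)
  if (is.null(fill)) fill <- if (source$unit == "HU") -1000 else 0
  sd <- dim(source$values)
  rd <- dim(reference$values)

  ## physical extent overlap check (voxel-centre bounding boxes, padded by
  ## half a voxel so touching extents count as overlapping)
  s_lo <- source$origin - source$spacing / 2
  s_hi <- source$origin + (sd - 1 + 0.5) * source$spacing
  r_lo <- reference$origin - reference$spacing / 2
  r_hi <- reference$origin + (rd - 1 + 0.5) * reference$spacing
  if (any(s_hi < r_lo) || any(s_lo > r_hi)) {
    stop("source and reference physical extents are disjoint", call. = FALSE)
  }

  ## fractional source indices of reference voxel centres, per axis
  fr <- lapply(1:3, function(a) {
    x <- reference$origin[a] + (seq_len(rd[a]) - 1) * reference$spacing[a]
    (x - source$origin[a]) / source$spacing[a] + 1
  })

  if (interpolation == "nearest") {
    idx <- lapply(1:3, function(a) {
      i <- round(fr[[a]])
      i[i < 1 | i > sd[a] | abs(fr[[a]] - i) > 0.5 + 1e-9] <- NA_integer_
      as.integer(i)
    })
    I <- rep(idx[[1L]], times = rd[2L] * rd[3L])
    J <- rep(rep(idx[[2L]], each = rd[1L]), times = rd[3L])
    K <- rep(idx[[3L]], each = rd[1L] * rd[2L])
    lin <- I + (J - 1L) * sd[1L] + (K - 1L) * sd[1L] * sd[2L]
    out <- rep(fill, prod(rd))
    ok <- !is.na(lin)
    out[ok] <- source$values[lin[ok]]
    return(with_values_grid(out, rd, reference, source$unit))
  }

  ## trilinear: clamp outside-but-within-half-voxel to the edge sample,
  ## beyond that -> fill
  lo <- lapply(1:3, function(a) {
    f <- fr[[a]]
    outside <- f < 0.5 - 1e-9 | f > sd[a] + 0.5 + 1e-9
    f <- pmin(pmax(f, 1), sd[a])
    i0 <- pmin(floor(f), sd[a] - 1L)
    if (sd[a] == 1L) i0 <- rep(1L, length(f))
    list(i0 = as.integer(i0), w = f - i0, outside = outside)
  })
  n <- prod(rd)
  I0 <- rep(lo[[1L]]$i0, times = rd[2L] * rd[3L])
  J0 <- rep(rep(lo[[2L]]$i0, each = rd[1L]), times = rd[3L])
  K0 <- rep(lo[[3L]]$i0, each = rd[1L] * rd[2L])
  WX <- rep(lo[[1L]]$w, times = rd[2L] * rd[3L])
  WY <- rep(rep(lo[[2L]]$w, each = rd[1L]), times = rd[3L])
  WZ <- rep(lo[[3L]]$w, each = rd[1L] * rd[2L])
  OUT <- rep(lo[[1L]]$outside, times = rd[2L] * rd[3L]) |
    rep(rep(lo[[2L]]$outside, each = rd[1L]), times = rd[3L]) |
    rep(lo[[3L]]$outside, each = rd[1L] * rd[2L])

  sxy <- sd[1L] * sd[2L]
  acc <- numeric(n)
  for (dz in 0:1) {
    kz <- pmin(K0 + dz, dim(source$values)[3L])
    wz <- if (dz == 0) 1 - WZ else WZ
    for (dy in 0:1) {
      jy <- pmin(J0 + dy, sd[2L])
      wy <- if (dy == 0) 1 - WY else WY
      for (dx in 0:1) {
        ix <- pmin(I0 + dx, sd[1L])
        wx <- if (dx == 0) 1 - WX else WX
        lin <- ix + (jy - 1L) * sd[1L] + (kz - 1L) * sxy
        acc <- acc + wx * wy * wz * source$values[lin]
      }
    }
  }
  acc[OUT] <- fill
  with_values_grid(acc, rd, reference, source$unit)
}

with_values_grid <- function(vals, rd, reference, unit) {
  scalar_image(array(vals, dim = rd), reference$spacing, reference$origin,
               unit)
}

#' Resample a binary mask onto a reference grid
#'
#' Nearest-neighbour resampling of a [voi_mask()]; the result is binary by
#' construction. Used to move CT-derived masks onto the SPECT grid.
#'
#' @param mask a [voi_mask()].
#' @param reference target grid ([scalar_image()] or [voi_mask()]).
#' @return A [voi_mask()] on the reference grid, same provenance.
#' @export
resample_mask <- function(mask, reference) {
  img <- scalar_image(array(as.numeric(mask$values), dim = dim(mask$values)),
                      mask$spacing, mask$origin, "dimensionless")
  res <- resample_to_grid(img, reference, interpolation = "nearest", fill = 0)
  voi_mask(res$values != 0, reference$spacing, reference$origin,
           mask$provenance)
}
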