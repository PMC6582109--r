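## 3-D binary morphology on logical arrays. Structuring element is the
## 6-connected cross (face neighbours); connected components use
## 26-connectivity. Both conventions are fixed so voxel-exact tests are
## reproducible.

shift_array <- function(arr, axis, by, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    idx_dst[[axis]] <- (by + 1L):n
    idx_src[[axis]] <- 1L:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1L:(n + by)
    idx_src[[axis]] <- (1L - by):n
  }
  out[idx_dst[[1L]], idx_dst[[2L]], idx_dst[[3L]]] <-
    arr[idx_src[[1L]], idx_src[[2L]], idx_src[[3L]]]
  out
}

erode_once <- function(m) {
  out <- m
  for (a in 1:3) {
    out <- out & shift_array(m, a, 1L) & shift_array(m, a, -1L)
  }
  out
}

dilate_once <- function(m) {
  out <- m
  for (a in 1:3) {
    out <- out | shift_array(m, a, 1L) | shift_array(m, a, -1L)
  }
  out
}

#' Binary erosion / dilation with a 6-connected structuring element
#'
#' Applies the face-neighbour (3-D cross) structuring element
#' `iterations` times. Grid boundaries act as background for erosion and
#' absorb dilation.
#'
#' @param mask a [voi_mask()] or logical 3-D array.
#' @param iterations non-negative integer number of passes.
#' @return Same type as the input.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  morph_apply(mask, iterations, erode_once)
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  morph_apply(mask, iterations, dilate_once)
}

morph_apply <- function(mask, iterations, fun) {
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("`iterations` must be >= 0", call. = FALSE)
  is_voi <- inherits(mask, "voi_mask")
  m <- if (is_voi) mask$values else mask
  for (i in seq_len(iterations)) m <- fun(m)
  if (is_voi) voi_mask(m, mask$spacing, mask$origin, mask$provenance) else m
}

#' Label connected components (26-connectivity)
#'
#' @param mask logical 3-D array or [voi_mask()].
#' @return Integer array of the same shape; 0 is background, components
#'   are numbered from 1 in decreasing size order.
#' @export
label_components <- function(mask) {
  m <- if (inherits(mask, "voi_mask")) mask$values else mask
  lab <- label_components_cpp(as.logical(m), dim(m))
  dim(lab) <- dim(m)
  ## renumber by decreasing size so component 1 is always the largest
  if (max(lab) > 1L) {
    sizes <- tabulate(lab)
    ord <- order(sizes, decreasing = TRUE)
    remap <- integer(length(sizes))
    remap[ord] <- seq_along(ord)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Keep only the largest connected component of a mask
#'
#' @param mask logical 3-D array or [voi_mask()].
#' @return Same type as the input.
#' @export
largest_component <- function(mask) {
  is_voi <- inherits(mask, "voi_mask")
  m <- if (is_voi) mask$values else mask
  if (!any(m)) return(mask)
  keep <- label_components(m) == 1L
  if (is_voi) voi_mask(keep, mask$spacing, mask$origin, mask$provenance)
  else keep
}
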