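#' Read and write phantom and simulation configurations as YAML
#'
#' [phantom_spec()] and [simulation_config()] objects round-trip through
#' plain YAML files, so study conditions can be version-controlled and
#' re-run.
#'
#' @param spec a [phantom_spec()].
#' @param config a [simulation_config()].
#' @param path file path.
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name config_yaml
NULL

#' @rdname config_yaml
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  shapes <- lapply(spec$shapes, function(s) {
    out <- unclass(s)
    if (!is.null(out$centers_mm)) {
      out$centers_mm <- apply(out$centers_mm, 1L, as.numeric,
                              simplify = FALSE)
    }
    out
  })
  yaml::write_yaml(list(shapes = shapes,
                        spect_grid = spec$spect_grid,
                        ct_grid = spec$ct_grid), path)
  invisible(path)
}

#' @rdname config_yaml
#' @export
read_phantom_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  shapes <- lapply(raw$shapes, function(s) {
    args <- s[setdiff(names(s), "type")]
    switch(s$type,
      cylinder = shape_cylinder(unlist(args$center), args$radius_mm,
                                args$height_mm, args$activity_MBq_per_mL,
                                args$hu),
      ellipsoid = shape_ellipsoid(unlist(args$center),
                                  unlist(args$semiaxes_mm),
                                  args$activity_MBq_per_mL, args$hu),
      shell = shape_shell(unlist(args$center), unlist(args$outer_mm),
                          unlist(args$inner_mm),
                          args$activity_MBq_per_mL, args$hu),
      spheres = shape_spheres(do.call(rbind, lapply(args$centers_mm,
                                                    unlist)),
                              unlist(args$radii_mm),
                              args$activity_MBq_per_mL, args$hu),
      stop("unknown shape type: ", s$type, call. = FALSE))
  })
  g <- function(x) grid3(unlist(x$dim), unlist(x$spacing), unlist(x$origin))
  phantom_spec(shapes, g(raw$spect_grid), g(raw$ct_grid))
}

#' @rdname config_yaml
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  out <- unclass(config)
  out$photopeaks <- list(energy_keV = config$photopeaks$energy_keV,
                         branching = config$photopeaks$branching)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname config_yaml
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$photopeaks <- data.frame(
    energy_keV = unlist(raw$photopeaks$energy_keV),
    branching = unlist(raw$photopeaks$branching))
  do.call(simulation_config, raw)
}
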