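#' Define the phantom and detector geometry
#'
#' Coordinate frame: `x` along the beam axis with the phantom entrance at
#' `x = 0`, `y` toward the detector, `z` vertical; all lengths in cm. The
#' water phantom occupies `x in [0, phantom_extent[1]]` and is centred on the
#' beam axis laterally (`|y|, |z| <= extent/2`). The converter is a thin slab
#' parallel to the beam axis (normal along -y, facing the phantom); all
#' conversions are placed on its midplane (thin-converter approximation). The
#' two ideal tracking planes sit `tracker1_offset` and `tracker2_offset`
#' behind the converter midplane and share its lateral coverage.
#'
#' @param phantom_extent Phantom size `(x, y, z)`, cm.
#' @param converter_center Converter midplane centre `(x, y, z)`, cm. The
#'   default (via [default_geometry()]) centres it at the Bragg-peak depth,
#'   10 cm lateral to the beam axis.
#' @param converter_thickness Converter thickness, cm.
#' @param converter_area Converter (and tracker) coverage `(x, z)`, cm.
#' @param tracker1_offset,tracker2_offset Distances of the tracking planes
#'   behind the converter midplane, cm; must satisfy
#'   `tracker2 > tracker1 > thickness/2`.
#' @return An object of class `geometry_spec`.
#' @export
#' @examples
#' geometry_spec(converter_center = c(25.6, 10, 0))
geometry_spec <- function(phantom_extent = c(35, 10, 10),
                          converter_center = c(17.5, 10, 0),
                          converter_thickness = 0.5,
                          converter_area = c(20, 20),
                          tracker1_offset = 1.25,
                          tracker2_offset = 6.25) {
  stopifnot(length(phantom_extent) == 3, all(phantom_extent > 0),
            length(converter_center) == 3,
            converter_thickness > 0, length(converter_area) == 2,
            all(converter_area > 0))
  if (!(tracker2_offset > tracker1_offset &&
        tracker1_offset > converter_thickness / 2))
    stop("need tracker2_offset > tracker1_offset > converter_thickness/2")
  g <- structure(list(
    phantom_extent = as.numeric(phantom_extent),
    converter_center = as.numeric(converter_center),
    converter_thickness = converter_thickness,
    converter_area = as.numeric(converter_area),
    tracker1_offset = tracker1_offset,
    tracker2_offset = tracker2_offset
  ), class = "geometry_spec")
  g$midplane_y <- g$converter_center[2]
  g$tracker_y <- g$midplane_y + c(tracker1_offset, tracker2_offset)
  g$area_x <- g$converter_center[1] + c(-1, 1) * g$converter_area[1] / 2
  g$area_z <- g$converter_center[3] + c(-1, 1) * g$converter_area[2] / 2
  g
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat(sprintf("<geometry_spec> phantom %.0fx%.0fx%.0f cm\n",
              x$phantom_extent[1], x$phantom_extent[2], x$phantom_extent[3]))
  cat(sprintf("  converter midplane y = %g cm, centre x = %g cm, area %gx%g cm\n",
              x$midplane_y, x$converter_center[1],
              x$converter_area[1], x$converter_area[2]))
  cat(sprintf("  tracker planes at y = %g, %g cm\n",
              x$tracker_y[1], x$tracker_y[2]))
  invisible(x)
}

#' Default detector geometry for a beam
#'
#' Centres the converter at the Bragg-peak depth of the beam, with its
#' midplane 10 cm lateral to the beam axis, as in the reference setup.
#'
#' @param beam A [beam_spec()].
#' @param lateral_distance Beam axis to converter midplane, cm.
#' @param ... Passed to [geometry_spec()].
#' @return A `geometry_spec`.
#' @export
#' @examples
#' default_geometry(beam_config("200MeV"))
default_geometry <- function(beam, lateral_distance = 10, ...) {
  stopifnot(inherits(beam, "beam_spec"))
  geometry_spec(converter_center = c(beam$peak_depth, lateral_distance, 0),
                ...)
}
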