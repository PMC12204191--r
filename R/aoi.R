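#' Screen geometry for pixel-to-degree conversion
#'
#' Describes the display and viewing distance so that gaze displacements in
#' pixels can be converted to degrees of visual angle with a pinhole model.
#'
#' @param screen_w,screen_h Screen resolution in pixels.
#' @param physical_w,physical_h Physical screen size in cm.
#' @param distance Viewing distance in cm (eye to screen).
#' @return An object of class `screen_geometry` with per-axis
#'   degrees-per-pixel conversion factors.
#' @examples
#' g <- screen_geometry()
#' g$deg_per_px_x
#' @export
screen_geometry <- function(screen_w = 1920, screen_h = 1080,
                            physical_w = 34.5, physical_h = 19.4,
                            distance = 64) {
  if (any(c(screen_w, screen_h, physical_w, physical_h, distance) <= 0)) {
    stopf("screen_geometry: all dimensions and the distance must be positive")
  }
  deg_per_px_x <- atan((physical_w / screen_w) / distance) * 180 / pi
  deg_per_px_y <- atan((physical_h / screen_h) / distance) * 180 / pi
  structure(
    list(screen_w = screen_w, screen_h = screen_h,
         physical_w = physical_w, physical_h = physical_h,
         distance = distance,
         deg_per_px_x = deg_per_px_x, deg_per_px_y = deg_per_px_y),
    class = "screen_geometry"
  )
}

# Euclidean amplitude in degrees between two pixel positions.
px_dist_deg <- function(x0, y0, x1, y1, geometry) {
  sqrt(((x1 - x0) * geometry$deg_per_px_x)^2 +
         ((y1 - y0) * geometry$deg_per_px_y)^2)
}

#' Area-of-interest layout
#'
#' Named, axis-aligned, pairwise-disjoint rectangles on the screen. Boxes are
#' half-open: a point (x, y) is inside `[x0, x1) x [y0, y1)`. Retrieval trials
#' use boxes named `cue` (top row), `target` and `lure` (bottom row);
#' exposure trials use `left` and `right`.
#'
#' @param boxes Named list; each element a numeric vector
#'   `c(x0, y0, x1, y1)` in pixels, origin top-left, y down.
#' @param screen_w,screen_h Screen size in pixels.
#' @return An `aoi_layout` object.
#' @examples
#' aoi_layout(list(cue = c(700, 80, 1220, 460),
#'                 target = c(160, 620, 680, 1000),
#'                 lure = c(1240, 620, 1760, 1000)))
#' @export
aoi_layout <- function(boxes, screen_w = 1920, screen_h = 1080) {
  if (is.null(names(boxes)) || any(!nzchar(names(boxes)))) {
    stopf("aoi_layout: boxes must be a named list")
  }
  for (nm in names(boxes)) {
    b <- boxes[[nm]]
    if (length(b) != 4 || any(!is.finite(b))) {
      stopf("aoi_layout: box '%s' must be c(x0, y0, x1, y1)", nm)
    }
    if (b[1] >= b[3] || b[2] >= b[4]) {
      stopf("aoi_layout: box '%s' has non-positive extent", nm)
    }
    if (b[1] < 0 || b[2] < 0 || b[3] > screen_w || b[4] > screen_h) {
      stopf("aoi_layout: box '%s' extends beyond the screen", nm)
    }
  }
  nms <- names(boxes)
  for (i in seq_along(boxes)) {
    for (j in seq_len(i - 1L)) {
      a <- boxes[[i]]; b <- boxes[[j]]
      if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]) {
        stopf("aoi_layout: boxes '%s' and '%s' overlap", nms[i], nms[j])
      }
    }
  }
  structure(list(screen_w = screen_w, screen_h = screen_h, boxes = boxes),
            class = "aoi_layout")
}

#' Default retrieval-trial layout
#'
#' Cue box centred on the top row, associate boxes on the bottom row. The
#' `target_side` argument controls whether the target box is on the left or
#' the right; the lure occupies the other bottom box.
#'
#' @param target_side `"left"` or `"right"`.
#' @param screen_w,screen_h Screen size in pixels.
#' @return An `aoi_layout` with boxes `cue`, `target`, `lure`.
#' @export
default_retrieval_layout <- function(target_side = "left",
                                     screen_w = 1920, screen_h = 1080) {
  target_side <- match.arg(target_side, c("left", "right"))
  sx <- screen_w / 1920
  sy <- screen_h / 1080
  top <- c(700, 80, 1220, 460) * c(sx, sy, sx, sy)
  left <- c(160, 620, 680, 1000) * c(sx, sy, sx, sy)
  right <- c(1240, 620, 1760, 1000) * c(sx, sy, sx, sy)
  boxes <- if (target_side == "left") {
    list(cue = top, target = left, lure = right)
  } else {
    list(cue = top, target = right, lure = left)
  }
  aoi_layout(boxes, screen_w, screen_h)
}

# Exposure-phase layout: two objects side by side.
default_exposure_layout <- function(screen_w = 1920, screen_h = 1080) {
  sx <- screen_w / 1920
  sy <- screen_h / 1080
  aoi_layout(list(left = c(260, 350, 780, 730) * c(sx, sy, sx, sy),
                  right = c(1140, 350, 1660, 730) * c(sx, sy, sx, sy)),
             screen_w, screen_h)
}

#' Assign a gaze point to an area of interest
#'
#' Containment uses the half-open convention `[x0, x1) x [y0, y1)`, so a point
#' exactly on a box's right or bottom edge is outside it. Disjointness of the
#' layout guarantees a unique label.
#'
#' @param x,y Gaze coordinates in pixels (vectorised).
#' @param layout An [aoi_layout()].
#' @return Character vector of box names, `"off"` where no box contains the
#'   point (including non-finite coordinates).
#' @examples
#' lay <- default_retrieval_layout()
#' assign_aoi(420, 800, lay)  # centre of the left (target) box
#' @export
assign_aoi <- function(x, y, layout) {
  out <- rep("off", length(x))
  ok <- is.finite(x) & is.finite(y)
  for (nm in names(layout$boxes)) {
    b <- layout$boxes[[nm]]
    hit <- ok & x >= b[1] & x < b[3] & y >= b[2] & y < b[4]
    out[hit] <- nm
  }
  out
}

# Serialize / restore a layout through the JSON rectangle map used in the
# trials file.
aoi_to_json <- function(layout) {
  jsonlite::toJSON(list(screen_w = layout$screen_w, screen_h = layout$screen_h,
                        boxes = lapply(layout$boxes, as.numeric)),
                   auto_unbox = TRUE, digits = NA)
}

aoi_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  aoi_layout(lapply(obj$boxes, as.numeric),
             screen_w = obj$screen_w, screen_h = obj$screen_h)
}
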