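#' Default synthetic report page layout
#'
#' The page emulates a single-maneuver spirometry report: a demographic text
#' block in the top half and the two curve plots side by side in the bottom
#' half, volume-time on the left and flow-volume to its right. Dimensions are
#' pixels at the nominal `dpi`; plot boxes are `c(top, left, bottom, right)`
#' half-open 0-based intervals and must lie entirely in the bottom half.
#'
#' @param page_height,page_width Page size in pixels (portrait default
#'   1400 x 1000 at 150 dpi).
#' @param dpi Nominal resolution.
#' @param vt_box,fv_box Plot boxes for the volume-time and flow-volume curves.
#' @param stroke_radius Curve stroke radius in pixels (stroke width is
#'   `2 * stroke_radius + 1`).
#' @param pre_color,post_color RGB triplets in `[0, 1]` for the
#'   pre-bronchodilator (blue) and post-bronchodilator (red-family) curves.
#' @param axis_gray Gray level of the plot axes, light enough to binarize to
#'   background.
#' @return A `report_layout` list.
#' @export
default_layout <- function(page_height = 1400L, page_width = 1000L, dpi = 150L,
                           vt_box = c(780L, 60L, 1320L, 460L),
                           fv_box = c(780L, 540L, 1320L, 940L),
                           stroke_radius = 2L,
                           pre_color = c(0, 0, 0.8),
                           post_color = c(1, 0, 0),
                           axis_gray = 0.85) {
  lay <- structure(list(page_height = page_height, page_width = page_width,
                        dpi = dpi, vt_box = vt_box, fv_box = fv_box,
                        stroke_radius = stroke_radius, pre_color = pre_color,
                        post_color = post_color, axis_gray = axis_gray),
                   class = "report_layout")
  for (b in list(vt_box, fv_box)) {
    if (b[1] < page_height / 2 || b[3] > page_height ||
        b[2] < 0 || b[4] > page_width)
      stop("layout error: plot boxes must lie in the bottom half of the page",
           call. = FALSE)
  }
  lay
}

# Map data coordinates into a plot box. Returns 0-based pixel coords.
# y axis points up in data space, down in pixel space.
data_to_box <- function(x, y, xlim, ylim, box, margin = 12) {
  top <- box[1] + margin; left <- box[2] + margin
  bottom <- box[3] - margin; right <- box[4] - margin
  px <- left + (x - xlim[1]) / diff(xlim) * (right - left - 1)
  py <- bottom - 1 - (y - ylim[1]) / diff(ylim) * (bottom - top - 1)
  list(x = px, y = py)
}

#' Render a manoeuvre as a synthetic spirometry report page
#'
#' Draws the volume-time curve (volume vs. time) and the flow-volume curve
#' (flow vs. volume) of the pre-bronchodilator manoeuvre in blue inside the
#' layout's plot boxes; optionally overlays a perturbed post-bronchodilator
#' copy in the layout's red-family color. The demographic fields are carried
#' as a plain-text "text layer" (the `text` field, also written as a sidecar
#' file by [generate_dataset()]) in the labelled-line format parsed by
#' [parse_demographics()]; a decorative text block is stamped into the top
#' half of the page. The manoeuvre's artifact interval, if any, is mapped to a
#' pixel bounding box on the flow-volume plot.
#'
#' @param m A [simulate_maneuver()] / [inject_artifact()] result.
#' @param demographics A list/object with fields `sex` (`"man"`/`"woman"`),
#'   `age` (years), `bmi` (kg/m2).
#' @param include_post_bd Overlay a perturbed red post-bronchodilator copy?
#' @param layout A [default_layout()] object.
#' @return An object of class `synthetic_report`: fields `page` (a
#'   `report_page`), `text` (the demographic text layer), `demographics`,
#'   `label`, `artifact`, `artifact_annotation` (pixel box or `NULL`).
#' @export
render_report <- function(m, demographics, include_post_bd = FALSE,
                          layout = default_layout()) {
  stopifnot(inherits(m, "maneuver"), inherits(layout, "report_layout"))
  h <- layout$page_height; w <- layout$page_width

  # strokes are collected as (index, color) pairs and stamped onto the page
  # in a single pass at the end (later strokes overwrite earlier ones)
  strokes <- list()
  add <- function(xs, ys, color, radius) {
    strokes[[length(strokes) + 1L]] <<-
      list(lin = stroke_indices(h, w, xs, ys, radius), color = color)
  }

  # decorative header block (top half); demographic content lives in the
  # text layer, not in pixels
  for (i in 0:5) {
    y <- 80 + i * 40
    add(c(80, 80 + 250 + (i * 37) %% 300), c(y, y), rep(0.45, 3), 1L)
  }

  for (box in list(layout$vt_box, layout$fv_box)) {
    add(c(box[2], box[2]), c(box[1], box[3] - 1), rep(layout$axis_gray, 3), 0L)
    add(c(box[2], box[4] - 1), c(box[3] - 1, box[3] - 1),
        rep(layout$axis_gray, 3), 0L)
  }

  # axis limits with headroom; shared by pre and post curves
  tmax <- max(m$time) * 1.05 + 1e-9
  vmax <- max(m$volume) * 1.15 + 1e-9
  fmax <- max(m$flow) * 1.15 + 1e-9
  fmin <- min(0, min(m$flow) * 1.15)

  add_curves <- function(mm, col) {
    vt <- data_to_box(mm$time, mm$volume, c(0, tmax), c(0, vmax),
                      layout$vt_box)
    add(vt$x, vt$y, col, layout$stroke_radius)
    fv <- data_to_box(mm$volume, mm$flow, c(0, vmax), c(fmin, fmax),
                      layout$fv_box)
    add(fv$x, fv$y, col, layout$stroke_radius)
  }

  # the post-bronchodilator copy is drawn first so the pre-BD reference curve
  # stays on top where the two overlap; the color mask must still remove every
  # red pixel or extraction would see a third (or merged) region
  if (include_post_bd) {
    post <- m
    post$flow <- m$flow * 1.07
    post$volume <- m$volume * 0.96
    add_curves(post, layout$post_color)
  }
  add_curves(m, layout$pre_color)

  page <- array(1, dim = c(h, w, 3L))
  n <- h * w
  for (s in strokes) {
    page[s$lin] <- s$color[1]
    page[s$lin + n] <- s$color[2]
    page[s$lin + 2 * n] <- s$color[3]
  }

  ann_px <- NULL
  if (!is.null(m$artifact_annotation)) {
    a <- m$artifact_annotation
    win <- m$time >= a$t_start & m$time <= a$t_end
    if (any(win)) {
      fv <- data_to_box(m$volume[win], m$flow[win], c(0, vmax), c(fmin, fmax),
                        layout$fv_box)
      r <- layout$stroke_radius
      ann_px <- c(top = floor(min(fv$y)) - r, left = floor(min(fv$x)) - r,
                  bottom = ceiling(max(fv$y)) + r + 1,
                  right = ceiling(max(fv$x)) + r + 1)
    }
  }

  demo <- as_demographics(demographics)
  text <- paste0("Sex: ", if (demo$sex == "woman") "Woman" else "Man",
                 "\nAge: ", format(demo$age),
                 "\nBMI: ", format(demo$bmi))
  pg <- structure(list(pixels = page, dpi = layout$dpi, source_path = NA_character_,
                       text = text),
                  class = "report_page")
  structure(list(page = pg, text = text, demographics = demo,
                 label = m$label, artifact = m$artifact,
                 artifact_annotation = ann_px, layout = layout),
            class = "synthetic_report")
}

#' @export
print.synthetic_report <- function(x, ...) {
  cat("<synthetic_report> ", dim(x$page$pixels)[1], "x", dim(x$page$pixels)[2],
      " page; label = ", x$label, "; artifact = ", x$artifact, "\n", sep = "")
  invisible(x)
}
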