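#' Normalization bounds for the demographic frame
#'
#' MIN-MAX normalization bounds used when encoding demographics as grayscale
#' frame sections: age is mapped from `[10, 84]` years and BMI from
#' `[15, 54]` kg/m2 onto `[0, 1]`; sex is encoded man = 0, woman = 1.
#' Out-of-range values are clamped (with a warning) rather than rejected.
#'
#' @param age_min,age_max Age bounds in years.
#' @param bmi_min,bmi_max BMI bounds in kg/m2.
#' @return A `normalization_spec` object.
#' @export
normalization_spec <- function(age_min = 10, age_max = 84,
                               bmi_min = 15, bmi_max = 54) {
  if (age_min >= age_max || bmi_min >= bmi_max)
    stop("normalization bounds must satisfy min < max", call. = FALSE)
  structure(list(age_min = age_min, age_max = age_max,
                 bmi_min = bmi_min, bmi_max = bmi_max),
            class = "normalization_spec")
}

#' Tunable parameters of the construct pipeline
#'
#' @param area_min Connected components with foreground area strictly below
#'   this many pixels are discarded as noise (default 1000).
#' @param closing_size Side of the square structuring element used by the
#'   morphological closing that repairs strokes broken by the color mask.
#' @param red_hue_tol Half-width, in degrees, of the hue window around pure
#'   red that the post-bronchodilator mask treats as red-family.
#' @param red_sat_min,red_val_min Minimum HSV saturation/value for a pixel to
#'   count as red-family (keeps gray/near-black pixels out of the mask).
#' @param vt_position Which of the two retained regions is the volume-time
#'   curve: `"left"` (default layout) or `"right"`.
#' @return A `construct_config` object.
#' @export
construct_config <- function(area_min = 1000L, closing_size = 5L,
                             red_hue_tol = 20, red_sat_min = 0.25,
                             red_val_min = 0.2,
                             vt_position = c("left", "right")) {
  vt_position <- match.arg(vt_position)
  structure(list(area_min = area_min, closing_size = closing_size,
                 red_hue_tol = red_hue_tol, red_sat_min = red_sat_min,
                 red_val_min = red_val_min, vt_position = vt_position),
            class = "construct_config")
}

#' Remove the post-bronchodilator curve with a color mask
#'
#' Every pixel whose hue lies within `red_hue_tol` degrees of pure red and
#' whose saturation and value exceed the configured minima — covering red,
#' maroon and pink tones — is set to white; all other pixels are untouched.
#' Pages without red-family pixels pass through unchanged.
#'
#' @param page A `report_page`.
#' @param config A [construct_config()].
#' @return The masked `report_page`.
#' @export
mask_post_bd_colors <- function(page, config = construct_config()) {
  stopifnot(inherits(page, "report_page"))
  px <- page$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  n <- h * w
  r <- px[seq_len(n)]; g <- px[n + seq_len(n)]; b <- px[2 * n + seq_len(n)]
  # only chromatic pixels can be red-family; skip the gray/white majority
  cand <- which(abs(r - g) > 1e-3 | abs(g - b) > 1e-3)
  if (length(cand)) {
    hsv <- grDevices::rgb2hsv(rbind(r[cand], g[cand], b[cand]),
                              maxColorValue = 1)
    hue_deg <- hsv[1, ] * 360
    red <- (hue_deg <= config$red_hue_tol |
              hue_deg >= 360 - config$red_hue_tol) &
      hsv[2, ] >= config$red_sat_min & hsv[3, ] >= config$red_val_min
    idx <- cand[red]
    px[idx] <- 1; px[idx + n] <- 1; px[idx + 2 * n] <- 1
  }
  page$pixels <- px
  page
}

#' Extract the two curve regions from the bottom half of a page
#'
#' Implements the curve-extraction stage: grayscale conversion, retention of
#' the bottom half of the page, Otsu binarization with inversion (curves white
#' on black), removal of connected components with area strictly below
#' `area_min` pixels, morphological closing, 8-connected labelling, and
#' selection of the two largest components, which are the volume-time and
#' flow-volume curves. The pair is assigned `(vt, fv)` by the horizontal
#' order of their bounding boxes according to `config$vt_position`. An area
#' tie between the second and third components is resolved toward the
#' leftmost-topmost bounding box (with a message).
#'
#' @param page A masked `report_page`.
#' @param config A [construct_config()].
#' @return A list with elements `vt` and `fv`, each `list(box, crop)` where
#'   `box` is the 0-based half-open bounding box in full-page coordinates and
#'   `crop` a binary matrix in `{0, 255}`; plus `half_offset`, the row index
#'   where the bottom half starts.
#' @export
extract_curve_regions <- function(page, config = construct_config()) {
  stopifnot(inherits(page, "report_page"))
  gray <- to_gray(page$pixels)
  h <- nrow(gray)
  half_offset <- floor(h / 2)              # 0-based first row kept
  bottom <- gray[(half_offset + 1):h, , drop = FALSE]
  thr <- EBImage::otsu(EBImage::Image(bottom), range = c(0, 1))
  fg <- bottom < thr                        # invert: dark curves -> TRUE

  lab <- label_components(fg, connectivity = 8L)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    small <- which(areas < config$area_min)
    if (length(small)) fg[lab %in% small] <- FALSE
  }

  kern <- EBImage::makeBrush(config$closing_size, shape = "box")
  closed <- EBImage::closing(fg * 1, kern) > 0

  lab <- label_components(closed, connectivity = 8L)
  n_comp <- max(lab)
  if (n_comp < 2L)
    stop("no-curves-found error: fewer than 2 curve regions survive ",
         "filtering", call. = FALSE)
  areas <- tabulate(lab[lab > 0L])
  boxes <- t(vapply(seq_len(n_comp), function(k) component_box(lab, k),
                    numeric(4)))
  ord <- order(-areas, boxes[, 2], boxes[, 1])
  if (n_comp > 2L && areas[ord[2]] == areas[ord[3]])
    message("area tie between regions resolved toward leftmost-topmost box")
  keep <- ord[1:2]

  crops <- lapply(keep, function(k) {
    b <- component_box(lab, k)
    crop <- (lab[(b[1] + 1):b[3], (b[2] + 1):b[4], drop = FALSE] == k) * 255
    b[1] <- b[1] + half_offset; b[3] <- b[3] + half_offset  # page coords
    list(box = b, crop = crop)
  })
  lefts <- vapply(crops, function(cr) cr$box[2], numeric(1))
  vt_idx <- if (config$vt_position == "left") which.min(lefts) else
    which.max(lefts)
  list(vt = crops[[vt_idx]], fv = crops[[3 - vt_idx]],
       half_offset = half_offset)
}

#' Stack the two curve crops into a 700 x 500 panel
#'
#' Each binary crop is rescaled preserving aspect ratio to fit a 350 x 500
#' sub-panel and centred in it; the volume-time curve occupies rows
#' `[0, 350)`, the flow-volume curve rows `[350, 700)`. The result is
#' re-binarized to `{0, 255}`.
#'
#' @param vt,fv Binary crop matrices (values `{0, 255}`), e.g. the `crop`
#'   fields from [extract_curve_regions()].
#' @return A list: `panel` (700 x 500 matrix in `{0, 255}`) and `placement`,
#'   the per-crop scale and offsets needed to map crop pixels into the panel.
#' @export
compose_panel <- function(vt, fv) {
  place_one <- function(crop, row_base) {
    if (!is.matrix(crop) || nrow(crop) == 0L || ncol(crop) == 0L ||
        !any(crop > 0))
      stop("invalid-region error: empty curve crop", call. = FALSE)
    s <- min(350 / nrow(crop), 500 / ncol(crop))
    hs <- max(1L, round(nrow(crop) * s)); ws <- max(1L, round(ncol(crop) * s))
    scaled <- resize_matrix(crop, hs, ws) >= 127.5
    row_off <- row_base + floor((350 - hs) / 2)
    col_off <- floor((500 - ws) / 2)
    list(mask = scaled, scale = s, row_off = row_off, col_off = col_off,
         rows = hs, cols = ws)
  }
  panel <- matrix(0, 700, 500)
  pv <- place_one(vt, 0L)
  pf <- place_one(fv, 350L)
  panel[pv$row_off + seq_len(pv$rows), pv$col_off + seq_len(pv$cols)] <-
    pv$mask * 255
  panel[pf$row_off + seq_len(pf$rows), pf$col_off + seq_len(pf$cols)] <-
    pf$mask * 255
  list(panel = panel, placement = list(vt = pv, fv = pf))
}

# Frame section row ranges (1-based): sex, age, bmi top to bottom. 700 rows
# cannot be split into three equal integers; heights are 234/233/233.
frame_sections <- list(sex = 1:234, age = 235:467, bmi = 468:700)

normalize_demographic <- function(demo, spec) {
  clamp01 <- function(v, what) {
    if (v < 0 || v > 1) {
      warning(what, " outside normalization bounds; clamped", call. = FALSE)
      v <- min(max(v, 0), 1)
    }
    v
  }
  c(sex = if (demo$sex == "woman") 1 else 0,
    age = clamp01((demo$age - spec$age_min) / (spec$age_max - spec$age_min),
                  "age"),
    bmi = clamp01((demo$bmi - spec$bmi_min) / (spec$bmi_max - spec$bmi_min),
                  "bmi"))
}

#' Add the demographic frame to the curve panel
#'
#' Expands the 700 x 500 panel to a 700 x 700 square by appending a
#' 200-column frame on the right, split into three vertical sections (sex,
#' age, BMI, top to bottom). Each section is a constant gray equal to the
#' MIN-MAX normalized variable value times 255, rounded half-up.
#'
#' @param panel A 700 x 500 panel matrix (see [compose_panel()]).
#' @param demo A `demographics` object.
#' @param spec A [normalization_spec()].
#' @return A list: `framed` (700 x 700 grayscale matrix on `[0, 255]`) and
#'   `frame_grays` (named vector sex/age/bmi).
#' @export
encode_demographics_frame <- function(panel, demo, spec = normalization_spec()) {
  stopifnot(is.matrix(panel), all(dim(panel) == c(700L, 500L)))
  demo <- as_demographics(demo)
  v <- normalize_demographic(demo, spec)
  grays <- round_half_up(v * 255)
  framed <- matrix(0, 700, 700)
  framed[, 1:500] <- panel
  for (nm in names(frame_sections))
    framed[frame_sections[[nm]], 501:700] <- grays[[nm]]
  list(framed = framed, frame_grays = grays)
}

#' Resize the framed construct to the network input size
#'
#' Bilinear, antialiased resize of the 700 x 700 framed image to 224 x 224,
#' replicated onto three identical channels. Values stay on the `[0, 255]`
#' scale; rescaling to network statistics is the classifier's concern.
#'
#' @param framed A 700 x 700 grayscale matrix on `[0, 255]`.
#' @return A 224 x 224 x 3 array on `[0, 255]`.
#' @export
finalize_construct <- function(framed) {
  stopifnot(is.matrix(framed), all(dim(framed) == c(700L, 700L)))
  small <- resize_matrix(framed, 224L, 224L, antialias = TRUE)
  small <- pmin(pmax(small, 0), 255)
  array(rep(small, 3L), dim = c(224L, 224L, 3L))
}

#' Build the graphical construct from a report page and demographics
#'
#' Runs the full pipeline — post-bronchodilator color mask, curve-region
#' extraction from the bottom half, 700 x 500 panel composition, demographic
#' frame encoding to 700 x 700, and the final 224 x 224 resize — keeping all
#' intermediates for inspection. Stage failures are re-raised with the stage
#' name attached.
#'
#' @param page A `report_page`.
#' @param demo A `demographics` object (or list with sex/age/bmi).
#' @param spec A [normalization_spec()].
#' @param config A [construct_config()].
#' @return An object of class `graphical_construct` with fields
#'   `network_input` (224 x 224 x 3, `[0, 255]`), `framed` (700 x 700),
#'   `panel` (700 x 500), `frame_grays`, `regions`, `placement`,
#'   `demographics`.
#' @export
build_construct <- function(page, demo, spec = normalization_spec(),
                            config = construct_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("construct stage \"", name, "\" failed: ", conditionMessage(e),
           call. = FALSE))
  }
  demo <- stage("demographics", as_demographics(demo))
  masked <- stage("mask", mask_post_bd_colors(page, config))
  regions <- stage("extract", extract_curve_regions(masked, config))
  comp <- stage("compose", compose_panel(regions$vt$crop, regions$fv$crop))
  enc <- stage("frame", encode_demographics_frame(comp$panel, demo, spec))
  net <- stage("finalize", finalize_construct(enc$framed))
  structure(list(network_input = net, framed = enc$framed,
                 panel = comp$panel, frame_grays = enc$frame_grays,
                 regions = regions, placement = comp$placement,
                 demographics = demo),
            class = "graphical_construct")
}

#' @export
print.graphical_construct <- function(x, ...) {
  cat("<graphical_construct> 700x700 framed, 224x224x3 input; frame grays ",
      paste(names(x$frame_grays), x$frame_grays, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Map a page-coordinate box into network-input coordinates
#'
#' Propagates a bounding box given in full-page pixel coordinates (e.g. an
#' artifact annotation from [render_report()]) through the construct's
#' geometry: region crop, sub-panel scaling and placement, and the final
#' 700 -> 224 resize. The box is matched to whichever retained region it
#' overlaps most.
#'
#' @param construct A [build_construct()] result.
#' @param box `c(top, left, bottom, right)`, 0-based half-open page pixels.
#' @return The transformed box in 224 x 224 network-input coordinates, or
#'   `NULL` if the box does not intersect either retained region.
#' @export
map_page_box_to_construct <- function(construct, box) {
  stopifnot(inherits(construct, "graphical_construct"), length(box) == 4L)
  overlap <- function(a, b) {
    max(0, min(a[3], b[3]) - max(a[1], b[1])) *
      max(0, min(a[4], b[4]) - max(a[2], b[2]))
  }
  regions <- construct$regions
  ov <- c(vt = overlap(box, regions$vt$box), fv = overlap(box, regions$fv$box))
  if (max(ov) == 0) return(NULL)
  which_r <- names(ov)[which.max(ov)]
  rb <- regions[[which_r]]$box
  pl <- construct$placement[[which_r]]
  # clip to the region, shift to crop coords, scale + place into the panel
  top <- max(box[1], rb[1]) - rb[1]; bottom <- min(box[3], rb[3]) - rb[1]
  left <- max(box[2], rb[2]) - rb[2]; right <- min(box[4], rb[4]) - rb[2]
  panel_box <- c(top * pl$scale + pl$row_off, left * pl$scale + pl$col_off,
                 bottom * pl$scale + pl$row_off, right * pl$scale + pl$col_off)
  panel_box * 224 / 700
}
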