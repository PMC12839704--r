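#' Geometric data-augmentation configuration
#'
#' Random geometric transforms applied to each training image once per epoch
#' (never at validation or test time): rotation in degrees, horizontal and
#' vertical translation in pixels, and anisotropic scaling, each sampled
#' uniformly from its range. Pixels exposed by the transform are filled with
#' black, the construct's background.
#'
#' @param rotation_deg,translate_x_px,translate_y_px,scale_x,scale_y
#'   Two-element ranges `c(min, max)`.
#' @param enabled Set `FALSE` to disable augmentation entirely.
#' @return An `augment_config` object.
#' @export
augment_config <- function(rotation_deg = c(-10, 10),
                           translate_x_px = c(-5, 5),
                           translate_y_px = c(-5, 5),
                           scale_x = c(0.9, 1.1),
                           scale_y = c(0.9, 1.1),
                           enabled = TRUE) {
  structure(list(rotation_deg = rotation_deg,
                 translate_x_px = translate_x_px,
                 translate_y_px = translate_y_px,
                 scale_x = scale_x, scale_y = scale_y, enabled = enabled),
            class = "augment_config")
}

sample_transform <- function(ac) {
  list(rot = runif(1, ac$rotation_deg[1], ac$rotation_deg[2]),
       tx = runif(1, ac$translate_x_px[1], ac$translate_x_px[2]),
       ty = runif(1, ac$translate_y_px[1], ac$translate_y_px[2]),
       sx = runif(1, ac$scale_x[1], ac$scale_x[2]),
       sy = runif(1, ac$scale_y[1], ac$scale_y[2]))
}

# Apply an affine transform (scale about the centre, then rotate, then
# translate) to a grayscale matrix by inverse mapping with bilinear
# interpolation; out-of-image samples are 0 (black). Identity transforms
# return the input unchanged.
affine_image <- function(img, rot = 0, tx = 0, ty = 0, sx = 1, sy = 1) {
  if (rot == 0 && tx == 0 && ty == 0 && sx == 1 && sy == 1) return(img)
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  xo <- rep(seq_len(w) - cx, each = h) - tx
  yo <- rep(seq_len(h) - cy, times = w) - ty
  th <- -rot * pi / 180                       # inverse rotation
  xi <- (cos(th) * xo - sin(th) * yo) / sx + cx
  yi <- (sin(th) * xo + cos(th) * yo) / sy + cy
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  sample_at <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- numeric(length(r))
    v[ok] <- img[(c[ok] - 1) * h + r[ok]]
    v
  }
  v <- (1 - fy) * (1 - fx) * sample_at(y0, x0) +
    fy * (1 - fx) * sample_at(y0 + 1, x0) +
    (1 - fy) * fx * sample_at(y0, x0 + 1) +
    fy * fx * sample_at(y0 + 1, x0 + 1)
  matrix(v, h, w)
}
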