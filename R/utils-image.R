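# Shared raster helpers. Images are numeric arrays [row, col(, channel)],
# top-left origin. Boxes are c(top, left, bottom, right), 0-based, half-open.

#' @keywords internal
#' @noRd
luma_weights <- c(0.299, 0.587, 0.114)

# RGB array (h x w x 3, [0,1]) -> grayscale matrix on the same scale.
to_gray <- function(page) {
  stopifnot(length(dim(page)) == 3L, dim(page)[3] >= 3L)
  page[, , 1] * luma_weights[1] + page[, , 2] * luma_weights[2] +
    page[, , 3] * luma_weights[3]
}

# Round-half-up to integers (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# 8- or 4-connected component labelling of a logical/binary matrix.
# EBImage's labeller is 4-connected, so adjacency is built explicitly and
# resolved with igraph; returns an integer matrix of labels (0 = background).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask > 0)
  lab <- matrix(0L, h, w)
  if (length(fg) == 0L) return(lab)
  pos <- integer(h * w)           # linear index -> vertex id
  pos[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))            # down, right
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- NULL
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    idx2 <- (c2[ok] - 1L) * h + r2[ok]
    nb <- pos[idx2]
    keep <- nb > 0L
    if (any(keep)) {
      edges <- c(edges, rbind(which(ok)[keep], nb[keep]))
    }
  }
  if (is.null(edges)) {
    comp <- seq_along(fg)
  } else {
    g <- igraph::make_graph(edges = as.vector(edges), n = length(fg),
                            directed = FALSE)
    comp <- igraph::components(g)$membership
  }
  lab[fg] <- as.integer(comp)
  lab
}

# Bounding box (top,left,bottom,right), 0-based half-open, of label k.
component_box <- function(lab, k) {
  idx <- which(lab == k)
  h <- nrow(lab)
  rows <- ((idx - 1L) %% h)
  cols <- ((idx - 1L) %/% h)
  c(top = min(rows), left = min(cols), bottom = max(rows) + 1L,
    right = max(cols) + 1L)
}

# Bilinear resize of a matrix via EBImage (x is [row, col]; EBImage stores
# images x-major so the matrix is transposed on the way in and out).
resize_matrix <- function(m, out_rows, out_cols, antialias = TRUE) {
  r <- EBImage::resize(EBImage::Image(t(m)), w = out_cols, h = out_rows,
                       antialias = antialias)
  t(EBImage::imageData(r))
}

# 1-based linear indices (into an h x w matrix) covered by a thick polyline.
# xs/ys are 0-based pixel coordinates (x = column, y = row); radius in px.
stroke_indices <- function(h, w, xs, ys, radius = 2L) {
  stopifnot(length(xs) == length(ys))
  # densify along chord length so strokes have no holes
  if (length(xs) > 1L) {
    d <- pmax(abs(diff(xs)), abs(diff(ys)), 1e-6)
    s <- cumsum(c(0, d))
    sout <- seq(0, s[length(s)], by = 0.5)
    px <- stats::approx(s, xs, xout = sout)$y
    py <- stats::approx(s, ys, xout = sout)$y
  } else {
    px <- xs; py <- ys
  }
  cx <- round(px); cy <- round(py)
  # disc offsets
  od <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  od <- od[od$dr^2 + od$dc^2 <= radius^2 + 0.25, ]
  rr <- outer(cy, od$dr, `+`); cc <- outer(cx, od$dc, `+`)
  ok <- rr >= 0 & rr < h & cc >= 0 & cc < w
  unique(cc[ok] * h + rr[ok] + 1)   # 1-based linear index into [h, w]
}

# Stamp a thick polyline into an RGB page array.
draw_polyline <- function(page, xs, ys, color, radius = 2L) {
  stopifnot(length(color) == 3L)
  h <- dim(page)[1]; w <- dim(page)[2]
  lin <- stroke_indices(h, w, xs, ys, radius)
  n <- h * w
  page[lin] <- color[1]
  page[lin + n] <- color[2]
  page[lin + 2 * n] <- color[3]
  page
}

# Ensure an array read from disk is h x w x 3 in [0,1].
ensure_rgb <- function(px) {
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] == 2L) px <- array(rep(px[, , 1], 3L), dim = c(dim(px)[1:2], 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px
}
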