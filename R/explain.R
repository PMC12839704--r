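#' Gradient-weighted class-activation heatmap (Grad-CAM)
#'
#' Computes the gradient of the target class score (pre-softmax logit) with
#' respect to the activations of the last convolutional block, averages the
#' gradient over space to obtain one weight per channel, forms the weighted
#' sum of the activation maps, rectifies it, bilinearly upsamples it to the
#' 224 x 224 network input and normalizes the maximum to 1.
#'
#' @param classifier A fitted `spiro_classifier` (an untrained one is
#'   allowed and produces a valid but uninformative map, with a warning).
#' @param construct A [build_construct()] result or 224x224(x3) array.
#' @param target_class `"unacceptable"`, `"acceptable"`, or `NULL` for the
#'   predicted class.
#' @return A `heatmap` object: `values` (224 x 224 matrix in `[0, 1]`) and
#'   `target_class`.
#' @export
grad_cam <- function(classifier, construct, target_class = NULL) {
  stopifnot(inherits(classifier, "spiro_classifier"))
  if (!classifier$trained)
    warning("classifier is untrained; heatmap is uninformative",
            call. = FALSE)
  x <- as_input_batch(construct)
  stopifnot(dim(x)[3] == 1L)
  fwd <- nn_forward(classifier$params, classifier$geom, x, keep = TRUE)
  if (is.null(target_class))
    target_class <- classifier$classes[which.max(fwd$logits[, 1])]
  cls <- match(target_class, classifier$classes)
  if (is.na(cls)) stop("invalid target class: ", target_class, call. = FALSE)

  cache <- fwd$cache
  F3 <- classifier$geom$channels[3]
  # d(logit_cls)/d(a3): through the linear head, GAP and the last max-pool
  dg <- classifier$params$Wf[, cls]
  dp3 <- array(rep(dg, each = 7L * 7L) / (7 * 7), dim = c(7L, 7L, F3, 1L))
  da3 <- maxpool_backward(dp3, cache$p3$masks, dim(cache$a3))
  alpha <- apply(da3[, , , 1], 3, mean)               # channel weights
  a3 <- cache$a3[, , , 1]
  cam <- matrix(0, 14L, 14L)
  for (f in seq_len(F3)) cam <- cam + alpha[f] * a3[, , f]
  cam <- pmax(cam, 0)                                 # rectify
  up <- resize_matrix(cam, 224L, 224L)
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  structure(list(values = up, target_class = target_class),
            class = "heatmap")
}

#' Overlay a Grad-CAM heatmap on a construct
#'
#' Renders the construct in gray and alpha-blends a perceptually ordered
#' colormap of the heatmap on top: `out = (1 - alpha) * gray + alpha *
#' colormap(heat)`.
#'
#' @param construct A [build_construct()] result or 224x224(x3) array on
#'   `[0, 255]`.
#' @param heatmap A [grad_cam()] result (or 224 x 224 matrix in `[0, 1]`).
#' @param alpha Heatmap opacity in `[0, 1]` (default 0.4).
#' @param colormap Palette name passed to [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @return A 224 x 224 x 3 RGB array in `[0, 1]`.
#' @export
overlay_heatmap <- function(construct, heatmap, alpha = 0.4,
                            colormap = "viridis") {
  gray <- as_input_batch(construct)[, , 1] / 255
  hv <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  if (!all(dim(hv) == dim(gray)))
    stop("shape error: heatmap and construct dimensions differ",
         call. = FALSE)
  stopifnot(alpha >= 0, alpha <= 1)
  pal <- grDevices::hcl.colors(256L, colormap)
  idx <- pmin(pmax(floor(hv * 255) + 1L, 1L), 256L)
  cm <- grDevices::col2rgb(pal[idx]) / 255            # 3 x npix
  out <- array(0, dim = c(dim(gray), 3L))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * gray + alpha * matrix(cm[ch, ], nrow(gray))
  out
}
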