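#' Training configuration for the acceptability classifier
#'
#' Defaults follow the standard fine-tuning recipe for this task: Adam,
#' mini-batch 64, at most 100 epochs, learning rate 1e-4, and early stopping
#' with a patience of 20 validation evaluations (one evaluation per epoch),
#' returning the parameters from the evaluation with the lowest validation
#' error.
#'
#' @param optimizer Only `"adam"` is implemented.
#' @param mini_batch Mini-batch size.
#' @param max_epochs Maximum number of epochs.
#' @param learning_rate Adam step size.
#' @param validation_patience Consecutive evaluations without improvement
#'   before training stops.
#' @return A `train_config` object.
#' @export
train_config <- function(optimizer = "adam", mini_batch = 64L,
                         max_epochs = 100L, learning_rate = 1e-4,
                         validation_patience = 20L) {
  stopifnot(identical(optimizer, "adam"), mini_batch > 0, max_epochs > 0,
            learning_rate > 0, validation_patience > 0)
  structure(list(optimizer = optimizer, mini_batch = as.integer(mini_batch),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 validation_patience = as.integer(validation_patience)),
            class = "train_config")
}

#' Train / validation / test split specification
#'
#' @param test_fraction Fraction held out as the test set (default 0.10).
#' @param validation Either a count of training images reserved for
#'   validation or a fraction (< 1) of the training portion.
#' @param stratified Stratify by class (default `TRUE`, so both classes are
#'   present in every split even at small n).
#' @param seed Integer seed for the split.
#' @return A `split_spec` object.
#' @export
split_spec <- function(test_fraction = 0.10, validation = 0.115,
                       stratified = TRUE, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, validation > 0)
  structure(list(test_fraction = test_fraction, validation = validation,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split labelled data into disjoint train/validation/test index sets
#'
#' @param labels Character/factor vector of class labels.
#' @param spec A [split_spec()].
#' @return A list of integer index vectors `train`, `validation`, `test`
#'   whose union is `seq_along(labels)`.
#' @export
split_dataset <- function(labels, spec = split_spec()) {
  labels <- as.character(labels)
  n <- length(labels)
  set.seed(spec$seed)
  take <- function(pool, k) if (k <= 0) integer(0) else
    pool[sample.int(length(pool), min(k, length(pool)))]
  groups <- if (spec$stratified) split(seq_len(n), labels) else
    list(all = seq_len(n))
  test <- unlist(lapply(groups, function(g)
    take(g, round_half_up(length(g) * spec$test_fraction))), use.names = FALSE)
  rest <- setdiff(seq_len(n), test)
  n_val <- if (spec$validation < 1) round_half_up(length(rest) * spec$validation)
    else as.integer(spec$validation)
  groups_r <- if (spec$stratified) split(rest, labels[rest]) else
    list(all = rest)
  val <- unlist(lapply(seq_along(groups_r), function(i) {
    g <- groups_r[[i]]
    take(g, round_half_up(n_val * length(g) / length(rest)))
  }), use.names = FALSE)
  if (length(val) == 0L) val <- take(rest, n_val)
  list(train = sort(setdiff(rest, val)), validation = sort(val),
       test = sort(test))
}

# Early-stopping bookkeeping: given the sequence of validation errors so far,
# return the index of the best evaluation and whether training should stop
# (no improvement for `patience` consecutive evaluations after the best).
early_stop_status <- function(val_errors, patience) {
  best <- which.min(val_errors)
  list(best = best, stop = (length(val_errors) - best) >= patience)
}

#' Build the acceptability classifier
#'
#' A compact convolutional network: a 2x2 average-pool stem on the 224x224
#' grayscale construct followed by three 3x3 convolution + ReLU + max-pool
#' blocks (8, 16, 32 channels), global average pooling and a 2-class linear
#' head whose softmax output for the `unacceptable` class is the risk score.
#' The network is small enough to train from random initialization on a CPU
#' in minutes; `pretrained = TRUE` would require external backbone weight
#' files that this package does not ship and raises an error.
#'
#' @param pretrained Must be `FALSE`; see Details.
#' @param seed Seed for the random weight initialization.
#' @return An object of class `spiro_classifier` (untrained).
#' @export
build_classifier <- function(pretrained = FALSE, seed = 1L) {
  if (isTRUE(pretrained))
    stop("pretrained backbone weights are not bundled with this package; ",
         "use pretrained = FALSE (train from random initialization)",
         call. = FALSE)
  channels <- c(8L, 16L, 32L)
  structure(list(params = nn_init_params(seed, channels),
                 geom = nn_geometry(channels),
                 classes = c("acceptable", "unacceptable"),
                 trained = FALSE, history = NULL),
            class = "spiro_classifier")
}

#' @export
print.spiro_classifier <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<spiro_classifier> compact CNN, ", np, " parameters; ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  if (!is.null(x$history))
    cat("  best epoch ", x$best_epoch, ", validation loss ",
        sprintf("%.4f", min(x$history$val_loss)), "\n", sep = "")
  invisible(x)
}

# Coerce assorted inputs to a (224, 224, N) grayscale batch on [0, 255].
as_input_batch <- function(x) {
  gray_one <- function(z) {
    if (inherits(z, "graphical_construct")) z <- z$network_input
    d <- dim(z)
    if (length(d) == 3L) {
      if (!all(d == c(224L, 224L, 3L)))
        stop("shape error: expected a 224 x 224 x 3 network input, got ",
             paste(d, collapse = " x "), call. = FALSE)
      z <- (z[, , 1] + z[, , 2] + z[, , 3]) / 3
    } else if (!all(d == c(224L, 224L))) {
      stop("shape error: expected 224 x 224 input, got ",
           paste(d, collapse = " x "), call. = FALSE)
    }
    z
  }
  if (is.list(x) && !inherits(x, "graphical_construct")) {
    mats <- lapply(x, gray_one)
    array(unlist(mats), dim = c(224L, 224L, length(mats)))
  } else if (is.array(x) && length(dim(x)) == 3L &&
             !all(dim(x) == c(224L, 224L, 3L))) {
    stopifnot(dim(x)[1] == 224L, dim(x)[2] == 224L)
    x
  } else {
    array(gray_one(x), dim = c(224L, 224L, 1L))
  }
}

#' Risk that a manoeuvre is unacceptable
#'
#' Runs the classifier forward (no augmentation) and returns the softmax
#' probability of the `unacceptable` class, a scalar in `[0, 1]` per input.
#'
#' @param classifier A `spiro_classifier`.
#' @param x A [build_construct()] result, a 224x224(x3) array, a
#'   (224, 224, N) batch, or a list of constructs.
#' @return Numeric vector of risks in `[0, 1]`.
#' @export
predict_risk <- function(classifier, x) {
  stopifnot(inherits(classifier, "spiro_classifier"))
  batch <- as_input_batch(x)
  if (!classifier$trained)
    warning("classifier is untrained; risks are uninformative", call. = FALSE)
  fwd <- nn_forward(classifier$params, classifier$geom, batch)
  unname(fwd$probs[2, ])
}

#' Fit the acceptability classifier
#'
#' Minimizes 2-class cross-entropy with Adam on the training indices,
#' evaluating the validation loss once per epoch. Training stops when the
#' validation error has not improved for `tc$validation_patience` consecutive
#' evaluations (or at `tc$max_epochs`), and the returned parameters are those
#' of the best-validation epoch. Augmentation transforms are resampled for
#' every training image at every epoch from a dedicated RNG stream, so
#' disabling augmentation does not perturb the main training stream.
#'
#' @param classifier An untrained [build_classifier()] result.
#' @param x Constructs: a (224, 224, N) grayscale array on `[0, 255]`, or a
#'   list of [build_construct()] results.
#' @param labels Vector of `"acceptable"`/`"unacceptable"` labels, length N.
#' @param tc A [train_config()].
#' @param ac An [augment_config()].
#' @param train_idx,val_idx Integer index vectors (e.g. from
#'   [split_dataset()]); both must be non-empty and the training part must
#'   contain both classes.
#' @param seed Seed controlling shuffling and augmentation.
#' @param verbose Print per-epoch progress?
#' @return The fitted `spiro_classifier`, with `history` (a data.frame of
#'   per-epoch train/validation losses) and `best_epoch`.
#' @export
train_classifier <- function(classifier, x, labels, tc = train_config(),
                             ac = augment_config(), train_idx, val_idx,
                             seed = 1L, verbose = FALSE) {
  stopifnot(inherits(classifier, "spiro_classifier"),
            inherits(tc, "train_config"), inherits(ac, "augment_config"))
  batch_all <- as_input_batch(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == dim(batch_all)[3])
  if (length(val_idx) == 0L)
    stop("configuration error: validation set is empty", call. = FALSE)
  y_all <- match(labels, classifier$classes)
  if (anyNA(y_all))
    stop("labels must be \"acceptable\" or \"unacceptable\"", call. = FALSE)
  if (length(unique(y_all[train_idx])) < 2L)
    stop("training error: training set contains a single class",
         call. = FALSE)

  params <- classifier$params; geom <- classifier$geom
  opt <- adam_init(params)
  xval <- batch_all[, , val_idx, drop = FALSE]
  yval <- y_all[val_idx]
  best_params <- params
  hist_rows <- list()
  val_errors <- numeric(0)
  set.seed(as.integer(seed))
  aug_seed <- (as.integer(seed) + 777L) %% .Machine$integer.max

  for (epoch in seq_len(tc$max_epochs)) {
    ord <- sample(train_idx)
    xtr <- batch_all[, , ord, drop = FALSE]
    if (isTRUE(ac$enabled)) {
      # dedicated augmentation stream: the main stream is untouched, so a
      # zero-width (identity) configuration reproduces the unaugmented run
      main_state <- .Random.seed
      set.seed(aug_seed + epoch)
      for (i in seq_len(dim(xtr)[3])) {
        tr <- sample_transform(ac)
        xtr[, , i] <- affine_image(xtr[, , i], tr$rot, tr$tx, tr$ty,
                                   tr$sx, tr$sy)
      }
      assign(".Random.seed", main_state, envir = globalenv())
    }
    ytr <- y_all[ord]
    n_tr <- length(ord)
    tr_loss <- 0
    starts <- seq(1L, n_tr, by = tc$mini_batch)
    for (s0 in starts) {
      sel <- s0:min(s0 + tc$mini_batch - 1L, n_tr)
      fwd <- nn_forward(params, geom, xtr[, , sel, drop = FALSE], keep = TRUE)
      tr_loss <- tr_loss + nn_loss(fwd$probs, ytr[sel]) * length(sel)
      grads <- nn_backward(params, geom, fwd, ytr[sel])
      stepped <- adam_step(params, grads, opt, tc$learning_rate)
      params <- stepped$params; opt <- stepped$state
    }
    vfwd <- nn_forward(params, geom, xval)
    vloss <- nn_loss(vfwd$probs, yval)
    verr <- mean(max.col(t(vfwd$probs)) != yval)
    val_errors <- c(val_errors, vloss)
    hist_rows[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = tr_loss / n_tr,
                                     val_loss = vloss, val_error = verr)
    st <- early_stop_status(val_errors, tc$validation_patience)
    if (st$best == epoch) best_params <- params
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  (best %d)",
                      epoch, tr_loss / n_tr, vloss, st$best))
    if (st$stop) break
  }
  st <- early_stop_status(val_errors, tc$validation_patience)
  classifier$params <- best_params
  classifier$trained <- TRUE
  classifier$history <- do.call(rbind, hist_rows)
  classifier$best_epoch <- st$best
  classifier
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is a single RDS file holding parameters, architecture
#' geometry, class mapping and training history.
#'
#' @param classifier A `spiro_classifier`.
#' @param path Checkpoint file path.
#' @return `load_classifier` returns the `spiro_classifier`.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "spiro_classifier"))
  saveRDS(unclass(classifier), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), all(c("params", "geom", "classes") %in% names(obj)))
  structure(obj, class = "spiro_classifier")
}
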