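# The fitted-model interface: cgrnet() trains the CNN on CGR feature tensors
# and returns a classed object with the usual methods.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. seed = NULL uses the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Network architecture configuration
#'
#' The default reproduces the reference architecture: two convolution blocks
#' (5x5 kernels, stride 1, padding 2, ReLU, then 2x2 max pooling with stride
#' 2) with 64 and 128 output channels, a 512-unit fully connected layer, and
#' a softmax output over the host classes. For a `(3, 2^k, 2^k)` input with
#' k = 7 the activation chain is (3,128,128) -> (64,128,128) -> (64,64,64) ->
#' (128,64,64) -> (128,32,32).
#'
#' @param k k-mer length; the input grid side is 2^k.
#' @param n_classes number of host taxa (>= 2).
#' @param conv_channels output channels of each convolution block; the number
#'   of blocks is its length. 2^k must be divisible by 2^(number of blocks).
#' @param fc_units width of the fully connected layer.
#' @param kernel,pad convolution kernel size and zero padding.
#' @return A list of class `cgrnet_config`.
#' @export
model_config <- function(k, n_classes, conv_channels = c(64L, 128L),
                         fc_units = 512L, kernel = 5L, pad = 2L) {
  k <- .check_k(k)
  if (n_classes < 2) stop("`n_classes` must be at least 2")
  nb <- length(conv_channels)
  if (2L^k %% 2L^nb != 0L || 2L^k < 2L^nb)
    stop(sprintf("input side %d is not divisible by 2^%d pooling stages",
                 2L^k, nb))
  structure(list(k = k, n_classes = as.integer(n_classes),
                 conv_channels = as.integer(conv_channels),
                 fc_units = as.integer(fc_units),
                 kernel = as.integer(kernel), pad = as.integer(pad)),
            class = "cgrnet_config")
}

#' Activation shapes of a configured network
#'
#' @param config a [model_config()].
#' @return A named list of `(channels, height, width)` integer triples, from
#'   the input through each convolution and pooling stage.
#' @export
model_shapes <- function(config) {
  stopifnot(inherits(config, "cgrnet_config"))
  side <- as.integer(2^config$k)
  shapes <- list(input = c(3L, side, side))
  ch <- 3L
  for (i in seq_along(config$conv_channels)) {
    ch <- config$conv_channels[i]
    shapes[[paste0("conv", i)]] <- c(ch, side, side)
    side <- side %/% 2L
    shapes[[paste0("pool", i)]] <- c(ch, side, side)
  }
  shapes
}

# Stack a list of cgr_tensor objects into an (side, side, 3, n) array,
# normalizing raw tensors on the way in. Checks a common k.
.stack_tensors <- function(tensors, k = NULL) {
  stopifnot(is.list(tensors), length(tensors) >= 1L)
  ks <- vapply(tensors, function(t) attr(t, "k"), integer(1))
  if (length(unique(ks)) != 1L)
    stop("all tensors must share the same k (found: ",
         paste(unique(ks), collapse = ", "), ")")
  if (!is.null(k) && ks[1] != k)
    stop(sprintf("tensors have k = %d but the model expects k = %d", ks[1], k))
  tensors <- lapply(tensors, function(t)
    if (isTRUE(attr(t, "normalized"))) t else minmax_normalize(t))
  side <- 2L^ks[1]
  X <- array(0, dim = c(side, side, 3L, length(tensors)))
  for (i in seq_along(tensors)) X[, , , i] <- tensors[[i]]
  list(X = X, k = ks[1])
}

.as_tensor_list <- function(x, k, corners) {
  if (inherits(x, "cgr_tensor")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "cgr_tensor")))
    return(x)
  if (is.character(x) || methods::is(x, "DNAStringSet")) {
    if (is.null(names(x)))
      names(x) <- paste0("seq", seq_along(x))
    return(featurize(x, k = k, corners = corners, normalize = TRUE))
  }
  stop("`x` must be cgr_tensor objects, DNA strings, or a DNAStringSet")
}

#' Fit the CGR-CNN host classifier
#'
#' Trains the convolutional network on normalized CGR feature tensors with
#' the Adam optimizer (learning rate 0.001 by default) on the categorical
#' cross-entropy loss. A validation split is used for model selection: the
#' weights from the epoch with the best validation accuracy are kept, and
#' training stops early when validation accuracy has not improved for
#' `patience` epochs.
#'
#' @param x training inputs: a named list of `cgr_tensor` objects (see
#'   [featurize()]), a named character vector of DNA strings, or a
#'   `DNAStringSet` (sequences are featurized with `k` and `corners`).
#' @param labels host taxon of each training item (character or factor);
#'   at least two distinct classes are required.
#' @param k k-mer length used when `x` holds raw sequences; otherwise taken
#'   from the tensors.
#' @param corners CGR corner assignment used when featurizing sequences.
#' @param conv_channels,fc_units architecture knobs, see [model_config()].
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of passes over the training data.
#' @param patience early-stopping patience, in epochs without validation
#'   improvement; ignored when there is no validation set.
#' @param validation either a fraction in (0, 1) carved off the training data
#'   for model selection, a list with elements `x` and `labels`, or 0 for no
#'   validation (the final-epoch weights are kept).
#' @param seed integer seed controlling initialization, shuffling and the
#'   validation carve-out; fits are reproducible given the same seed.
#' @param verbose print per-epoch progress.
#' @return An object of class `cgrnet` with components `params` (weights),
#'   `config`, `levels` (class labels in index order), `corners`, `k`,
#'   `history` (per-epoch loss and validation accuracy), `best_epoch`, and
#'   `training` (the settings used).
#' @seealso [predict.cgrnet()], [save_cgrnet()]
#' @examples
#' \donttest{
#' specs <- make_class_specs(2, separation = 1, seed = 1)
#' ds <- sample_sequences(specs, n_per_class = 12, length = 400, seed = 1)
#' fit <- cgrnet(ds$sequences, ds$labels, k = 2, max_epochs = 5, seed = 1)
#' predict(fit, ds$sequences[1:3])
#' }
#' @export
cgrnet <- function(x, labels, k = 7, corners = cgr_corners(),
                   conv_channels = c(64L, 128L), fc_units = 512L,
                   learning_rate = 0.001, batch_size = 32L,
                   max_epochs = 100L, patience = 10L,
                   validation = 0.1, seed = 1L, verbose = FALSE) {
  cl <- match.call()
  tensors <- .as_tensor_list(x, k, corners)
  if (length(tensors) != length(labels))
    stop("`labels` must have one entry per training item")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2)
    stop("training labels contain a single class; at least 2 are required")

  st <- .stack_tensors(tensors)
  k <- st$k
  config <- model_config(k, length(lev), conv_channels, fc_units)
  y_all <- match(labels, lev)

  .with_seed(seed, {
    # validation carve-out / explicit validation set
    if (is.list(validation)) {
      vt <- .as_tensor_list(validation$x, k, corners)
      vst <- .stack_tensors(vt, k = k)
      Xval <- vst$X
      yval <- match(as.character(validation$labels), lev)
      if (anyNA(yval))
        stop("validation labels contain classes absent from training")
      Xtr <- st$X; ytr <- y_all
    } else if (is.numeric(validation) && validation > 0) {
      n <- length(y_all)
      nval <- max(1L, round(validation * n))
      vidx <- sample.int(n, nval)
      Xval <- st$X[, , , vidx, drop = FALSE]; yval <- y_all[vidx]
      Xtr <- st$X[, , , -vidx, drop = FALSE]; ytr <- y_all[-vidx]
    } else {
      Xval <- NULL; yval <- NULL
      Xtr <- st$X; ytr <- y_all
    }
    if (length(unique(ytr)) != length(lev))
      stop("after the validation carve-out the training split does not cover ",
           "every class; supply more data or an explicit validation set")

    params <- nn_init_params(config)
    opt <- adam_init(params)
    n <- length(ytr)
    best <- list(acc = -Inf, epoch = 0L, params = params)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_accuracy = numeric())
    stall <- 0L
    for (ep in seq_len(max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = batch_size)) {
        take <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- Xtr[, , , take, drop = FALSE]
        yb <- ytr[take]
        fw <- nn_forward(params, Xb, config, keep = TRUE)
        losses <- c(losses, cross_entropy(fw$probs, yb))
        grads <- nn_backward(params, fw, yb, config)
        upd <- adam_step(params, grads, opt, lr = learning_rate)
        params <- upd$params; opt <- upd$state
      }
      vacc <- if (!is.null(Xval)) {
        pv <- .nn_predict_probs(params, Xval, config, batch_size)
        mean(max.col(pv, ties.method = "first") == yval)
      } else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                     val_accuracy = vacc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val acc %s", ep, mean(losses),
                        ifelse(is.na(vacc), "-", sprintf("%.3f", vacc))))
      if (!is.null(Xval)) {
        if (vacc > best$acc) {
          best <- list(acc = vacc, epoch = ep, params = params)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      } else {
        best <- list(acc = NA_real_, epoch = ep, params = params)
      }
    }
  })

  structure(list(params = best$params, config = config, levels = lev,
                 corners = corners, k = k, history = hist,
                 best_epoch = best$epoch, val_accuracy = best$acc,
                 training = list(learning_rate = learning_rate,
                                 batch_size = batch_size,
                                 max_epochs = max_epochs,
                                 patience = patience, seed = seed),
                 call = cl),
            class = "cgrnet")
}

# Batched forward pass returning an (n x n_classes) probability matrix.
.nn_predict_probs <- function(params, X, config, batch_size = 64L) {
  n <- dim(X)[4]
  P <- matrix(0, nrow = n, ncol = config$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    P[take, ] <- nn_forward(params, X[, , , take, drop = FALSE], config)$probs
  }
  P
}

#' Predict host taxa for new sequences or tensors
#'
#' @param object a fitted [cgrnet()] model.
#' @param newdata tensors, DNA strings, or a `DNAStringSet`; sequences are
#'   featurized with the model's k and corner assignment.
#' @param type `"class"` for the top-1 taxon, `"prob"` for the full
#'   probability matrix (rows sum to 1), or `"rank"` for a matrix of class
#'   labels ordered by decreasing probability (ties broken by class index).
#' @param ... unused.
#' @return A character vector (`"class"`), numeric matrix (`"prob"`), or
#'   character matrix (`"rank"`), with one row/entry per input, named by
#'   sequence ID where available.
#' @export
predict.cgrnet <- function(object, newdata,
                           type = c("class", "prob", "rank"), ...) {
  type <- match.arg(type)
  tensors <- .as_tensor_list(newdata, object$k, object$corners)
  st <- .stack_tensors(tensors, k = object$k)
  P <- .nn_predict_probs(object$params, st$X, object$config)
  colnames(P) <- object$levels
  ids <- names(tensors)
  if (is.null(ids))
    ids <- vapply(tensors, function(t) {
      id <- attr(t, "id"); if (is.null(id)) NA_character_ else id
    }, character(1))
  rownames(P) <- ids
  switch(type,
    prob = P,
    class = stats::setNames(object$levels[max.col(P, ties.method = "first")],
                            ids),
    rank = {
      R <- t(apply(P, 1L, function(p)
        object$levels[order(-p, seq_along(p))]))
      rownames(R) <- ids
      R
    })
}

#' @export
print.cgrnet <- function(x, ...) {
  cat("CGR-CNN host classifier\n")
  cat(sprintf("  k = %d (input 3 x %d x %d), %d classes\n",
              x$k, 2^x$k, 2^x$k, x$config$n_classes))
  cat(sprintf("  conv blocks: %s; fc units: %d\n",
              paste(x$config$conv_channels, collapse = ", "),
              x$config$fc_units))
  cat(sprintf("  epochs run: %d; best epoch: %d; validation accuracy: %s\n",
              nrow(x$history), x$best_epoch,
              ifelse(is.na(x$val_accuracy), "-",
                     sprintf("%.3f", x$val_accuracy))))
  invisible(x)
}

#' @export
summary.cgrnet <- function(object, ...) {
  np <- sum(vapply(object$params, length, integer(1)))
  out <- list(k = object$k, config = object$config, levels = object$levels,
              n_parameters = np, history = object$history,
              best_epoch = object$best_epoch,
              val_accuracy = object$val_accuracy,
              training = object$training)
  class(out) <- "summary.cgrnet"
  out
}

#' @export
print.summary.cgrnet <- function(x, ...) {
  cat("CGR-CNN host classifier\n")
  cat(sprintf("  classes (%d): %s\n", length(x$levels),
              paste(utils::head(x$levels, 8), collapse = ", ")))
  cat(sprintf("  trainable parameters: %s\n",
              format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  training: lr %g, batch %d, seed %d\n",
              x$training$learning_rate, x$training$batch_size,
              x$training$seed))
  cat(sprintf("  best epoch %d of %d, validation accuracy %s\n",
              x$best_epoch, nrow(x$history),
              ifelse(is.na(x$val_accuracy), "-",
                     sprintf("%.3f", x$val_accuracy))))
  invisible(x)
}

#' @export
coef.cgrnet <- function(object, ...) object$params

#' @export
plot.cgrnet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "Cross-entropy loss", ...)
  if (!all(is.na(h$val_accuracy))) {
    plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
         ylab = "validation accuracy", main = "Model selection", ylim = c(0, 1),
         ...)
    graphics::abline(v = x$best_epoch, lty = 2)
  }
  invisible(x)
}

#' Save / load a fitted model
#'
#' The checkpoint is a single self-describing file: weights, class label map,
#' architecture, k and corner assignment, so prediction needs nothing else.
#'
#' @param object a fitted `cgrnet` model.
#' @param path file path (conventionally `.rds`).
#' @return `load_cgrnet()` returns the model; `save_cgrnet()` its path,
#'   invisibly.
#' @export
save_cgrnet <- function(object, path) {
  stopifnot(inherits(object, "cgrnet"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_cgrnet
#' @export
load_cgrnet <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "cgrnet"))
    stop("file does not contain a cgrnet model checkpoint")
  obj
}
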