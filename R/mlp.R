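#' Network configuration for the MPA predictor
#'
#' Hyperparameters of the feed-forward MPA regression network: two hidden
#' layers of 10 and 7 rectified-linear nodes, one linear output node, adaptive
#' moment estimation (Adam) on the mean-squared-error loss, and early stopping
#' on a held-out validation split with best-weights restore after 50 epochs
#' without improvement. Defaults follow the published defaults of the Adam
#' optimizer (learning rate 1e-3, beta1 0.9, beta2 0.999) and a minibatch
#' size of 32.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param learning_rate,beta1,beta2,epsilon Adam parameters.
#' @param batch_size minibatch size.
#' @param max_epochs upper bound on training epochs.
#' @param patience epochs without validation-loss improvement before stopping.
#' @param val_fraction fraction of the training set held out (seeded) for
#'   early-stopping validation.
#' @return A named list of class `mlp_config`.
#' @export
mlp_config <- function(hidden_sizes = c(10, 7), learning_rate = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       batch_size = 32, max_epochs = 5000, patience = 50,
                       val_fraction = 0.2) {
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
            learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, val_fraction > 0, val_fraction < 1)
  structure(
    list(hidden_sizes = as.integer(hidden_sizes), learning_rate = learning_rate,
         beta1 = beta1, beta2 = beta2, epsilon = epsilon,
         batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), val_fraction = val_fraction),
    class = "mlp_config"
  )
}

relu <- function(x) x * (x > 0)

mlp_forward <- function(w, x) {
  h <- x
  acts <- list()
  n_layers <- length(w$W)
  for (l in seq_len(n_layers - 1L)) {
    h <- relu(sweep(h %*% w$W[[l]], 2, w$b[[l]], `+`))
    acts[[l]] <- h
  }
  out <- sweep(h %*% w$W[[n_layers]], 2, w$b[[n_layers]], `+`)
  list(yhat = out[, 1], acts = acts)
}

mlp_loss <- function(w, x, y) mean((mlp_forward(w, x)$yhat - y)^2)

#' Train the abbreviated-protocol MPA network
#'
#' Fits the feed-forward network of [mlp_config()] to predict full-protocol
#' MPA from abbreviated-protocol features. Features are z-scored (columns
#' with zero variance are centered and left on unit scale) and the target is
#' z-scored for training and inverse-transformed at prediction. A seeded
#' validation split of the training data drives early stopping: training
#' stops after `patience` epochs without validation-loss improvement and the
#' weights achieving the best validation loss are restored. Fully
#' reproducible given `seed`.
#'
#' @param features data frame of predictors (a `patient_id` column, if
#'   present, is dropped); one row per training patient.
#' @param target positive numeric vector of reference MPA values (mCi).
#' @param config an [mlp_config()].
#' @param seed integer seed for initialization, the validation split and
#'   minibatch shuffling.
#' @return An object of class `mpa_mlp` with weights, scalers, per-epoch
#'   training history and the config. Supports `predict()`,
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
train_mpa_model <- function(features, target, config = mlp_config(), seed = 1) {
  x <- as.matrix(dplyr::select(tibble::as_tibble(features),
                               -dplyr::any_of("patient_id")))
  storage.mode(x) <- "double"
  y <- as.numeric(target)
  n <- nrow(x)
  if (n < 2L) stop("need >= 2 training examples", call. = FALSE)
  if (length(y) != n) stop("features and target lengths differ", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("target MPA values must be finite and > 0", call. = FALSE)
  }
  if (stats::sd(y) < 1e-12) {
    stop("degenerate constant target: nothing to learn", call. = FALSE)
  }

  x_center <- colMeans(x)
  x_scale <- apply(x, 2, stats::sd)
  x_scale[x_scale < 1e-12] <- 1 # zero-variance features map to 0
  xs <- sweep(sweep(x, 2, x_center), 2, x_scale, `/`)
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  ys <- (y - y_center) / y_scale

  set.seed(seed)
  sizes <- c(ncol(x), config$hidden_sizes, 1L)
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  w <- list(
    W = lapply(seq_len(length(sizes) - 1L),
               function(l) glorot(sizes[l], sizes[l + 1L])),
    b = lapply(seq_len(length(sizes) - 1L), function(l) numeric(sizes[l + 1L]))
  )
  m <- list(W = lapply(w$W, function(z) z * 0), b = lapply(w$b, function(z) z * 0))
  v <- m

  perm <- sample.int(n)
  n_val <- max(1L, floor(config$val_fraction * n))
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  if (length(tr_idx) < 1L) stop("training split is empty", call. = FALSE)
  x_tr <- xs[tr_idx, , drop = FALSE]; y_tr <- ys[tr_idx]
  x_val <- xs[val_idx, , drop = FALSE]; y_val <- ys[val_idx]

  n_layers <- length(w$W)
  lr <- config$learning_rate; b1 <- config$beta1; b2 <- config$beta2
  eps <- config$epsilon
  step <- 0L
  best_val <- Inf; best_w <- w; best_epoch <- 0L; wait <- 0L
  history <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nrow(x_tr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bi in batches) {
      xb <- x_tr[bi, , drop = FALSE]; yb <- y_tr[bi]
      nb <- length(bi)
      # forward with cached activations
      fwd <- mlp_forward(w, xb)
      delta <- matrix(2 * (fwd$yhat - yb) / nb, ncol = 1)
      gW <- vector("list", n_layers); gb <- vector("list", n_layers)
      for (l in rev(seq_len(n_layers))) {
        h_in <- if (l == 1L) xb else fwd$acts[[l - 1L]]
        gW[[l]] <- crossprod(h_in, delta)
        gb[[l]] <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(w$W[[l]])) * (fwd$acts[[l - 1L]] > 0)
        }
      }
      step <- step + 1L
      corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
      for (l in seq_len(n_layers)) {
        m$W[[l]] <- b1 * m$W[[l]] + (1 - b1) * gW[[l]]
        v$W[[l]] <- b2 * v$W[[l]] + (1 - b2) * gW[[l]]^2
        w$W[[l]] <- w$W[[l]] - lr * (m$W[[l]] / corr1) /
          (sqrt(v$W[[l]] / corr2) + eps)
        m$b[[l]] <- b1 * m$b[[l]] + (1 - b1) * gb[[l]]
        v$b[[l]] <- b2 * v$b[[l]] + (1 - b2) * gb[[l]]^2
        w$b[[l]] <- w$b[[l]] - lr * (m$b[[l]] / corr1) /
          (sqrt(v$b[[l]] / corr2) + eps)
      }
    }
    train_loss <- mlp_loss(w, x_tr, y_tr)
    val_loss <- mlp_loss(w, x_val, y_val)
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      stop(sprintf("training diverged at epoch %d (loss train=%g val=%g); %s",
                   epoch, train_loss, val_loss,
                   "try a smaller learning rate"), call. = FALSE)
    }
    history[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                          val_loss = val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss; best_w <- w; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  history <- tibble::as_tibble(do.call(rbind, history[!vapply(history, is.null,
                                                              logical(1))]))
  structure(
    list(
      weights = best_w,
      sizes = sizes,
      feature_names = colnames(x),
      x_center = x_center, x_scale = x_scale,
      y_center = y_center, y_scale = y_scale,
      history = history,
      best_epoch = best_epoch,
      best_val_loss = best_val,
      config = config,
      seed = seed
    ),
    class = "mpa_mlp"
  )
}

#' Predict MPA from abbreviated-protocol features
#'
#' Forward pass of a trained [train_mpa_model()] network, de-standardized to
#' mCi. Predictions are independent of batch composition and order.
#'
#' @param object an `mpa_mlp` model.
#' @param newdata data frame or matrix of features; a data frame is aligned
#'   to the training feature columns by name.
#' @param ... unused.
#' @return Numeric vector of predicted MPA values (mCi).
#' @export
predict.mpa_mlp <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- tibble::as_tibble(newdata)
    if (all(object$feature_names %in% names(newdata))) {
      newdata <- newdata[object$feature_names]
    } else {
      newdata <- dplyr::select(newdata, -dplyr::any_of("patient_id"))
    }
    newdata <- as.matrix(newdata)
  }
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != length(object$x_center)) {
    stop(sprintf("expected %d features, got %d",
                 length(object$x_center), ncol(newdata)), call. = FALSE)
  }
  if (any(!is.finite(newdata))) stop("non-finite feature values", call. = FALSE)
  xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, `/`)
  mlp_forward(object$weights, xs)$yhat * object$y_scale + object$y_center
}

#' Number of trainable parameters of a network
#'
#' @param model an `mpa_mlp` model.
#' @return Integer count of weights plus biases (175 for the default
#'   8-10-7-1 architecture).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "mpa_mlp"))
  sum(vapply(model$weights$W, length, integer(1))) +
    sum(vapply(model$weights$b, length, integer(1)))
}

#' @export
print.mpa_mlp <- function(x, ...) {
  cat(sprintf(
    "<mpa_mlp> %s network, %d parameters; trained %d epochs (best %d, val MSE %.4g)\n",
    paste(x$sizes, collapse = "-"), n_parameters(x),
    nrow(x$history), x$best_epoch, x$best_val_loss
  ))
  invisible(x)
}

#' @export
tidy.mpa_mlp <- function(x, ...) {
  n_layers <- length(x$weights$W)
  tibble::tibble(
    layer = seq_len(n_layers),
    input_dim = x$sizes[-length(x$sizes)],
    output_dim = x$sizes[-1],
    activation = c(rep("relu", n_layers - 1L), "linear"),
    n_weights = vapply(x$weights$W, length, integer(1)),
    n_biases = vapply(x$weights$b, length, integer(1))
  )
}

#' @export
glance.mpa_mlp <- function(x, ...) {
  tibble::tibble(
    architecture = paste(x$sizes, collapse = "-"),
    n_params = n_parameters(x),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss
  )
}

#' @export
autoplot.mpa_mlp <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "series", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE (standardized target)",
                  title = "Training history (dashed: restored best epoch)") +
    ggplot2::theme_minimal()
}

#' Serialize / deserialize a trained model as JSON
#'
#' The model (architecture, scalers, weights, history, config) is stored as
#' plain JSON — no opaque binary — so trained predictors can be versioned and
#' audited.
#'
#' @param model an `mpa_mlp` model.
#' @param path file path for the JSON artifact.
#' @return `write_mpa_model()`: `path`, invisibly. `read_mpa_model()`: the
#'   reconstructed `mpa_mlp` object.
#' @export
write_mpa_model <- function(model, path) {
  stopifnot(inherits(model, "mpa_mlp"))
  payload <- list(
    sizes = model$sizes,
    feature_names = model$feature_names,
    weights = model$weights$W,
    biases = model$weights$b,
    x_center = as.list(model$x_center), x_scale = as.list(model$x_scale),
    y_center = model$y_center, y_scale = model$y_scale,
    history = model$history,
    best_epoch = model$best_epoch,
    best_val_loss = model$best_val_loss,
    config = unclass(model$config),
    seed = model$seed
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mpa_model
#' @export
read_mpa_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- list(
    W = lapply(p$weights, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
      unname(m)
    }),
    b = lapply(p$biases, as.numeric)
  )
  structure(
    list(
      weights = w,
      sizes = as.integer(p$sizes),
      feature_names = p$feature_names,
      x_center = unlist(p$x_center), x_scale = unlist(p$x_scale),
      y_center = p$y_center, y_scale = p$y_scale,
      history = tibble::as_tibble(p$history),
      best_epoch = p$best_epoch,
      best_val_loss = p$best_val_loss,
      config = do.call(mlp_config, p$config[names(p$config) != "hidden_sizes"] |>
                         c(list(hidden_sizes = p$config$hidden_sizes))),
      seed = p$seed
    ),
    class = "mpa_mlp"
  )
}
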