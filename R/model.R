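# Dense neural classifier: sigmoid-output multilayer perceptron with batch
# normalization, LeakyReLU and dropout in every hidden block, trained with
# Adam on binary cross-entropy under early stopping, learning-rate
# reduction and best-checkpoint restoration. Implemented with base matrix
# algebra (BLAS matmuls); no external deep-learning runtime.

#' Model configuration for the pair classifier
#'
#' The published architecture: four hidden layers of 512/256/128/64 units,
#' each dense layer followed by batch normalization, LeakyReLU (alpha 0.1)
#' and dropout at rate 0.3, ending in a single sigmoid unit trained with
#' Adam on binary cross-entropy. Optimizer and schedule settings that the
#' architecture leaves open (learning rate, batch size, epochs, patiences,
#' validation fraction) default to common practice and are fully
#' configurable.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param leaky_alpha Negative-slope coefficient of LeakyReLU. Default 0.1.
#' @param dropout_rate Dropout probability after each hidden block, in
#'   \[0, 1). Default 0.3.
#' @param learning_rate Initial Adam learning rate. Default 1e-3.
#' @param batch_size Minibatch size. Default 64.
#' @param max_epochs Upper bound on training epochs. Default 200.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping. Default 20.
#' @param lr_reduce_factor Multiplier applied to the learning rate after
#'   `lr_reduce_patience` stagnant epochs. Default 0.5.
#' @param lr_reduce_patience Stagnant epochs before a learning-rate
#'   reduction. Default 10.
#' @param validation_fraction Stratified fraction of the training rows held
#'   out to monitor validation loss. Default 0.1.
#' @param seed Integer seed governing weight initialization, shuffling, the
#'   validation split and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(hidden_sizes = c(512L, 256L, 128L, 64L),
                         leaky_alpha = 0.1,
                         dropout_rate = 0.3,
                         learning_rate = 1e-3,
                         batch_size = 64L,
                         max_epochs = 200L,
                         early_stop_patience = 20L,
                         lr_reduce_factor = 0.5,
                         lr_reduce_patience = 10L,
                         validation_fraction = 0.1,
                         seed = 1L) {
  if (length(hidden_sizes) == 0L || any(hidden_sizes < 1)) {
    stop_input("hidden_sizes must be a nonempty vector of positive integers")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_input("dropout_rate must be in [0, 1)")
  }
  if (leaky_alpha <= 0) stop_input("leaky_alpha must be > 0")
  if (validation_fraction < 0 || validation_fraction >= 0.5) {
    stop_input("validation_fraction must be in [0, 0.5)")
  }
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 leaky_alpha = leaky_alpha, dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Trainable parameter count of the classifier, in closed form
#'
#' Sums dense weights and biases plus the two batch-norm affine vectors
#' (scale and shift) per hidden layer.
#'
#' @param input_dim Input dimension.
#' @param hidden_sizes Hidden-layer widths.
#' @return Integer parameter count.
#' @export
#' @examples
#' mlp_parameter_count(10, 4)  # 10*4 + 4 dense + 2*4 batch-norm + 4*1 + 1
mlp_parameter_count <- function(input_dim, hidden_sizes) {
  prev <- input_dim
  total <- 0
  for (h in hidden_sizes) {
    total <- total + prev * h + h + 2 * h
    prev <- h
  }
  total + prev * 1 + 1
}

#' Build the untrained pair classifier
#'
#' Initializes the network `input -> [dense(h) -> batch norm ->
#' LeakyReLU -> dropout] per hidden width -> dense(1) -> sigmoid` with
#' He-scaled Gaussian weights (seeded from `config$seed`).
#'
#' @param input_dim Number of input features (>= 1).
#' @param config A [model_config()].
#' @return An object of class `ppi_mlp` holding the layer parameters.
#' @export
build_classifier <- function(input_dim, config = model_config()) {
  if (length(input_dim) != 1L || input_dim < 1) {
    stop_input("input_dim must be a positive integer")
  }
  input_dim <- as.integer(input_dim)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  prev <- input_dim
  layers <- list()
  for (h in config$hidden_sizes) {
    layers[[length(layers) + 1L]] <- list(
      W = matrix(stats::rnorm(prev * h, sd = sqrt(2 / prev)), prev, h),
      b = numeric(h),
      gamma = rep(1, h), beta = numeric(h),
      r_mean = numeric(h), r_var = rep(1, h))
    prev <- h
  }
  out <- list(W = matrix(stats::rnorm(prev, sd = sqrt(1 / prev)), prev, 1),
              b = 0)
  structure(list(layers = layers, out = out, input_dim = input_dim,
                 config = config, trained = FALSE),
            class = "ppi_mlp")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.ppi_mlp <- function(x, ...) {
  cat("<ppi_mlp> ", x$input_dim, " -> ",
      paste(x$config$hidden_sizes, collapse = " -> "), " -> 1 (sigmoid), ",
      mlp_parameter_count(x$input_dim, x$config$hidden_sizes),
      " trainable parameters", if (isTRUE(x$trained)) ", trained" else "",
      "\n", sep = "")
  invisible(x)
}

.leaky <- function(z, alpha) ifelse(z > 0, z, alpha * z)
.bn_eps <- 1e-5

# Forward pass. training = TRUE uses batch statistics and dropout and
# returns caches for backprop; training = FALSE uses running statistics.
.mlp_forward <- function(net, x, cfg, training = FALSE) {
  caches <- vector("list", length(net$layers))
  a <- x
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    z <- a %*% ly$W
    z <- sweep(z, 2, ly$b, "+")
    if (training) {
      mu <- colMeans(z)
      vr <- colMeans(sweep(z, 2, mu, "-")^2)
      zc <- sweep(z, 2, mu, "-")
      zhat <- sweep(zc, 2, sqrt(vr + .bn_eps), "/")
    } else {
      mu <- ly$r_mean; vr <- ly$r_var
      zhat <- sweep(sweep(z, 2, mu, "-"), 2, sqrt(vr + .bn_eps), "/")
    }
    zbn <- sweep(sweep(zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    h <- .leaky(zbn, cfg$leaky_alpha)
    if (training && cfg$dropout_rate > 0) {
      mask <- matrix(stats::runif(length(h)) >= cfg$dropout_rate,
                     nrow(h), ncol(h)) / (1 - cfg$dropout_rate)
      hd <- h * mask
    } else {
      mask <- NULL
      hd <- h
    }
    caches[[l]] <- list(a_in = a, z = z, mu = mu, vr = vr, zhat = zhat,
                        zbn = zbn, mask = mask)
    a <- hd
  }
  logit <- as.numeric(a %*% net$out$W + net$out$b)
  p <- 1 / (1 + exp(-logit))
  list(p = p, a_last = a, caches = caches)
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# One Adam minibatch step; returns updated net and adam state.
.mlp_train_step <- function(net, adam, xb, yb, cfg, lr, t) {
  fw <- .mlp_forward(net, xb, cfg, training = TRUE)
  m <- nrow(xb)
  # output layer gradient (BCE + sigmoid): dL/dlogit = (p - y) / m
  dlogit <- matrix((fw$p - yb) / m, ncol = 1)
  grads <- list(out = list(W = t(fw$a_last) %*% dlogit,
                           b = sum(dlogit)),
                layers = vector("list", length(net$layers)))
  da <- dlogit %*% t(net$out$W)
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    ca <- fw$caches[[l]]
    if (!is.null(ca$mask)) da <- da * ca$mask
    dh <- da * ifelse(ca$zbn > 0, 1, cfg$leaky_alpha)
    dgamma <- colSums(dh * ca$zhat)
    dbeta <- colSums(dh)
    dzhat <- sweep(dh, 2, ly$gamma, "*")
    inv_sd <- 1 / sqrt(ca$vr + .bn_eps)
    # batch-norm backward (batch statistics)
    dz <- sweep(dzhat -
                  matrix(colMeans(dzhat), m, length(ly$b), byrow = TRUE) -
                  sweep(ca$zhat, 2, colMeans(dzhat * ca$zhat), "*"),
                2, inv_sd, "*")
    grads$layers[[l]] <- list(W = t(ca$a_in) %*% dz, b = colSums(dz),
                              gamma = dgamma, beta = dbeta)
    # update running statistics (momentum 0.9)
    net$layers[[l]]$r_mean <- 0.9 * ly$r_mean + 0.1 * ca$mu
    net$layers[[l]]$r_var <- 0.9 * ly$r_var +
      0.1 * ca$vr * m / max(m - 1, 1)
    if (l > 1L) da <- dz %*% t(ly$W)
  }
  upd <- function(param, g, st) {
    st$m <- 0.9 * st$m + 0.1 * g
    st$v <- 0.999 * st$v + 0.001 * g^2
    mhat <- st$m / (1 - 0.9^t)
    vhat <- st$v / (1 - 0.999^t)
    list(param = param - lr * mhat / (sqrt(vhat) + 1e-8), st = st)
  }
  for (l in seq_along(net$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      u <- upd(net$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               adam$layers[[l]][[nm]])
      net$layers[[l]][[nm]] <- u$param
      adam$layers[[l]][[nm]] <- u$st
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(net$out[[nm]], grads$out[[nm]], adam$out[[nm]])
    net$out[[nm]] <- u$param
    adam$out[[nm]] <- u$st
  }
  loss <- .bce(fw$p, yb)
  list(net = net, adam = adam, loss = loss)
}

.adam_init <- function(net) {
  zero_like <- function(p) list(m = p * 0, v = p * 0)
  list(layers = lapply(net$layers, function(ly) {
    lapply(ly[c("W", "b", "gamma", "beta")], zero_like)
  }),
  out = lapply(net$out[c("W", "b")], zero_like))
}

#' Train the pair classifier
#'
#' Fits a standardizer on the supplied training rows, splits off a
#' stratified validation fraction, and optimizes binary cross-entropy with
#' Adam. Validation loss is monitored every epoch: the best weights are
#' checkpointed and restored at the end, the learning rate is multiplied by
#' `lr_reduce_factor` after `lr_reduce_patience` stagnant epochs, and
#' training stops after `early_stop_patience` stagnant epochs or at
#' `max_epochs`. Fully deterministic given `config$seed`.
#'
#' @param model An untrained [build_classifier()] (built automatically from
#'   `ncol(x)` when `NULL`).
#' @param x Numeric feature matrix (pairs x features), unstandardized.
#' @param y Binary labels (0/1), one per row of `x`.
#' @param config A [model_config()]; defaults to the one inside `model`.
#' @param schema Optional feature schema (tibble) stored for compatibility
#'   checks at prediction time.
#' @return An object of class `ppi_model`: the best-checkpoint network with
#'   its attached standardizer, per-epoch `history` tibble (train loss,
#'   validation loss, learning rate) and `best_epoch`.
#' @export
train_classifier <- function(model = NULL, x, y, config = NULL,
                             schema = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop_input("rows of x must match length of y")
  if (!all(y %in% c(0L, 1L))) stop_input("labels must be 0/1")
  if (length(unique(y)) < 2L) {
    stop_training("training labels contain a single class")
  }
  if (is.null(model)) {
    model <- build_classifier(ncol(x), config %||% model_config())
  }
  cfg <- config %||% model$config
  if (ncol(x) != model$input_dim) {
    stop_dimension(paste0("model expects ", model$input_dim,
                          " features, got ", ncol(x)))
  }
  std <- fit_standardizer(x)
  xs <- apply_standardizer(std, x)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)

  # stratified validation split
  n <- nrow(xs)
  val_idx <- integer(0)
  if (cfg$validation_fraction > 0) {
    for (cl in c(0L, 1L)) {
      members <- which(y == cl)
      n_val <- max(1L, round(length(members) * cfg$validation_fraction))
      val_idx <- c(val_idx, members[sample.int(length(members), n_val)])
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  x_tr <- xs[tr_idx, , drop = FALSE]; y_tr <- y[tr_idx]
  x_val <- xs[val_idx, , drop = FALSE]; y_val <- y[val_idx]
  monitor_val <- length(val_idx) > 0L

  net <- model[c("layers", "out")]
  adam <- .adam_init(net)
  lr <- cfg$learning_rate
  t <- 0L
  best_loss <- Inf
  best_net <- net
  best_epoch <- 0L
  stale <- 0L
  lr_stale <- 0L
  history <- vector("list", cfg$max_epochs)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(length(y_tr))
    starts <- seq(1L, length(ord), by = cfg$batch_size)
    # avoid a trailing singleton batch (batch norm needs >= 2 rows)
    if (length(starts) > 1L && length(ord) - starts[length(starts)] == 0L) {
      starts <- starts[-length(starts)]
    }
    ep_losses <- numeric(length(starts))
    for (s in seq_along(starts)) {
      from <- starts[s]
      to <- if (s < length(starts)) starts[s + 1L] - 1L else length(ord)
      bi <- ord[from:to]
      t <- t + 1L
      step <- .mlp_train_step(net, adam, x_tr[bi, , drop = FALSE], y_tr[bi],
                              cfg, lr, t)
      net <- step$net; adam <- step$adam
      ep_losses[s] <- step$loss
    }
    train_loss <- mean(ep_losses)
    if (!is.finite(train_loss)) {
      stop_training(paste0("non-finite training loss at epoch ", epoch))
    }
    monitored <- if (monitor_val) {
      .bce(.mlp_forward(net, x_val, cfg, training = FALSE)$p, y_val)
    } else train_loss
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss,
      val_loss = if (monitor_val) monitored else NA_real_,
      learning_rate = lr)
    if (monitored < best_loss - 1e-9) {
      best_loss <- monitored
      best_net <- net
      best_epoch <- epoch
      stale <- 0L
      lr_stale <- 0L
    } else {
      stale <- stale + 1L
      lr_stale <- lr_stale + 1L
      if (lr_stale >= cfg$lr_reduce_patience) {
        lr <- lr * cfg$lr_reduce_factor
        lr_stale <- 0L
      }
      if (stale >= cfg$early_stop_patience) break
    }
  }

  structure(list(layers = best_net$layers, out = best_net$out,
                 input_dim = model$input_dim, config = cfg,
                 standardizer = std,
                 history = dplyr::bind_rows(history),
                 best_epoch = best_epoch, best_val_loss = best_loss,
                 schema = schema, trained = TRUE),
            class = c("ppi_model", "ppi_mlp"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict interaction probabilities
#'
#' Applies the model's own standardizer to the raw feature rows and returns
#' the sigmoid probability of interaction plus the thresholded label
#' (probability >= 0.5 maps to 1).
#'
#' @param object A trained `ppi_model` from [train_classifier()].
#' @param newdata Numeric feature matrix with the model's input dimension.
#' @param ... Unused.
#' @return A tibble with columns `prob` and `label`, one row per input row.
#' @export
predict.ppi_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_dim) {
    stop_dimension(paste0("model expects ", object$input_dim,
                          " features, got ", ncol(newdata)))
  }
  sch <- attr(newdata, "schema")
  if (!is.null(sch) && !is.null(object$schema) &&
      !identical(sch$block, object$schema$block)) {
    stop_schema("feature schema of newdata does not match the trained model")
  }
  xs <- apply_standardizer(object$standardizer, newdata)
  p <- .mlp_forward(object[c("layers", "out")], xs, object$config,
                    training = FALSE)$p
  tibble::tibble(prob = p, label = as.integer(p >= 0.5))
}

#' @exportS3Method generics::tidy
tidy.ppi_model <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.ppi_model <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_learning_rate = x$history$learning_rate[nrow(x$history)],
    n_parameters = mlp_parameter_count(x$input_dim, x$config$hidden_sizes))
}

#' @exportS3Method ggplot2::autoplot
autoplot.ppi_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "Epoch", y = "Binary cross-entropy",
                  colour = NULL, title = "Training history",
                  subtitle = "Dashed line: restored checkpoint") +
    ggplot2::theme_minimal()
}

# actual trainable parameter count of a built network (used in tests
# against the closed form)
.mlp_count_actual <- function(model) {
  n <- 0
  for (ly in model$layers) {
    n <- n + length(ly$W) + length(ly$b) + length(ly$gamma) + length(ly$beta)
  }
  n + length(model$out$W) + length(model$out$b)
}
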