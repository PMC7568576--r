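# Minimal 2-D CNN engine: batched im2col convolutions, non-overlapping
# max pooling, dense layers, ReLU/sigmoid, binary cross-entropy, Adam.
# Spatial activations are stored as (positions*batch) x channels
# matrices (positions column-major over H x W), so convolution is one
# gather plus one BLAS matmul per layer.

#' Training configuration for the scalogram CNN
#'
#' @param epochs maximum training epochs per fit.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size (default 8e-4).
#' @param folds cross-validation folds on the non-held-out data.
#' @param holdout_ratio fraction of images held out untouched for the
#'   final test metrics.
#' @param patience early-stopping patience (epochs without validation
#'   improvement) when a validation set is available.
#' @param seed integer seed fixing splits, initialization and shuffling.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(epochs = 12, batch_size = 32, learning_rate = 8e-4,
                       folds = 10, holdout_ratio = 0.2, patience = 3,
                       seed = 1) {
  stopifnot(learning_rate > 0, holdout_ratio > 0, holdout_ratio < 1,
            epochs >= 1, folds >= 2)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, folds = folds,
                 holdout_ratio = holdout_ratio, patience = patience,
                 seed = seed), class = "cnn_config")
}

conv_geom <- function(h, w, c_in, kh, kw, sh, sw) {
  oh <- floor((h - kh) / sh) + 1
  ow <- floor((w - kw) / sw) + 1
  if (oh < 1 || ow < 1) {
    abort("output shape underflow", class = "cardiowave_shape_underflow")
  }
  p_out <- oh * ow
  # spatial gather indices: column j = (dx * kh + dy) + 1
  idx <- matrix(0L, p_out, kh * kw)
  y_out <- rep(seq_len(oh), times = ow)
  x_out <- rep(seq_len(ow), each = oh)
  j <- 0L
  for (dx in 0:(kw - 1)) {
    for (dy in 0:(kh - 1)) {
      j <- j + 1L
      idx[, j] <- ((x_out - 1L) * sw + dx) * h + (y_out - 1L) * sh + dy + 1L
    }
  }
  list(h = h, w = w, c_in = c_in, kh = kh, kw = kw, oh = oh, ow = ow,
       p_in = h * w, p_out = p_out, idx = idx)
}

init_network <- function(spec, seed) {
  h <- spec$input_hwc[1]; w <- spec$input_hwc[2]; c_in <- spec$input_hwc[3]
  flat <- NA_integer_
  layers <- vector("list", length(spec$layers))
  with_seed(seed, {
    for (i in seq_along(spec$layers)) {
      ly <- spec$layers[[i]]
      st <- list(kind = ly$kind)
      if (ly$kind == "CONV2D") {
        g <- conv_geom(h, w, c_in, ly$kernel_hw[1], ly$kernel_hw[2],
                       ly$stride_hw[1], ly$stride_hw[2])
        fan_in <- g$kh * g$kw * c_in
        st$geom <- g
        st$W <- matrix(rnorm(fan_in * ly$filters, sd = sqrt(2 / fan_in)),
                       fan_in, ly$filters)
        st$b <- numeric(ly$filters)
        h <- g$oh; w <- g$ow; c_in <- ly$filters
      } else if (ly$kind == "MAXPOOL2D") {
        g <- conv_geom(h, w, c_in, ly$kernel_hw[1], ly$kernel_hw[2],
                       ly$stride_hw[1], ly$stride_hw[2])
        st$geom <- g
        h <- g$oh; w <- g$ow
      } else if (ly$kind == "FLATTEN") {
        st$p <- h * w; st$c <- c_in
        flat <- h * w * c_in
      } else if (ly$kind == "DENSE") {
        d_in <- if (!is.na(flat)) flat else h * w * c_in
        st$W <- matrix(rnorm(d_in * ly$units, sd = sqrt(2 / d_in)),
                       d_in, ly$units)
        st$b <- numeric(ly$units)
        flat <- ly$units
      } else if (ly$kind == "ACTIVATION") {
        st$fun <- ly$fun
      }
      layers[[i]] <- st
    }
  })
  structure(list(layers = layers, input_hwc = spec$input_hwc),
            class = "cnn_model")
}

#' Count the parameters actually held by an instantiated model
#'
#' Sums the lengths of every weight and bias array of a [cnn_model]
#' built by the trainer; serves as an independent cross-check of
#' [infer_shapes_and_params()].
#'
#' @param model a `cnn_model` (internal trainer state, returned in
#'   `train_cnn()` output).
#' @return integer parameter count.
#' @export
count_model_params <- function(model) {
  sum(vapply(model$layers, function(st) {
    length(st$W %||% numeric(0)) + length(st$b %||% numeric(0))
  }, numeric(1)))
}

# expand spatial gather indices across a batch
batch_rows <- function(idx_col, p_in, B) {
  rep(idx_col, times = B) + rep((seq_len(B) - 1L) * p_in, each = length(idx_col))
}

# per-(layer, batch-size) cache of batch-expanded gather indices
get_rows <- function(cache, key, g, B) {
  found <- cache[[key]]
  if (!is.null(found)) return(found)
  rows <- lapply(seq_len(ncol(g$idx)), function(j)
    batch_rows(g$idx[, j], g$p_in, B))
  cache[[key]] <- rows
  rows
}

cnn_forward <- function(model, M, B, train = TRUE,
                        cache_env = new.env(parent = emptyenv())) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    st <- model$layers[[i]]
    if (st$kind == "CONV2D") {
      g <- st$geom
      kk <- ncol(g$idx)
      rows <- get_rows(cache_env, paste0(i, "_", B), g, B)
      col <- matrix(0, g$p_out * B, kk * g$c_in)
      for (j in seq_len(kk)) {
        col[, (j - 1L) * g$c_in + seq_len(g$c_in)] <-
          M[rows[[j]], , drop = FALSE]
      }
      M <- col %*% st$W
      M <- M + rep(st$b, each = nrow(M))
      if (train) caches[[i]] <- list(col = col, rows = rows)
    } else if (st$kind == "MAXPOOL2D") {
      g <- st$geom
      kk <- ncol(g$idx)
      rows <- get_rows(cache_env, paste0(i, "_", B), g, B)
      cur <- NULL; argrows <- NULL
      for (j in seq_len(kk)) {
        v <- M[rows[[j]], , drop = FALSE]
        rows_mat <- matrix(rows[[j]], nrow(v), ncol(v))
        if (is.null(cur)) {
          cur <- v
          argrows <- rows_mat
        } else {
          upd <- v > cur
          cur[upd] <- v[upd]
          argrows[upd] <- rows_mat[upd]
        }
      }
      caches[[i]] <- list(argrows = argrows, p_in = g$p_in,
                          n_in_rows = g$p_in * B, c = ncol(cur))
      M <- cur
    } else if (st$kind == "ACTIVATION") {
      if (st$fun == "relu") {
        mask <- M > 0
        M <- M * mask
        if (train) caches[[i]] <- list(mask = mask)
      } else {
        M <- 1 / (1 + exp(-M))
        caches[[i]] <- list(out = M)
      }
    } else if (st$kind == "FLATTEN") {
      p <- st$p; cc <- st$c
      a <- array(M, c(p, B, cc))
      M <- t(matrix(aperm(a, c(1, 3, 2)), p * cc, B))
      caches[[i]] <- list(p = p, c = cc)
    } else if (st$kind == "DENSE") {
      if (train) caches[[i]] <- list(x = M)
      M <- M %*% st$W
      M <- M + rep(st$b, each = nrow(M))
    }
  }
  list(out = M, caches = caches)
}

cnn_backward <- function(model, caches, dM, B) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    st <- model$layers[[i]]
    if (st$kind == "DENSE") {
      x <- caches[[i]]$x
      grads[[i]] <- list(dW = crossprod(x, dM), db = colSums(dM))
      dM <- dM %*% t(st$W)
    } else if (st$kind == "ACTIVATION") {
      if (st$fun == "relu") {
        dM <- dM * caches[[i]]$mask
      }
      # sigmoid: gradient folded into the BCE delta at the output
    } else if (st$kind == "FLATTEN") {
      p <- caches[[i]]$p; cc <- caches[[i]]$c
      a <- array(t(dM), c(p, cc, B))
      dM <- matrix(aperm(a, c(1, 3, 2)), p * B, cc)
    } else if (st$kind == "MAXPOOL2D") {
      ca <- caches[[i]]
      dX <- matrix(0, ca$n_in_rows, ca$c)
      for (cc in seq_len(ca$c)) {
        dX[cbind(ca$argrows[, cc], cc)] <- dM[, cc]
      }
      dM <- dX
    } else if (st$kind == "CONV2D") {
      g <- st$geom
      col <- caches[[i]]$col
      grads[[i]] <- list(dW = crossprod(col, dM), db = colSums(dM))
      if (i == 1) next  # nothing below the input needs a gradient
      dcol <- dM %*% t(st$W)
      dX <- matrix(0, g$p_in * B, g$c_in)
      kk <- ncol(g$idx)
      rows <- caches[[i]]$rows
      for (j in seq_len(kk)) {
        cols_j <- (j - 1L) * g$c_in + seq_len(g$c_in)
        dX[rows[[j]], ] <- dX[rows[[j]], ] + dcol[, cols_j, drop = FALSE]
      }
      dM <- dX
    }
  }
  grads
}

images_to_input <- function(images, idx) {
  # images: H x W x N array (single channel); returns (H*W*B) x 1 matrix
  matrix(as.vector(images[, , idx, drop = FALSE]), ncol = 1)
}

cnn_predict_prob <- function(model, images, chunk = 64,
                             cache_env = new.env(parent = emptyenv())) {
  n <- dim(images)[3]
  probs <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    M <- images_to_input(images, idx)
    probs[idx] <- as.numeric(
      cnn_forward(model, M, length(idx), train = FALSE,
                  cache_env = cache_env)$out)
  }
  probs
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

train_network <- function(spec, images, y, config, val_idx = NULL) {
  model <- init_network(spec, config$seed)
  # Adam state per parameterized layer
  opt <- lapply(model$layers, function(st) {
    if (is.null(st$W)) return(NULL)
    list(mW = st$W * 0, vW = st$W * 0, mb = st$b * 0, vb = st$b * 0)
  })
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0
  n <- dim(images)[3]
  train_idx <- setdiff(seq_len(n), val_idx)
  cache_env <- new.env(parent = emptyenv())
  best <- list(loss = Inf, layers = model$layers, epoch = 0)
  bad <- 0
  for (epoch in seq_len(config$epochs)) {
    order_idx <- with_seed(config$seed + 7919L * epoch,
                           sample(train_idx))
    for (start in seq(1, length(order_idx), by = config$batch_size)) {
      bidx <- order_idx[start:min(start + config$batch_size - 1,
                                  length(order_idx))]
      B <- length(bidx)
      M <- images_to_input(images, bidx)
      fw <- cnn_forward(model, M, B, train = TRUE, cache_env = cache_env)
      p <- as.numeric(fw$out)
      dM <- matrix((p - y[bidx]) / B, ncol = 1)
      grads <- cnn_backward(model, fw$caches, dM, B)
      t_step <- t_step + 1
      corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
      for (i in seq_along(model$layers)) {
        if (is.null(grads[[i]])) next
        o <- opt[[i]]
        o$mW <- beta1 * o$mW + (1 - beta1) * grads[[i]]$dW
        o$vW <- beta2 * o$vW + (1 - beta2) * grads[[i]]$dW^2
        o$mb <- beta1 * o$mb + (1 - beta1) * grads[[i]]$db
        o$vb <- beta2 * o$vb + (1 - beta2) * grads[[i]]$db^2
        model$layers[[i]]$W <- model$layers[[i]]$W -
          config$learning_rate * (o$mW / corr1) / (sqrt(o$vW / corr2) + eps)
        model$layers[[i]]$b <- model$layers[[i]]$b -
          config$learning_rate * (o$mb / corr1) / (sqrt(o$vb / corr2) + eps)
        opt[[i]] <- o
      }
    }
    if (length(val_idx)) {
      pv <- cnn_predict_prob(model, images[, , val_idx, drop = FALSE],
                             cache_env = cache_env)
      loss <- bce_loss(pv, y[val_idx])
      if (loss < best$loss - 1e-5) {
        best <- list(loss = loss, layers = model$layers, epoch = epoch)
        bad <- 0
      } else {
        bad <- bad + 1
        if (bad >= config$patience) break
      }
    }
  }
  if (length(val_idx)) model$layers <- best$layers
  model
}

#' Train and evaluate the scalogram CNN
#'
#' Holds out `holdout_ratio` of the images (stratified), runs
#' `folds`-fold cross-validation on the remainder (each fold trained
#' with early stopping on its validation fold), retrains on the full
#' remainder, and reports fold-mean accuracy plus held-out metrics. The
#' network is trained with Adam (learning rate 8e-4 by default) under
#' binary cross-entropy.
#'
#' @param images `H x W x N` array of single-channel images in
#'   `[0, 1]`-ish range (e.g. from [render_image()] or
#'   [simulate_band_images()]).
#' @param labels length-N vector of 0/1 (or a 2-level factor).
#' @param spec an `architecture_spec`; defaults to the custom
#'   architecture re-inferred at the images' size.
#' @param config a [cnn_config()].
#' @return an `evaluation_report` with scheme `"KFOLD"`; extra fields
#'   `fold_accuracies` (length `folds`), `holdout_index`, `model`
#'   (the trained `cnn_model`), `probabilities`.
#' @export
train_cnn <- function(images, labels, spec = NULL, config = cnn_config()) {
  stopifnot(length(dim(images)) == 3)
  n <- dim(images)[3]
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    stopifnot(length(lv) == 2)
    y <- as.integer(as.character(labels) == lv[2])
  } else {
    lv <- c("0", "1")
    y <- as.integer(labels)
  }
  stopifnot(length(y) == n, all(y %in% c(0L, 1L)), length(unique(y)) == 2)
  if (is.null(spec)) {
    spec <- build_custom_architecture(c(dim(images)[1], dim(images)[2], 1))
  }
  if (spec$input_hwc[1] != dim(images)[1] ||
      spec$input_hwc[2] != dim(images)[2]) {
    abort("architecture input shape does not match the images",
          class = "cardiowave_shape_mismatch")
  }

  holdout <- with_seed(config$seed, {
    sort(unlist(lapply(unique(y), function(cl) {
      rows <- which(y == cl)
      sample(rows, round(length(rows) * config$holdout_ratio))
    })))
  })
  rest <- setdiff(seq_len(n), holdout)

  foldid <- split_folds(as.character(y[rest]), config$folds,
                        config$seed + 1L)
  fold_acc <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    tr_local <- rest[foldid != f]
    va_local <- rest[foldid == f]
    sub_idx <- c(tr_local, va_local)
    sub_imgs <- images[, , sub_idx, drop = FALSE]
    model_f <- train_network(spec, sub_imgs, y[sub_idx], config,
                             val_idx = length(tr_local) + seq_along(va_local))
    pv <- cnn_predict_prob(model_f,
                           images[, , va_local, drop = FALSE])
    fold_acc[f] <- mean((pv > 0.5) == y[va_local])
  }

  # final fit on the full remainder, small internal split for early stop
  val_local <- with_seed(config$seed + 2L, {
    unlist(lapply(unique(y[rest]), function(cl) {
      rows <- which(y[rest] == cl)
      sample(rows, max(1, round(0.1 * length(rows))))
    }))
  })
  model <- train_network(spec, images[, , rest, drop = FALSE], y[rest],
                         config, val_idx = val_local)
  prob <- cnn_predict_prob(model, images[, , holdout, drop = FALSE])
  preds <- tibble(
    subject_id = NA_character_,
    truth = lv[y[holdout] + 1L],
    pred = lv[(prob > 0.5) + 1L]
  )
  new_evaluation_report(
    "KFOLD", preds, "CNN",
    list(epochs = config$epochs, batch_size = config$batch_size,
         learning_rate = config$learning_rate),
    config$seed,
    extra = list(fold_accuracies = fold_acc, holdout_index = holdout,
                 model = model, probabilities = prob))
}
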