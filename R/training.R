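#' Training configuration
#'
#' @param optimizer `"adam"`, `"adam_nesterov"` (Adam with Nesterov
#'   momentum, the default for membrane-potential fitting) or `"adamax"`
#'   (the default for the multicompartment surrogate).
#' @param lr learning rate; defaults to 1e-3 (adam family) or 2e-3
#'   (adamax).
#' @param loss `"mse"` (needed once action potentials are present, to put
#'   weight on the rare spike samples) or `"mae"` (sufficient for passive
#'   traces).
#' @param clip_norm global gradient-norm clip (default 1).
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience in epochs (validation loss).
#' @param seed RNG seed for shuffling and dropout.
#' @param frozen predicate `function(layer) TRUE/FALSE`; frozen layers are
#'   excluded from updates (used by [partial_retrain()]).
#' @param verbose print per-epoch losses?
#' @return a list of class `vc_train_config`.
#' @export
training_config <- function(optimizer = c("adam_nesterov", "adam", "adamax"),
                            lr = NULL, loss = c("mse", "mae"), clip_norm = 1,
                            batch_size = 256, max_epochs = 20, patience = 10,
                            seed = NULL, frozen = NULL, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  lr <- lr %||% if (optimizer == "adamax") 2e-3 else 1e-3
  if (clip_norm <= 0) abort("`clip_norm` must be > 0")
  if (patience > max_epochs) abort("`patience` must be <= `max_epochs`")
  structure(list(optimizer = optimizer, lr = lr, loss = loss,
                 clip_norm = clip_norm, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience, seed = seed,
                 frozen = frozen, verbose = isTRUE(verbose)),
            class = "vc_train_config")
}

loss_value <- function(loss, pred, y) {
  switch(loss,
    mse = mean((pred - y)^2),
    mae = mean(abs(pred - y)))
}

loss_grad <- function(loss, pred, y) {
  switch(loss,
    mse = 2 * (pred - y) / length(y),
    mae = sign(pred - y) / length(y))
}

# --- optimizer -------------------------------------------------------------

opt_init <- function() list(t = 0, m = list(), v = list())

opt_step <- function(model, grads, state, cfg, trainable_mask) {
  # global-norm gradient clipping across all trainable tensors
  sq <- 0
  for (i in seq_along(grads)) {
    if (!trainable_mask[i]) next
    for (g in grads[[i]]) sq <- sq + sum(g^2)
  }
  gn <- sqrt(sq)
  scale <- if (gn > cfg$clip_norm) cfg$clip_norm / gn else 1
  state$t <- state$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (i in seq_along(grads)) {
    if (!trainable_mask[i] || length(grads[[i]]) == 0) next
    key <- as.character(i)
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- lapply(grads[[i]], function(g) array(0, dim(g) %||% length(g)))
      state$v[[key]] <- lapply(grads[[i]], function(g) array(0, dim(g) %||% length(g)))
    }
    for (pn in names(grads[[i]])) {
      g <- grads[[i]][[pn]] * scale
      m <- b1 * state$m[[key]][[pn]] + (1 - b1) * g
      state$m[[key]][[pn]] <- m
      if (cfg$optimizer == "adamax") {
        u <- pmax(b2 * state$v[[key]][[pn]], abs(g))
        state$v[[key]][[pn]] <- u
        delta <- cfg$lr / bc1 * m / (u + eps)
      } else {
        v <- b2 * state$v[[key]][[pn]] + (1 - b2) * g^2
        state$v[[key]][[pn]] <- v
        if (cfg$optimizer == "adam_nesterov") {
          mhat <- (b1 * m / bc1) + ((1 - b1) * g / bc1)
          delta <- cfg$lr * mhat / (sqrt(v / bc2) + eps)
        } else {
          delta <- cfg$lr * (m / bc1) / (sqrt(v / bc2) + eps)
        }
      }
      p <- model$layers[[i]]$params[[pn]]
      model$layers[[i]]$params[[pn]] <- p - array(delta, dim(p) %||% length(p))
    }
  }
  list(model = model, state = state, grad_norm = gn)
}

# evaluate mean loss over an index set in chunks (memory-bounded)
eval_loss <- function(model, ds, idx, loss, chunk = 4096) {
  if (length(idx) == 0) return(NA_real_)
  tot <- 0
  for (start in seq(1, length(idx), by = chunk)) {
    ii <- idx[start:min(start + chunk - 1, length(idx))]
    pred <- model_forward(model, ds$inputs[ii, , , drop = FALSE])$y
    tot <- tot + loss_value(loss, pred, ds$targets[ii, , drop = FALSE]) * length(ii)
  }
  tot / length(idx)
}

#' Train a surrogate model
#'
#' Minibatch gradient training with the configured optimizer, global-norm
#' gradient clipping, and early stopping on validation loss: training stops
#' once the validation loss has not improved for `patience` consecutive
#' epochs, and the best-validation weights are restored. Pass a
#' [curriculum()] to train the three stages sequentially with replay.
#'
#' @param model a `vc_surrogate`.
#' @param data a normalized, split `vc_dataset`, or a `vc_curriculum`.
#' @param config a [training_config()].
#' @return list with `model` (trained, with the dataset's normalization
#'   attached) and `history` (a `vc_history` tibble: stage, epoch,
#'   train/val loss, max gradient norm).
#' @export
train_surrogate <- function(model, data, config = training_config()) {
  stages <- if (inherits(data, "vc_curriculum")) data else {
    structure(list(stages = list(main = data), mix_fraction = 0),
              class = "vc_curriculum")
  }
  with_seed(config$seed, {
    opt <- opt_init()
    hist <- list()
    trainable_mask <- vapply(model$layers, function(l) {
      l$trainable && (is.null(config$frozen) || !isTRUE(config$frozen(l)))
    }, logical(1))
    if (!any(trainable_mask)) abort("frozen predicate leaves no trainable layers")
    for (si in seq_along(stages$stages)) {
      plan <- curriculum_plan(stages, si, config$batch_size)
      ds <- plan$stage
      if (ncol(ds$targets) != model$output_width) {
        abort(sprintf("dataset target width %d does not match model output width %d",
                      ncol(ds$targets), model$output_width))
      }
      tr_idx <- dataset_index(ds, "train")
      val_idx <- dataset_index(ds, "val")
      replay_pool <- purrr::map(plan$replay, function(d) {
        list(ds = d, idx = dataset_index(d, "train"))
      })
      best_val <- Inf; best_params <- NULL; wait <- 0
      for (epoch in seq_len(config$max_epochs)) {
        sh <- sample(tr_idx)
        n_batches <- max(1L, floor(length(sh) / config$batch_size))
        max_gn <- 0; tr_loss_acc <- 0; n_seen <- 0
        for (bi in seq_len(n_batches)) {
          ii <- sh[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, length(sh))]
          x <- ds$inputs[ii, , , drop = FALSE]
          y <- ds$targets[ii, , drop = FALSE]
          if (plan$n_replay > 0) {
            rp <- replay_pool[[sample.int(length(replay_pool), 1)]]
            jj <- sample(rp$idx, min(plan$n_replay, length(rp$idx)))
            x2 <- rp$ds$inputs[jj, , , drop = FALSE]
            y2 <- rp$ds$targets[jj, , drop = FALSE]
            xa <- array(0, c(dim(x)[1] + dim(x2)[1], dim(x)[2], dim(x)[3]))
            xa[seq_len(dim(x)[1]), , ] <- x
            xa[dim(x)[1] + seq_len(dim(x2)[1]), , ] <- x2
            x <- xa; y <- rbind(y, y2)
          }
          fw <- model_forward(model, x, training = TRUE, keep_cache = TRUE)
          tr_loss_acc <- tr_loss_acc + loss_value(config$loss, fw$y, y) * nrow(y)
          n_seen <- n_seen + nrow(y)
          if (!all(is.finite(fw$y))) {
            abort(sprintf("training diverged (non-finite loss) at stage %d epoch %d",
                          si, epoch))
          }
          grads <- model_backward(model, fw$caches, loss_grad(config$loss, fw$y, y))
          st <- opt_step(model, grads, opt, config, trainable_mask)
          model <- st$model; opt <- st$state
          max_gn <- max(max_gn, min(st$grad_norm, config$clip_norm))
        }
        val_loss <- eval_loss(model, ds, val_idx, config$loss)
        hist[[length(hist) + 1]] <- tibble(
          stage = names(stages$stages)[si], epoch = epoch,
          train_loss = tr_loss_acc / n_seen, val_loss = val_loss,
          grad_norm = max_gn)
        if (config$verbose) {
          message(sprintf("[%s] epoch %d train %.3g val %.3g",
                          names(stages$stages)[si], epoch,
                          tr_loss_acc / n_seen, val_loss))
        }
        if (is.finite(val_loss) && val_loss < best_val - 1e-12) {
          best_val <- val_loss
          best_params <- lapply(model$layers, `[[`, "params")
          wait <- 0
        } else {
          wait <- wait + 1
          if (wait >= config$patience) break
        }
      }
      if (!is.null(best_params)) {
        for (i in seq_along(model$layers)) model$layers[[i]]$params <- best_params[[i]]
      }
      last_norm <- ds$norm
    }
    model$norm <- stages$stages[[length(stages$stages)]]$norm
    history <- dplyr::bind_rows(hist)
    class(history) <- c("vc_history", class(history))
    list(model = model, history = history)
  })
}

#' @export
glance.vc_history <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x, .data$stage),
                   epochs = max(.data$epoch),
                   final_train = .data$train_loss[which.max(.data$epoch)],
                   best_val = min(.data$val_loss), .groups = "drop")
}

#' Retrain only the fully connected head of a trained model
#'
#' All layers except those selected by `head_predicate` are frozen
#' (bit-identical before/after); the head is retrained on the new corpus.
#' This is the adaptation route used for biophysical-variant models (e.g.
#' a shifted delayed-rectifier): the convolutional/recurrent feature layers
#' keep their synaptic representation and only the readout adapts.
#'
#' @param model a trained `vc_surrogate`.
#' @param data a normalized, split `vc_dataset`.
#' @param config a [training_config()]; its `frozen` field is derived from
#'   `head_predicate`.
#' @param head_predicate function(layer) identifying the trainable head;
#'   defaults to dense layers whose name starts with `"head"`.
#' @return list with `model` and `history` as in [train_surrogate()].
#' @export
partial_retrain <- function(model, data, config = training_config(),
                            head_predicate = NULL) {
  head_predicate <- head_predicate %||% function(l) {
    l$type %in% c("dense", "td_dense") && grepl("^head", l$name)
  }
  config$frozen <- function(l) !isTRUE(head_predicate(l))
  train_surrogate(model, data, config)
}

#' Post-hoc output bias correction
#'
#' Refits the additive bias of the affine output head on the validation
#' split (closed form: the mean residual), correcting the systematic offset
#' that skewed target distributions induce.
#'
#' @param model a trained `vc_surrogate` whose last layer is the affine head.
#' @param ds a normalized, split `vc_dataset`.
#' @return the model with adjusted head bias.
#' @export
fit_output_bias <- function(model, ds) {
  idx <- dataset_index(ds, "val")
  pred <- model_forward(model, ds$inputs[idx, , , drop = FALSE])$y
  resid <- colMeans(ds$targets[idx, , drop = FALSE] - pred)
  nl <- length(model$layers)
  if (model$layers[[nl]]$type != "dense") abort("last layer is not an affine head")
  model$layers[[nl]]$params$b <- model$layers[[nl]]$params$b + resid
  model
}
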