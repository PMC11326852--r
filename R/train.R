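#' Training configuration
#'
#' @param epochs Number of passes over the kept examples.
#' @param batch_size Mini-batch size; batches are always drawn within one
#'   tensor-size bin, so this must not exceed the smallest kept bin.
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2,adam_eps Adam moment decay rates and guard.
#' @param clip_norm Global gradient-norm ceiling (Inf disables); clipping
#'   keeps large-learning-rate runs out of divergent regions.
#' @param seed Seed for initialization and batch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         clip_norm = Inf, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, clip_norm > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "train_config")
}

clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] - cfg$lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

# Prepare the fixed per-example tensors once (inputs never change during
# training, so their flattened matrices are cached up front).
prepare_training_set <- function(examples, config, recycled = NULL) {
  lapply(seq_along(examples), function(i) {
    ex <- examples[[i]]
    if (!all(ex$patterson$dims == config$grid_dims)) {
      stop("all training examples must share the model grid dims; ",
           "filter to a single tensor-size bin first", call. = FALSE)
    }
    list(id = ex$id,
         X = model_input_matrix(ex, config,
                                recycled = if (!is.null(recycled))
                                  recycled[[ex$id]]),
         partials = lapply(ex$partials$grids,
                           function(g) matrix(as.vector(g$values),
                                              ncol = 1L)),
         target = as.vector(ex$density$values))
  })
}

#' Train the Patterson-to-density model
#'
#' Mini-batch Adam on the weighted MSE + negative-Pearson loss. All
#' randomness (initialization, batch shuffling) is derived from
#' `train_cfg$seed`, so two runs with the same inputs are bit-identical.
#' Training aborts with an error carrying the last finite-loss parameters
#' if the loss diverges to NaN/Inf.
#'
#' @param examples List of `example_record`s from one tensor-size bin.
#' @param config A [model_config] whose `grid_dims` match the examples.
#' @param train_cfg A [train_config].
#' @param loss_cfg A [loss_config].
#' @param params Optional warm-start parameters (default: fresh
#'   initialization from the seed).
#' @param recycled Optional named list (by example id) of previous
#'   predictions for two-channel recycling models.
#' @param verbose Print per-epoch progress.
#' @return A list with `params`, `config`, `history` (data.frame epoch /
#'   loss / mean_pc), `train_cfg`, `loss_cfg`.
#' @export
train_model <- function(examples, config, train_cfg = train_config(),
                        loss_cfg = loss_config(), params = NULL,
                        recycled = NULL, verbose = FALSE) {
  if (length(examples) == 0L) stop("empty dataset", call. = FALSE)
  if (train_cfg$batch_size > length(examples)) {
    stop("batch size exceeds the number of examples in the bin",
         call. = FALSE)
  }
  idx <- model_indices(config)
  prep <- prepare_training_set(examples, config, recycled = recycled)
  if (is.null(params)) params <- init_parameters(config, train_cfg$seed)
  set.seed(train_cfg$seed + 1L)
  state <- adam_init(params)
  n <- length(prep)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        mean_pc = numeric(0))
  last_good <- params
  for (epoch in seq_len(train_cfg$epochs)) {
    order_i <- sample.int(n)
    starts <- seq(1L, n, by = train_cfg$batch_size)
    ep_loss <- 0
    ep_pc <- 0
    ep_n <- 0L
    for (s in starts) {
      batch <- order_i[s:min(s + train_cfg$batch_size - 1L, n)]
      grads <- zero_like(params)
      b_loss <- 0
      for (i in batch) {
        ex <- prep[[i]]
        fwd <- forward_model(ex$X, ex$partials, params, config, idx,
                             want_cache = TRUE)
        ls <- map_loss(fwd$out, ex$target, loss_cfg, gradient = TRUE)
        b_loss <- b_loss + ls$loss
        ep_pc <- ep_pc + ls$pc
        grads <- backward_model(ls$grad / length(batch), fwd$cache, params,
                                config, idx, grads)
      }
      b_loss <- b_loss / length(batch)
      if (!is.finite(b_loss)) {
        stop(structure(class = c("divergence_error", "error", "condition"),
                       list(message = "training diverged to non-finite loss",
                            call = NULL, last_params = last_good)))
      }
      last_good <- params
      grads <- clip_gradients(grads, train_cfg$clip_norm)
      upd <- adam_step(params, grads, state, train_cfg)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + b_loss * length(batch)
      ep_n <- ep_n + length(batch)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = ep_loss / ep_n,
                                mean_pc = ep_pc / ep_n))
    if (verbose && (epoch %% 10L == 0L || epoch == 1L)) {
      cat(sprintf("epoch %4d  loss %.6f  mean PC %.4f\n", epoch,
                  ep_loss / ep_n, ep_pc / ep_n))
    }
  }
  list(params = params, config = config, history = history,
       train_cfg = train_cfg, loss_cfg = loss_cfg)
}

#' Recycling run: retrain with previous predictions as a second channel
#'
#' Trains a freshly initialized two-channel model whose stem sees the
#' Patterson map and the base model's prediction for the same example,
#' channel-concatenated in that fixed order.
#'
#' @param base A fit returned by [train_model()] (or an `xtalformer`
#'   object) whose predictions seed the second channel.
#' @param examples Training examples (each id must receive a base
#'   prediction).
#' @param train_cfg,loss_cfg As in [train_model()]; the seed is offset so
#'   the recycled model starts from a different initialization.
#' @return As [train_model()], with `recycled_from` recording base
#'   predictions by id.
#' @export
recycle_train <- function(base, examples, train_cfg = NULL,
                          loss_cfg = loss_config()) {
  base_fit <- if (inherits(base, "xtalformer")) base$fit else base
  if (is.null(train_cfg)) train_cfg <- base_fit$train_cfg
  idx <- model_indices(base_fit$config)
  preds <- lapply(examples, function(ex) {
    predict_example(ex, base_fit$params, base_fit$config, idx)
  })
  names(preds) <- vapply(examples, `[[`, character(1L), "id")
  cfg2 <- base_fit$config
  cfg2$in_channels <- 2L
  tc2 <- train_cfg
  tc2$seed <- train_cfg$seed + 1000L
  fit <- train_model(examples, cfg2, tc2, loss_cfg, recycled = preds)
  fit$recycled_from <- preds
  fit
}
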