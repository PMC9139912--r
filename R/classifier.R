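#' Classifier hyperparameters
#'
#' Defaults follow the full-scale fine-tuning recipe this harness emulates:
#' dropout 0.2 in the remodeled head, batch size 256 and learning rate
#' 1e-5. Desk-scale experiments on the `tinycnn` typically raise the
#' learning rate (around 1e-3) and train for a few epochs.
#'
#' @param architecture "resnet18" or "tinycnn".
#' @param pretrained if TRUE, `weights_path` must point to a saved parameter
#'   set; no download is ever attempted. The `pretrained = FALSE` path is
#'   fully supported and is what all desk-scale runs use.
#' @param dropout dropout probability in the head, in [0, 1).
#' @param batch_size minibatch size (auto-clamped to the dataset size with a
#'   warning when larger).
#' @param learning_rate Adam step size.
#' @param epochs training epochs (0 is a valid no-op).
#' @param input_size spatial input size; tinycnn requires a multiple of 8.
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @return an object of class `hyperparams`.
#' @export
hyperparams <- function(architecture = c("tinycnn", "resnet18"),
                        pretrained = FALSE,
                        dropout = 0.2,
                        batch_size = 256,
                        learning_rate = 1e-5,
                        epochs = 5,
                        input_size = if (match.arg(architecture) == "resnet18") 224 else 32,
                        seed = 1L) {
  architecture <- match.arg(architecture)
  if (dropout < 0 || dropout >= 1) stop_labeled("bad_hp", "dropout must be in [0, 1)")
  if (batch_size < 1) stop_labeled("bad_hp", "batch_size must be positive")
  if (learning_rate <= 0) stop_labeled("bad_hp", "learning_rate must be positive")
  if (epochs < 0) stop_labeled("bad_hp", "epochs must be >= 0")
  if (architecture == "tinycnn" && input_size %% 8 != 0)
    stop_labeled("bad_hp", "tinycnn input_size must be a multiple of 8")
  structure(list(architecture = architecture, pretrained = pretrained,
                 dropout = dropout, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 input_size = as.integer(input_size), seed = as.integer(seed)),
            class = "hyperparams")
}

basic_block <- function(in_ch, out_ch, stride) {
  main <- list(nn_conv(in_ch, out_ch, 3L, stride = stride, pad = 1L),
               nn_bn(out_ch), nn_relu(),
               nn_conv(out_ch, out_ch, 3L, stride = 1L, pad = 1L),
               nn_bn(out_ch))
  shortcut <- if (stride != 1L || in_ch != out_ch)
    list(nn_conv(in_ch, out_ch, 1L, stride = stride, pad = 0L), nn_bn(out_ch))
  else NULL
  nn_res(main, shortcut)
}

# Modeled classification head shared by both architectures:
# linear -> ReLU -> dropout -> linear to 2 logits.
binary_head <- function(feat_dim, hidden, dropout)
  list(nn_dense(feat_dim, hidden), nn_relu(), nn_dropout(dropout),
       nn_dense(hidden, 2L))

build_layers <- function(hp) {
  if (hp$architecture == "tinycnn") {
    s <- hp$input_size
    c(list(nn_conv(3L, 8L, 3L, pad = 1L), nn_relu(), nn_avgpool(2L),
           nn_conv(8L, 16L, 3L, pad = 1L), nn_relu(), nn_avgpool(2L),
           nn_conv(16L, 32L, 3L, pad = 1L), nn_relu(), nn_avgpool(2L),
           nn_flatten()),
      binary_head((s %/% 8L)^2 * 32L, 64L, hp$dropout))
  } else {
    stages <- list(c(64, 64, 1), c(64, 64, 1),
                   c(64, 128, 2), c(128, 128, 1),
                   c(128, 256, 2), c(256, 256, 1),
                   c(256, 512, 2), c(512, 512, 1))
    c(list(nn_conv(3L, 64L, 7L, stride = 2L, pad = 3L), nn_bn(64L), nn_relu(),
           nn_maxpool(3L, 2L, 1L)),
      lapply(stages, function(s) basic_block(s[1], s[2], s[3])),
      list(nn_gap()),
      binary_head(512L, 128L, hp$dropout))
  }
}

#' Build an (untrained) binary slice classifier
#'
#' `resnet18` is the standard 18-weight-layer residual architecture with
#' its final fully connected layer replaced by a binary head
#' (linear, ReLU, dropout, linear to 2 logits) and every layer trainable.
#' `tinycnn` is a three-block convolutional net (8/16/32 filters, each
#' block conv-ReLU-average-pool) with the identical head, sized for CPU
#' desk-scale experiments. Initialization is deterministic given
#' `hp$seed`.
#'
#' @param hp a [hyperparams()].
#' @param weights_path optional path to parameters saved by
#'   [save_model()]; required when `hp$pretrained` is TRUE.
#' @return an object of class `sliceleak_model`.
#' @export
build_model <- function(hp, weights_path = NULL) {
  stopifnot(inherits(hp, "hyperparams"))
  layers <- with_seed(derive_seed(hp$seed, "init", hp$architecture),
                      build_layers(hp))
  model <- structure(list(architecture = hp$architecture, layers = layers,
                          hp = hp, trained = FALSE, history = list()),
                     class = "sliceleak_model")
  if (isTRUE(hp$pretrained)) {
    if (is.null(weights_path))
      stop_labeled("no_weights",
                   "pretrained = TRUE requires weights_path (no download is attempted)")
    model <- load_model_weights(model, weights_path)
  }
  model
}

#' @export
print.sliceleak_model <- function(x, ...) {
  cat(sprintf("<sliceleak_model> %s, %s, %d epochs trained, %d parameters\n",
              x$architecture, if (x$trained) "trained" else "untrained",
              length(x$history), length(model_param_vector(x))))
  invisible(x)
}

model_param_vector <- function(model)
  tree_flatten(lapply(model$layers, layer_params))

#' Deterministic checksum of a model's parameters
#' @param model a `sliceleak_model`.
#' @return character checksum.
#' @export
model_checksum <- function(model) param_checksum(model_param_vector(model))

#' Train a binary slice classifier
#'
#' Minimizes cross-entropy over the two logits with Adam at the stated
#' learning rate and batch size for `hp$epochs` epochs; all layers update.
#' Per-epoch mean loss and training accuracy are recorded in the history.
#' With `epochs = 0` the model is returned unchanged with an empty history.
#' Deterministic given `(hp$seed, data)` under a fixed single-threaded
#' BLAS configuration.
#'
#' @param model a `sliceleak_model` from [build_model()].
#' @param x prepared slice array (S, S, 3, N) from [prepare_slices()].
#' @param y integer 0/1 labels of length N.
#' @param hp optional [hyperparams()] override (defaults to the model's).
#' @return the trained `sliceleak_model` with `history` filled.
#' @export
train_model <- function(model, x, y, hp = model$hp) {
  stopifnot(inherits(model, "sliceleak_model"))
  n <- dim(x)[4]
  if (length(y) != n) stop_labeled("bad_labels", "labels do not match slice count")
  if (length(unique(y)) < 2 && hp$epochs > 0)
    stop_labeled("single_class", "training set contains a single class (%s)",
                 unique(y))
  if (hp$epochs == 0) { model$history <- list(); return(model) }
  batch <- hp$batch_size
  if (batch > n) {
    warning(sprintf("batch_size %d exceeds dataset size %d; clamping", batch, n))
    batch <- n
  }
  params <- lapply(model$layers, layer_params)
  state <- adam_init(params)
  history <- vector("list", hp$epochs)
  for (e in seq_len(hp$epochs)) {
    epoch_seed <- derive_seed(hp$seed, "epoch", e)
    res <- with_seed(epoch_seed, {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- y[idx]
        fw <- seq_forward(model$layers, xb, train = TRUE)
        model$layers <- fw$layers
        ls <- softmax_xent(fw$out, yb)
        bw <- seq_backward(model$layers, fw$caches, ls$grad, need_gin = FALSE)
        st <- adam_step(lapply(model$layers, layer_params), bw$grads, state,
                        lr = hp$learning_rate)
        state <- st$state
        model$layers <- Map(set_layer_params, model$layers, st$params)
        tot_loss <- tot_loss + ls$loss * length(idx)
        tot_correct <- tot_correct + sum((ls$prob[2, ] > 0.5) == (yb == 1))
      }
      list(model = model, state = state,
           loss = tot_loss / n, accuracy = tot_correct / n)
    })
    model <- res$model
    state <- res$state
    history[[e]] <- list(epoch = e, loss = res$loss, accuracy = res$accuracy)
  }
  model$trained <- TRUE
  model$history <- history
  model
}

#' Predict labels and class-1 scores for prepared slices
#'
#' @param object a `sliceleak_model`.
#' @param x prepared slice array (S, S, 3, N).
#' @param allow_untrained permit inference from an untrained model (used for
#'   chance-level controls); otherwise an untrained model is an error.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return data.frame with `label` (0/1; ties at score 0.5 break toward 0)
#'   and `score` (class-1 probability in [0, 1]).
#' @export
predict.sliceleak_model <- function(object, x, allow_untrained = FALSE,
                                    batch_size = 512L, ...) {
  n <- dim(x)[4]
  if (n == 0) stop_labeled("empty_input", "no slices to predict")
  if (!object$trained && !allow_untrained)
    stop_labeled("untrained_model",
                 "model is untrained; pass allow_untrained = TRUE to score anyway")
  scores <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- seq_forward(object$layers, x[, , , idx, drop = FALSE], train = FALSE)
    mx <- apply(fw$out, 2, max)
    e <- exp(sweep(fw$out, 2, mx))
    scores[idx] <- e[2, ] / colSums(e)
  }
  data.frame(label = as.integer(scores > 0.5), score = scores)
}

#' Save / load model parameters as plain JSON
#'
#' Parameters are stored as a flat numeric vector plus the architecture tag,
#' a text format that round-trips exactly at full double precision.
#' @param model a `sliceleak_model`.
#' @param path file path.
#' @return `save_model` the path; `load_model_weights` the model.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(list(architecture = model$architecture,
                            params = model_param_vector(model),
                            trained = model$trained),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @param target model whose architecture the weights must match.
#' @export
load_model_weights <- function(target, path) {
  blob <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(blob$architecture, target$architecture))
    stop_labeled("arch_mismatch", "weights are for '%s', model is '%s'",
                 blob$architecture, target$architecture)
  vec <- as.numeric(blob$params)
  params <- lapply(target$layers, layer_params)
  pos <- 0L
  refill <- function(p) {
    if (is.null(p)) return(NULL)
    if (is_param_leaf(p)) {
      k <- length(p)
      out <- vec[(pos + 1L):(pos + k)]
      pos <<- pos + k
      if (is.matrix(p)) dim(out) <- dim(p)
      return(out)
    }
    lapply(p, refill)
  }
  params <- refill(params)
  if (pos != length(vec))
    stop_labeled("weight_size", "weight vector length %d does not match model (%d used)",
                 length(vec), pos)
  target$layers <- Map(set_layer_params, target$layers, params)
  target$trained <- isTRUE(blob$trained)
  target
}
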