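#' Configuration of the R2AttU-Net segmenter
#'
#' The network combines a recurrent-residual encoder (as in R2U-Net)
#' with an attention-gated decoder (as in Attention U-Net). Each
#' encoder level is a recurrent-residual block: a 1x1 projection to the
#' level's channel width, two recurrent convolution layers (a shared
#' 3x3 kernel applied `recurrence_steps` times, step i convolving the
#' block input plus step i-1's output), and a residual shortcut around
#' the pair, followed by 2x2 max pooling. Each decoder level upsamples
#' by a 2x2 transposed convolution, rescales the encoder skip with an
#' additive attention gate (coefficients in `[0, 1]`), concatenates,
#' and applies a double 3x3 convolution block. A 1x1 sigmoid head
#' produces the per-pixel lesion probability. Channel widths double per
#' level (`base_channels * 2^(level - 1)`).
#'
#' @param depth Number of resolution levels (>= 2).
#' @param base_channels Feature maps at the first level.
#' @param recurrence_steps t, the number of recurrent applications of
#'   each recurrent convolution layer (>= 1).
#' @param input_size Square input side in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(depth = 3, base_channels = 8, recurrence_steps = 2,
                       input_size = 64) {
  stopifnot(depth >= 2, base_channels >= 1, recurrence_steps >= 1,
            input_size >= 2^(depth - 1))
  if (input_size %% 2^(depth - 1) != 0) {
    abort(sprintf("input_size %d is not divisible by 2^(depth-1) = %d",
                  input_size, 2^(depth - 1)))
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 recurrence_steps = as.integer(recurrence_steps),
                 input_size = as.integer(input_size)),
            class = "seg_config")
}

#' Training configuration
#'
#' Defaults follow the published training recipe for the segmenter:
#' Adam, learning rate 0.001, batch size 4, 200 epochs.
#'
#' @param learning_rate Optimizer step size.
#' @param optimizer_name `"adam"` or `"sgd"`.
#' @param batch_size Samples per gradient step.
#' @param epochs Training epochs.
#' @param seed RNG seed controlling weight initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, optimizer_name = c("adam", "sgd"),
                         batch_size = 4, epochs = 200, seed = 1L) {
  optimizer_name <- match.arg(optimizer_name)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, optimizer_name = optimizer_name,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- parameter construction -------------------------------------------------

# He-style initialization for a conv kernel of dims (kh, kw, cin, cout)
init_conv <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  array(rnorm(kh * kw * cin * cout, sd = sd), dim = c(kh, kw, cin, cout))
}

# channel widths per level
level_channels <- function(config) config$base_channels * 2L^(seq_len(config$depth) - 1L)

#' Build an untrained R2AttU-Net
#'
#' Allocates and initializes all parameters (seed the RNG first for
#' reproducible weights, or use [train_segmentation()] which seeds from
#' its `train_config`).
#'
#' @param config A [seg_config()].
#' @return An object of class `r2attunet`: a list with `config` and a
#'   named list `params` of weight arrays.
#' @examples
#' set.seed(1)
#' model <- build_r2attunet(seg_config(depth = 2, base_channels = 4, input_size = 16))
#' n_parameters(model)
#' @export
build_r2attunet <- function(config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  ch <- level_channels(config)
  p <- list()
  cin <- 1L
  for (i in seq_len(config$depth)) {
    nm <- paste0("enc", i)
    p[[paste0(nm, "_proj_w")]] <- init_conv(1, 1, cin, ch[i])
    p[[paste0(nm, "_proj_b")]] <- numeric(ch[i])
    p[[paste0(nm, "_rcl1_w")]] <- init_conv(3, 3, ch[i], ch[i])
    p[[paste0(nm, "_rcl1_b")]] <- numeric(ch[i])
    p[[paste0(nm, "_rcl2_w")]] <- init_conv(3, 3, ch[i], ch[i])
    p[[paste0(nm, "_rcl2_b")]] <- numeric(ch[i])
    cin <- ch[i]
  }
  for (i in rev(seq_len(config$depth - 1L))) {
    nm <- paste0("dec", i)
    p[[paste0(nm, "_up_w")]] <- init_conv(2, 2, ch[i], ch[i + 1L]) # (2,2,Cout,Cin)
    p[[paste0(nm, "_up_b")]] <- numeric(ch[i])
    fint <- max(1L, ch[i] %/% 2L)
    p[[paste0(nm, "_att_wg")]] <- init_conv(1, 1, ch[i], fint)
    p[[paste0(nm, "_att_wx")]] <- init_conv(1, 1, ch[i], fint)
    p[[paste0(nm, "_att_bg")]] <- numeric(fint)
    p[[paste0(nm, "_att_wpsi")]] <- init_conv(1, 1, fint, 1L)
    p[[paste0(nm, "_att_bpsi")]] <- numeric(1L)
    p[[paste0(nm, "_conv1_w")]] <- init_conv(3, 3, 2L * ch[i], ch[i])
    p[[paste0(nm, "_conv1_b")]] <- numeric(ch[i])
    p[[paste0(nm, "_conv2_w")]] <- init_conv(3, 3, ch[i], ch[i])
    p[[paste0(nm, "_conv2_b")]] <- numeric(ch[i])
  }
  p[["head_w"]] <- init_conv(1, 1, ch[1], 1L)
  p[["head_b"]] <- numeric(1L)
  structure(list(config = config, params = p), class = "r2attunet")
}

#' Number of trainable parameters
#' @param model An `r2attunet`.
#' @return Integer count of all weights and biases.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "r2attunet"))
  sum(vapply(model$params, length, integer(1)))
}

# ---- forward pass -----------------------------------------------------------

# recurrent conv layer: z1 = relu(conv(x)); z_i = relu(conv(x + z_{i-1}))
rcl_forward <- function(tape, x, w, b, t_steps) {
  z <- op_relu(tape, op_conv(tape, x, w, b, pad = 1L))
  if (t_steps > 1L) {
    for (s in 2:t_steps) {
      z <- op_relu(tape, op_conv(tape, op_add(tape, x, z), w, b, pad = 1L))
    }
  }
  z
}

rr_block_forward <- function(tape, x, pn, model, leaf) {
  t_steps <- model$config$recurrence_steps
  proj <- op_conv(tape, x, leaf(paste0(pn, "_proj_w")), leaf(paste0(pn, "_proj_b")),
                  pad = 0L)
  z <- rcl_forward(tape, proj, leaf(paste0(pn, "_rcl1_w")), leaf(paste0(pn, "_rcl1_b")), t_steps)
  z <- rcl_forward(tape, z, leaf(paste0(pn, "_rcl2_w")), leaf(paste0(pn, "_rcl2_b")), t_steps)
  op_add(tape, proj, z)
}

# additive attention gate; returns gated skip and the coefficient node
attention_forward <- function(tape, skip, gate, pn, leaf) {
  zero_b <- function(n) tape_leaf(tape, numeric(n))
  fint <- dim(leaf(paste0(pn, "_att_wg"))$value)[4]
  g1 <- op_conv(tape, gate, leaf(paste0(pn, "_att_wg")), leaf(paste0(pn, "_att_bg")), pad = 0L)
  x1 <- op_conv(tape, skip, leaf(paste0(pn, "_att_wx")), zero_b(fint), pad = 0L)
  a <- op_relu(tape, op_add(tape, g1, x1))
  psi <- op_sigmoid(tape, op_conv(tape, a, leaf(paste0(pn, "_att_wpsi")),
                                  leaf(paste0(pn, "_att_bpsi")), pad = 0L))
  list(gated = op_gate(tape, skip, psi), psi = psi)
}

# full forward pass; returns the logits node, the tape, the parameter
# leaves (for gradient readout) and the attention coefficient nodes
r2attunet_forward <- function(model, x) {
  tape <- new_tape()
  leaves <- list()
  leaf <- function(nm) {
    if (is.null(leaves[[nm]])) leaves[[nm]] <<- tape_leaf(tape, model$params[[nm]])
    leaves[[nm]]
  }
  depth <- model$config$depth
  cur <- tape_leaf(tape, as_hwc(x))
  skips <- vector("list", depth)
  for (i in seq_len(depth)) {
    cur <- rr_block_forward(tape, cur, paste0("enc", i), model, leaf)
    skips[[i]] <- cur
    if (i < depth) cur <- op_maxpool2(tape, cur)
  }
  attn <- list()
  for (i in rev(seq_len(depth - 1L))) {
    pn <- paste0("dec", i)
    up <- op_convT2(tape, cur, leaf(paste0(pn, "_up_w")), leaf(paste0(pn, "_up_b")))
    ag <- attention_forward(tape, skips[[i]], up, pn, leaf)
    attn[[pn]] <- ag$psi
    cat_ <- op_concat(tape, ag$gated, up)
    cur <- op_relu(tape, op_conv(tape, cat_, leaf(paste0(pn, "_conv1_w")),
                                 leaf(paste0(pn, "_conv1_b")), pad = 1L))
    cur <- op_relu(tape, op_conv(tape, cur, leaf(paste0(pn, "_conv2_w")),
                                 leaf(paste0(pn, "_conv2_b")), pad = 1L))
  }
  logits <- op_conv(tape, cur, leaf("head_w"), leaf("head_b"), pad = 0L)
  list(logits = logits, tape = tape, leaves = leaves, attention = attn)
}

#' Forward pass of the segmenter
#'
#' @param model An `r2attunet`.
#' @param img Numeric matrix (`input_size` x `input_size`) in `[0, 1]`.
#' @param with_attention If `TRUE`, also return the attention
#'   coefficient maps of each decoder level.
#' @return Probability matrix in (0, 1) of the input's spatial shape;
#'   with `with_attention = TRUE` a list `probs` + `attention`.
#' @export
predict_probs <- function(model, img, with_attention = FALSE) {
  stopifnot(inherits(model, "r2attunet"), is.matrix(img))
  check_input_size(model, img)
  fw <- r2attunet_forward(model, normalize_unit(img))
  probs <- 1 / (1 + exp(-fw$logits$value[, , 1L]))
  if (!with_attention) return(probs)
  list(probs = probs,
       attention = lapply(fw$attention, function(n) n$value[, , 1L]))
}

check_input_size <- function(model, img) {
  s <- model$config$input_size
  if (nrow(img) != s || ncol(img) != s) {
    abort(sprintf("model expects %dx%d input, got %dx%d", s, s, nrow(img), ncol(img)))
  }
}

# min-max normalization to [0, 1]; constant images map to 0
normalize_unit <- function(img) {
  rg <- range(img)
  if (rg[2] > rg[1]) (img - rg[1]) / (rg[2] - rg[1]) else img * 0
}

# ---- losses -----------------------------------------------------------------

# stable binary cross-entropy with logits; returns loss value and dL/dlogits
bce_with_logits <- function(z, target) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * target + log1p(exp(-abs(z)))) / n
  probs <- 1 / (1 + exp(-z))
  list(loss = loss, grad = (probs - target) / n)
}

# soft Dice loss on sigmoid probabilities
dice_with_logits <- function(z, target, eps = 1e-7) {
  p <- 1 / (1 + exp(-z))
  num <- 2 * sum(p * target) + eps
  den <- sum(p) + sum(target) + eps
  loss <- 1 - num / den
  dp <- -(2 * target * den - num) / den^2
  list(loss = loss, grad = dp * p * (1 - p))
}

# ---- optimizer --------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- training ---------------------------------------------------------------

#' Train the segmenter
#'
#' Minimizes a binary segmentation loss (binary cross-entropy by
#' default, soft Dice optionally) with Adam (or plain SGD). Weight
#' initialization and shuffling are seeded from `train_config$seed`, so
#' two runs with identical inputs produce identical loss histories.
#'
#' @param samples List of `list(image =, mask =)` pairs, or
#'   `phantom_sample` objects; images and masks are resized to the
#'   model input size (bilinear / nearest).
#' @param config A [seg_config()].
#' @param tc A [train_config()].
#' @param loss `"bce"` or `"dice"`.
#' @param model Optional pre-built/pre-trained `r2attunet` to continue
#'   training (its config overrides `config`).
#' @param dice_every Evaluate mean training Dice every this many epochs
#'   (recorded in the history; 0 disables).
#' @param target_dice If non-`NULL`, stop once the evaluated mean
#'   training Dice reaches this value.
#' @param verbose Print one line per `dice_every` epochs.
#' @return A list of class `seg_fit`: `model`, `history` (tibble with
#'   `epoch`, `loss`, `train_dice`), `loss`, `config`, `train_config`.
#' @examples
#' \donttest{
#' specs <- lapply(1:2, function(i) phantom_spec(height = 32, width = 32, seed = i))
#' samples <- lapply(specs, generate_phantom)
#' fit <- train_segmentation(samples, seg_config(depth = 2, base_channels = 4,
#'                                               input_size = 32),
#'                           train_config(epochs = 2, seed = 1))
#' fit$history
#' }
#' @export
train_segmentation <- function(samples, config = seg_config(), tc = train_config(),
                               loss = c("bce", "dice"), model = NULL,
                               dice_every = 0L, target_dice = NULL, verbose = FALSE) {
  stopifnot(length(samples) >= 1, inherits(tc, "train_config"))
  loss <- match.arg(loss)
  set.seed(tc$seed)
  if (is.null(model)) {
    model <- build_r2attunet(config)
  } else {
    stopifnot(inherits(model, "r2attunet"))
    config <- model$config
  }
  s <- config$input_size
  xs <- lapply(samples, function(sm) normalize_unit(resize_image(sm$image, s, s)))
  ys <- lapply(samples, function(sm) resize_mask(sm$mask, s, s))
  loss_fn <- if (loss == "bce") bce_with_logits else dice_with_logits
  opt <- adam_state(model$params)
  n <- length(samples)
  history <- vector("list", tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      grads <- NULL
      batch_loss <- 0
      for (j in batch) {
        fw <- r2attunet_forward(model, xs[[j]])
        lf <- loss_fn(fw$logits$value, as_hwc(ys[[j]]))
        if (!is.finite(lf$loss)) {
          abort(sprintf("training diverged: non-finite loss at epoch %d", epoch))
        }
        batch_loss <- batch_loss + lf$loss
        fw$logits$grad <- array(lf$grad, dim = dim(fw$logits$value))
        tape_backward(fw$tape, fw$logits)
        g <- lapply(fw$leaves, function(l) l$grad)
        grads <- if (is.null(grads)) g else mapply(`+`, grads, g[names(grads)], SIMPLIFY = FALSE)
      }
      grads <- lapply(grads, function(g) g / length(batch))
      if (tc$optimizer_name == "adam") {
        upd <- adam_step(model$params, grads, opt, tc$learning_rate)
        model$params <- upd$params
        opt <- upd$state
      } else {
        for (nm in names(grads)) {
          model$params[[nm]] <- model$params[[nm]] - tc$learning_rate * grads[[nm]]
        }
      }
      epoch_loss <- epoch_loss + batch_loss
    }
    train_dice <- NA_real_
    if (dice_every > 0L && (epoch %% dice_every == 0L || epoch == tc$epochs)) {
      train_dice <- mean(vapply(seq_len(n), function(j) {
        probs <- 1 / (1 + exp(-r2attunet_forward(model, xs[[j]])$logits$value[, , 1L]))
        dice(matrix(as.integer(probs >= 0.5), s, s), ys[[j]])
      }, numeric(1)))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, train dice %.3f",
                        epoch, epoch_loss / n, train_dice))
      }
    }
    history[[epoch]] <- tibble(epoch = epoch, loss = epoch_loss / n,
                               train_dice = train_dice)
    if (!is.null(target_dice) && !is.na(train_dice) && train_dice >= target_dice) {
      history <- history[seq_len(epoch)]
      break
    }
  }
  structure(list(model = model, history = dplyr::bind_rows(history),
                 loss = loss, config = config, train_config = tc),
            class = "seg_fit")
}

#' Predict a binary lesion mask
#'
#' Resizes the image to the model input size (bilinear), min-max
#' normalizes, thresholds the sigmoid output, and maps the mask back to
#' the original image dimensions by nearest-neighbour resizing.
#'
#' @param model An `r2attunet` or a `seg_fit`.
#' @param img Numeric matrix of any size.
#' @param threshold Probability threshold in `[0, 1]`; 0 gives an
#'   all-ones mask, 1 an all-zeros mask.
#' @return Binary integer matrix with the dimensions of `img`.
#' @export
predict_mask <- function(model, img, threshold = 0.5) {
  if (inherits(model, "seg_fit")) model <- model$model
  stopifnot(inherits(model, "r2attunet"), is.matrix(img),
            threshold >= 0, threshold <= 1)
  s <- model$config$input_size
  probs <- predict_probs(model, normalize_unit(resize_image(img, s, s)))
  # sigmoid output is strictly inside (0, 1), so a strict comparison gives
  # the all-ones mask at threshold 0 and the all-zeros mask at threshold 1
  small <- matrix(as.integer(probs > threshold), s, s)
  resize_mask(small, nrow(img), ncol(img))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b Binary matrices of identical shape.
#' @return Score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  assert_binary_mask(a, "a"); assert_binary_mask(b, "b")
  assert_same_shape(a, b, "masks")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Save / load a segmenter checkpoint
#'
#' Single-file checkpoint holding the configuration and all weights.
#'
#' @param model An `r2attunet` or `seg_fit`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the `r2attunet`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "seg_fit")) model <- model$model
  stopifnot(inherits(model, "r2attunet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "r2attunet")) abort("checkpoint does not contain an r2attunet model")
  model
}

#' @export
print.r2attunet <- function(x, ...) {
  cat(sprintf("<r2attunet> depth %d, base %d, t = %d, input %dx%d, %d parameters\n",
              x$config$depth, x$config$base_channels, x$config$recurrence_steps,
              x$config$input_size, x$config$input_size, n_parameters(x)))
  invisible(x)
}

#' @export
print.seg_fit <- function(x, ...) {
  final <- x$history[nrow(x$history), ]
  cat(sprintf("<seg_fit> %d epoch(s), final loss %.4f%s\n",
              nrow(x$history), final$loss,
              if (is.na(final$train_dice)) "" else sprintf(", train dice %.3f", final$train_dice)))
  invisible(x)
}

#' Tidy the training history of a segmenter fit
#' @param x A `seg_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `train_dice`.
#' @export
tidy.seg_fit <- function(x, ...) x$history

#' One-row summary of a segmenter fit
#' @param x A `seg_fit`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `final_loss`, `final_train_dice`,
#'   `n_parameters`.
#' @export
glance.seg_fit <- function(x, ...) {
  final <- x$history[nrow(x$history), ]
  last_dice <- x$history$train_dice[!is.na(x$history$train_dice)]
  tibble(epochs = nrow(x$history), final_loss = final$loss,
         final_train_dice = if (length(last_dice)) last_dice[length(last_dice)] else NA_real_,
         n_parameters = n_parameters(x$model))
}
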