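# Compact trainable U-Net segmenter: 3x3 conv blocks with ReLU, 2x2
# max-pooling, nearest-neighbour upsampling with skip concatenation, a 1x1
# output head with sigmoid. Layer kernels run in compiled code; the training
# loop (Adam, Dice loss, best-validation-checkpoint selection) lives here.

#' Training configuration
#'
#' @param batch_size Images per optimizer step (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param max_epochs Maximum training epochs (>= 1).
#' @param input_size Network input size S; must be divisible by `2^depth`
#'   of the model trained with it.
#' @param seed Integer RNG seed controlling weight init, shuffling and
#'   crop/jitter sampling during training.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(batch_size, learning_rate, max_epochs, input_size,
                         seed = 2022L) {
  stopifnot(batch_size >= 1, learning_rate > 0, max_epochs >= 1,
            input_size >= 8)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf("<train_config batch=%d lr=%g epochs=%d S=%d seed=%d>\n",
              x$batch_size, x$learning_rate, x$max_epochs, x$input_size,
              x$seed))
  invisible(x)
}

#' Named hyperparameter presets
#'
#' The per-dataset training hyperparameters used for the reference tasks:
#' cell nuclei in microscopy, polyps in endoscopy, and the aorta in CT.
#'
#' @param name One of `"cells"`, `"polyp"`, `"aorta"`.
#' @param input_size Network input size S to embed in the config.
#' @param seed RNG seed (default 2022).
#' @return A [train_config()].
#' @examples
#' train_preset("cells", input_size = 64)
#' @export
train_preset <- function(name, input_size = 64L, seed = 2022L) {
  stopifnot(length(name) == 1)
  p <- switch(name,
    cells = list(16L, 5e-4, 100L),
    polyp = list(8L, 1e-3, 175L),
    aorta = list(8L, 1e-3, 100L),
    stop("unknown preset '", name, "' (use cells, polyp or aorta)"))
  train_config(p[[1]], p[[2]], p[[3]], input_size, seed)
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

unet_channels <- function(arch, level) arch$base * 2L^(level - 1L)

he_mat <- function(fan_in, n_out) {
  matrix(stats::rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
}

#' Initialise a U-Net model
#'
#' A depth- and width-configurable encoder-decoder. `depth` is the number
#' of pooling steps; channel width doubles per level starting at `base`.
#' Defaults (depth 3, base 16) give a small network; desk-scale experiments
#' in this package typically use depth 2, base 8.
#'
#' @param channels_in Input channel count (default 1, grayscale).
#' @param depth Number of 2x2 pooling steps (>= 1).
#' @param base Channel width of the first level.
#' @param input_size Expected input size S; must be divisible by `2^depth`.
#' @return An object of class `"unet"` holding flat named parameters.
#' @export
unet_init <- function(channels_in = 1L, depth = 3L, base = 16L,
                      input_size = 64L) {
  depth <- as.integer(depth); base <- as.integer(base)
  input_size <- as.integer(input_size)
  stopifnot(depth >= 1, base >= 1, input_size %% 2L^depth == 0)
  arch <- list(channels_in = as.integer(channels_in), depth = depth,
               base = base)
  p <- list()
  add_conv <- function(p, key, cin, cout) {
    p[[paste0(key, ".W")]] <- he_mat(cin * 9L, cout)
    p[[paste0(key, ".b")]] <- matrix(0, 1, cout)
    p
  }
  cin <- arch$channels_in
  for (l in seq_len(depth)) {
    ch <- unet_channels(arch, l)
    p <- add_conv(p, sprintf("enc%d.c1", l), cin, ch)
    p <- add_conv(p, sprintf("enc%d.c2", l), ch, ch)
    cin <- ch
  }
  chb <- unet_channels(arch, depth + 1L)
  p <- add_conv(p, "bot.c1", cin, chb)
  p <- add_conv(p, "bot.c2", chb, chb)
  up <- chb
  for (l in rev(seq_len(depth))) {
    ch <- unet_channels(arch, l)
    p <- add_conv(p, sprintf("dec%d.c1", l), up + ch, ch)
    p <- add_conv(p, sprintf("dec%d.c2", l), ch, ch)
    up <- ch
  }
  p[["out.W"]] <- he_mat(unet_channels(arch, 1L), 1L)
  p[["out.b"]] <- matrix(0, 1, 1)
  structure(list(params = p, arch = arch, input_size = input_size),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  n <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<unet depth=%d base=%d S=%d params=%d>\n",
              x$arch$depth, x$arch$base, x$input_size, n))
  invisible(x)
}

as_input_cube <- function(x, channels_in) {
  d <- dim(x)
  if (length(d) == 2) {
    if (channels_in != 1L) stop("model expects ", channels_in, " channels")
    dim(x) <- c(d, 1L)
  } else if (d[3] != channels_in) {
    stop("model expects ", channels_in, " channels, got ", d[3])
  }
  storage.mode(x) <- "double"
  x
}

conv_fwd <- function(p, key, x) {
  cpp_conv3x3_fwd(x, p[[paste0(key, ".W")]],
                  as.numeric(p[[paste0(key, ".b")]]))
}

unet_forward <- function(model, x, with_cache = FALSE) {
  p <- model$params
  depth <- model$arch$depth
  x <- as_input_cube(x, model$arch$channels_in)
  cache <- list(enc = vector("list", depth), dec = vector("list", depth))
  cur <- x
  for (l in seq_len(depth)) {
    key1 <- sprintf("enc%d.c1", l); key2 <- sprintf("enc%d.c2", l)
    z1 <- conv_fwd(p, key1, cur); a1 <- relu(z1)
    z2 <- conv_fwd(p, key2, a1); a2 <- relu(z2)
    pl <- cpp_maxpool2_fwd(a2)
    if (with_cache)
      cache$enc[[l]] <- list(x = cur, a1 = a1, m1 = z1 > 0, m2 = z2 > 0,
                             a2 = a2, idx = pl$idx,
                             H = dim(a2)[1], W = dim(a2)[2])
    else
      cache$enc[[l]] <- list(a2 = a2)
    cur <- pl$y
  }
  z1 <- conv_fwd(p, "bot.c1", cur); b1 <- relu(z1)
  z2 <- conv_fwd(p, "bot.c2", b1); b2 <- relu(z2)
  if (with_cache)
    cache$bot <- list(x = cur, a1 = b1, m1 = z1 > 0, m2 = z2 > 0)
  cur <- b2
  for (l in rev(seq_len(depth))) {
    up <- cpp_upsample2(cur)
    skip <- cache$enc[[l]]$a2
    du <- dim(up)
    cat3 <- array(c(up, skip), dim = c(du[1], du[2], du[3] + dim(skip)[3]))
    key1 <- sprintf("dec%d.c1", l); key2 <- sprintf("dec%d.c2", l)
    z1 <- conv_fwd(p, key1, cat3); a1 <- relu(z1)
    z2 <- conv_fwd(p, key2, a1); a2 <- relu(z2)
    if (with_cache)
      cache$dec[[l]] <- list(x = cat3, a1 = a1, m1 = z1 > 0, m2 = z2 > 0,
                             nup = du[3])
    cur <- a2
  }
  d <- dim(cur)
  xm <- matrix(cur, d[1] * d[2], d[3])
  logits <- matrix(xm %*% p[["out.W"]] + as.numeric(p[["out.b"]]), d[1], d[2])
  if (with_cache) {
    cache$final_in <- cur
    list(scores = sigmoid(logits), cache = cache)
  } else {
    sigmoid(logits)
  }
}

# backward pass: dlogits is dLoss/dlogits (H x W). Returns flat named grads.
unet_backward <- function(model, cache, dlogits) {
  p <- model$params
  depth <- model$arch$depth
  g <- list()
  fin <- cache$final_in
  d <- dim(fin)
  xm <- matrix(fin, d[1] * d[2], d[3])
  dv <- matrix(as.numeric(dlogits), ncol = 1)
  g[["out.W"]] <- crossprod(xm, dv)
  g[["out.b"]] <- matrix(sum(dv), 1, 1)
  dcur <- array(dv %*% t(p[["out.W"]]), dim = d)

  conv_bwd <- function(key, xin, dz) {
    r <- cpp_conv3x3_bwd(xin, p[[paste0(key, ".W")]], dz)
    g[[paste0(key, ".W")]] <<- r$dW
    g[[paste0(key, ".b")]] <<- matrix(r$db, nrow = 1)
    r$dx
  }

  dskip <- vector("list", depth)
  for (l in seq_len(depth)) {           # reverse of decoder's depth..1 order
    cc <- cache$dec[[l]]
    dz2 <- dcur * cc$m2
    da1 <- conv_bwd(sprintf("dec%d.c2", l), cc$a1, dz2)
    dz1 <- da1 * cc$m1
    dcat <- conv_bwd(sprintf("dec%d.c1", l), cc$x, dz1)
    nup <- cc$nup
    dup <- dcat[, , seq_len(nup), drop = FALSE]
    dskip[[l]] <- dcat[, , (nup + 1):dim(dcat)[3], drop = FALSE]
    dcur <- cpp_upsample2_bwd(dup)
  }
  cc <- cache$bot
  dz2 <- dcur * cc$m2
  da1 <- conv_bwd("bot.c2", cc$a1, dz2)
  dz1 <- da1 * cc$m1
  dcur <- conv_bwd("bot.c1", cc$x, dz1)
  for (l in rev(seq_len(depth))) {
    cc <- cache$enc[[l]]
    da2 <- cpp_maxpool2_bwd(dcur, cc$idx, cc$H, cc$W) + dskip[[l]]
    dz2 <- da2 * cc$m2
    da1 <- conv_bwd(sprintf("enc%d.c2", l), cc$a1, dz2)
    dz1 <- da1 * cc$m1
    dcur <- conv_bwd(sprintf("enc%d.c1", l), cc$x, dz1)
  }
  g
}

# soft Dice loss and its gradient w.r.t. the sigmoid scores
dice_loss <- function(scores, gt, eps = 1) {
  inter <- sum(scores * gt)
  s <- sum(scores) + sum(gt)
  loss <- 1 - (2 * inter + eps) / (s + eps)
  dscores <- -(2 * gt * (s + eps) - (2 * inter + eps)) / (s + eps)^2
  list(loss = loss, dscores = dscores)
}

# binary cross-entropy loss (alternative optimization target)
bce_loss <- function(scores, gt, eps = 1e-7) {
  pcl <- pmin(pmax(scores, eps), 1 - eps)
  n <- length(scores)
  loss <- -mean(gt * log(pcl) + (1 - gt) * log(1 - pcl))
  dscores <- (pcl - gt) / (pcl * (1 - pcl)) / n
  list(loss = loss, dscores = dscores)
}

#' Train a U-Net segmenter
#'
#' Optimizes with Adam on a pixel-overlap loss (soft Dice by default). After
#' each epoch the mean validation Dice is computed at input resolution
#' (predictions binarized at 0.5, no upscaling), and the parameters of the
#' best-validation epoch are returned — the returned model is the best
#' checkpoint, not the last.
#'
#' @param pairs Training set: list of `list(image = <S x S[, C]>,
#'   mask = <S x S binary>)`, or a function `(epoch) -> such a list` for
#'   epoch-resampled sets (used for crop training, where a fresh random
#'   crop and jitter is drawn per image per epoch).
#' @param val_pairs Validation set, same list form (fixed across epochs).
#' @param cfg A [train_config()].
#' @param depth,base U-Net size passed to [unet_init()].
#' @param loss `"dice"` (default) or `"bce"`.
#' @param init Optional `"unet"` model to start from (e.g. transfer from a
#'   trained rough network); its architecture overrides `depth`/`base`.
#' @param verbose Print one line per epoch.
#' @return An object of class `"unet"` with extra fields `history`
#'   (epoch/loss/val-Dice data frame), `best_epoch` and `best_val_dice`.
#' @export
train_unet <- function(pairs, val_pairs, cfg, depth = 3L, base = 16L,
                       loss = c("dice", "bce"), init = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(inherits(cfg, "train_config"), length(val_pairs) >= 1)
  fixed_pairs <- !is.function(pairs)
  if (fixed_pairs && length(pairs) == 0) stop("empty training set")
  set.seed(cfg$seed)
  first_set <- if (fixed_pairs) pairs else pairs(1L)
  model <- if (is.null(init)) {
    probe <- first_set[[1]]$image
    cin <- if (length(dim(probe)) == 2) 1L else dim(probe)[3]
    unet_init(cin, depth, base, cfg$input_size)
  } else {
    stopifnot(inherits(init, "unet"))
    init
  }
  loss_fn <- if (loss == "dice") dice_loss else bce_loss

  # Adam state
  mom <- lapply(model$params, function(w) w * 0)
  vel <- lapply(model$params, function(w) w * 0)
  t <- 0L
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8

  val_dice <- function(m) {
    mean(vapply(val_pairs, function(pr) {
      score(binarize(unet_forward(m, pr$image)), pr$mask)$dsc
    }, numeric(1)))
  }

  best <- list(dice = -Inf, params = model$params, epoch = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(), val_dsc = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    ep_pairs <- if (fixed_pairs) pairs
                else if (epoch == 1L) first_set else pairs(epoch)
    n <- length(ep_pairs)
    ord <- sample.int(n)
    ep_loss <- 0
    i <- 1L
    while (i <= n) {
      take <- ord[i:min(n, i + cfg$batch_size - 1L)]
      gsum <- NULL
      for (j in take) {
        pr <- ep_pairs[[j]]
        fw <- unet_forward(model, pr$image, with_cache = TRUE)
        lo <- loss_fn(fw$scores, pr$mask)
        ep_loss <- ep_loss + lo$loss
        dlogits <- lo$dscores * fw$scores * (1 - fw$scores)
        gr <- unet_backward(model, fw$cache, dlogits)
        gsum <- if (is.null(gsum)) gr
                else mapply(`+`, gsum, gr[names(gsum)], SIMPLIFY = FALSE)
      }
      t <- t + 1L
      inv <- 1 / length(take)
      for (k in names(model$params)) {
        gk <- gsum[[k]] * inv
        mom[[k]] <- b1 * mom[[k]] + (1 - b1) * gk
        vel[[k]] <- b2 * vel[[k]] + (1 - b2) * gk^2
        mhat <- mom[[k]] / (1 - b1^t)
        vhat <- vel[[k]] / (1 - b2^t)
        model$params[[k]] <- model$params[[k]] -
          cfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
      }
      i <- i + cfg$batch_size
    }
    vd <- val_dice(model)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss / n,
                                   val_dsc = vd))
    if (vd > best$dice)
      best <- list(dice = vd, params = model$params, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val DSC %.4f", epoch,
                      ep_loss / n, vd))
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model$best_val_dice <- best$dice
  model$train_config <- cfg
  model
}

#' Predict scores with a U-Net
#'
#' @param model A `"unet"`.
#' @param image `S x S` matrix or `S x S x C` array.
#' @return `S x S` score matrix in `[0, 1]`.
#' @export
unet_predict <- function(model, image) {
  stopifnot(inherits(model, "unet"))
  unet_forward(model, image)
}

#' Wrap a trained U-Net as a pipeline segmenter
#'
#' @param model A `"unet"`.
#' @param name Label for printing.
#' @return A [segmenter()] usable as either pipeline stage.
#' @export
unet_segmenter <- function(model, name = "unet") {
  stopifnot(inherits(model, "unet"))
  segmenter(function(img) unet_forward(model, img),
            input_size = model$input_size,
            channels = model$arch$channels_in, name = name)
}

#' Save / load a U-Net checkpoint
#'
#' Weights are serialized natively; a JSON sidecar (`<path>.json`) records
#' the architecture, input size and training configuration for inspection.
#'
#' @param model A `"unet"`.
#' @param path Checkpoint file path.
#' @return `save_unet` returns `path` invisibly; `load_unet` the model.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "unet"))
  saveRDS(model, path)
  side <- list(arch = model$arch, input_size = model$input_size)
  if (!is.null(model$train_config))
    side$train_config <- unclass(model$train_config)
  if (!is.null(model$best_val_dice)) {
    side$best_val_dice <- model$best_val_dice
    side$best_epoch <- model$best_epoch
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet"))
  model
}
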