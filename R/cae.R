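#' Configure the convolutional autoencoder
#'
#' Full scale mirrors the study architecture: input `64 x 80 x 64`, an
#' encoder of four `4^3` stride-2 convolutions with ReLU and group
#' normalization and filter counts doubling from 16, a flatten of width
#' 10240 and a dense bottleneck of 100 latent features; the decoder
#' re-enters through a dense layer back to the flattened width, then
#' four blocks of nearest-neighbor upsampling by 2 followed by `4^3`
#' stride-1 convolutions (filters mirrored), and three final `3^3`
#' convolutions reducing the channel dimension through 8 and 4 to 1.
#' The `mini` scale (input `32 x 48 x 32`, filters from 8) exists so
#' training runs on a plain CPU; every input dimension must be
#' divisible by `2^4`.
#'
#' @param scale `"full"` or `"mini"`.
#' @param input_shape integer triple; defaults by scale.
#' @param encoder_filters four filter counts; defaults by scale.
#' @param latent_dim bottleneck width (default 100).
#' @param groupnorm_groups group-norm groups (default 8; capped at the
#'   channel count).
#' @param epochs,batch_size,lr training defaults (200 epochs, batch 2,
#'   Adam at 1e-3 full scale / 2e-3 mini: the smaller net takes far
#'   fewer gradient steps per run and tolerates the larger step).
#' @param seed initialization seed.
#' @return A `cae_config`.
#' @export
cae_config <- function(scale = c("full", "mini"), input_shape = NULL,
                       encoder_filters = NULL, latent_dim = 100,
                       groupnorm_groups = 8, epochs = 200, batch_size = 2,
                       lr = NULL, seed = 1) {
  scale <- match.arg(scale)
  lr <- lr %||% if (scale == "full") 1e-3 else 2e-3
  input_shape <- input_shape %||%
    if (scale == "full") c(64L, 80L, 64L) else c(32L, 48L, 32L)
  encoder_filters <- encoder_filters %||%
    if (scale == "full") c(16L, 32L, 64L, 128L) else c(8L, 16L, 32L, 64L)
  if (any(input_shape %% 16L != 0L))
    stopf("every input dimension must be divisible by 2^4")
  if (latent_dim < 1) stopf("latent_dim must be >= 1")
  structure(list(scale = scale, input_shape = as.integer(input_shape),
                 encoder_filters = as.integer(encoder_filters),
                 extra_filters = c(8L, 4L, 1L), latent_dim = as.integer(latent_dim),
                 groupnorm_groups = as.integer(groupnorm_groups),
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 seed = as.integer(seed)),
            class = "cae_config")
}

#' Per-layer output shapes implied by a configuration
#'
#' @param cfg a [cae_config()].
#' @return data.frame with `layer` and `output_shape` columns; the
#'   flatten row carries the flattened width.
#' @export
cae_shape_table <- function(cfg) {
  s <- cfg$input_shape
  rows <- list(list("input", c(s, 1L)))
  ch <- 1L
  for (i in 1:4) {
    s <- s %/% 2L; ch <- cfg$encoder_filters[i]
    rows <- c(rows, list(list(sprintf("enc_conv%d", i), c(s, ch))))
  }
  flat <- prod(s) * ch
  rows <- c(rows, list(list("flatten", flat)),
            list(list("latent", cfg$latent_dim)),
            list(list("dec_dense", flat)),
            list(list("reshape", c(s, ch))))
  dec_f <- rev(cfg$encoder_filters)
  for (i in 1:4) {
    s <- s * 2L; ch <- dec_f[i]
    rows <- c(rows, list(list(sprintf("dec_conv%d", i), c(s, ch))))
  }
  for (i in 1:3) {
    ch <- cfg$extra_filters[i]
    rows <- c(rows, list(list(sprintf("dec_extra%d", i), c(s, ch))))
  }
  data.frame(layer = vapply(rows, `[[`, "", 1),
             output_shape = vapply(rows, function(r)
               paste(r[[2]], collapse = "x"), ""),
             stringsAsFactors = FALSE)
}

gn_groups <- function(groups, channels) {
  g <- min(groups, channels)
  while (channels %% g != 0L) g <- g - 1L
  g
}

#' Build a seeded autoencoder model
#'
#' He-initialized weights; identical seeds give identical initial
#' weights. The model records its layer list, the shape table, and the
#' index at which the encoder ends.
#'
#' @param cfg a [cae_config()].
#' @return A `cae_model`.
#' @export
build_cae <- function(cfg) {
  s <- cfg$input_shape
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  with_seed(cfg$seed, {
    he_conv <- function(k, cin, cout)
      array(rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
            c(k, k, k, cin, cout))
    cin <- 1L
    for (i in 1:4) {
      cout <- cfg$encoder_filters[i]
      add(list(type = "conv", w = he_conv(4, cin, cout), b = numeric(cout),
               stride = 2L, pad_lo = c(1L, 1L, 1L), pad_hi = c(1L, 1L, 1L),
               act = "relu"))
      add(list(type = "gn", gamma = rep(1, cout), beta = numeric(cout),
               groups = gn_groups(cfg$groupnorm_groups, cout)))
      cin <- cout
    }
    fs <- s %/% 16L
    flat <- prod(fs) * cin
    add(list(type = "flatten"))
    add(list(type = "dense", w = matrix(rnorm(flat * cfg$latent_dim, 0,
                                              sqrt(2 / flat)),
                                        flat, cfg$latent_dim),
             b = numeric(cfg$latent_dim), act = "linear"))
    enc_end <- length(layers)
    add(list(type = "dense", w = matrix(rnorm(cfg$latent_dim * flat, 0,
                                              sqrt(2 / cfg$latent_dim)),
                                        cfg$latent_dim, flat),
             b = numeric(flat), act = "linear"))
    add(list(type = "reshape", shape = c(fs, cin)))
    dec_f <- rev(cfg$encoder_filters)
    for (i in 1:4) {
      cout <- dec_f[i]
      add(list(type = "upsample"))
      add(list(type = "conv", w = he_conv(4, cin, cout), b = numeric(cout),
               stride = 1L, pad_lo = c(1L, 1L, 1L), pad_hi = c(2L, 2L, 2L),
               act = "relu"))
      add(list(type = "gn", gamma = rep(1, cout), beta = numeric(cout),
               groups = gn_groups(cfg$groupnorm_groups, cout)))
      cin <- cout
    }
    for (i in 1:3) {
      cout <- cfg$extra_filters[i]
      add(list(type = "conv",
               w = array(rnorm(27 * cin * cout, 0, sqrt(2 / (27 * cin))),
                         c(3, 3, 3, cin, cout)),
               b = numeric(cout),
               stride = 1L, pad_lo = c(1L, 1L, 1L), pad_hi = c(1L, 1L, 1L),
               act = if (i < 3) "relu" else "linear"))
      cin <- cout
    }
    structure(list(cfg = cfg, layers = layers, enc_end = enc_end,
                   shape_table = cae_shape_table(cfg)),
              class = "cae_model")
  })
}

GN_EPS <- 1e-5

layer_forward <- function(l, x) {
  switch(l$type,
    conv = {
      pre <- .cpp_conv3d_forward(x, l$w, l$b, l$stride, l$pad_lo, l$pad_hi)
      list(y = if (l$act == "relu") pre * (pre > 0) else pre, pre = pre)
    },
    gn = {
      d <- dim(x); C <- d[4]; gs <- C %/% l$groups
      xm <- matrix(x, ncol = C)
      y <- xm; stats <- vector("list", l$groups)
      for (g in seq_len(l$groups)) {
        cols <- ((g - 1) * gs + 1):(g * gs)
        v <- xm[, cols, drop = FALSE]
        mu <- mean(v); va <- mean((v - mu)^2)
        xhat <- (v - mu) / sqrt(va + GN_EPS)
        y[, cols] <- sweep(xhat, 2, l$gamma[cols], `*`) +
          matrix(l$beta[cols], nrow(xm), gs, byrow = TRUE)
        stats[[g]] <- list(mu = mu, va = va, xhat = xhat)
      }
      list(y = array(y, d), stats = stats)
    },
    flatten = list(y = as.vector(x), shape = dim(x)),
    dense = {
      pre <- drop(crossprod(l$w, as.vector(x))) + l$b
      list(y = if (l$act == "relu") pre * (pre > 0) else pre, pre = pre)
    },
    reshape = list(y = array(x, l$shape)),
    upsample = {
      d <- dim(x)
      list(y = x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
                 rep(seq_len(d[3]), each = 2), , drop = FALSE])
    },
    stopf("unknown layer type %s", l$type))
}

layer_backward <- function(l, x, fwd, dy) {
  switch(l$type,
    conv = {
      if (l$act == "relu") dy <- dy * (fwd$pre > 0)
      g <- .cpp_conv3d_backward(x, l$w, dy, l$stride, l$pad_lo, l$pad_hi)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    gn = {
      d <- dim(x); C <- d[4]; gs <- C %/% l$groups
      dym <- matrix(dy, ncol = C)
      dxm <- dym
      dgamma <- numeric(C); dbeta <- numeric(C)
      for (g in seq_len(l$groups)) {
        cols <- ((g - 1) * gs + 1):(g * gs)
        st <- fwd$stats[[g]]
        dyg <- dym[, cols, drop = FALSE]
        xhat <- st$xhat
        dgamma[cols] <- colSums(dyg * xhat)
        dbeta[cols] <- colSums(dyg)
        dxhat <- sweep(dyg, 2, l$gamma[cols], `*`)
        n <- length(dxhat)
        sdinv <- 1 / sqrt(st$va + GN_EPS)
        dxm[, cols] <- sdinv * (dxhat - mean(dxhat) -
                                  xhat * mean(dxhat * xhat))
      }
      list(dx = array(dxm, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    flatten = list(dx = array(dy, fwd$shape)),
    dense = {
      if (l$act == "relu") dy <- dy * (fwd$pre > 0)
      list(dx = drop(l$w %*% dy), grads = list(w = outer(as.vector(x), dy),
                                               b = dy))
    },
    reshape = list(dx = as.vector(dy)),
    upsample = {
      d <- dim(x)
      dx <- array(0, d)
      for (ox in 0:1) for (oy in 0:1) for (oz in 0:1)
        dx <- dx + dy[seq(1 + ox, by = 2, length.out = d[1]),
                      seq(1 + oy, by = 2, length.out = d[2]),
                      seq(1 + oz, by = 2, length.out = d[3]), , drop = FALSE]
      list(dx = dx)
    })
}

cae_forward <- function(model, x3, upto = length(model$layers), cache = TRUE) {
  x <- array(x3, c(dim(x3), 1L))
  inputs <- if (cache) vector("list", upto)
  fwds <- if (cache) vector("list", upto)
  for (i in seq_len(upto)) {
    if (cache) inputs[[i]] <- x
    f <- layer_forward(model$layers[[i]], x)
    if (cache) fwds[[i]] <- f
    x <- f$y
  }
  list(out = x, inputs = inputs, fwds = fwds)
}

cae_backward <- function(model, fw, dy) {
  n <- length(model$layers)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    bk <- layer_backward(model$layers[[i]], fw$inputs[[i]], fw$fwds[[i]], dy)
    grads[[i]] <- bk$grads %||% list()
    dy <- bk$dx
  }
  grads
}

#' Train the autoencoder by voxelwise MSE
#'
#' Each epoch presents every training volume and its z-flipped copy
#' (doubling the gradient steps), in a seeded shuffled order, optimized
#' with Adam. Aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model a [build_cae()] model.
#' @param volumes list of padded, normalized 3D arrays (or [vol3d()]s)
#'   matching the configured input shape.
#' @param epochs,batch_size,lr override the config defaults.
#' @param clip_norm global gradient-norm clip applied per batch
#'   (default 5); guards against the occasional gradient blow-up
#'   through a normalization group with near-zero variance.
#' @param val_volumes optional held-out volumes for a per-epoch
#'   validation MSE.
#' @param verbose print per-epoch losses.
#' @return The trained model, with a `history` data.frame attached.
#' @export
train_cae <- function(model, volumes, epochs = NULL, batch_size = NULL,
                      lr = NULL, clip_norm = 5, val_volumes = NULL,
                      verbose = FALSE) {
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- lr %||% cfg$lr
  as_arr <- function(v) if (inherits(v, "vol3d")) v$data else v
  volumes <- lapply(volumes, as_arr)
  if (length(volumes) < 1)
    stopf("need at least one training volume (augmentation doubles it)")
  for (v in volumes)
    if (!all(dim(v) == cfg$input_shape))
      stopf("volume shape does not match the configured input shape")
  flip_z <- function(a) a[, , rev(seq_len(dim(a)[3]))]
  samples <- c(volumes, lapply(volumes, flip_z))

  adam <- new.env(parent = emptyenv())
  adam$t <- 0
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  state <- lapply(model$layers, function(l)
    lapply(l[intersect(names(l), c("w", "b", "gamma", "beta"))],
           function(p) list(m = p * 0, v = p * 0)))

  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric(), steps = integer())
  nvox <- prod(cfg$input_shape)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 10000 + ep),
                     sample(length(samples)))
    losses <- numeric(0)
    b0 <- 1
    while (b0 <= length(ord)) {
      idx <- ord[b0:min(b0 + batch_size - 1, length(ord))]
      b0 <- b0 + batch_size
      acc <- NULL
      bl <- 0
      for (si in idx) {
        x3 <- samples[[si]]
        fw <- cae_forward(model, x3)
        resid <- as.vector(fw$out) - as.vector(x3)
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stopf("NaN/Inf loss at epoch %d; reduce the learning rate", ep)
        bl <- bl + loss
        dy <- array(2 * resid / nvox, dim(fw$out))
        g <- cae_backward(model, fw, dy)
        acc <- if (is.null(acc)) g else
          mapply(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE),
                 acc, g, SIMPLIFY = FALSE)
      }
      losses <- c(losses, bl / length(idx))
      # global gradient-norm clipping
      if (is.finite(clip_norm)) {
        sq <- 0
        for (i in seq_along(model$layers))
          for (pn in names(state[[i]]))
            sq <- sq + sum((acc[[i]][[pn]] / length(idx))^2)
        gscale <- if (sqrt(sq) > clip_norm) clip_norm / sqrt(sq) else 1
      } else gscale <- 1
      adam$t <- adam$t + 1
      corr <- sqrt(1 - beta2^adam$t) / (1 - beta1^adam$t)
      for (i in seq_along(model$layers)) {
        for (pn in names(state[[i]])) {
          gr <- gscale * acc[[i]][[pn]] / length(idx)
          st <- state[[i]][[pn]]
          st$m <- beta1 * st$m + (1 - beta1) * gr
          st$v <- beta2 * st$v + (1 - beta2) * gr^2
          state[[i]][[pn]] <- st
          model$layers[[i]][[pn]] <- model$layers[[i]][[pn]] -
            lr * corr * st$m / (sqrt(st$v) + aeps)
        }
      }
    }
    val <- if (!is.null(val_volumes))
      mean(vapply(val_volumes, function(v) {
        v <- as_arr(v)
        mean((as.vector(cae_forward(model, v, cache = FALSE)$out) -
                as.vector(v))^2)
      }, 0)) else NA_real_
    history <- rbind(history, data.frame(epoch = ep,
                                         train_mse = mean(losses),
                                         val_mse = val,
                                         steps = length(losses)))
    if (verbose)
      message(sprintf("epoch %3d  train MSE %.5f  val MSE %s", ep,
                      mean(losses),
                      ifelse(is.na(val), "-", sprintf("%.5f", val))))
  }
  model$history <- history
  model
}

#' Prepare a normalized volume for the autoencoder
#'
#' Clips white-stripe z-scores to a bounded window and zero-pads to the
#' model grid. Clipping keeps the broad sub-WM background from
#' dominating the voxelwise MSE: the darker tissue saturates at the
#' lower bound, the normal-appearing ridge sits at 0, and the
#' hyperintense lesion (z ~ 10) carries most of the remaining variance,
#' which is what the reconstruction objective should spend its capacity
#' on.
#'
#' @param v a normalized [vol3d()].
#' @param target model input shape (e.g. `cae_config()$input_shape`).
#' @param clip lower/upper clip bounds in z units (default `c(-5, 15)`).
#' @return A clipped, padded [vol3d()].
#' @export
cae_prepare <- function(v, target, clip = c(-5, 15)) {
  d <- pmin(pmax(v$data, clip[1]), clip[2])
  pad_to_cae_grid(vol3d(d, v$spacing_mm, v$origin_offset), target)
}

#' Encode a volume into the latent space
#'
#' Deterministic at inference; returns the bottleneck activations.
#'
#' @param model a (trained) `cae_model`.
#' @param v padded normalized [vol3d()] or 3D array on the model grid.
#' @return Numeric vector of length `latent_dim`, named `z000`,
#'   `z001`, ...
#' @export
encode <- function(model, v) {
  a <- if (inherits(v, "vol3d")) v$data else v
  if (!all(dim(a) == model$cfg$input_shape))
    stopf("volume shape does not match the model input shape")
  z <- cae_forward(model, a, upto = model$enc_end, cache = FALSE)$out
  names(z) <- sprintf("z%03d", seq_along(z) - 1)
  z
}

#' Reconstruction, difference map and MSE for one volume
#'
#' @param model a trained `cae_model`.
#' @param v padded normalized [vol3d()].
#' @param out_dir optional directory; when given, the original,
#'   reconstruction and absolute difference map are written as NIfTI.
#' @param id file stem used when writing.
#' @return list with `reconstruction` and `difference` ([vol3d()]s) and
#'   the scalar `mse`.
#' @export
reconstruction_report <- function(model, v, out_dir = NULL, id = "subject") {
  a <- if (inherits(v, "vol3d")) v$data else v
  sp <- if (inherits(v, "vol3d")) v$spacing_mm else 1
  rec <- array(cae_forward(model, a, cache = FALSE)$out, dim(a))
  diffmap <- abs(a - rec)
  mse <- mean((a - rec)^2)
  rec_v <- vol3d(rec, sp); diff_v <- vol3d(diffmap, sp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(vol3d(a, sp), file.path(out_dir, paste0(id, "_orig.nii.gz")))
    write_volume(rec_v, file.path(out_dir, paste0(id, "_recon.nii.gz")))
    write_volume(diff_v, file.path(out_dir, paste0(id, "_diff.nii.gz")))
  }
  list(reconstruction = rec_v, difference = diff_v, mse = mse)
}
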