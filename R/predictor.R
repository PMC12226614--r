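#' Landmark predictor configuration
#'
#' Architecture and training knobs of the convolutional landmark
#' regressor. The network is a small strided-convolution encoder (3x3
#' kernels, stride 2, ReLU) followed by a fully connected head that
#' outputs, per landmark, a 2D mean position (in coordinates normalized
#' to `[-1, 1]`) and one shared variance via a softplus map. It is
#' trained with the Gaussian negative log-likelihood loss
#' ([gaussian_nll()]) using Adam.
#'
#' @param image_size training image side length (square, >= 32).
#' @param n_landmarks number of landmarks (>= 1).
#' @param channels conv channel widths, one per stride-2 stage.
#' @param fc_hidden width of the fully connected hidden layer.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation NLL.
#' @param val_fraction fraction of samples held out for validation.
#' @param augment_cfg list of [augment()] arguments applied during
#'   training (`NULL` disables augmentation).
#' @param mask_occluded exclude z-buffer-occluded landmarks from the loss.
#' @param seed integer seed (weight init, shuffling, augmentation).
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(image_size = 64L, n_landmarks = 1000L,
                             channels = c(16L, 32L, 64L), fc_hidden = 128L,
                             lr = 1e-3, batch_size = 16L, epochs = 60L,
                             patience = 10L, val_fraction = 0.15,
                             augment_cfg = list(max_rot_deg = 10,
                                                flip_prob = 0,
                                                color_shift = 0.05,
                                                noise_sd = 0.01),
                             mask_occluded = FALSE, seed = 1L) {
  if (n_landmarks < 1L) stop("n_landmarks must be >= 1")
  if (image_size < 32L) stop("image_size must be >= 32")
  structure(list(image_size = as.integer(image_size),
                 n_landmarks = as.integer(n_landmarks),
                 channels = as.integer(channels),
                 fc_hidden = as.integer(fc_hidden), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, augment_cfg = augment_cfg,
                 mask_occluded = mask_occluded, seed = as.integer(seed)),
            class = "predictor_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
relu <- function(x) pmax(x, 0)

# --- conv plumbing ---------------------------------------------------------
# Feature maps are (H*W) x C matrices in column-major (H, W) pixel order.
# 3x3 / stride-2 / pad-1 convolution via im2col gather with precomputed
# indices into the zero-padded pixel grid.

conv_plan <- function(Hin, Win) {
  Hout <- (Hin - 1L) %/% 2L + 1L
  Wout <- (Win - 1L) %/% 2L + 1L
  Hp <- Hin + 2L
  oy <- rep(seq_len(Hout), times = Wout)       # output pixel coords (1-based)
  ox <- rep(seq_len(Wout), each = Hout)
  iy <- 2L * (oy - 1L)                          # top-left tap in padded grid
  ix <- 2L * (ox - 1L)
  idx <- matrix(0L, Hout * Wout, 9L)
  t <- 0L
  for (kx in 0:2) for (ky in 0:2) {
    t <- t + 1L
    idx[, t] <- (ix + kx) * Hp + (iy + ky) + 1L
  }
  list(Hin = Hin, Win = Win, Hout = Hout, Wout = Wout, idx = idx)
}

pad_map <- function(x, Hin, Win) {
  # x: (Hin*Win) x C -> padded ((Hin+2)*(Win+2)) x C
  C <- ncol(x)
  xp <- matrix(0, (Hin + 2L) * (Win + 2L), C)
  rows <- as.integer(outer(2:(Hin + 1L), (2:(Win + 1L) - 1L) * (Hin + 2L), `+`))
  xp[rows, ] <- x
  xp
}

unpad_map <- function(xp, Hin, Win) {
  rows <- as.integer(outer(2:(Hin + 1L), (2:(Win + 1L) - 1L) * (Hin + 2L), `+`))
  xp[rows, , drop = FALSE]
}

conv_forward <- function(x, W, b, plan) {
  Cin <- ncol(x)
  xp <- pad_map(x, plan$Hin, plan$Win)
  Xcol <- matrix(0, nrow(plan$idx), 9L * Cin)
  for (t in 1:9)
    Xcol[, ((t - 1L) * Cin + 1L):(t * Cin)] <- xp[plan$idx[, t], , drop = FALSE]
  y <- Xcol %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = y, Xcol = Xcol)
}

conv_backward <- function(dY, Xcol, W, plan, Cin) {
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)
  dxp <- matrix(0, (plan$Hin + 2L) * (plan$Win + 2L), Cin)
  for (t in 1:9) {
    blk <- dXcol[, ((t - 1L) * Cin + 1L):(t * Cin), drop = FALSE]
    r <- plan$idx[, t]
    dxp[r, ] <- dxp[r, ] + blk
  }
  list(dW = dW, db = db, dx = unpad_map(dxp, plan$Hin, plan$Win))
}

init_predictor_params <- function(cfg) {
  local_rng(cfg$seed)({
    sz <- cfg$image_size
    chans <- c(3L, cfg$channels)
    plans <- list()
    params <- list()
    H <- sz; W <- sz
    for (i in seq_along(cfg$channels)) {
      plans[[i]] <- conv_plan(H, W)
      fan_in <- 9L * chans[i]
      params[[paste0("Wc", i)]] <-
        matrix(stats::rnorm(fan_in * chans[i + 1L], 0, sqrt(2 / fan_in)),
               fan_in, chans[i + 1L])
      params[[paste0("bc", i)]] <- numeric(chans[i + 1L])
      H <- plans[[i]]$Hout; W <- plans[[i]]$Wout
    }
    D <- H * W * cfg$channels[length(cfg$channels)]
    params$W1 <- matrix(stats::rnorm(D * cfg$fc_hidden, 0, sqrt(2 / D)),
                        D, cfg$fc_hidden)
    params$b1 <- numeric(cfg$fc_hidden)
    nout <- 3L * cfg$n_landmarks
    params$W2 <- matrix(stats::rnorm(cfg$fc_hidden * nout, 0,
                                     sqrt(1 / cfg$fc_hidden)),
                        cfg$fc_hidden, nout)
    params$b2 <- numeric(nout)
    # start with moderate predicted variance: softplus(0.5) ~ 0.97
    params$b2[(2L * cfg$n_landmarks + 1L):nout] <- 0.5
    list(params = params, plans = plans, flat_dim = D)
  })
}

predictor_forward <- function(net, cfg, img, keep = FALSE) {
  x <- matrix(as.numeric(img), ncol = 3L)    # (H*W) x 3, column-major
  cache <- list(x = list(x))
  p <- net$params
  for (i in seq_along(cfg$channels)) {
    cf <- conv_forward(x, p[[paste0("Wc", i)]], p[[paste0("bc", i)]],
                       net$plans[[i]])
    a <- relu(cf$y)
    if (keep) {
      cache$Xcol[[i]] <- cf$Xcol
      cache$pre[[i]] <- cf$y
      cache$x[[i + 1L]] <- a
    }
    x <- a
  }
  flat <- as.numeric(x)
  h_pre <- as.numeric(crossprod(p$W1, flat)) + p$b1
  h <- relu(h_pre)
  out <- as.numeric(crossprod(p$W2, h)) + p$b2
  L <- cfg$n_landmarks
  mu <- matrix(out[1:(2L * L)], L, 2L)
  sraw <- out[(2L * L + 1L):(3L * L)]
  res <- list(mu = mu, sigma2 = softplus(sraw), sraw = sraw)
  if (keep) {
    cache$flat <- flat; cache$h_pre <- h_pre; cache$h <- h
    res$cache <- cache
  }
  res
}

# Gradient of the mean NLL over 2L coordinates for one sample.
predictor_backward <- function(net, cfg, fwd, y, wmask = NULL) {
  p <- net$params
  L <- cfg$n_landmarks
  eps <- .Machine$double.eps
  e <- fwd$mu - y                              # L x 2
  s2 <- pmax(fwd$sigma2, eps)
  w <- if (is.null(wmask)) rep(1, L) else wmask
  nact <- max(sum(w > 0), 1L)
  denom <- 2L * nact
  loss <- sum(w * (0.5 * (2 * log(s2) + rowSums(e^2) / s2))) / denom
  dmu <- (w * e / s2) / denom                  # L x 2
  ds2 <- w * 0.5 * (2 / s2 - rowSums(e^2) / s2^2) / denom
  ds2[fwd$sigma2 < eps] <- 0
  dsraw <- ds2 / (1 + exp(-fwd$sraw))
  dout <- c(as.numeric(dmu), dsraw)
  cache <- fwd$cache
  grads <- list()
  grads$W2 <- cache$h %o% dout
  grads$b2 <- dout
  dh <- as.numeric(p$W2 %*% dout)
  dh[cache$h_pre <= 0] <- 0
  grads$W1 <- cache$flat %o% dh
  grads$b1 <- dh
  dx <- p$W1 %*% dh
  nC <- length(cfg$channels)
  dx <- matrix(dx, ncol = cfg$channels[nC])
  chans <- c(3L, cfg$channels)
  for (i in nC:1) {
    dx[cache$pre[[i]] <= 0] <- 0
    cb <- conv_backward(dx, cache$Xcol[[i]], p[[paste0("Wc", i)]],
                        net$plans[[i]], chans[i])
    grads[[paste0("Wc", i)]] <- cb$dW
    grads[[paste0("bc", i)]] <- cb$db
    dx <- cb$dx
  }
  list(loss = loss, grads = grads)
}

sample_loss <- function(net, cfg, img, y, wmask = NULL) {
  fwd <- predictor_forward(net, cfg, img)
  L <- cfg$n_landmarks
  w <- if (is.null(wmask)) rep(1, L) else wmask
  nact <- max(sum(w > 0), 1L)
  e <- fwd$mu - y
  s2 <- pmax(fwd$sigma2, .Machine$double.eps)
  nll <- sum(w * 0.5 * (2 * log(s2) + rowSums(e^2) / s2)) / (2L * nact)
  rmse <- sqrt(sum(w * rowSums(e^2)) / (2L * nact))
  c(nll = nll, rmse = rmse)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Normalize pixel coordinates to [-1, 1] (pixel centers at integers).
normalize_coords <- function(uv, W, H) {
  cbind(2 * (uv[, 1] + 0.5) / W - 1, 2 * (uv[, 2] + 0.5) / H - 1)
}

denormalize_coords <- function(xy, W, H) {
  cbind((xy[, 1] + 1) * W / 2 - 0.5, (xy[, 2] + 1) * H / 2 - 0.5)
}

resize_image <- function(img, H2, W2) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H == H2 && W == W2) return(img)
  sy <- (seq_len(H2) - 0.5) * H / H2 + 0.5 - 1   # 1-based source coords
  sx <- (seq_len(W2) - 0.5) * W / W2 + 0.5 - 1
  y0 <- pmin(pmax(floor(sy), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(sx), 1), W); x1 <- pmin(x0 + 1, W)
  fy <- sy - y0; fx <- sx - x0
  out <- array(0, c(H2, W2, 3))
  for (ch in 1:3) {
    p <- img[, , ch]
    out[, , ch] <- (1 - fy) %o% (1 - fx) * p[y0, x0] +
      (1 - fy) %o% fx * p[y0, x1] +
      fy %o% (1 - fx) * p[y1, x0] +
      fy %o% fx * p[y1, x1]
  }
  out
}

load_dataset <- function(manifest, cfg) {
  dir <- manifest$dir
  sz <- cfg$image_size
  samples <- manifest$samples
  W0 <- manifest$image_size; H0 <- manifest$image_size
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    img <- png::readPNG(file.path(dir, samples$image[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img <- img[, , 1:3, drop = FALSE]
    lm <- read_landmarks(file.path(dir, samples$landmarks[i]))
    if (nrow(lm$points) != cfg$n_landmarks)
      stop("manifest landmarks (", nrow(lm$points),
           ") inconsistent with cfg$n_landmarks (", cfg$n_landmarks, ")")
    pts <- (lm$points + 0.5) * sz / W0 - 0.5   # pixel-center-exact rescale
    out[[i]] <- list(image = resize_image(img, sz, sz),
                     points = pts,
                     visible = lm$visible,
                     mesh_id = samples$mesh_id[i])
  }
  out
}

#' Train the uncertainty-aware landmark regressor
#'
#' Minimizes the mean [gaussian_nll()] over all landmark coordinates of a
#' rendered synthetic dataset, with seeded shuffling, optional
#' augmentation, and early stopping on validation NLL ("train until
#' convergence", operationalized with a patience window). The training
#' log records NLL and RMSE per epoch, including the untrained epoch-0
#' state.
#'
#' @param manifest a dataset directory path or the manifest returned by
#'   [make_dataset()] (read via its `manifest.json`).
#' @param cfg a [predictor_config()].
#' @param verbose print per-epoch progress.
#' @return An object of class `landmark_predictor` with the trained
#'   parameters, the config, and a `log` data frame (epoch, train_nll,
#'   val_nll, val_rmse_norm, val_rmse_px).
#' @export
train_predictor <- function(manifest, cfg, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  data <- load_dataset(manifest, cfg)
  if (length(data) == 0L) stop("empty dataset")
  sz <- cfg$image_size
  net <- init_predictor_params(cfg)
  n <- length(data)
  n_val <- max(1L, round(cfg$val_fraction * n))
  ord <- local_rng(stage_seed(cfg$seed, "split"))(sample.int(n))
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- setdiff(ord, val_idx)
  if (length(tr_idx) == 0L) stop("empty dataset after validation split")

  targets <- lapply(data, function(s) normalize_coords(s$points, sz, sz))
  masks <- lapply(data, function(s) {
    if (cfg$mask_occluded && !is.null(s$visible)) as.numeric(s$visible)
    else NULL
  })

  eval_set <- function(idx) {
    m <- vapply(idx, function(i)
      sample_loss(net, cfg, data[[i]]$image, targets[[i]], masks[[i]]),
      c(nll = 0, rmse = 0))
    rowMeans(m)
  }

  state <- list(m = lapply(net$params, function(p) p * 0),
                v = lapply(net$params, function(p) p * 0))
  tstep <- 0L
  log <- list()
  ev_tr <- eval_set(tr_idx); ev_va <- eval_set(val_idx)
  log[[1]] <- data.frame(epoch = 0L, train_nll = ev_tr["nll"],
                         val_nll = ev_va["nll"],
                         val_rmse_norm = ev_va["rmse"],
                         val_rmse_px = ev_va["rmse"] * sz / 2)
  best <- list(nll = ev_va["nll"], params = net$params, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    idx <- local_rng(stage_seed(cfg$seed, paste0("shuffle/", epoch)))(
      sample(tr_idx))
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    tr_loss <- 0
    for (bb in batches) {
      acc <- NULL
      bl <- 0
      for (i in bb) {
        img <- data[[i]]$image
        y <- targets[[i]]
        if (!is.null(cfg$augment_cfg)) {
          aseed <- stage_seed(cfg$seed, paste0("aug/", epoch, "/", i))
          pts_px <- denormalize_coords(y, sz, sz)
          a <- do.call(augment, c(list(image = img,
                                       landmarks = landmarks2d(pts_px),
                                       seed = aseed), cfg$augment_cfg))
          img <- a$image
          y <- normalize_coords(a$landmarks$points, sz, sz)
        }
        fwd <- predictor_forward(net, cfg, img, keep = TRUE)
        bk <- predictor_backward(net, cfg, fwd, y, masks[[i]])
        bl <- bl + bk$loss
        if (is.null(acc)) acc <- bk$grads
        else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + bk$grads[[nm]]
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(bb)
      if (!all(vapply(acc, function(g) all(is.finite(g)), TRUE)))
        stop("non-finite loss gradient during training; diagnostics: epoch ",
             epoch)
      tstep <- tstep + 1L
      up <- adam_step(net$params, acc, state, cfg$lr, tstep)
      net$params <- up$params
      state <- up$state
      tr_loss <- tr_loss + bl
    }
    ev_va <- eval_set(val_idx)
    log[[epoch + 1L]] <- data.frame(epoch = epoch,
                                    train_nll = tr_loss / length(idx),
                                    val_nll = ev_va["nll"],
                                    val_rmse_norm = ev_va["rmse"],
                                    val_rmse_px = ev_va["rmse"] * sz / 2)
    if (verbose)
      message(sprintf("epoch %3d  train NLL %.4f  val NLL %.4f  val RMSE %.2f px",
                      epoch, tr_loss / length(idx), ev_va["nll"],
                      ev_va["rmse"] * sz / 2))
    if (ev_va["nll"] < best$nll - 1e-6) {
      best <- list(nll = ev_va["nll"], params = net$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  net$params <- best$params
  structure(list(params = net$params, plans = net$plans, cfg = cfg,
                 log = do.call(rbind, log), best_epoch = best$epoch),
            class = "landmark_predictor")
}

#' @export
print.landmark_predictor <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(
    "landmark_predictor: %d landmarks @ %dpx, %d epochs (best %d)\n",
    x$cfg$n_landmarks, x$cfg$image_size, max(x$log$epoch), x$best_epoch))
  cat(sprintf("  final val NLL %.4f, val RMSE %.3f px\n",
              last$val_nll, last$val_rmse_px))
  invisible(x)
}

#' Predict landmarks (with uncertainty) on an image
#'
#' Resizes the input to the training resolution if needed and reports
#' landmark coordinates and variances back on the ORIGINAL image scale.
#'
#' @param object a trained [train_predictor()] model.
#' @param image H x W x 3 array in `[0, 1]`.
#' @param ... unused.
#' @return A [landmarks2d()] with `sigma2` in squared original pixels.
#' @export
predict.landmark_predictor <- function(object, image, ...) {
  if (is.null(object$params)) stop("uninitialized model")
  cfg <- object$cfg
  H <- dim(image)[1]; W <- dim(image)[2]
  img <- resize_image(image, cfg$image_size, cfg$image_size)
  fwd <- predictor_forward(object, cfg, img)
  pts <- denormalize_coords(fwd$mu, cfg$image_size, cfg$image_size)
  scale_back <- W / cfg$image_size
  landmarks2d((pts + 0.5) * scale_back - 0.5,
              sigma2 = pmax(fwd$sigma2, .Machine$double.eps) *
                (cfg$image_size / 2 * scale_back)^2)
}
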