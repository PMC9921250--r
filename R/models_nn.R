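# Minimal feed-forward network machinery: shared Adam optimiser, an MLP with
# ReLU hidden layers and sigmoid output, and a 1-D CNN that reads the tabular
# feature vector as a length-p single-channel sequence (same padding, no
# pooling) followed by a dense layer and a 2-way softmax. Sized for clinical
# tabular data (tens of features), so plain R matrix arithmetic suffices.

.adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# seeded He-uniform init
.init_mat <- function(nin, nout)
  matrix(runif(nin * nout, -1, 1) * sqrt(6 / nin), nin, nout)

.epoch_split <- function(n, val_frac) {
  nv <- floor(n * val_frac)
  if (nv < 1 || n - nv < 2) return(list(train = seq_len(n), val = integer(0)))
  val <- sample(n, nv)
  list(train = setdiff(seq_len(n), val), val = val)
}

#' Multilayer perceptron classifier (ReLU hidden layers, Adam)
#'
#' Three hidden ReLU layers by default, sigmoid output trained with binary
#' cross-entropy, Adam at learning rate 0.01, mini-batches of 32, early
#' stopping on a 10\% validation split with patience 20. Fully seeded.
#'
#' @param x feature matrix; @param y 0/1 labels.
#' @param hidden integer vector of hidden-layer widths.
#' @param lr,epochs,batch,val_frac,patience training schedule.
#' @param seed RNG seed.
#' @return object of class `mlp_model`.
#' @keywords internal
mlp_fit <- function(x, y, hidden = c(32, 32, 32), lr = 0.01, epochs = 200L,
                    batch = 32L, val_frac = 0.1, patience = 20L, seed = 1L) {
  x <- as.matrix(x)
  with_seed(seed, {
    dims <- c(ncol(x), hidden, 1L)
    nl <- length(dims) - 1L
    params <- list()
    for (l in seq_len(nl)) {
      params[[2 * l - 1]] <- .init_mat(dims[l], dims[l + 1])
      params[[2 * l]] <- matrix(0, 1, dims[l + 1])
    }
    forward <- function(par, xb) {
      acts <- list(xb)
      for (l in seq_len(nl)) {
        z <- sweep(acts[[l]] %*% par[[2 * l - 1]], 2, -par[[2 * l]], "-")
        acts[[l + 1]] <- if (l < nl) pmax(z, 0) else z
      }
      acts
    }
    bce <- function(p, yy) -mean(yy * log(pmax(p, 1e-12)) +
                                 (1 - yy) * log(pmax(1 - p, 1e-12)))
    sp <- .epoch_split(nrow(x), val_frac)
    state <- .adam_init(params)
    best <- list(loss = Inf, params = params, since = 0L)
    for (ep in seq_len(epochs)) {
      idx <- sample(sp$train)
      for (start in seq(1, length(idx), by = batch)) {
        b <- idx[start:min(start + batch - 1, length(idx))]
        acts <- forward(params, x[b, , drop = FALSE])
        p <- sigmoid(acts[[nl + 1]])
        delta <- (p - y[b]) / length(b)
        grads <- vector("list", 2 * nl)
        for (l in rev(seq_len(nl))) {
          grads[[2 * l - 1]] <- t(acts[[l]]) %*% delta
          grads[[2 * l]] <- matrix(colSums(delta), 1)
          if (l > 1)
            delta <- (delta %*% t(params[[2 * l - 1]])) * (acts[[l]] > 0)
        }
        up <- .adam_step(params, grads, state, lr)
        params <- up$params; state <- up$state
      }
      if (length(sp$val)) {
        vp <- sigmoid(forward(params, x[sp$val, , drop = FALSE])[[nl + 1]])
        vl <- bce(vp, y[sp$val])
        if (vl < best$loss - 1e-6) best <- list(loss = vl, params = params, since = 0L)
        else {
          best$since <- best$since + 1L
          if (best$since >= patience) break
        }
      }
    }
    final <- if (length(sp$val)) best$params else params
    structure(list(params = final, nl = nl), class = "mlp_model")
  })
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  a <- as.matrix(newdata)
  for (l in seq_len(object$nl)) {
    z <- sweep(a %*% object$params[[2 * l - 1]], 2,
               -object$params[[2 * l]], "-")
    a <- if (l < object$nl) pmax(z, 0) else z
  }
  drop(sigmoid(a))
}

# ---- 1-D CNN -------------------------------------------------------------

# im2col for kernel 3, same padding: (B, p, C) -> (B*p, 3C)
.im2col3 <- function(a) {
  d <- dim(a); B <- d[1]; p <- d[2]; C <- d[3]
  out <- matrix(0, B * p, 3 * C)
  for (o in -1:1) {
    src <- seq_len(p) + o
    ok <- src >= 1 & src <= p
    block <- (o + 1) * C + seq_len(C)
    # row (t-1)*B + b of the col matrix holds position t of sample b
    m <- matrix(a[, src[ok], , drop = FALSE], B * sum(ok), C)
    out[as.vector(outer(seq_len(B), (which(ok) - 1) * B, "+")), block] <- m
  }
  out
}

.col2im3 <- function(dcol, B, p, C) {
  da <- array(0, c(B, p, C))
  for (o in -1:1) {
    src <- seq_len(p) + o
    ok <- src >= 1 & src <= p
    block <- (o + 1) * C + seq_len(C)
    rows <- as.vector(outer(seq_len(B), (which(ok) - 1) * B, "+"))
    contrib <- array(dcol[rows, block], c(B, sum(ok), C))
    da[, src[ok], ] <- da[, src[ok], , drop = FALSE] + contrib
  }
  da
}

.conv_forward <- function(a, W, b) {
  d <- dim(a); B <- d[1]; p <- d[2]
  cols <- .im2col3(a)
  z <- sweep(cols %*% W, 2, -b, "-")
  list(z = array(z, c(B, p, ncol(W))), cols = cols)
}

#' 1-D convolutional network classifier for tabular rows
#'
#' Treats the p features of a row as a length-p single-channel sequence.
#' Architecture: conv(32, k=3) -> conv(32, k=3) -> conv(64, k=3) (ReLU, same
#' padding, stride 1, no pooling) -> dense(128, ReLU) -> dense(2) -> softmax.
#' Trained with cross-entropy and Adam (lr 0.01), mini-batches of 32, early
#' stopping on a 10\% validation split with patience 20.
#'
#' @param x feature matrix; @param y 0/1 labels.
#' @param filters filter counts of the three conv layers.
#' @param fc_size dense-layer width.
#' @param lr,epochs,batch,val_frac,patience training schedule.
#' @param seed RNG seed.
#' @return object of class `cnn_model`.
#' @keywords internal
cnn_fit <- function(x, y, filters = c(32, 32, 64), fc_size = 128, lr = 0.01,
                    epochs = 200L, batch = 32L, val_frac = 0.1,
                    patience = 20L, seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  with_seed(seed, {
    chans <- c(1L, filters)
    params <- list()
    for (l in 1:3) {
      params[[2 * l - 1]] <- .init_mat(3 * chans[l], chans[l + 1])
      params[[2 * l]] <- matrix(0, 1, chans[l + 1])
    }
    params[[7]] <- .init_mat(p * filters[3], fc_size)
    params[[8]] <- matrix(0, 1, fc_size)
    params[[9]] <- .init_mat(fc_size, 2)
    params[[10]] <- matrix(0, 1, 2)

    forward <- function(par, xb) {
      B <- nrow(xb)
      a <- array(xb, c(B, p, 1))
      cache <- list()
      for (l in 1:3) {
        cv <- .conv_forward(a, par[[2 * l - 1]], par[[2 * l]])
        cache[[l]] <- list(cols = cv$cols, pre = cv$z)
        a <- pmax(cv$z, 0)
      }
      flat <- matrix(a, B, p * filters[3])
      zf <- sweep(flat %*% par[[7]], 2, -par[[8]], "-")
      hf <- pmax(zf, 0)
      logits <- sweep(hf %*% par[[9]], 2, -par[[10]], "-")
      mx <- apply(logits, 1, max)
      el <- exp(logits - mx)
      probs <- el / rowSums(el)
      list(cache = cache, a3 = a, flat = flat, zf = zf, hf = hf, probs = probs)
    }
    ce <- function(probs, yy)
      -mean(log(pmax(probs[cbind(seq_along(yy), yy + 1)], 1e-12)))

    sp <- .epoch_split(nrow(x), val_frac)
    state <- .adam_init(params)
    best <- list(loss = Inf, params = params, since = 0L)
    for (ep in seq_len(epochs)) {
      idx <- sample(sp$train)
      for (start in seq(1, length(idx), by = batch)) {
        b <- idx[start:min(start + batch - 1, length(idx))]
        B <- length(b)
        fw <- forward(params, x[b, , drop = FALSE])
        onehot <- matrix(0, B, 2)
        onehot[cbind(seq_len(B), y[b] + 1)] <- 1
        dlogits <- (fw$probs - onehot) / B
        grads <- vector("list", 10)
        grads[[9]] <- t(fw$hf) %*% dlogits
        grads[[10]] <- matrix(colSums(dlogits), 1)
        dhf <- (dlogits %*% t(params[[9]])) * (fw$zf > 0)
        grads[[7]] <- t(fw$flat) %*% dhf
        grads[[8]] <- matrix(colSums(dhf), 1)
        da <- array(dhf %*% t(params[[7]]), c(B, p, filters[3]))
        for (l in 3:1) {
          dz <- da * (fw$cache[[l]]$pre > 0)
          dzm <- matrix(dz, B * p, dim(dz)[3])
          grads[[2 * l - 1]] <- t(fw$cache[[l]]$cols) %*% dzm
          grads[[2 * l]] <- matrix(colSums(dzm), 1)
          if (l > 1) {
            dcol <- dzm %*% t(params[[2 * l - 1]])
            da <- .col2im3(dcol, B, p, chans[l])
          }
        }
        up <- .adam_step(params, grads, state, lr)
        params <- up$params; state <- up$state
      }
      if (length(sp$val)) {
        vp <- forward(params, x[sp$val, , drop = FALSE])$probs
        vl <- ce(vp, y[sp$val])
        if (vl < best$loss - 1e-6) best <- list(loss = vl, params = params, since = 0L)
        else {
          best$since <- best$since + 1L
          if (best$since >= patience) break
        }
      }
    }
    final <- if (length(sp$val)) best$params else params
    structure(list(params = final, p = p, filters = filters), class = "cnn_model")
  })
}

#' @export
predict.cnn_model <- function(object, newdata, ...) {
  xb <- as.matrix(newdata)
  par <- object$params
  p <- object$p
  B <- nrow(xb)
  a <- array(xb, c(B, p, 1))
  for (l in 1:3) {
    cv <- .conv_forward(a, par[[2 * l - 1]], par[[2 * l]])
    a <- pmax(cv$z, 0)
  }
  flat <- matrix(a, B, p * object$filters[3])
  hf <- pmax(sweep(flat %*% par[[7]], 2, -par[[8]], "-"), 0)
  logits <- sweep(hf %*% par[[9]], 2, -par[[10]], "-")
  mx <- apply(logits, 1, max)
  el <- exp(logits - mx)
  (el / rowSums(el))[, 2]     # softmax positive-class probability
}
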