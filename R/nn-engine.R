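#' @include stacking.R
NULL

# ---------------------------------------------------------------------
# Native sequential/residual CNN engine.
#
# A network is a list of layer descriptors; parameters live in a flat
# named list (arrays), batch-norm running statistics in a parallel
# `buffers` list. Activations are (H, W, C, N) arrays up to the first
# flatten/global-pool, then (D, N) matrices. Convolution and max
# pooling run in compiled code; everything else is vectorized R.
# ---------------------------------------------------------------------

.lyr <- local({
  counter <- 0L
  # first parameter deliberately dot-prefixed: several layer fields
  # ("k", "pad", ...) would otherwise partially match a name like
  # "kind" and silently hijack it
  function(.kind, ...) {
    counter <<- counter + 1L
    c(list(kind = .kind, id = sprintf("L%03d", counter)), list(...))
  }
})

.reset_layer_ids <- function() {
  environment(.lyr)$counter <- 0L
}

.conv_lyr <- function(inC, outC, k, stride = 1L, pad = 0L,
                      role = "conv")
  .lyr(role, inC = inC, outC = outC, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
.bn_lyr <- function(C) .lyr("batch_norm", C = C)
.relu_lyr <- function() .lyr("activation")
.maxpool_lyr <- function(k, stride, pad = 0L)
  .lyr("pool", pool = "max", k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
.gap_lyr <- function() .lyr("pool", pool = "global_avg")
.flatten_lyr <- function() .lyr("flatten")
.fc_lyr <- function(inD, outD)
  .lyr("fully_connected", inD = as.integer(inD), outD = as.integer(outD))
.res_lyr <- function(branch, shortcut = NULL)
  .lyr("residual_block", branch = branch, shortcut = shortcut,
       variant = if (is.null(shortcut)) "identity" else "projection")

# ---- parameter initialization (He for convs, Xavier for FC) ----

.init_layer_params <- function(layers, params, buffers) {
  for (ly in layers) {
    if (ly$kind %in% c("conv", "shortcut_conv")) {
      fanin <- ly$k * ly$k * ly$inC
      params[[paste0(ly$id, ".W")]] <-
        matrix(rnorm(fanin * ly$outC, 0, sqrt(2 / fanin)), fanin, ly$outC)
      params[[paste0(ly$id, ".b")]] <- numeric(ly$outC)
    } else if (ly$kind == "batch_norm") {
      params[[paste0(ly$id, ".gamma")]] <- rep(1, ly$C)
      params[[paste0(ly$id, ".beta")]] <- numeric(ly$C)
      buffers[[paste0(ly$id, ".rmean")]] <- numeric(ly$C)
      buffers[[paste0(ly$id, ".rvar")]] <- rep(1, ly$C)
    } else if (ly$kind == "fully_connected") {
      s <- sqrt(6 / (ly$inD + ly$outD))
      params[[paste0(ly$id, ".W")]] <-
        matrix(runif(ly$inD * ly$outD, -s, s), ly$outD, ly$inD)
      params[[paste0(ly$id, ".b")]] <- numeric(ly$outD)
    } else if (ly$kind == "residual_block") {
      res <- .init_layer_params(ly$branch, params, buffers)
      params <- res$params; buffers <- res$buffers
      if (!is.null(ly$shortcut)) {
        res <- .init_layer_params(ly$shortcut, params, buffers)
        params <- res$params; buffers <- res$buffers
      }
    }
  }
  list(params = params, buffers = buffers)
}

# trainable parameter names, in layer order
.collect_params <- function(layers) {
  nm <- character(0)
  collect <- function(lys) {
    for (ly in lys) {
      if (ly$kind %in% c("conv", "shortcut_conv", "fully_connected"))
        nm <<- c(nm, paste0(ly$id, ".W"), paste0(ly$id, ".b"))
      else if (ly$kind == "batch_norm")
        nm <<- c(nm, paste0(ly$id, ".gamma"), paste0(ly$id, ".beta"))
      else if (ly$kind == "residual_block") {
        collect(ly$branch)
        if (!is.null(ly$shortcut)) collect(ly$shortcut)
      }
    }
  }
  collect(layers)
  nm
}

# ---- batch norm helpers ----

.bn_stats <- function(X) {
  d <- dim(X); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  B <- matrix(X, HW, C * N)
  s1 <- matrix(.colSums(B, HW, C * N), C, N)
  s2 <- matrix(.colSums(B * B, HW, C * N), C, N)
  n <- HW * N
  m <- rowSums(s1) / n
  v <- rowSums(s2) / n - m^2
  list(mean = m, var = pmax(v, 0), n = n)
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# ---- forward ----

.nn_forward <- function(layers, params, buffers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    id <- ly$id
    if (ly$kind %in% c("conv", "shortcut_conv")) {
      caches[[i]] <- list(X = X)
      X <- .conv_fwd(X, params[[paste0(id, ".W")]],
                     params[[paste0(id, ".b")]], ly$k, ly$stride, ly$pad)
    } else if (ly$kind == "batch_norm") {
      d <- dim(X); HW <- d[1] * d[2]
      if (training) {
        st <- .bn_stats(X)
        m <- st$mean; v <- st$var
        buffers[[paste0(id, ".rmean")]] <-
          (1 - .BN_MOMENTUM) * buffers[[paste0(id, ".rmean")]] +
          .BN_MOMENTUM * m
        buffers[[paste0(id, ".rvar")]] <-
          (1 - .BN_MOMENTUM) * buffers[[paste0(id, ".rvar")]] +
          .BN_MOMENTUM * v * st$n / max(st$n - 1, 1)
      } else {
        m <- buffers[[paste0(id, ".rmean")]]
        v <- buffers[[paste0(id, ".rvar")]]
      }
      invstd <- 1 / sqrt(v + .BN_EPS)
      xhat <- (X - rep(m, each = HW)) * rep(invstd, each = HW)
      caches[[i]] <- list(xhat = xhat, invstd = invstd, dims = d)
      X <- xhat * rep(params[[paste0(id, ".gamma")]], each = HW) +
        rep(params[[paste0(id, ".beta")]], each = HW)
      dim(X) <- d
    } else if (ly$kind == "activation") {
      mask <- X > 0
      caches[[i]] <- list(mask = mask)
      X <- X * mask
    } else if (ly$kind == "pool" && ly$pool == "max") {
      caches[[i]] <- list(xdim = dim(X))
      mp <- .maxpool_fwd(X, ly$k, ly$stride, ly$pad)
      caches[[i]]$argmax <- mp$argmax
      X <- mp$Y
    } else if (ly$kind == "pool" && ly$pool == "global_avg") {
      d <- dim(X); HW <- d[1] * d[2]
      caches[[i]] <- list(xdim = d)
      X <- matrix(.colSums(matrix(X, HW, d[3] * d[4]), HW, d[3] * d[4]),
                  d[3], d[4]) / HW
    } else if (ly$kind == "flatten") {
      caches[[i]] <- list(xdim = dim(X))
      dim(X) <- c(prod(dim(X)[1:3]), dim(X)[4])
    } else if (ly$kind == "fully_connected") {
      caches[[i]] <- list(X = X)
      X <- params[[paste0(id, ".W")]] %*% X + params[[paste0(id, ".b")]]
    } else if (ly$kind == "residual_block") {
      xin <- X
      br <- .nn_forward(ly$branch, params, buffers, X, training)
      buffers <- br$buffers
      if (is.null(ly$shortcut)) {
        sc <- list(out = xin, caches = NULL)
      } else {
        sc <- .nn_forward(ly$shortcut, params, buffers, xin, training)
        buffers <- sc$buffers
      }
      s <- br$out + sc$out
      mask <- s > 0
      caches[[i]] <- list(branch = br$caches, shortcut = sc$caches,
                          mask = mask)
      X <- s * mask
    } else stop("unknown layer kind: ", ly$kind)
  }
  list(out = X, caches = caches, buffers = buffers)
}

# ---- backward ----

.nn_backward <- function(layers, params, caches, dY) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    id <- ly$id
    ca <- caches[[i]]
    if (ly$kind %in% c("conv", "shortcut_conv")) {
      bw <- .conv_bwd(ca$X, params[[paste0(id, ".W")]], dY,
                      ly$k, ly$stride, ly$pad)
      grads[[paste0(id, ".W")]] <- bw$dW
      grads[[paste0(id, ".b")]] <- bw$db
      dY <- bw$dX
    } else if (ly$kind == "batch_norm") {
      d <- ca$dims; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
      n <- HW * N
      xhat <- ca$xhat
      chsum <- function(A) {
        B <- matrix(A, HW, C * N)
        rowSums(matrix(.colSums(B, HW, C * N), C, N))
      }
      dgamma <- chsum(dY * xhat)
      dbeta <- chsum(dY)
      grads[[paste0(id, ".gamma")]] <- dgamma
      grads[[paste0(id, ".beta")]] <- dbeta
      g <- rep(params[[paste0(id, ".gamma")]], each = HW)
      istd <- rep(ca$invstd, each = HW)
      dxhat <- dY * g
      gam <- params[[paste0(id, ".gamma")]]
      # per channel: sum(dxhat) = gamma*dbeta, sum(dxhat*xhat) = gamma*dgamma
      dY <- istd * (dxhat - rep(gam * dbeta, each = HW) / n -
                      xhat * rep(gam * dgamma, each = HW) / n)
      dim(dY) <- d
    } else if (ly$kind == "activation") {
      dY <- dY * ca$mask
    } else if (ly$kind == "pool" && ly$pool == "max") {
      dY <- .maxpool_bwd(dY, ca$argmax, ca$xdim)
    } else if (ly$kind == "pool" && ly$pool == "global_avg") {
      d <- ca$xdim; HW <- d[1] * d[2]
      dX <- array(rep(as.numeric(dY), each = HW) / HW, dim = d)
      dY <- dX
    } else if (ly$kind == "flatten") {
      dim(dY) <- ca$xdim
    } else if (ly$kind == "fully_connected") {
      grads[[paste0(id, ".W")]] <- dY %*% t(ca$X)
      grads[[paste0(id, ".b")]] <- rowSums(dY)
      dY <- t(params[[paste0(id, ".W")]]) %*% dY
    } else if (ly$kind == "residual_block") {
      ds <- dY * ca$mask
      gb <- .nn_backward(ly$branch, params, ca$branch, ds)
      grads[names(gb$grads)] <- gb$grads
      if (is.null(ly$shortcut)) {
        dsc <- ds
      } else {
        gs <- .nn_backward(ly$shortcut, params, ca$shortcut, ds)
        grads[names(gs$grads)] <- gs$grads
        dsc <- gs$dX
      }
      dY <- gb$dX + dsc
    }
  }
  list(grads = grads, dX = dY)
}

# ---- softmax / cross-entropy ----

.softmax <- function(logits) {
  z <- logits - rep(apply(logits, 2, max), each = nrow(logits))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(logits))
}

.ce_loss <- function(probs, yIdx) {
  n <- length(yIdx)
  -mean(log(pmax(probs[cbind(yIdx, seq_len(n))], 1e-12)))
}

.ce_grad <- function(probs, yIdx) {
  n <- length(yIdx)
  d <- probs
  d[cbind(yIdx, seq_len(n))] <- d[cbind(yIdx, seq_len(n))] - 1
  d / n
}

# ---- Adam ----

.adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
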