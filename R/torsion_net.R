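# Torsion-angle prediction: windowed per-residue features into a small 1-D
# convolutional network with sin/cos output encoding. The network (forward
# pass, analytic backpropagation, Adam) is implemented here in base R with
# batched array algebra; the architecture is fixed small (three conv blocks,
# two dense layers, 4 outputs).

#' Feature window around a residue
#'
#' Extracts the `(2w + 1) x 24` block of per-residue features centered on
#' `position`; rows falling off either chain end are zero-padded, matching
#' the [0, 1] normalization floor of the features.
#'
#' @param features L x 24 numeric matrix in [0, 1] (or a `feature_table`).
#' @param position center residue index (1-based).
#' @param w context half-width in residues (default 17, giving 35 rows).
#' @return `(2w + 1) x 24` matrix.
#' @export
build_window <- function(features, position, w = 17L) {
  if (inherits(features, "feature_table")) features <- features$features
  stopifnot(is.matrix(features), ncol(features) == 24L)
  if (w < 1L) stop("parameter error: window half-width must be >= 1")
  L <- nrow(features)
  stopifnot(position >= 1L, position <= L)
  rows <- (position - w):(position + w)
  out <- matrix(0, 2L * w + 1L, ncol(features))
  inside <- rows >= 1L & rows <= L
  out[inside, ] <- features[rows[inside], , drop = FALSE]
  out
}

#' Construct the torsion-prediction network
#'
#' Architecture: a first convolutional layer of 16 width-5 filters sliding
#' along the window rows, max-pool (width 2), two further convolutional
#' layers (width-3 filters, 32 then 64 channels, each followed by a width-2
#' max-pool), then two fully-connected layers ending in 4 linear outputs
#' `(sin phi, cos phi, sin psi, cos psi)`. Weights are initialized from a
#' zero-centered Gaussian with per-layer standard deviation `5/N` (N = layer
#' fan-in), the literal stated rule; `init = "sqrt5/N"` selects the
#' `sqrt(5/N)` variant.
#'
#' @param w context half-width (default 17; window has 2w + 1 rows).
#' @param n_features feature columns per residue (default 24).
#' @param hidden size of the first dense layer (default 64).
#' @param init `"5/N"` (default) or `"sqrt5/N"`.
#' @param seed RNG seed for the initialization.
#' @return object of class `torsion_net`.
#' @export
torsion_net <- function(w = 17L, n_features = 24L, hidden = 64L,
                        init = c("5/N", "sqrt5/N"), seed = 1L) {
  init <- match.arg(init)
  t_in <- 2L * w + 1L
  arch <- list(
    list(type = "conv", k = 5L, out = 16L),
    list(type = "pool"),
    list(type = "conv", k = 3L, out = 32L),
    list(type = "pool"),
    list(type = "conv", k = 3L, out = 64L),
    list(type = "pool"),
    list(type = "flatten"),
    list(type = "dense", out = hidden, act = "relu"),
    list(type = "dense", out = 4L, act = "linear"))
  set.seed(seed)
  t_cur <- t_in; c_cur <- n_features
  layers <- list()
  for (ly in arch) {
    if (ly$type == "conv") {
      fan_in <- ly$k * c_cur
      sdv <- if (init == "5/N") 5 / fan_in else sqrt(5 / fan_in)
      ly$W <- matrix(rnorm(fan_in * ly$out, 0, sdv), fan_in, ly$out)
      ly$b <- numeric(ly$out)
      t_cur <- t_cur - ly$k + 1L; c_cur <- ly$out
    } else if (ly$type == "pool") {
      t_cur <- t_cur %/% 2L
    } else if (ly$type == "flatten") {
      c_cur <- t_cur * c_cur; t_cur <- 1L
    } else if (ly$type == "dense") {
      fan_in <- c_cur
      sdv <- if (init == "5/N") 5 / fan_in else sqrt(5 / fan_in)
      ly$W <- matrix(rnorm(fan_in * ly$out, 0, sdv), fan_in, ly$out)
      ly$b <- numeric(ly$out)
      c_cur <- ly$out
    }
    layers[[length(layers) + 1L]] <- ly
  }
  structure(list(layers = layers, w = w, n_features = n_features,
                 init = init, seed = seed),
            class = "torsion_net")
}

#' @export
print.torsion_net <- function(x, ...) {
  cat("Torsion-angle CNN (window ", 2 * x$w + 1, " x ", x$n_features,
      ", init sd = ", x$init, ", seed ", x$seed, ")\n", sep = "")
  for (ly in x$layers) {
    cat(" ", ly$type,
        if (ly$type == "conv") paste0("k=", ly$k, " channels=", ly$out)
        else if (ly$type == "dense") paste0("units=", ly$out, " (", ly$act, ")")
        else "", "\n")
  }
  invisible(x)
}

# ---- batched array layers; input A is B x T x C -------------------------

conv_fwd <- function(A, W, b, k) {
  dm <- dim(A); B <- dm[1]; Tt <- dm[2]; Cin <- dm[3]
  t_out <- Tt - k + 1L
  U <- matrix(0, B * t_out, k * Cin)
  for (d in seq_len(k)) {
    sl <- A[, d:(d + t_out - 1L), , drop = FALSE]
    dim(sl) <- c(B * t_out, Cin)
    U[, ((d - 1L) * Cin + 1L):(d * Cin)] <- sl
  }
  Z <- U %*% W
  Z <- Z + rep(b, each = nrow(Z))
  dim(Z) <- c(B, t_out, ncol(W))
  list(Z = Z, U = U)
}

conv_bwd <- function(dZ, U, W, k, in_dim) {
  B <- in_dim[1]; Tt <- in_dim[2]; Cin <- in_dim[3]
  t_out <- dim(dZ)[2]; Cout <- dim(dZ)[3]
  dZm <- dZ; dim(dZm) <- c(B * t_out, Cout)
  dW <- crossprod(U, dZm)
  db <- colSums(dZm)
  dU <- dZm %*% t(W)
  dA <- array(0, in_dim)
  for (d in seq_len(k)) {
    sl <- dU[, ((d - 1L) * Cin + 1L):(d * Cin), drop = FALSE]
    dim(sl) <- c(B, t_out, Cin)
    dA[, d:(d + t_out - 1L), ] <- dA[, d:(d + t_out - 1L), , drop = FALSE] + sl
  }
  list(dA = dA, dW = dW, db = db)
}

pool_fwd <- function(A) {
  dm <- dim(A); np <- dm[2] %/% 2L
  A1 <- A[, seq(1L, 2L * np, 2L), , drop = FALSE]
  A2 <- A[, seq(2L, 2L * np, 2L), , drop = FALSE]
  mask <- A1 >= A2
  list(Z = pmax(A1, A2), mask = mask, in_dim = dm)
}

pool_bwd <- function(dZ, mask, in_dim) {
  np <- dim(dZ)[2]
  dA <- array(0, in_dim)
  dA[, seq(1L, 2L * np, 2L), ] <- dZ * mask
  dA[, seq(2L, 2L * np, 2L), ] <- dZ * !mask
  dA
}

net_forward <- function(model, A) {
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "conv") {
      cf <- conv_fwd(A, ly$W, ly$b, ly$k)
      caches[[li]] <- list(U = cf$U, in_dim = dim(A), Z = cf$Z)
      A <- cf$Z * (cf$Z > 0)                    # ReLU
    } else if (ly$type == "pool") {
      pf <- pool_fwd(A)
      caches[[li]] <- pf
      A <- pf$Z
    } else if (ly$type == "flatten") {
      caches[[li]] <- list(in_dim = dim(A))
      dim(A) <- c(dim(A)[1], prod(dim(A)[-1]))
    } else if (ly$type == "dense") {
      Z <- A %*% ly$W + rep(ly$b, each = nrow(A))
      caches[[li]] <- list(A_in = A, Z = Z)
      A <- if (ly$act == "relu") Z * (Z > 0) else Z
    }
  }
  list(out = A, caches = caches)
}

net_backward <- function(model, caches, dOut) {
  grads <- vector("list", length(model$layers))
  dA <- dOut
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    cc <- caches[[li]]
    if (ly$type == "dense") {
      dZ <- if (ly$act == "relu") dA * (cc$Z > 0) else dA
      grads[[li]] <- list(dW = crossprod(cc$A_in, dZ), db = colSums(dZ))
      dA <- dZ %*% t(ly$W)
    } else if (ly$type == "flatten") {
      dim(dA) <- cc$in_dim
    } else if (ly$type == "pool") {
      dA <- pool_bwd(dA, cc$mask, cc$in_dim)
    } else if (ly$type == "conv") {
      dZ <- dA * (cc$Z > 0)
      cb <- conv_bwd(dZ, cc$U, ly$W, ly$k, cc$in_dim)
      grads[[li]] <- list(dW = cb$dW, db = cb$db)
      dA <- cb$dA
    }
  }
  grads
}

#' Network forward pass
#'
#' @param model a `torsion_net`.
#' @param windows one window matrix `(2w+1) x 24`, or a `B x (2w+1) x 24`
#'   array of windows.
#' @return B x 4 matrix of raw `(sin phi, cos phi, sin psi, cos psi)`
#'   outputs.
#' @export
predict_raw <- function(model, windows) {
  if (is.matrix(windows)) {
    A <- array(windows, c(1L, dim(windows)))
  } else A <- windows
  net_forward(model, A)$out
}

#' Encode angles as sin/cos pairs
#' @param phi,psi angles in degrees.
#' @return length(phi) x 4 matrix `(sin phi, cos phi, sin psi, cos psi)`.
#' @export
encode_angles <- function(phi, psi) {
  r <- pi / 180
  cbind(sin(phi * r), cos(phi * r), sin(psi * r), cos(psi * r))
}

#' Decode sin/cos outputs to angles
#'
#' Each `(sin, cos)` pair is renormalized to the unit circle and decoded
#' with the quadrant-aware arctangent; results lie in (-180, 180].
#'
#' @param raw length-4 vector or B x 4 matrix
#'   `(sin phi, cos phi, sin psi, cos psi)`.
#' @return data.frame with columns `phi`, `psi` in degrees.
#' @export
decode_angles <- function(raw) {
  if (is.null(dim(raw))) raw <- matrix(raw, 1L)
  stopifnot(ncol(raw) == 4L)
  dec <- function(s, c) {
    n <- sqrt(s^2 + c^2)
    if (any(n == 0))
      stop("undefined angle: sin and cos outputs are both zero")
    a <- atan2(s / n, c / n) * 180 / pi
    wrap_angle(a)
  }
  data.frame(phi = dec(raw[, 1], raw[, 2]), psi = dec(raw[, 3], raw[, 4]))
}

#' Train the torsion network
#'
#' Minimizes the mean squared error between raw outputs and the sin/cos
#' encoding of the target angles, with full-batch Adam updates. Training is
#' deterministic for a fixed model (its init seed) and fixed data.
#'
#' @param model a `torsion_net`.
#' @param windows B x (2w+1) x 24 array of feature windows.
#' @param phi,psi target angles in degrees, length B.
#' @param epochs number of passes (default 200).
#' @param lr Adam learning rate (default 0.01).
#' @return list with `model` (trained) and `losses` (per-epoch MSE).
#' @export
train_torsion_net <- function(model, windows, phi, psi, epochs = 200L,
                              lr = 0.01) {
  stopifnot(length(dim(windows)) == 3L, dim(windows)[1] == length(phi),
            length(phi) == length(psi))
  if (dim(windows)[1] == 0L) stop("input error: empty training set")
  Y <- encode_angles(phi, psi)
  B <- nrow(Y)
  opt <- list()   # Adam moments, keyed by layer index
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  losses <- numeric(epochs)
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    fw <- net_forward(model, windows)
    resid <- fw$out - Y
    loss <- mean(resid^2)
    if (!is.finite(loss)) stop("training divergence: non-finite loss at epoch ", ep)
    losses[ep] <- loss
    grads <- net_backward(model, fw$caches, 2 * resid / (B * 4))
    t_step <- t_step + 1L
    for (li in seq_along(model$layers)) {
      if (is.null(grads[[li]])) next
      key <- as.character(li)
      if (is.null(opt[[key]]))
        opt[[key]] <- list(mW = 0 * grads[[li]]$dW, vW = 0 * grads[[li]]$dW,
                           mb = 0 * grads[[li]]$db, vb = 0 * grads[[li]]$db)
      st <- opt[[key]]
      st$mW <- beta1 * st$mW + (1 - beta1) * grads[[li]]$dW
      st$vW <- beta2 * st$vW + (1 - beta2) * grads[[li]]$dW^2
      st$mb <- beta1 * st$mb + (1 - beta1) * grads[[li]]$db
      st$vb <- beta2 * st$vb + (1 - beta2) * grads[[li]]$db^2
      corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
      model$layers[[li]]$W <- model$layers[[li]]$W -
        lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
      model$layers[[li]]$b <- model$layers[[li]]$b -
        lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
      opt[[key]] <- st
    }
  }
  list(model = model, losses = losses)
}

#' Predict torsions for a whole chain
#'
#' Builds the window for every residue, runs the network, and decodes
#' angles.
#'
#' @param model a trained `torsion_net`.
#' @param features L x 24 feature matrix (or `feature_table`).
#' @return object of class `torsion_prediction`: data.frame with columns
#'   `phi`, `psi` (degrees) and attribute `raw` (L x 4 sin/cos outputs).
#' @export
predict_torsions <- function(model, features) {
  if (inherits(features, "feature_table")) features <- features$features
  L <- nrow(features)
  A <- array(0, c(L, 2L * model$w + 1L, ncol(features)))
  for (i in seq_len(L)) A[i, , ] <- build_window(features, i, model$w)
  raw <- predict_raw(model, A)
  out <- decode_angles(raw)
  structure(out, raw = raw, class = c("torsion_prediction", "data.frame"))
}

#' Stack windows for a labelled training set
#' @param features L x 24 feature matrix.
#' @param w context half-width.
#' @return L x (2w+1) x 24 array.
#' @export
stack_windows <- function(features, w = 17L) {
  if (inherits(features, "feature_table")) features <- features$features
  L <- nrow(features)
  A <- array(0, c(L, 2L * w + 1L, ncol(features)))
  for (i in seq_len(L)) A[i, , ] <- build_window(features, i, w)
  A
}

#' Mean absolute error between angle sets
#'
#' `periodic = TRUE` (default) measures the minimal circular difference, so
#' 170 vs -170 degrees scores 20; `periodic = FALSE` uses the literal
#' absolute difference. Callers evaluating chain predictions should exclude
#' the terminal residues, whose measured angles are undefined.
#'
#' @param pred,obs numeric angle vectors in degrees, equal length.
#' @param periodic use circular difference (default TRUE).
#' @return mean absolute error in degrees.
#' @export
angle_mae <- function(pred, obs, periodic = TRUE) {
  stopifnot(length(pred) == length(obs))
  if (length(pred) == 0L) stop("undefined: empty input")
  d <- if (periodic) abs(wrap_angle(pred - obs)) else abs(pred - obs)
  mean(d)
}

#' Save / load a trained network
#' @param model a `torsion_net`.
#' @param path checkpoint path (RDS container).
#' @return `path` invisibly; `load_torsion_net` returns the model.
#' @export
save_torsion_net <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_torsion_net
#' @export
load_torsion_net <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "torsion_net"))
  model
}

#' Write torsion predictions as TSV
#' @param pred a `torsion_prediction`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_torsion_predictions <- function(pred, path) {
  df <- data.frame(residue = seq_len(nrow(pred)),
                   phi = round(pred$phi, 3), psi = round(pred$psi, 3))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
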