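#' Two-hidden-layer feed-forward classifier
#'
#' Minimal fully-connected binary classifier: two ReLU hidden layers and
#' a sigmoid output, trained on the binary cross-entropy by full-batch
#' Adam with early stopping on the training loss.  Inputs are
#' standardized internally.  Weight initialization draws from the
#' current RNG stream, so callers seed it for reproducibility.
#'
#' @param x numeric matrix of predictors (rows = samples).
#' @param y binary 0/1 vector.
#' @param hidden sizes of the two hidden layers.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param patience epochs without loss improvement before stopping.
#' @return An object of class `profnet_mlp` usable with `predict()`.
#' @export
mlp_fit <- function(x, y, hidden = c(64L, 32L), epochs = 300L, lr = 0.01,
                    patience = 25L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), length(hidden) == 2L)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  X <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  n <- nrow(X); d <- ncol(X)
  h1 <- hidden[1L]; h2 <- hidden[2L]

  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(2 / nin)), nin, nout)
  par <- list(W1 = he(d, h1), b1 = numeric(h1),
              W2 = he(h1, h2), b2 = numeric(h2),
              W3 = he(h2, 1L), b3 = 0)
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  b1c <- 0.9; b2c <- 0.999; eps <- 1e-8
  best <- Inf; stall <- 0L

  for (t in seq_len(epochs)) {
    A1 <- X %*% par$W1
    A1 <- sweep(A1, 2L, par$b1, "+"); H1 <- pmax(A1, 0)
    A2 <- H1 %*% par$W2
    A2 <- sweep(A2, 2L, par$b2, "+"); H2 <- pmax(A2, 0)
    z <- drop(H2 %*% par$W3) + par$b3
    pr <- 1 / (1 + exp(-z))
    loss <- -mean(y * log(pmax(pr, 1e-12)) +
                  (1 - y) * log(pmax(1 - pr, 1e-12)))
    if (loss < best - 1e-6) { best <- loss; stall <- 0L } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
    dz <- (pr - y) / n                      # dL/dz
    gW3 <- crossprod(H2, dz); gb3 <- sum(dz)
    dH2 <- outer(dz, drop(par$W3)) * (A2 > 0)
    gW2 <- crossprod(H1, dH2); gb2 <- colSums(dH2)
    dH1 <- (dH2 %*% t(par$W2)) * (A1 > 0)
    gW1 <- crossprod(X, dH1); gb1 <- colSums(dH1)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                  W3 = gW3, b3 = gb3)
    for (nm in names(par)) {
      m[[nm]] <- b1c * m[[nm]] + (1 - b1c) * grads[[nm]]
      v[[nm]] <- b2c * v[[nm]] + (1 - b2c) * grads[[nm]]^2
      mh <- m[[nm]] / (1 - b1c^t)
      vh <- v[[nm]] / (1 - b2c^t)
      par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  structure(list(par = par, center = ctr, scale = scl, epochs_run = t,
                 final_loss = loss),
            class = "profnet_mlp")
}

#' @param object a fitted `profnet_mlp`.
#' @param newdata numeric matrix of predictors.
#' @param type `"class"` (0/1) or `"prob"`.
#' @param ... unused.
#' @rdname mlp_fit
#' @export
predict.profnet_mlp <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  X <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L,
             object$scale, "/")
  p <- object$par
  H1 <- pmax(sweep(X %*% p$W1, 2L, p$b1, "+"), 0)
  H2 <- pmax(sweep(H1 %*% p$W2, 2L, p$b2, "+"), 0)
  pr <- 1 / (1 + exp(-(drop(H2 %*% p$W3) + p$b3)))
  if (type == "prob") pr else as.integer(pr >= 0.5)
}
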