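# The imputation model: a fully-connected multilayer perceptron with
# ReLU/PReLU hidden layers, inverted dropout, a softmax output over the four
# race/ethnicity classes, categorical cross-entropy loss, Adam updates, and
# early stopping with model caching. Written in plain matrix code so that
# every layer's pre- and post-activation values are available to the
# DeepLIFT interpreter.

#' Describe an MLP architecture
#'
#' @param input_dim number of input nodes (the vocabulary size)
#' @param hidden_dims integer vector of hidden-layer widths (default two
#'   hidden layers of 512, the full-scale architecture; tests and desk-scale
#'   experiments use narrower layers)
#' @param activation `"prelu"` (per-unit learned slope alpha for x <= 0) or
#'   `"relu"` (alpha fixed at 0)
#' @param dropout_rate dropout probability applied to each hidden layer
#'   during training, in [0, 1)
#' @param n_classes number of softmax output nodes
#' @param prelu_alpha_init initial value of the learned PReLU slope
#' @return a `network_spec`
#' @export
network_spec <- function(input_dim, hidden_dims = c(512, 512),
                         activation = c("prelu", "relu"),
                         dropout_rate = 0.5, n_classes = 4,
                         prelu_alpha_init = 0.25) {
  activation <- match.arg(activation)
  stopifnot(input_dim >= 1, length(hidden_dims) >= 1, all(hidden_dims >= 1),
            n_classes >= 2, dropout_rate >= 0, dropout_rate < 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 activation = activation,
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 prelu_alpha_init = prelu_alpha_init),
            class = "network_spec")
}

#' Training configuration
#'
#' @param learning_rate Adam step size
#' @param batch_size minibatch size
#' @param max_epochs upper bound on passes over the training data
#' @param patience epochs of non-improving validation loss tolerated before
#'   stopping (0 = stop at the first non-improvement)
#' @param seed integer seed governing shuffling and dropout
#' @return a `train_config`
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128,
                         max_epochs = 100, patience = 5, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1, patience >= 0)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Parametric rectified linear unit
#'
#' `f(x) = x` for `x > 0` and `alpha * x` otherwise; `alpha = 0` gives the
#' ReLU. Vectorized over `x`.
#'
#' @param x numeric vector or matrix of pre-activations
#' @param alpha scalar slope for the non-positive branch (learned per hidden
#'   layer during training)
#' @return element-wise activations, same shape as `x`
#' @export
prelu <- function(x, alpha) {
  pmax(x, 0) + alpha * pmin(x, 0)
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Initialize an untrained MLP
#'
#' Weights use seeded variance-scaling (fan-in) Gaussian initialization,
#' biases start at zero, and PReLU slopes at `prelu_alpha_init` (fixed at 0
#' for ReLU).
#'
#' @param spec a `network_spec`
#' @param seed integer seed for the weight draw
#' @return an `mlp_model` with elements `spec`, `layers` (each `W`, `b` and,
#'   for hidden layers, `alpha`), empty `history` and `best_epoch = NA`
#' @export
build_mlp <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  dims <- c(spec$input_dim, spec$hidden_dims, spec$n_classes)
  L <- length(dims) - 1
  layers <- vector("list", L)
  withr::with_seed(seed, {
    for (l in seq_len(L)) {
      fan_in <- dims[l]
      layers[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)),
                   fan_in, dims[l + 1]),
        b = numeric(dims[l + 1]))
      if (l < L) {
        # one learned slope per hidden layer (fixed at 0 for ReLU)
        layers[[l]]$alpha <- if (spec$activation == "prelu") spec$prelu_alpha_init else 0
      }
    }
  })
  structure(list(spec = spec, layers = layers,
                 history = data.frame(epoch = integer(), train_loss = numeric(),
                                      val_loss = numeric()),
                 best_epoch = NA_integer_),
            class = "mlp_model")
}

#' Number of trainable parameters (weights, biases, PReLU slopes)
#' @param model an `mlp_model`
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    length(l$W) + length(l$b) + if (model$spec$activation == "prelu") length(l$alpha %||% numeric()) else 0L
  }, 0))
}

# Forward pass. Returns pre-activations z, post-activations a (a[[1]] = input)
# and softmax probabilities. Dropout masks (already scaled by 1/keep) are
# applied to hidden activations when supplied.
mlp_forward <- function(model, X, drop_masks = NULL) {
  L <- length(model$layers)
  z <- vector("list", L)
  a <- vector("list", L + 1)
  a[[1]] <- X
  for (l in seq_len(L)) {
    ly <- model$layers[[l]]
    z[[l]] <- sweep(as.matrix(a[[l]] %*% ly$W), 2, ly$b, `+`)
    if (l < L) {
      h <- prelu(z[[l]], ly$alpha)
      if (!is.null(drop_masks)) h <- h * drop_masks[[l]]
      a[[l + 1]] <- h
    } else {
      a[[l + 1]] <- z[[l]]
    }
  }
  list(z = z, a = a, logits = z[[L]], probs = softmax(z[[L]]))
}

cross_entropy <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y)]
  -mean(log(pmin(pmax(p, 1e-15), 1)))
}

#' Train an MLP with Adam, dropout and early stopping
#'
#' Minimizes categorical cross-entropy by minibatch Adam. After each epoch
#' the validation loss (dropout disabled) is recorded; the weights from the
#' epoch with minimal validation loss are cached and returned ("model
#' caching"). Training halts once validation loss has failed to improve for
#' more than `patience` consecutive epochs, or at `max_epochs`.
#'
#' @param model an `mlp_model` from [build_mlp()]
#' @param X training matrix (patients x features; dense or sparse)
#' @param y integer class labels in 1..n_classes
#' @param val_X,val_y validation data for early stopping
#' @param config a `train_config`
#' @return the trained `mlp_model`, with `history` (per-epoch train and
#'   validation loss) and `best_epoch`
#' @export
train_mlp <- function(model, X, y, val_X, val_y, config = train_config()) {
  stopifnot(inherits(model, "mlp_model"), inherits(config, "train_config"))
  X <- as.matrix(X); val_X <- as.matrix(val_X)
  if (ncol(X) != model$spec$input_dim) stop_("training matrix width != input_dim")
  y <- as.integer(y); val_y <- as.integer(val_y)
  n <- nrow(X)
  L <- length(model$layers)
  learn_alpha <- model$spec$activation == "prelu"
  keep <- 1 - model$spec$dropout_rate

  # Adam state, one moment pair per parameter array
  adam <- lapply(model$layers, function(ly) {
    st <- list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    if (!is.null(ly$alpha)) { st$ma <- ly$alpha * 0; st$va <- ly$alpha * 0 }
    st
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0
  best_loss <- Inf; best_layers <- model$layers; best_epoch <- NA_integer_
  hist_epoch <- integer(); hist_train <- numeric(); hist_val <- numeric()
  since_best <- 0L

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        nb <- length(idx)
        masks <- NULL
        if (keep < 1) {
          masks <- lapply(model$spec$hidden_dims, function(h)
            matrix(stats::rbinom(nb * h, 1, keep) / keep, nb, h))
        }
        fw <- mlp_forward(model, Xb, drop_masks = masks)
        loss <- cross_entropy(fw$probs, yb)
        if (!is.finite(loss))
          stop_("non-finite training loss at epoch ", epoch,
                "; reduce the learning rate")
        epoch_loss <- epoch_loss + loss * nb

        # backward
        Y1 <- matrix(0, nb, model$spec$n_classes)
        Y1[cbind(seq_len(nb), yb)] <- 1
        delta <- (fw$probs - Y1) / nb
        t_step <- t_step + 1
        corr <- function(m, b) m / (1 - b^t_step)
        for (l in L:1) {
          A_prev <- fw$a[[l]]
          gW <- crossprod(A_prev, delta)
          gb <- colSums(delta)
          if (l > 1) {
            dA <- tcrossprod(delta, model$layers[[l]]$W)  # grad wrt a[[l]]
            if (!is.null(masks)) dA <- dA * masks[[l - 1]]
            zprev <- fw$z[[l - 1]]
            neg <- zprev <= 0
            alpha_prev <- model$layers[[l - 1]]$alpha
            if (learn_alpha)
              galpha_prev <- sum(dA * zprev * neg)
            delta_next <- dA * ((!neg) + alpha_prev * neg)
          }
          # Adam update for layer l
          st <- adam[[l]]
          st$mW <- b1 * st$mW + (1 - b1) * gW
          st$vW <- b2 * st$vW + (1 - b2) * gW^2
          model$layers[[l]]$W <- model$layers[[l]]$W -
            config$learning_rate * corr(st$mW, b1) / (sqrt(corr(st$vW, b2)) + eps)
          st$mb <- b1 * st$mb + (1 - b1) * gb
          st$vb <- b2 * st$vb + (1 - b2) * gb^2
          model$layers[[l]]$b <- model$layers[[l]]$b -
            config$learning_rate * corr(st$mb, b1) / (sqrt(corr(st$vb, b2)) + eps)
          if (l > 1 && learn_alpha) {
            stp <- adam[[l - 1]]
            stp$ma <- b1 * stp$ma + (1 - b1) * galpha_prev
            stp$va <- b2 * stp$va + (1 - b2) * galpha_prev^2
            model$layers[[l - 1]]$alpha <- model$layers[[l - 1]]$alpha -
              config$learning_rate * corr(stp$ma, b1) / (sqrt(corr(stp$va, b2)) + eps)
            adam[[l - 1]] <- stp
          }
          adam[[l]] <- st
          if (l > 1) delta <- delta_next
        }
      }
      train_loss <- epoch_loss / n
      val_probs <- mlp_forward(model, val_X)$probs
      val_loss <- cross_entropy(val_probs, val_y)
      if (!is.finite(val_loss))
        stop_("non-finite validation loss at epoch ", epoch)
      hist_epoch <- c(hist_epoch, epoch)
      hist_train <- c(hist_train, train_loss)
      hist_val <- c(hist_val, val_loss)
      if (val_loss < best_loss) {
        best_loss <- val_loss; best_layers <- model$layers; best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best > config$patience) break
      }
    }
  })
  model$layers <- best_layers
  model$best_epoch <- best_epoch
  model$history <- data.frame(epoch = hist_epoch, train_loss = hist_train,
                              val_loss = hist_val)
  model
}

#' Class-probability predictions
#'
#' Deterministic forward pass (dropout disabled); each output row lies on
#' the probability simplex.
#'
#' @param model an `mlp_model`
#' @param X matrix or `encoded_batch` with `input_dim` columns
#' @return numeric matrix (rows = patients, columns = `RE_CLASSES` for
#'   4-class models)
#' @export
predict_proba <- function(model, X) {
  if (inherits(X, "encoded_batch")) X <- X$matrix
  X <- as.matrix(X)
  if (ncol(X) != model$spec$input_dim)
    stop_("input has ", ncol(X), " columns but the model expects ",
          model$spec$input_dim)
  p <- mlp_forward(model, X)$probs
  if (model$spec$n_classes == length(RE_CLASSES)) colnames(p) <- RE_CLASSES
  p
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("MLP:", x$spec$input_dim, "->",
      paste(x$spec$hidden_dims, collapse = " -> "), "->", x$spec$n_classes,
      sprintf("(%s, dropout %.2f, %d parameters)\n", x$spec$activation,
              x$spec$dropout_rate, n_params(x)))
  if (nrow(x$history) > 0)
    cat("trained", nrow(x$history), "epochs; best epoch", x$best_epoch,
        sprintf("(val loss %.4f)\n", min(x$history$val_loss)))
  invisible(x)
}

#' Describe a randomized hyperparameter search space
#'
#' @param activation candidate activations
#' @param dropout_range range for a uniform draw of the dropout rate
#' @param learning_rate_range range for a log-uniform draw of the Adam step
#' @param batch_sizes candidate minibatch sizes
#' @param n_draws number of random configurations to evaluate
#' @param tuning_subsample at most this many samples are used for tuning
#' @return a `hyper_space`
#' @export
hyper_space <- function(activation = c("relu", "prelu"),
                        dropout_range = c(0.2, 0.8),
                        learning_rate_range = c(1e-4, 1e-2),
                        batch_sizes = c(64, 128, 256),
                        n_draws = 5, tuning_subsample = 10000) {
  stopifnot(n_draws >= 1)
  structure(list(activation = activation, dropout_range = dropout_range,
                 learning_rate_range = learning_rate_range,
                 batch_sizes = batch_sizes, n_draws = as.integer(n_draws),
                 tuning_subsample = as.integer(tuning_subsample)),
            class = "hyper_space")
}

draw_candidates <- function(space, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(space$n_draws), function(i) {
      list(activation = sample(space$activation, 1),
           dropout_rate = stats::runif(1, space$dropout_range[1], space$dropout_range[2]),
           learning_rate = exp(stats::runif(1, log(space$learning_rate_range[1]),
                                            log(space$learning_rate_range[2]))),
           batch_size = sample(space$batch_sizes, 1))
    })
  })
}

#' Randomized grid search over MLP hyperparameters
#'
#' Draws `n_draws` configurations uniformly from the space, trains each
#' briefly on a subsample of the tuning data (80/20 internal split) and
#' returns the configuration with minimal validation loss; ties are broken
#' by draw order.
#'
#' @param space a `hyper_space`
#' @param X,y tuning data (typically validation samples)
#' @param base_spec a `network_spec` providing the fixed architecture
#'   (input_dim, hidden_dims, n_classes)
#' @param seed integer seed for drawing and training
#' @param search_epochs epochs per candidate during search
#' @return list with the winning `spec` (a `network_spec`), `config`
#'   (a `train_config`) and the per-candidate `results` data frame
#' @export
random_grid_search <- function(space, X, y, base_spec, seed = 1,
                               search_epochs = 10) {
  stopifnot(inherits(space, "hyper_space"))
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X)
  if (n > space$tuning_subsample) {
    keep <- withr::with_seed(derive_seed(seed, "subsample"),
                             sample.int(n, space$tuning_subsample))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
    n <- nrow(X)
  }
  idx_val <- withr::with_seed(derive_seed(seed, "split"),
                              sample.int(n, max(1, round(0.2 * n))))
  cands <- draw_candidates(space, derive_seed(seed, "draw"))
  losses <- vapply(seq_along(cands), function(i) {
    cand <- cands[[i]]
    spec <- network_spec(base_spec$input_dim, base_spec$hidden_dims,
                         cand$activation, cand$dropout_rate,
                         base_spec$n_classes, base_spec$prelu_alpha_init)
    cfg <- train_config(cand$learning_rate, cand$batch_size,
                        max_epochs = search_epochs, patience = search_epochs,
                        seed = derive_seed(seed, "fit", i))
    fit <- tryCatch(
      train_mlp(build_mlp(spec, derive_seed(seed, "init", i)),
                X[-idx_val, , drop = FALSE], y[-idx_val],
                X[idx_val, , drop = FALSE], y[idx_val], cfg),
      error = function(e) NULL)   # diverging candidates lose
    if (is.null(fit)) Inf else min(fit$history$val_loss)
  }, 0)
  best <- which.min(losses)
  cand <- cands[[best]]
  results <- data.frame(
    draw = seq_along(cands),
    activation = vapply(cands, `[[`, "", "activation"),
    dropout_rate = vapply(cands, `[[`, 0, "dropout_rate"),
    learning_rate = vapply(cands, `[[`, 0, "learning_rate"),
    batch_size = vapply(cands, function(c) as.integer(c$batch_size), 0L),
    val_loss = losses)
  list(spec = network_spec(base_spec$input_dim, base_spec$hidden_dims,
                           cand$activation, cand$dropout_rate,
                           base_spec$n_classes, base_spec$prelu_alpha_init),
       config = train_config(cand$learning_rate, cand$batch_size),
       results = results)
}
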