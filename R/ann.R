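#' Configuration of the feed-forward PFS regressor
#'
#' Architecture: input layer, then three fully connected hidden layers of
#' equal width, each followed by a sigmoid activation and layer
#' normalization (zero mean / unit variance across the layer's units per
#' sample, with learnable gain and offset), and a linear output unit (no
#' output activation, since the target is months). Trained by L-BFGS.
#'
#' @param input_dim Number of input features (15 after MRMR selection).
#' @param width Hidden layer width; the search grid is {5, 10, 15}.
#' @param loss `"mse"`, `"mae"` or `"huber"`.
#' @param huber_delta Huber transition point (months).
#' @param max_iter Total L-BFGS iteration cap.
#' @param chunk_iter Iterations between validation checks.
#' @param patience Validation checks without improvement before stopping.
#' @param pgtol Projected-gradient tolerance passed to the optimizer.
#' @param ln_eps Layer-normalization variance epsilon.
#' @param normalize Standardize inputs and target to zero mean / unit SD
#'   using training-set statistics before optimization (stored in the
#'   model, applied transparently at prediction). Without this the
#'   network starts deep in the sigmoid's linear regime for
#'   correlation-scale inputs and month-scale targets.
#' @return Object of class `ann_config`.
#' @export
ann_config <- function(input_dim = 15L, width = 5L,
                       loss = c("mse", "mae", "huber"), huber_delta = 1,
                       max_iter = 500L, chunk_iter = 10L, patience = 20L,
                       pgtol = 1e-7, ln_eps = 1e-5, normalize = TRUE) {
  loss <- match.arg(loss)
  stopifnot(input_dim >= 1L, width >= 1L, huber_delta > 0,
            max_iter >= 1L, chunk_iter >= 1L)
  structure(list(input_dim = as.integer(input_dim), width = as.integer(width),
                 n_hidden = 3L, loss = loss, huber_delta = huber_delta,
                 max_iter = as.integer(max_iter),
                 chunk_iter = as.integer(chunk_iter),
                 patience = as.integer(patience), pgtol = pgtol,
                 ln_eps = ln_eps, normalize = isTRUE(normalize)),
            class = "ann_config")
}

# Parameter layout: per hidden layer l: W (in x H), b, g, o; output: w, b.
ann_param_shapes <- function(config) {
  d <- config$input_dim; H <- config$width
  ins <- c(d, H, H)
  shapes <- list()
  for (l in 1:3) {
    shapes[[paste0("W", l)]] <- c(ins[l], H)
    shapes[[paste0("b", l)]] <- c(H, 1L)
    shapes[[paste0("g", l)]] <- c(H, 1L)
    shapes[[paste0("o", l)]] <- c(H, 1L)
  }
  shapes$W4 <- c(H, 1L)
  shapes$b4 <- c(1L, 1L)
  shapes
}

ann_pack <- function(params) unlist(params, use.names = FALSE)

ann_unpack <- function(theta, config) {
  shapes <- ann_param_shapes(config)
  params <- list()
  pos <- 0L
  for (nm in names(shapes)) {
    sz <- prod(shapes[[nm]])
    params[[nm]] <- matrix(theta[pos + seq_len(sz)],
                           shapes[[nm]][1], shapes[[nm]][2])
    pos <- pos + sz
  }
  params
}

#' Initialize network parameters
#'
#' Weights drawn from a symmetric uniform scaled by fan-in
#' (U(-1/sqrt(fan_in), 1/sqrt(fan_in))); biases and layer-norm offsets 0,
#' layer-norm gains 1. Deterministic per seed.
#'
#' @param config An [ann_config()].
#' @param seed Integer seed.
#' @return Named list of parameter matrices.
#' @export
ann_init <- function(config, seed = 1L) {
  shapes <- ann_param_shapes(config)
  with_seed(seed, {
    params <- list()
    for (nm in names(shapes)) {
      sh <- shapes[[nm]]
      if (startsWith(nm, "W")) {
        a <- 1 / sqrt(sh[1])
        params[[nm]] <- matrix(stats::runif(prod(sh), -a, a), sh[1], sh[2])
      } else if (startsWith(nm, "g")) {
        params[[nm]] <- matrix(1, sh[1], sh[2])
      } else {
        params[[nm]] <- matrix(0, sh[1], sh[2])
      }
    }
    params
  })
}

# Forward pass on a batch X (n x d). Returns prediction vector and, when
# keep_cache, the per-layer quantities needed for backprop.
ann_forward_batch <- function(params, X, config, keep_cache = FALSE) {
  eps <- config$ln_eps
  A <- X
  cache <- if (keep_cache) vector("list", 3L) else NULL
  for (l in 1:3) {
    W <- params[[paste0("W", l)]]
    b <- params[[paste0("b", l)]][, 1]
    g <- params[[paste0("g", l)]][, 1]
    o <- params[[paste0("o", l)]][, 1]
    Z <- sweep(A %*% W, 2, b, "+")
    S <- stats::plogis(Z)
    mu <- rowMeans(S)
    D <- S - mu
    sig <- sqrt(rowMeans(D * D) + eps)
    Shat <- D / sig
    A_next <- sweep(sweep(Shat, 2, g, "*"), 2, o, "+")
    if (keep_cache) cache[[l]] <- list(A_in = A, S = S, Shat = Shat, sig = sig)
    A <- A_next
  }
  yhat <- as.numeric(A %*% params$W4[, 1] + params$b4[1, 1])
  list(yhat = yhat, A3 = A, cache = cache)
}

#' Predict PFS for a batch of feature vectors
#'
#' Applies the model's stored input/target normalization (if any) around
#' the forward pass.
#'
#' @param model A trained `ann_model` (or a list with `params` and
#'   `config`).
#' @param X Numeric matrix (n x input_dim) or a single vector.
#' @return Numeric vector of predicted PFS in months.
#' @export
ann_predict <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  stopifnot(ncol(X) == model$config$input_dim, all(is.finite(X)))
  nrm <- model$norm
  if (!is.null(nrm)) {
    X <- sweep(sweep(X, 2, nrm$x_mu), 2, nrm$x_sd, "/")
  }
  yhat <- ann_forward_batch(model$params, X, model$config)$yhat
  if (!is.null(nrm)) yhat <- nrm$y_mu + nrm$y_sd * yhat
  yhat
}

#' Regression losses: MSE, MAE, Huber
#'
#' Standard definitions; Huber is `r^2/2` for `|r| <= delta` and
#' `delta * (|r| - delta/2)` beyond, averaged over points.
#'
#' @param predictions,targets Numeric vectors.
#' @param kind `"mse"`, `"mae"` or `"huber"`.
#' @param huber_delta Huber transition point.
#' @return Non-negative scalar loss.
#' @export
ann_loss <- function(predictions, targets, kind = c("mse", "mae", "huber"),
                     huber_delta = 1) {
  kind <- match.arg(kind)
  r <- predictions - targets
  switch(kind,
         mse = mean(r^2),
         mae = mean(abs(r)),
         huber = {
           a <- abs(r)
           mean(ifelse(a <= huber_delta, 0.5 * r^2,
                       huber_delta * (a - huber_delta / 2)))
         })
}

loss_grad <- function(r, kind, delta) {
  n <- length(r)
  switch(kind,
         mse = 2 * r / n,
         mae = sign(r) / n,
         huber = ifelse(abs(r) <= delta, r, delta * sign(r)) / n)
}

# Loss and packed analytic gradient at theta. Layer-norm backward uses the
# exact per-row formula dS = (dShat - mean(dShat) - Shat * mean(dShat*Shat)) / sig.
ann_obj_grad <- function(theta, X, y, config) {
  params <- ann_unpack(theta, config)
  fw <- ann_forward_batch(params, X, config, keep_cache = TRUE)
  r <- fw$yhat - y
  loss <- ann_loss(fw$yhat, y, config$loss, config$huber_delta)
  dy <- loss_grad(r, config$loss, config$huber_delta)

  grads <- list()
  grads$W4 <- matrix(crossprod(fw$A3, dy), ncol = 1)
  grads$b4 <- matrix(sum(dy), 1, 1)
  dA <- outer(dy, params$W4[, 1])
  for (l in 3:1) {
    cc <- fw$cache[[l]]
    g <- params[[paste0("g", l)]][, 1]
    grads[[paste0("g", l)]] <- matrix(colSums(dA * cc$Shat), ncol = 1)
    grads[[paste0("o", l)]] <- matrix(colSums(dA), ncol = 1)
    dShat <- sweep(dA, 2, g, "*")
    dS <- (dShat - rowMeans(dShat) - cc$Shat * rowMeans(dShat * cc$Shat)) / cc$sig
    dZ <- dS * cc$S * (1 - cc$S)
    grads[[paste0("W", l)]] <- crossprod(cc$A_in, dZ)
    grads[[paste0("b", l)]] <- matrix(colSums(dZ), ncol = 1)
    dA <- dZ %*% t(params[[paste0("W", l)]])
  }
  shapes <- ann_param_shapes(config)
  list(loss = loss,
       grad = unlist(grads[names(shapes)], use.names = FALSE))
}

#' Train the regressor by chunked L-BFGS with validation termination
#'
#' Minimizes the configured loss on the training set by limited-memory
#' quasi-Newton iteration (memory 10), checking the validation loss every
#' `chunk_iter` iterations. Training stops on optimizer convergence
#' (gradient tolerance), the iteration cap, or `patience` validation checks
#' without improvement; the parameters from the best validation checkpoint
#' are returned.
#'
#' @param init_params Parameter list from [ann_init()] (or NULL to
#'   initialize from `seed`).
#' @param x_train,y_train Training inputs (n x d) and targets.
#' @param x_val,y_val Validation inputs and targets (disjoint from
#'   training).
#' @param config An [ann_config()].
#' @param seed Seed for initialization when `init_params` is NULL.
#' @param x_score,y_score Optional extra scoring set (e.g. the fold's
#'   unaugmented training subjects). When given, checkpoints are ranked by
#'   the mean of the validation loss and the MSE on this set, instead of
#'   the validation loss alone.
#' @return Object of class `ann_model`: `params`, `config`, `norm`,
#'   `validation_loss`, `train_loss`, `iterations`, `converged`.
#' @export
ann_train <- function(init_params = NULL, x_train, y_train, x_val, y_val,
                      config, seed = 1L, x_score = NULL, y_score = NULL) {
  stopifnot(inherits(config, "ann_config"),
            nrow(x_train) == length(y_train), nrow(x_val) == length(y_val),
            nrow(x_train) >= 1L, nrow(x_val) >= 1L)
  if (is.null(init_params)) init_params <- ann_init(config, seed)
  theta <- ann_pack(init_params)

  # input/target standardization from training-set statistics only
  norm <- NULL
  x_opt <- x_train; y_opt <- y_train
  xv_opt <- x_val
  opt_config <- config
  if (isTRUE(config$normalize)) {
    x_sd <- apply(x_train, 2, stats::sd)
    y_sd <- stats::sd(y_train)
    norm <- list(x_mu = colMeans(x_train),
                 x_sd = ifelse(is.finite(x_sd) & x_sd > 1e-8, x_sd, 1),
                 y_mu = mean(y_train),
                 y_sd = if (is.finite(y_sd) && y_sd > 1e-8) y_sd else 1)
    scale_x <- function(X) sweep(sweep(X, 2, norm$x_mu), 2, norm$x_sd, "/")
    x_opt <- scale_x(x_train)
    xv_opt <- scale_x(x_val)
    y_opt <- (y_train - norm$y_mu) / norm$y_sd
    # the Huber knee is specified in months; rescale for the scaled residuals
    opt_config$huber_delta <- config$huber_delta / norm$y_sd
  }

  # optim calls fn and gr separately at the same point; cache the pair
  memo <- new.env(parent = emptyenv())
  at <- function(th) {
    if (!is.null(memo$th) && identical(th, memo$th)) return(memo$og)
    og <- ann_obj_grad(th, x_opt, y_opt, opt_config)
    memo$th <- th
    memo$og <- og
    og
  }
  fn <- function(th) {
    v <- at(th)$loss
    if (!is.finite(v)) stop(structure(
      class = c("ann_nonfinite", "error", "condition"),
      list(message = "non-finite training loss", call = NULL)))
    v
  }
  gr <- function(th) at(th)$grad

  # validation loss on the months scale
  predict_at <- function(th, X) {
    p <- ann_unpack(th, config)
    if (!is.null(norm)) {
      X <- sweep(sweep(X, 2, norm$x_mu), 2, norm$x_sd, "/")
    }
    yhat <- ann_forward_batch(p, X, config)$yhat
    if (!is.null(norm)) yhat <- norm$y_mu + norm$y_sd * yhat
    yhat
  }
  val_loss_at <- function(th) {
    p <- ann_unpack(th, config)
    yhat <- ann_forward_batch(p, xv_opt, config)$yhat
    if (!is.null(norm)) yhat <- norm$y_mu + norm$y_sd * yhat
    ann_loss(yhat, y_val, config$loss, config$huber_delta)
  }
  # checkpoint criterion: validation loss, averaged with the scoring-set
  # MSE when a scoring set is supplied
  check_at <- function(th) {
    v <- val_loss_at(th)
    if (is.null(x_score)) return(list(val = v, crit = v))
    s <- mean((predict_at(th, x_score) - y_score)^2)
    list(val = v, crit = 0.5 * v + 0.5 * s)
  }

  best_theta <- theta
  cc <- check_at(theta)
  best_crit <- cc$crit
  best_val <- cc$val
  iter_done <- 0L
  stall <- 0L
  converged <- FALSE
  while (iter_done < config$max_iter) {
    chunk <- min(config$chunk_iter, config$max_iter - iter_done)
    res <- stats::optim(theta, fn = fn, gr = gr, method = "L-BFGS-B",
                        control = list(maxit = chunk, lmm = 10,
                                       pgtol = config$pgtol, factr = 1e7))
    theta <- res$par
    iter_done <- iter_done + chunk
    cc <- check_at(theta)
    if (is.finite(cc$crit) && cc$crit < best_crit - 1e-12) {
      best_crit <- cc$crit
      best_val <- cc$val
      best_theta <- theta
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (res$convergence == 0L) { converged <- TRUE; break }
    if (stall >= config$patience) break
  }
  params <- ann_unpack(best_theta, config)
  yhat_tr <- ann_forward_batch(params, x_opt, config)$yhat
  if (!is.null(norm)) yhat_tr <- norm$y_mu + norm$y_sd * yhat_tr
  tr_loss <- ann_loss(yhat_tr, y_train, config$loss, config$huber_delta)
  structure(list(params = params, config = config, norm = norm,
                 validation_loss = best_val, train_loss = tr_loss,
                 iterations = iter_done, converged = converged),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("ann_model: %d-%d-%d-%d-1, loss %s, val loss %.4g (%d iters)\n",
              x$config$input_dim, x$config$width, x$config$width,
              x$config$width, x$config$loss, x$validation_loss, x$iterations))
  invisible(x)
}

#' Hyperparameter search with random restarts
#'
#' Enumerates widths x losses; for each configuration runs `restarts`
#' trainings, each from a fresh random initialization and — via `data_fn` —
#' a fresh augmented training/validation draw, retaining the model with the
#' lowest validation loss across the whole grid. A restart whose training
#' loss turns non-finite is retried once from a perturbed seed, then
#' recorded as failed (Inf). The full search trace is returned.
#'
#' @param data_fn Function(seed) returning a list with `x_train`,
#'   `y_train`, `x_val`, `y_val` for one optimization cycle.
#' @param input_dim Input dimension of the models.
#' @param widths Hidden widths to try (default c(5, 10, 15)).
#' @param losses Loss kinds to try.
#' @param restarts Random restarts per configuration (the study protocol
#'   uses ~50; tests use fewer).
#' @param seed Master seed.
#' @param control Named list of [ann_config()] overrides (e.g. `max_iter`).
#' @param score_fn Optional function(model) returning the retention score
#'   (lower is better); by default the model's augmented-validation loss.
#'   The LOOCV pipeline scores candidates on both the grouped validation
#'   loss and the fold's unaugmented training subjects, which evaluates
#'   each restart at the clean input distribution used at prediction time
#'   instead of on near-duplicates of its own training rows.
#' @param score_xy Optional list(x, y): scoring set forwarded to
#'   [ann_train()] for checkpoint ranking.
#' @return List with `best` (an `ann_model`), `best_score`, and `trace`
#'   (data frame: width, loss, restart, n_train, n_val, val_loss,
#'   train_loss, score).
#' @export
ann_hyperparameter_search <- function(data_fn, input_dim,
                                      widths = c(5L, 10L, 15L),
                                      losses = "mse", restarts = 50L,
                                      seed = 1L, control = list(),
                                      score_fn = NULL, score_xy = NULL) {
  grid <- expand.grid(width = widths, loss = losses,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L || restarts < 1L) stopf("empty hyperparameter grid")
  best <- NULL
  best_score <- Inf
  rows <- vector("list", nrow(grid) * restarts)
  ri <- 0L
  for (ci in seq_len(nrow(grid))) {
    cfg_args <- c(list(input_dim = input_dim, width = grid$width[ci],
                       loss = grid$loss[ci]), control)
    config <- do.call(ann_config, cfg_args)
    for (r in seq_len(restarts)) {
      s <- derive_seed(seed, ci, r)
      dat <- data_fn(s)
      model <- tryCatch(
        ann_train(NULL, dat$x_train, dat$y_train, dat$x_val, dat$y_val,
                  config, seed = derive_seed(s, 7L),
                  x_score = score_xy$x, y_score = score_xy$y),
        ann_nonfinite = function(e) {
          tryCatch(
            ann_train(NULL, dat$x_train, dat$y_train, dat$x_val, dat$y_val,
                      config, seed = derive_seed(s, 8L),
                      x_score = score_xy$x, y_score = score_xy$y),
            ann_nonfinite = function(e2) NULL)
        })
      score <- if (is.null(model)) Inf
               else if (is.null(score_fn)) model$validation_loss
               else score_fn(model)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(width = grid$width[ci], loss = grid$loss[ci],
                               restart = r, n_train = nrow(dat$x_train),
                               n_val = nrow(dat$x_val),
                               val_loss = if (is.null(model)) Inf
                                          else model$validation_loss,
                               train_loss = if (is.null(model)) Inf
                                            else model$train_loss,
                               score = score)
      if (score < best_score) { best_score <- score; best <- model }
    }
  }
  if (is.null(best)) stopf("all restarts failed with non-finite loss")
  list(best = best, best_score = best_score,
       best_val = best$validation_loss, trace = do.call(rbind, rows))
}
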