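# One-hidden-layer ReLU regressor trained with Levenberg-Marquardt.
#
# Input layer: 100 quantiles of the record's predicted energy-change CDF
# plus ordinal codes for the substitution type(s) and the protein — 103
# features in total. Hidden layer: 10 ReLU neurons by default. Output: one
# linear neuron giving the predicted ddG (kcal/mol). Features are z-scored
# on the training split only (LM on raw kcal/mol quantiles mixed with
# ordinal codes is badly scaled).
#
# LM minimizes the sum of squared residuals: each iteration builds the
# Jacobian J of the model output w.r.t. all weights (ReLU subgradient at 0
# taken as 0), solves (J'J + lambda I) delta = J' r and accepts the step iff
# the SSE decreases (lambda /= 10), otherwise rejects and retries with
# lambda *= 10. When parameters outnumber samples the step is computed
# through the dual form delta = J'(JJ' + lambda I)^{-1} r, which is
# algebraically identical and much cheaper.

#' Ordinal encoders for substitution keys and protein codes
#'
#' Built from the training universe only; categories unseen at prediction
#' time map to the reserved "unknown" code 0.
#'
#' @param records the training records (a `ddg_dataset`'s `records` frame,
#'   possibly subset).
#' @return list with `key_levels` and `protein_levels` (sorted unique).
#' @export
build_encoders <- function(records) {
  keys <- sort(unique(unlist(lapply(records$mutation, record_keys))))
  list(key_levels = keys,
       protein_levels = sort(unique(records$protein_id)))
}

encode_level <- function(x, levels) {
  i <- match(x, levels)
  ifelse(is.na(i), 0L, i)
}

#' Feature matrix: CDF quantile grid plus mutation and protein codes
#'
#' Each row is one record: `m` quantiles of its corrected predicted-CDF
#' samples, the ordinal code of its (first) substitution key, the code of
#' the second key (0 for single mutations), and the protein code. Unseen
#' keys/proteins encode as 0 (ordinal) or an all-zero indicator row
#' (one-hot) and are logged.
#'
#' The protein code is one-hot by default: the network's advantage over the
#' raw sampler median comes precisely from protein context, and an ordinal
#' protein code buries that signal behind an arbitrary ordering that the
#' small hidden layer cannot reliably unfold (`"ordinal"` retains the
#' compact 103-wide layout).
#'
#' @param records records frame (subset of a `ddg_dataset`'s `records`).
#' @param predictions named list record_id -> `predicted_cdf` (from
#'   [ensemble_predict()] / [run_sampler()]).
#' @param encoders from [build_encoders()].
#' @param m quantile-grid length (default 100).
#' @param protein_encoding `"onehot"` (default) or `"ordinal"`.
#' @return numeric matrix, one row per record (rownames = record_id);
#'   `m + 2 + n_proteins` columns for one-hot, `m + 3` for ordinal.
#' @export
build_features <- function(records, predictions, encoders, m = 100L,
                           protein_encoding = c("onehot", "ordinal")) {
  protein_encoding <- match.arg(protein_encoding)
  ids <- records$record_id
  missing_ids <- setdiff(ids, names(predictions))
  if (length(missing_ids)) {
    stop("no predicted CDF for record(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  n_prot_cols <- if (protein_encoding == "onehot") {
    length(encoders$protein_levels)
  } else 1L
  prot_names <- if (protein_encoding == "onehot") {
    paste0("protein_", encoders$protein_levels)
  } else "protein_code"
  X <- matrix(0, nrow = length(ids), ncol = m + 2L + n_prot_cols,
              dimnames = list(ids, c(sprintf("q%03d", seq_len(m)),
                                     "sub_code", "sub_code_2", prot_names)))
  n_unseen <- 0L
  for (i in seq_along(ids)) {
    p <- predictions[[ids[i]]]
    X[i, seq_len(m)] <- quantile_grid(build_ecdf(p$corrected), m)
    k <- record_keys(records$mutation[i])
    c1 <- encode_level(k[1], encoders$key_levels)
    c2 <- if (length(k) == 2L) encode_level(k[2], encoders$key_levels) else 0L
    cp <- encode_level(records$protein_id[i], encoders$protein_levels)
    n_unseen <- n_unseen + (c1 == 0L) + (length(k) == 2L && c2 == 0L) +
      (cp == 0L)
    X[i, m + 1:2] <- c(c1, c2)
    if (protein_encoding == "onehot") {
      if (cp > 0L) X[i, m + 2L + cp] <- 1
    } else {
      X[i, m + 3L] <- cp
    }
  }
  if (n_unseen > 0L) {
    ddg_log(n_unseen, " unseen key/protein code(s) mapped to the unknown",
            " code", level = "WARN")
  }
  X
}

#' Fit a per-feature z-score scaler on a training matrix
#'
#' Constant features get sd := 1 so scaling never divides by zero.
#'
#' @param X training feature matrix.
#' @return list `mean`, `sd`.
#' @export
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Levenberg-Marquardt training schedule parameters
#'
#' `lambda0` and `lambda_down` default to `NULL`, meaning "resolve at
#' training time from the problem shape": in the classic regime (at least
#' as many samples as parameters) the usual aggressive schedule
#' `lambda0 = 1e-3, lambda_down = 10` applies; when parameters outnumber
#' samples — the normal situation for the 10-neuron network on a few
#' hundred records — training starts strongly damped (`lambda0 = n`, with
#' z-scored features comparable to the data Gram matrix) and relaxes slowly
#' (`lambda_down = 1.7`). The damped trajectory then traces a fine
#' ridge-like shrinkage path from the near-zero initial weights, and the
#' best-test-SSE iterate picks the stopping point on that path; the coarse
#' schedule skips the well-generalizing region entirely in this regime.
#'
#' @param lambda0 initial damping (`NULL` = auto, see above).
#' @param lambda_up damping multiplier on a rejected step (default 10).
#' @param lambda_down damping divisor on an accepted step (`NULL` = auto).
#' @param max_iter maximum accepted iterations (default 200).
#' @param grad_tol stop when the max absolute gradient entry falls below
#'   this (default 1e-7).
#' @param lambda_max stop when damping exceeds this (default 1e10).
#' @param early_stop_patience consecutive test-SSE increases tolerated
#'   before stopping and restoring the best-test weights (default 6).
#' @return a `train_params` list.
#' @export
train_params <- function(lambda0 = NULL, lambda_up = 10, lambda_down = NULL,
                         max_iter = 200L, grad_tol = 1e-7,
                         lambda_max = 1e10, early_stop_patience = 6L) {
  p <- list(lambda0 = lambda0, lambda_up = lambda_up,
            lambda_down = lambda_down, max_iter = as.integer(max_iter),
            grad_tol = grad_tol, lambda_max = lambda_max,
            early_stop_patience = as.integer(early_stop_patience))
  if (any(unlist(p) <= 0)) stop("all training parameters must be positive",
                                call. = FALSE)
  structure(p, class = "train_params")
}

# Resolve the auto schedule for a given problem shape.
resolve_schedule <- function(params, n, n_params) {
  over <- n_params > n
  if (is.null(params$lambda0)) {
    params$lambda0 <- if (over) n else 1e-3
  }
  if (is.null(params$lambda_down)) {
    params$lambda_down <- if (over) 1.7 else 10
  }
  params
}

#' Initialize a network
#'
#' Weights are Uniform(-1/sqrt(fan_in), +1/sqrt(fan_in)); biases start at 0.
#' `n_hidden = 0` is a linear-bypass mode (`y = w.x + b`, no hidden layer)
#' used to validate the optimizer against closed-form least squares.
#'
#' @param input_width number of input features.
#' @param n_hidden hidden neurons (default 10; 0 = linear bypass).
#' @param seed RNG seed.
#' @return a `ddg_network` with `W1` (n_hidden x input_width), `b1`, `W2`
#'   (1 x n_hidden), `b2`, and a `scaler` slot (identity until training).
#' @export
init_network <- function(input_width, n_hidden = 10L, seed = 1L) {
  stopifnot(input_width >= 1L, n_hidden >= 0L)
  with_seed(derive_seed(seed, 31L), {
    if (n_hidden == 0L) {
      W1 <- matrix(stats::runif(input_width, -1, 1) / sqrt(input_width),
                   nrow = 1L)
      net <- list(W1 = W1, b1 = 0, W2 = matrix(1, 1, 1), b2 = 0,
                  n_hidden = 0L, input_width = as.integer(input_width))
    } else {
      lim1 <- 1 / sqrt(input_width)
      lim2 <- 1 / sqrt(n_hidden)
      net <- list(
        W1 = matrix(stats::runif(n_hidden * input_width, -lim1, lim1),
                    nrow = n_hidden),
        b1 = rep(0, n_hidden),
        W2 = matrix(stats::runif(n_hidden, -lim2, lim2), nrow = 1L),
        b2 = 0,
        n_hidden = as.integer(n_hidden),
        input_width = as.integer(input_width))
    }
    net$scaler <- list(mean = rep(0, input_width), sd = rep(1, input_width))
    structure(net, class = "ddg_network")
  })
}

#' Forward pass
#'
#' `yhat = W2 . max(0, W1 . scale(x) + b1) + b2` (linear bypass when
#' `n_hidden = 0`).
#'
#' @param net a `ddg_network`.
#' @param X feature matrix (rows = samples) or a single feature vector.
#' @return numeric vector of predicted ddG.
#' @export
nn_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$input_width) {
    stop("feature width ", ncol(X), " does not match network input width ",
         net$input_width, call. = FALSE)
  }
  Xs <- apply_scaler(net$scaler, X)
  if (net$n_hidden == 0L) {
    return(drop(Xs %*% t(net$W1)) + net$b2)
  }
  Z <- Xs %*% t(net$W1)
  Z <- sweep(Z, 2, net$b1, "+")
  A <- pmax(Z, 0)
  drop(A %*% t(net$W2)) + net$b2
}

# --- parameter packing -------------------------------------------------

pack_params <- function(net) {
  if (net$n_hidden == 0L) c(as.vector(net$W1), net$b2)
  else c(as.vector(t(net$W1)), net$b1, as.vector(net$W2), net$b2)
}

unpack_params <- function(net, theta) {
  h <- net$n_hidden; p <- net$input_width
  if (h == 0L) {
    net$W1 <- matrix(theta[seq_len(p)], nrow = 1L)
    net$b2 <- theta[p + 1L]
    return(net)
  }
  net$W1 <- matrix(theta[seq_len(h * p)], nrow = h, byrow = TRUE)
  off <- h * p
  net$b1 <- theta[off + seq_len(h)]; off <- off + h
  net$W2 <- matrix(theta[off + seq_len(h)], nrow = 1L); off <- off + h
  net$b2 <- theta[off + 1L]
  net
}

# Jacobian of model outputs w.r.t. packed parameters, on scaled inputs.
# ReLU derivative at exactly 0 is taken as 0.
nn_jacobian <- function(net, Xs) {
  n <- nrow(Xs)
  if (net$n_hidden == 0L) {
    return(cbind(Xs, rep(1, n)))
  }
  h <- net$n_hidden; p <- net$input_width
  Z <- sweep(Xs %*% t(net$W1), 2, net$b1, "+")
  D <- (Z > 0) * 1            # n x h indicator
  A <- pmax(Z, 0)
  w2 <- as.vector(net$W2)
  J <- matrix(0, n, h * p + 2L * h + 1L)
  for (j in seq_len(h)) {
    gj <- w2[j] * D[, j]                       # n
    J[, (j - 1L) * p + seq_len(p)] <- Xs * gj  # dW1[j, ]
  }
  J[, h * p + seq_len(h)] <- sweep(D, 2, w2, "*")  # db1
  J[, h * p + h + seq_len(h)] <- A                 # dW2
  J[, h * p + 2L * h + 1L] <- 1                    # db2
  J
}

# Solve (J'J + lambda I) delta = J' r, via the dual form when n < n_params.
lm_step <- function(J, r, lambda) {
  n <- nrow(J); np <- ncol(J)
  if (n >= np) {
    M <- crossprod(J)
    diag(M) <- diag(M) + lambda
    drop(solve(M, crossprod(J, r)))
  } else {
    M <- tcrossprod(J)
    diag(M) <- diag(M) + lambda
    drop(crossprod(J, solve(M, r)))
  }
}

#' Train a network with Levenberg-Marquardt
#'
#' Minimizes the training sum of squared errors. A step is accepted only if
#' it decreases the SSE, so the accepted-SSE trace is non-increasing.
#' Stopping: `max_iter` accepted iterations, gradient below `grad_tol`,
#' damping above `lambda_max`, or `early_stop_patience` consecutive
#' increases of the test-split SSE (the weights with the best test SSE are
#' restored). The feature scaler is fit on `X` here, never on test data.
#'
#' @param net a `ddg_network` from [init_network()].
#' @param X,y training features and observed ddG.
#' @param X_test,y_test optional held-out split used only for early
#'   stopping.
#' @param params a [train_params()].
#' @return list `net` (trained), `trace` (data frame: iteration, sse,
#'   lambda, test_sse), `stopped` (reason).
#' @export
train_lm <- function(net, X, y, X_test = NULL, y_test = NULL,
                     params = train_params()) {
  stopifnot(inherits(net, "ddg_network"), nrow(X) >= 1L,
            length(y) == nrow(X), all(is.finite(y)))
  net$scaler <- fit_scaler(X)
  Xs <- apply_scaler(net$scaler, X)
  Xts <- if (!is.null(X_test)) apply_scaler(net$scaler, X_test)
  forward_scaled <- function(nn, M) {
    if (nn$n_hidden == 0L) return(drop(M %*% t(nn$W1)) + nn$b2)
    A <- pmax(sweep(M %*% t(nn$W1), 2, nn$b1, "+"), 0)
    drop(A %*% t(nn$W2)) + nn$b2
  }
  theta <- pack_params(net)
  params <- resolve_schedule(params, nrow(X), length(theta))
  sse <- function(th) {
    r <- y - forward_scaled(unpack_params(net, th), Xs)
    sum(r * r)
  }
  test_sse <- function(th) {
    if (is.null(Xts)) return(NA_real_)
    r <- y_test - forward_scaled(unpack_params(net, th), Xts)
    sum(r * r)
  }
  lambda <- params$lambda0
  cur_sse <- sse(theta)
  if (!is.finite(cur_sse)) stop("non-finite initial loss", call. = FALSE)
  best_test <- test_sse(theta)
  best_theta <- theta
  prev_test <- best_test
  bad_streak <- 0L
  trace <- list(data.frame(iteration = 0L, sse = cur_sse, lambda = lambda,
                           test_sse = best_test))
  stopped <- "max_iter"
  iter <- 0L
  while (iter < params$max_iter) {
    cur_net <- unpack_params(net, theta)
    r <- y - forward_scaled(cur_net, Xs)
    J <- nn_jacobian(cur_net, Xs)
    g <- crossprod(J, r)
    if (max(abs(g)) < params$grad_tol) { stopped <- "grad_tol"; break }
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(lm_step(J, r, lambda), error = function(e) NULL)
      new_sse <- if (is.null(delta)) Inf else sse(theta + delta)
      if (!is.finite(new_sse)) new_sse <- Inf
      if (new_sse < cur_sse) {
        theta <- theta + delta
        cur_sse <- new_sse
        lambda <- lambda / params$lambda_down
        accepted <- TRUE
      } else {
        lambda <- lambda * params$lambda_up
        if (lambda > params$lambda_max) break
      }
    }
    if (!accepted) { stopped <- "lambda_max"; break }
    iter <- iter + 1L
    ts <- test_sse(theta)
    trace[[length(trace) + 1L]] <-
      data.frame(iteration = iter, sse = cur_sse, lambda = lambda,
                 test_sse = ts)
    if (!is.null(Xts)) {
      if (is.na(best_test) || ts < best_test) {
        best_test <- ts
        best_theta <- theta
      }
      if (!is.na(prev_test) && ts > prev_test) {
        bad_streak <- bad_streak + 1L
        if (bad_streak >= params$early_stop_patience) {
          stopped <- "early_stop"
          break
        }
      } else {
        bad_streak <- 0L
      }
      prev_test <- ts
    }
  }
  final_theta <- if (!is.null(Xts) && !is.na(best_test)) best_theta else theta
  list(net = unpack_params(net, final_theta),
       trace = do.call(rbind, trace), stopped = stopped)
}

#' Hidden-layer-size tuning on a data subset
#'
#' Mirrors architecture tuning on a reduced dataset: takes a
#' `tuning_frac` subset, re-splits it 70/15/15 internally, trains one
#' network per candidate size and reports validation Pearson/RMSE; the best
#' size minimizes RMSE.
#'
#' @param X,y full feature matrix and targets.
#' @param sizes candidate hidden sizes (e.g. `c(2, 5, 10, 20)`).
#' @param tuning_frac fraction of the data used for tuning (default 0.2).
#' @param params a [train_params()].
#' @param seed RNG seed.
#' @return list `table` (data frame: size, pearson, rmse), `best_size`.
#' @export
tune_hidden_size <- function(X, y, sizes, tuning_frac = 0.2,
                             params = train_params(), seed = 1L) {
  stopifnot(length(sizes) >= 1L)
  n <- nrow(X)
  idx <- with_seed(derive_seed(seed, 271L),
                   sample.int(n, max(10L, floor(tuning_frac * n))))
  Xt <- X[idx, , drop = FALSE]; yt <- y[idx]
  sp <- split_indices(length(yt), c(0.70, 0.15, 0.15),
                      seed = derive_seed(seed, 272L))
  rows <- lapply(seq_along(sizes), function(si) {
    h <- sizes[si]
    net <- init_network(ncol(X), n_hidden = h,
                        seed = derive_seed(seed, 273L + si))
    fit <- train_lm(net, Xt[sp$train, , drop = FALSE], yt[sp$train],
                    Xt[sp$test, , drop = FALSE], yt[sp$test], params)
    pred <- nn_forward(fit$net, Xt[sp$validation, , drop = FALSE])
    data.frame(size = h, pearson = pearson_cor(pred, yt[sp$validation]),
               rmse = rmse(pred, yt[sp$validation]))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, best_size = tab$size[which.min(tab$rmse)])
}

# Random disjoint train/test/validation indices with given fractions.
split_indices <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  with_seed(seed, {
    perm <- sample.int(n)
    n_train <- max(1L, floor(fractions[1] * n))
    n_test <- max(1L, floor(fractions[2] * n))
    if (n_train + n_test >= n) stop("degenerate split (empty partition)",
                                    call. = FALSE)
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[n_train + seq_len(n_test)]),
         validation = sort(perm[(n_train + n_test + 1L):n]))
  })
}

#' Repeated random 70/15/15 train/test/validation experiment
#'
#' The network is trained and validated `n_repeats` times on independent
#' random splits: 70% for learning, 15% for early-stopping ("testing") and
#' 15% for blind validation. Per repeat the feature scaler and the
#' categorical encoders are fit on the training split only (no leakage);
#' metrics are reported on the untouched validation split. When sampler
#' medians are supplied, each report also carries the sampler-median
#' baseline RMSE on the same validation records.
#'
#' Per repeat the network is trained `n_restarts` times from independent
#' random initializations and the restart with the lowest test-split SSE is
#' kept (restart selection is standard practice for small LM-trained
#' networks, whose fits depend visibly on the initial weights; it is model
#' selection on the test split, not an ensemble).
#'
#' @param records records frame of the dataset being modelled (only records
#'   with a predicted CDF).
#' @param predictions named list record_id -> `predicted_cdf`.
#' @param n_repeats number of random splits (default 100).
#' @param n_hidden hidden neurons (default 10).
#' @param m quantile-grid length (default 100).
#' @param params a [train_params()].
#' @param seed master seed.
#' @param baseline optional named vector record_id -> sampler median ddG.
#' @param n_restarts random initializations per repeat (default 3).
#' @param protein_encoding forwarded to [build_features()].
#' @return data frame of `eval_report` rows: repeat index, pearson, rmse,
#'   sign_accuracy, n_validation, split sizes, seed, baseline_rmse.
#' @export
repeated_split_experiment <- function(records, predictions,
                                      n_repeats = 100L, n_hidden = 10L,
                                      m = 100L, params = train_params(),
                                      seed = 1L, baseline = NULL,
                                      n_restarts = 3L,
                                      protein_encoding = "onehot") {
  ids <- intersect(records$record_id, names(predictions))
  records <- records[match(ids, records$record_id), , drop = FALSE]
  n <- nrow(records)
  if (n < 10L) stop("need at least 10 predicted records", call. = FALSE)
  y_all <- records$ddg
  reports <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, 1000L + rep_i)
    sp <- split_indices(n, c(0.70, 0.15, 0.15), seed = rep_seed)
    enc <- build_encoders(records[sp$train, , drop = FALSE])
    X <- build_features(records, predictions, enc, m = m,
                        protein_encoding = protein_encoding)
    best_fit <- NULL
    best_test_sse <- Inf
    for (s in seq_len(n_restarts)) {
      net <- init_network(ncol(X), n_hidden = n_hidden,
                          seed = derive_seed(rep_seed, 2L + s))
      fit <- train_lm(net, X[sp$train, , drop = FALSE], y_all[sp$train],
                      X[sp$test, , drop = FALSE], y_all[sp$test], params)
      t_sse <- sum((y_all[sp$test] -
                      nn_forward(fit$net, X[sp$test, , drop = FALSE]))^2)
      if (t_sse < best_test_sse) {
        best_test_sse <- t_sse
        best_fit <- fit
      }
    }
    fit <- best_fit
    pred <- nn_forward(fit$net, X[sp$validation, , drop = FALSE])
    obs <- y_all[sp$validation]
    base_rmse <- if (!is.null(baseline)) {
      rmse(baseline[records$record_id[sp$validation]], obs)
    } else NA_real_
    reports[[rep_i]] <- data.frame(
      repeat_index = rep_i,
      pearson = pearson_cor(pred, obs),
      rmse = rmse(pred, obs),
      sign_accuracy = holdout_accuracy(pred, obs),
      n_train = length(sp$train), n_test = length(sp$test),
      n_validation = length(sp$validation),
      seed = rep_seed, baseline_rmse = base_rmse)
  }
  do.call(rbind, reports)
}

#' Serialize a network to JSON
#' @param net a `ddg_network`.
#' @param path output path.
#' @export
network_to_json <- function(net, path) {
  jsonlite::write_json(list(W1 = net$W1, b1 = net$b1,
                            W2 = as.vector(net$W2), b2 = net$b2,
                            n_hidden = net$n_hidden,
                            input_width = net$input_width,
                            scaler = net$scaler),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a network from its JSON form
#' @param path JSON written by [network_to_json()].
#' @export
network_from_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  W1 <- if (is.matrix(o$W1)) o$W1 else matrix(o$W1, nrow = 1L)
  structure(list(W1 = W1,
                 b1 = as.numeric(o$b1),
                 W2 = matrix(as.numeric(o$W2), nrow = 1L),
                 b2 = as.numeric(o$b2),
                 n_hidden = as.integer(o$n_hidden),
                 input_width = as.integer(o$input_width),
                 scaler = list(mean = as.numeric(o$scaler$mean),
                               sd = as.numeric(o$scaler$sd))),
            class = "ddg_network")
}
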