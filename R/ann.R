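#' Shallow feedforward regression networks
#'
#' One-hidden-layer feedforward networks (tan-sigmoid hidden layer, linear
#' output layer) trained by damped Gauss-Newton: plain Levenberg-Marquardt
#' (LM) with validation-based early stopping, or Bayesian regularization
#' (BR) which minimizes `F = beta * E_D + alpha * E_W` and re-estimates
#' `alpha`, `beta` from the evidence framework after each accepted step.
#' Inputs and targets are min-max scaled to `[-1, 1]`; the error Jacobian is
#' assembled analytically by per-sample backpropagation.
#'
#' @name ann_regression
NULL

#' Network training configuration
#'
#' @param n_inputs,n_hidden,n_outputs layer sizes (all >= 1).
#' @param algorithm `"levenberg_marquardt"` or `"bayesian_regularization"`.
#' @param max_epochs iteration cap (default 1000).
#' @param mu_init initial LM damping (default 1e-3).
#' @param mu_factor damping multiplier/divisor (default 10).
#' @param mu_max damping ceiling; exceeding it stops training (default 1e10).
#' @param grad_tol stop when the objective gradient infinity-norm falls
#'   below this (default 1e-7).
#' @param val_patience consecutive validation-MSE increases tolerated before
#'   stopping (LM only, default 6); best-validation weights are restored.
#' @param seed integer seed for weight initialization.
#' @return list of class `network_config`.
#' @export
network_config <- function(n_inputs, n_hidden, n_outputs,
                           algorithm = c("levenberg_marquardt",
                                         "bayesian_regularization"),
                           max_epochs = 1000L, mu_init = 1e-3,
                           mu_factor = 10, mu_max = 1e10,
                           grad_tol = 1e-7, val_patience = 6L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_inputs >= 1L, n_hidden >= 1L, n_outputs >= 1L, max_epochs >= 1L)
  structure(
    list(n_inputs = n_inputs, n_hidden = n_hidden, n_outputs = n_outputs,
         algorithm = algorithm, max_epochs = max_epochs, mu_init = mu_init,
         mu_factor = mu_factor, mu_max = mu_max, grad_tol = grad_tol,
         val_patience = val_patience, seed = seed),
    class = "network_config"
  )
}

# ---- scaling -----------------------------------------------------------

# Per-feature affine map onto [-1, 1]; constant features map to 0 and are
# inverted back to their constant value.
minmax_scaler <- function(M) {
  M <- as.matrix(M)
  mn <- apply(M, 2, min)
  mx <- apply(M, 2, max)
  rng <- mx - mn
  rng[rng < 1e-12] <- 1  # constant feature: avoid division by zero
  list(min = mn, range = rng)
}

scale_apply <- function(scaler, M) {
  M <- as.matrix(M)
  sweep(sweep(M, 2, scaler$min), 2, scaler$range, "/") * 2 - 1
}

scale_invert <- function(scaler, S) {
  S <- as.matrix(S)
  sweep(sweep((S + 1) / 2, 2, scaler$range, "*"), 2, scaler$min, "+")
}

# ---- network -----------------------------------------------------------

# Nguyen-Widrow-style seeded initialization: hidden weight rows on a sphere
# of radius 0.7 * h^(1/p), biases spread across the input range.
init_network <- function(config, input_scaler, target_scaler) {
  h <- config$n_hidden; p <- config$n_inputs; q <- config$n_outputs
  with_seed(config$seed, {
    W1 <- matrix(stats::runif(h * p, -1, 1), h, p)
    norms <- sqrt(rowSums(W1^2))
    norms[norms < 1e-12] <- 1
    magnitude <- 0.7 * h^(1 / p)
    W1 <- magnitude * W1 / norms
    b1 <- if (h == 1L) 0 else magnitude * seq(-1, 1, length.out = h) * sign(W1[, 1])
    W2 <- matrix(stats::runif(q * h, -0.5, 0.5), q, h)
    b2 <- stats::runif(q, -0.5, 0.5)
    structure(
      list(W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2),
           input_scaler = input_scaler, target_scaler = target_scaler,
           config = config),
      class = "ann_network"
    )
  })
}

pack_weights <- function(net) {
  c(as.vector(net$W1), net$b1, as.vector(net$W2), net$b2)
}

unpack_weights <- function(net, w) {
  h <- nrow(net$W1); p <- ncol(net$W1); q <- nrow(net$W2)
  i <- 0L
  net$W1 <- matrix(w[i + seq_len(h * p)], h, p); i <- i + h * p
  net$b1 <- w[i + seq_len(h)]; i <- i + h
  net$W2 <- matrix(w[i + seq_len(q * h)], q, h); i <- i + q * h
  net$b2 <- w[i + seq_len(q)]
  net
}

# Forward pass in scaled space: returns hidden activations and outputs.
forward_scaled <- function(net, Xs) {
  A <- tanh(Xs %*% t(net$W1) + matrix(net$b1, nrow(Xs), length(net$b1),
                                      byrow = TRUE))
  Ys <- A %*% t(net$W2) + matrix(net$b2, nrow(Xs), length(net$b2),
                                 byrow = TRUE)
  list(A = A, Ys = Ys)
}

#' Network predictions on raw inputs
#'
#' `y = unscale(W2 %*% tanh(W1 %*% scale(x) + b1) + b2)`, vectorized over rows.
#'
#' @param object an `ann_network`.
#' @param newdata numeric matrix with `n_inputs` columns.
#' @param ... unused.
#' @return prediction matrix with `n_outputs` columns, in target units.
#' @export
predict.ann_network <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$W1)) {
    stop("input has ", ncol(newdata), " columns; network expects ",
         ncol(object$W1))
  }
  Xs <- scale_apply(object$input_scaler, newdata)
  scale_invert(object$target_scaler, forward_scaled(object, Xs)$Ys)
}

# Analytic Jacobian of the scaled error vector w.r.t. all weights.
# Error ordering: column-major over the (n x q) residual matrix, i.e. one
# block of n rows per output target. Column ordering matches pack_weights().
ann_jacobian <- function(net, Xs) {
  n <- nrow(Xs); h <- nrow(net$W1); p <- ncol(net$W1); q <- nrow(net$W2)
  fw <- forward_scaled(net, Xs)
  A <- fw$A
  D <- 1 - A^2  # tanh'
  n_w <- h * p + h + q * h + q
  J <- matrix(0, n * q, n_w)
  idx_W1 <- seq_len(h * p)
  idx_b1 <- h * p + seq_len(h)
  idx_W2 <- h * p + h + seq_len(q * h)
  idx_b2 <- h * p + h + q * h + seq_len(q)
  for (t in seq_len(q)) {
    rows <- (t - 1L) * n + seq_len(n)
    S <- D * matrix(net$W2[t, ], n, h, byrow = TRUE)      # n x h
    # dW1[j,k] column order: j fastest (column-major h x p)
    J[rows, idx_W1] <- S[, rep(seq_len(h), times = p)] *
      Xs[, rep(seq_len(p), each = h), drop = FALSE]
    J[rows, idx_b1] <- S
    # dW2[t',j] nonzero only for t' = t, column index t + (j-1)q
    J[rows, idx_W2[t + (seq_len(h) - 1L) * q]] <- A
    J[rows, idx_b2[t]] <- 1
  }
  J
}

#' One damped Gauss-Newton (Levenberg-Marquardt) step
#'
#' Solves `(beta * J'J + (alpha + mu) I) delta = -(beta * J'e + alpha * w)`.
#' With `alpha = 0`, `beta = 1` and `mu -> 0` this is the Gauss-Newton /
#' normal-equations step of a least-squares problem.
#'
#' @param J error Jacobian.
#' @param e error vector.
#' @param mu damping.
#' @param w current weight vector (only used when `alpha > 0`).
#' @param alpha,beta regularization and data weights.
#' @return weight update `delta`, or `NULL` if the system is singular.
#' @export
lm_step <- function(J, e, mu, w = NULL, alpha = 0, beta = 1) {
  A <- beta * crossprod(J)
  diag(A) <- diag(A) + alpha + mu
  rhs <- -(beta * crossprod(J, e))
  if (alpha > 0) rhs <- rhs - alpha * w
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  as.numeric(backsolve(ch, forwardsolve(t(ch), rhs)))
}

# Shared LM/BR training engine in scaled space.
# Xs/Ts: scaled training data; Xv/Tv: scaled validation data or NULL.
train_engine <- function(net, Xs, Ts, Xv = NULL, Tv = NULL,
                         bayesian = FALSE, update_hyper = TRUE) {
  cfg <- net$config
  w <- pack_weights(net)
  n_w <- length(w)
  n_obs <- length(Ts)  # scalar error terms N
  alpha <- 0
  beta <- 1
  gamma <- n_w
  mu <- cfg$mu_init
  resid <- function(w) {
    as.vector(forward_scaled(unpack_weights(net, w), Xs)$Ys - Ts)
  }
  objective <- function(e, w) {
    if (bayesian) beta * sum(e^2) + alpha * 0.5 * sum(w^2) else sum(e^2)
  }
  e <- resid(w)
  f_cur <- objective(e, w)
  best_val <- Inf; best_w <- w; val_up <- 0L
  trace_obj <- numeric(0)
  stop_reason <- "max_epochs"
  epochs <- 0L
  warn <- character(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    epochs <- epoch
    J <- ann_jacobian(unpack_weights(net, w), Xs)
    grad <- 2 * (beta * crossprod(J, e))
    if (bayesian) grad <- grad + alpha * w
    if (max(abs(grad)) < cfg$grad_tol) { stop_reason <- "gradient"; break }
    accepted <- FALSE
    while (!accepted) {
      delta <- lm_step(J, e, mu, w, alpha = if (bayesian) alpha else 0,
                       beta = if (bayesian) beta else 1)
      if (!is.null(delta)) {
        w_new <- w + delta
        e_new <- resid(w_new)
        f_new <- objective(e_new, w_new)
        if (is.finite(f_new) && f_new < f_cur) {
          w <- w_new; e <- e_new; f_cur <- f_new
          mu <- mu / cfg$mu_factor
          accepted <- TRUE
          break
        }
      }
      mu <- mu * cfg$mu_factor
      if (mu > cfg$mu_max) break
    }
    trace_obj <- c(trace_obj, f_cur)
    if (!accepted) { stop_reason <- "mu_max"; break }
    if (bayesian && update_hyper) {
      e_w <- 0.5 * sum(w^2)
      e_d <- sum(e^2)
      if (alpha > 0) {
        # Gauss-Newton Hessian of F = beta*sum(e^2) + alpha*0.5*sum(w^2);
        # gamma = sum_i lambda_i / (lambda_i + alpha) in [0, n_w]
        H <- 2 * beta * crossprod(J)
        diag(H) <- diag(H) + alpha
        tr_hinv <- sum(diag(chol2inv(chol(H))))
        gamma <- n_w - alpha * tr_hinv
      } else {
        gamma <- n_w  # alpha = 0: every weight counts as effective
      }
      if (e_w < 1e-12) {
        alpha <- 1e10
        warn <- union(warn, "E_W = 0 with gamma > 0: alpha capped at 1e10")
      } else {
        alpha <- gamma / (2 * e_w)
      }
      beta <- max((n_obs - gamma), 1e-3) / (2 * max(e_d, 1e-12))
      f_cur <- objective(e, w)  # hyperparameters changed; refresh objective
    }
    if (!is.null(Xv)) {
      val_mse <- mean((forward_scaled(unpack_weights(net, w), Xv)$Ys - Tv)^2)
      if (val_mse < best_val) {
        best_val <- val_mse; best_w <- w; val_up <- 0L
      } else {
        val_up <- val_up + 1L
        if (val_up >= cfg$val_patience) {
          stop_reason <- "validation"
          w <- best_w
          break
        }
      }
    }
  }
  if (!is.null(Xv) && stop_reason %in% c("max_epochs", "gradient", "mu_max") &&
      is.finite(best_val)) {
    # keep the best-validation weights seen, as with patience stopping
    w_mse <- mean((forward_scaled(unpack_weights(net, w), Xv)$Ys - Tv)^2)
    if (best_val < w_mse) w <- best_w
  }
  list(net = unpack_weights(net, w),
       result = list(epochs = epochs, objective = trace_obj,
                     stop_reason = stop_reason, mu = mu,
                     alpha = alpha, beta = beta, gamma = gamma,
                     n_weights = n_w, n_error_terms = n_obs,
                     warnings = warn))
}

#' Random train/validation/test split
#'
#' Seeded uniform permutation partitioned by the stage fractions.
#' Non-training stages receive `floor(fraction * n)` samples and training
#' the remainder, so realized counts stay within one of `fraction * n`
#' (e.g. n = 432 gives 324/108 at 75/25 and 260/86/86 at 60/20/20).
#'
#' @param n_samples number of samples (>= 5).
#' @param fractions numeric `(train, validation, test)` summing to 1.
#' @param seed integer seed.
#' @return object of class `split_spec`: list with `fractions`, `seed`,
#'   `assignment` (character vector: `"training"/"validation"/"testing"`).
#' @export
split_dataset <- function(n_samples, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(n_samples >= 5L, length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  n_val <- floor(fractions[2] * n_samples)
  n_test <- floor(fractions[3] * n_samples)
  n_train <- n_samples - n_val - n_test
  counts <- c(n_train, n_val, n_test)
  if (any(counts == 0L & fractions > 0)) {
    stop("split_dataset: a stage with positive fraction received no samples")
  }
  perm <- with_seed(seed, sample.int(n_samples))
  assignment <- character(n_samples)
  assignment[perm[seq_len(n_train)]] <- "training"
  if (n_val > 0L) assignment[perm[n_train + seq_len(n_val)]] <- "validation"
  if (n_test > 0L) assignment[perm[n_train + n_val + seq_len(n_test)]] <- "testing"
  structure(list(fractions = fractions, seed = seed, assignment = assignment),
            class = "split_spec")
}

#' Train a network on a dataset split
#'
#' Scales inputs and targets to `[-1, 1]` (min-max over the full dataset),
#' initializes weights (Nguyen-Widrow, seeded), and runs the algorithm named
#' in the config: LM with validation early stopping, or BR (train/test only,
#' evidence updates of `alpha`/`beta` after each accepted step starting from
#' `alpha = 0`, `beta = 1`).
#'
#' @param X input matrix (samples x features).
#' @param Y target matrix (samples x targets).
#' @param split a [split_dataset()] result.
#' @param config a [network_config()].
#' @param update_hyper internal switch; `FALSE` freezes `alpha = 0`,
#'   `beta = 1` in BR (then BR reduces to LM on the data misfit).
#' @return object of class `ann_fit`: list with `network`, `result`
#'   (trace, stop reason, `alpha`/`beta`/`gamma`), and `diagnostics`
#'   (per-stage tibble from [regression_diagnostics()]).
#' @export
train_network <- function(X, Y, split, config, update_hyper = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) == length(split$assignment),
            ncol(X) == config$n_inputs, ncol(Y) == config$n_outputs)
  bayesian <- config$algorithm == "bayesian_regularization"
  has_val <- any(split$assignment == "validation")
  if (bayesian && has_val) {
    stop("bayesian_regularization uses no validation stage (train/test only)")
  }
  in_sc <- minmax_scaler(X)
  tg_sc <- minmax_scaler(Y)
  Xs <- scale_apply(in_sc, X)
  Ys <- scale_apply(tg_sc, Y)
  tr <- split$assignment == "training"
  va <- split$assignment == "validation"
  net0 <- init_network(config, in_sc, tg_sc)
  fit <- train_engine(
    net0,
    Xs[tr, , drop = FALSE], Ys[tr, , drop = FALSE],
    Xv = if (has_val) Xs[va, , drop = FALSE] else NULL,
    Tv = if (has_val) Ys[va, , drop = FALSE] else NULL,
    bayesian = bayesian, update_hyper = update_hyper
  )
  pred <- predict(fit$net, X)
  stages <- c("training", if (has_val) "validation", "testing")
  diag_rows <- lapply(stages, function(s) {
    sel <- split$assignment == s
    regression_diagnostics(pred[sel, , drop = FALSE], Y[sel, , drop = FALSE],
                           stage = s)
  })
  diag_rows <- c(diag_rows, list(regression_diagnostics(pred, Y, "overall")))
  structure(
    list(network = fit$net, result = fit$result, split = split,
         diagnostics = do.call(rbind, diag_rows)),
    class = "ann_fit"
  )
}

#' Hidden-layer size sweep (neuron trimming)
#'
#' Trains one network per candidate hidden-layer size with a shared seed and
#' split. A candidate is admissible when `MSE_train <= MSE_test` and, when a
#' validation stage exists, `|MSE_val - MSE_test| <= 0.25 * MSE_test` (no
#' under- or overfitting). Among admissible candidates the one with the
#' highest overall R is selected, ties broken toward fewer neurons; when no
#' candidate is admissible the best-R one is returned flagged inadmissible.
#'
#' @inheritParams train_network
#' @param candidates integer vector of hidden sizes (default `c(3, 5, 7, 10)`).
#' @return object of class `trimming_report`: list with `candidates` tibble
#'   (`n_hidden`, per-stage MSEs, `overall_r`, `admissible`), `selected`,
#'   `admissible_found`, and `fits` (named list of `ann_fit`).
#' @export
neuron_trimming <- function(X, Y, split, config, candidates = c(3L, 5L, 7L, 10L)) {
  stopifnot(length(candidates) >= 1L)
  has_val <- any(split$assignment == "validation")
  fits <- list()
  rows <- lapply(candidates, function(h) {
    cfg <- config
    cfg$n_hidden <- h
    fit <- train_network(X, Y, split, cfg)
    fits[[as.character(h)]] <<- fit
    d <- fit$diagnostics
    mse_of <- function(s) {
      v <- d$mse[d$stage == s]
      if (length(v)) v else NA_real_
    }
    mse_tr <- mse_of("training"); mse_te <- mse_of("testing")
    mse_va <- mse_of("validation")
    admissible <- mse_tr <= mse_te &&
      (!has_val || abs(mse_va - mse_te) <= 0.25 * mse_te)
    tibble::tibble(n_hidden = h, mse_train = mse_tr, mse_val = mse_va,
                   mse_test = mse_te, overall_r = d$r[d$stage == "overall"],
                   admissible = admissible)
  })
  tab <- do.call(rbind, rows)
  pool <- if (any(tab$admissible)) tab[tab$admissible, ] else tab
  # highest overall R; R within 1e-3 counts as a tie, broken toward fewer
  # neurons (parsimony)
  r_cmp <- ifelse(is.na(pool$overall_r), -Inf, pool$overall_r)
  ord <- order(-r_cmp, pool$n_hidden)
  pool <- pool[ord, ]
  r_cmp <- r_cmp[ord]
  selected <- min(pool$n_hidden[r_cmp >= r_cmp[1] - 1e-3])
  structure(
    list(candidates = tab, selected = selected,
         admissible_found = any(tab$admissible), fits = fits),
    class = "trimming_report"
  )
}

#' Serialize a network (or fit) to JSON
#' @param net an `ann_network` or `ann_fit`.
#' @param path output JSON path.
#' @export
network_to_json <- function(net, path) {
  if (inherits(net, "ann_fit")) net <- net$network
  obj <- list(
    config = unclass(net$config),
    W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
    input_scaler = net$input_scaler, target_scaler = net$target_scaler
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a network from JSON
#' @param path JSON path written by [network_to_json()].
#' @return an `ann_network`.
#' @export
network_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, obj$config[c(
    "n_inputs", "n_hidden", "n_outputs", "algorithm", "max_epochs",
    "mu_init", "mu_factor", "mu_max", "grad_tol", "val_patience", "seed")])
  structure(
    list(W1 = matrix(obj$W1, cfg$n_hidden, cfg$n_inputs),
         b1 = as.numeric(obj$b1),
         W2 = matrix(obj$W2, cfg$n_outputs, cfg$n_hidden),
         b2 = as.numeric(obj$b2),
         input_scaler = lapply(obj$input_scaler, as.numeric),
         target_scaler = lapply(obj$target_scaler, as.numeric),
         config = cfg),
    class = "ann_network"
  )
}
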