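# Loss, gradients, Adam, dataset splitting, the training loop with
# periodic-validation model selection, and evaluation metrics.
#
# Quantum-circuit gradients use the parameter-shift rule: for any gate
# exp(-i theta P / 2) with P^2 = I, d f / d theta =
# (f(theta + pi/2) - f(theta - pi/2)) / 2, summed over every gate occurrence
# of a shared trainable angle.  Gradients flow into the angle extraction
# network by chaining the shift-rule derivative of the prediction with
# respect to each encoding angle through the network analytically.
# Classical-baseline gradients are computed by central finite differences
# (a handful of parameters, cheap dense forward).

#' Bundle a model family and its configuration
#'
#' @param type `"quantum"` (EDU-QGC, also covers hybrid encodings) or
#'   `"classical"`.
#' @param config a [model_config()] or [classical_config()].
#' @return a `model_spec` list.
#' @export
model_spec <- function(type = c("quantum", "classical"), config) {
  type <- match.arg(type)
  if (type == "quantum") stopifnot(inherits(config, "model_config"))
  else stopifnot(inherits(config, "classical_config"))
  structure(list(type = type, config = config), class = "model_spec")
}

#' Predict one molecule under a model spec
#'
#' Quantum models that expect a master node augment the graph on the fly
#' when it is absent, so datasets can be stored without master nodes.
#'
#' @param spec a [model_spec()].
#' @param params matching parameters.
#' @param g a `molgraph`.
#' @return scalar prediction in Hartree.
#' @export
predict_one <- function(spec, params, g) {
  if (spec$type == "quantum") {
    if (spec$config$master_node && !has_master(g)) g <- add_master_node(g)
    qgnn_forward(g, spec$config, params)
  } else {
    classical_forward(g, spec$config, params)
  }
}

#' Mean-squared-error loss
#' @param preds,targets numeric vectors of equal length >= 1, Hartree.
#' @return scalar, Hartree^2.
#' @export
mse_loss <- function(preds, targets) {
  stopifnot(length(preds) == length(targets), length(preds) >= 1)
  mean((preds - targets)^2)
}

# ---------------------------------------------------------------------------
# Parameter vector <-> structured parameters

param_template <- function(params) {
  if (inherits(params, "qgnn_params")) {
    fields <- c("node_angles", "master_angles", "d_angle", "v_angles",
                "r0", "r1", "r2")
    out <- list()
    for (f in fields) if (!is.null(params[[f]]))
      out[[f]] <- params[[f]]
    if (!is.null(params$net))
      for (f in c("W1", "b1", "W2", "b2"))
        out[[paste0("net.", f)]] <- params$net[[f]]
    out
  } else {
    params[!vapply(params, is.null, logical(1))]
  }
}

#' Flatten parameters to a named numeric vector (and back)
#'
#' The flat layout is what the optimizer and the finite-difference checks
#' operate on; `unflatten_params` inverts it given any same-shaped template.
#'
#' @param params a `qgnn_params` or `classical_params`.
#' @param vec numeric vector from `flatten_params`.
#' @return `flatten_params`: named numeric vector; `unflatten_params`: a
#'   parameter object shaped like `params`.
#' @export
flatten_params <- function(params) {
  tpl <- param_template(params)
  unlist(lapply(names(tpl), function(nm) {
    v <- as.numeric(tpl[[nm]])
    setNames(v, paste0(nm, "[", seq_along(v), "]"))
  }))
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(vec, params) {
  tpl <- param_template(params)
  pos <- 0L
  for (nm in names(tpl)) {
    k <- length(tpl[[nm]])
    vals <- vec[pos + seq_len(k)]
    pos <- pos + k
    tgt <- tpl[[nm]]
    if (is.matrix(tgt)) {
      m <- matrix(vals, nrow(tgt), ncol(tgt), dimnames = dimnames(tgt))
      tpl[[nm]] <- m
    } else {
      tpl[[nm]] <- setNames(as.numeric(vals), names(tgt))
    }
  }
  if (inherits(params, "qgnn_params")) {
    out <- params
    for (f in c("node_angles", "master_angles", "d_angle", "v_angles",
                "r0", "r1", "r2"))
      if (!is.null(out[[f]])) out[[f]] <- tpl[[f]]
    if (!is.null(out$net))
      for (f in c("W1", "b1", "W2", "b2"))
        out$net[[f]] <- tpl[[paste0("net.", f)]]
    out
  } else {
    out <- params
    for (nm in names(tpl)) out[[nm]] <- tpl[[nm]]
    out
  }
}

# ---------------------------------------------------------------------------
# Gradient of a single prediction (quantum): parameter-shift on the tape

zero_like <- function(params) {
  unflatten_params(rep(0, length(flatten_params(params))), params)
}

qgnn_grad_prediction <- function(g, config, params) {
  if (config$master_node && !has_master(g)) g <- add_master_node(g)
  check_params_shape(config, params)
  cc <- compile_circuit(g, config, params)
  tape <- cc$tape
  n <- cc$n
  # prefix[[i]] = amplitudes before gate i, so a shift at gate i only
  # replays the suffix of the circuit
  prefix <- vector("list", length(tape) + 1L)
  amps <- complex(cc$N)
  amps[1] <- 1 + 0i
  prefix[[1L]] <- amps
  for (i in seq_along(tape)) {
    gt <- cc$gates[[i]]
    if (gt$zz) {
      amps <- amps * gt$ph
    } else {
      a0 <- amps[gt$i0]; a1 <- amps[gt$i1]
      amps[gt$i0] <- gt$U[1, 1] * a0 + gt$U[1, 2] * a1
      amps[gt$i1] <- gt$U[2, 1] * a0 + gt$U[2, 2] * a1
    }
    prefix[[i + 1L]] <- amps
  }
  probs <- Re(amps * Conj(amps))
  m1 <- mean(vapply(seq_len(n), function(q) sum(cc$zsigns[[q]] * probs),
                    numeric(1)))
  m2 <- if (config$readout == "global") {
    par <- cc$zsigns[[1]]
    for (q in seq_len(n)[-1]) par <- par * cc$zsigns[[q]]
    sum(par * probs)
  } else NULL
  pred <- params$r0 + params$r1 * m1 +
    if (config$readout == "global") params$r2 * m2 else 0
  grads <- zero_like(params)
  run_shifted <- function(i, ai, delta) {
    ov <- shifted_gate(cc, i, ai, delta)
    st <- run_compiled(prefix[[i]], cc, from = i, override = ov,
                       override_at = i)
    readout_amps(st, cc, params, config$readout)
  }
  net_dangle <- matrix(0, n, 2)
  for (i in seq_along(tape)) {
    refs <- tape[[i]]$refs
    for (ai in seq_along(refs)) {
      r <- refs[[ai]]
      if (is.null(r)) next
      d <- (run_shifted(i, ai, pi / 2) - run_shifted(i, ai, -pi / 2)) / 2
      if (r$param == "net_angle") {
        net_dangle[r$index[1], r$index[2]] <-
          net_dangle[r$index[1], r$index[2]] + r$coef * d
      } else if (r$param == "master_angles" || r$param == "node_angles" ||
                 r$param == "v_angles") {
        grads[[r$param]][r$index[1], r$index[2]] <-
          grads[[r$param]][r$index[1], r$index[2]] + r$coef * d
      } else {  # d_angle
        grads[[r$param]][r$index] <- grads[[r$param]][r$index] + r$coef * d
      }
    }
  }
  grads$r0 <- 1
  grads$r1 <- m1
  if (config$readout == "global") grads$r2 <- m2
  if (!is.null(params$net)) {
    net <- params$net
    method <- config$encoding_method
    # re-uploading replays the same encoding gates, so net_dangle already
    # holds the summed sensitivity per node and output angle
    for (k in seq_len(n)) {
      if (isTRUE(g$atoms$is_master[k])) next
      x <- one_hot(g$atoms[k, , drop = FALSE], method)
      z1 <- drop(net$W1 %*% x + net$b1)
      h <- pmax(z1, 0)
      z2 <- drop(net$W2 %*% h + net$b2)
      sg <- plogis_(z2)
      dz2 <- net_dangle[k, ] * 2 * pi * sg * (1 - sg)
      grads$net$W2 <- grads$net$W2 + dz2 %o% h
      grads$net$b2 <- grads$net$b2 + dz2
      dz1 <- drop(t(net$W2) %*% dz2) * (z1 > 0)
      grads$net$W1 <- grads$net$W1 + dz1 %o% x
      grads$net$b1 <- grads$net$b1 + dz1
    }
  }
  list(pred = pred, grads = grads)
}

#' Gradient of the batch MSE loss
#'
#' Returns the exact gradient of `mean((pred - target)^2)` over the batch
#' with respect to every trainable scalar: parameter-shift (plus analytic
#' network backpropagation) for quantum/hybrid models, central finite
#' differences for the classical baselines.  Agrees with central finite
#' differences on every coordinate.
#'
#' @param spec a [model_spec()].
#' @param params matching parameters.
#' @param graphs list of labelled `molgraph` (the minibatch).
#' @return list with `loss` (scalar) and `grads` (same shape as `params`).
#' @export
loss_gradient <- function(spec, params, graphs) {
  stopifnot(length(graphs) >= 1)
  targets <- vapply(graphs, function(g) g$target_ha, numeric(1))
  if (anyNA(targets)) stop("batch contains unlabelled graphs")
  if (spec$type == "quantum") {
    gvec <- rep(0, length(flatten_params(params)))
    preds <- numeric(length(graphs))
    for (b in seq_along(graphs)) {
      gp <- qgnn_grad_prediction(graphs[[b]], spec$config, params)
      preds[b] <- gp$pred
      gvec <- gvec + 2 * (gp$pred - targets[b]) *
        flatten_params(gp$grads) / length(graphs)
    }
    list(loss = mse_loss(preds, targets),
         grads = unflatten_params(gvec, params))
  } else {
    vec <- flatten_params(params)
    f <- function(v) {
      p <- unflatten_params(v, params)
      preds <- vapply(graphs, function(g) classical_forward(g, spec$config, p),
                      numeric(1))
      mse_loss(preds, targets)
    }
    h <- 1e-6
    gvec <- vapply(seq_along(vec), function(k) {
      vp <- vec; vp[k] <- vp[k] + h
      vm <- vec; vm[k] <- vm[k] - h
      (f(vp) - f(vm)) / (2 * h)
    }, numeric(1))
    preds <- vapply(graphs, function(g)
      classical_forward(g, spec$config, params), numeric(1))
    list(loss = mse_loss(preds, targets),
         grads = unflatten_params(gvec, params))
  }
}

# ---------------------------------------------------------------------------
# Adam

#' Adam optimizer step
#'
#' Standard Adam with bias-corrected first and second moments and
#' `epsilon = 1e-8`.
#'
#' @param vec current flat parameter vector.
#' @param grad_vec gradient vector of the same length.
#' @param state optimizer state from a previous call, or `NULL` to start.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical floor.
#' @return list with updated `vec` and `state`.
#' @export
adam_step <- function(vec, grad_vec, state = NULL, lr = 0.01, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) state <- list(m = rep(0, length(vec)),
                                    v = rep(0, length(vec)), t = 0L)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad_vec
  state$v <- beta2 * state$v + (1 - beta2) * grad_vec^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(vec = vec - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# ---------------------------------------------------------------------------
# Splitting, training loop, evaluation

#' Split a dataset into train/validation/test
#'
#' Disjoint random subsets of the stated sizes, deterministic per seed.
#'
#' @param graphs list of `molgraph`.
#' @param sizes integer vector `c(train, val, test)`; must sum to at most
#'   `length(graphs)`.
#' @param seed RNG seed.
#' @return list with `train`, `val`, `test`.
#' @export
split_dataset <- function(graphs, sizes, seed = 0L) {
  stopifnot(length(sizes) == 3, sum(sizes) <= length(graphs))
  set.seed(as.integer(seed))
  idx <- sample(seq_along(graphs), sum(sizes))
  list(train = graphs[idx[seq_len(sizes[1])]],
       val = graphs[idx[sizes[1] + seq_len(sizes[2])]],
       test = graphs[idx[sizes[1] + sizes[2] + seq_len(sizes[3])]])
}

#' Training protocol configuration
#'
#' Defaults follow the experimental protocol: Adam with learning rate 0.01,
#' `beta1 = 0.9`, `beta2 = 0.999`, batch size 128, 150 epochs with
#' validation every 10 epochs, quantum weights initialized to 1, three
#' restarts for classical models and one for quantum/hybrid models.
#'
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param batch_size minibatch size (the last incomplete batch is used).
#' @param epochs training epochs.
#' @param val_every validate every this many epochs (the final epoch is
#'   always validated).
#' @param seed RNG seed for shuffling and initialization.
#' @param n_restarts independent restarts (best validation loss wins);
#'   `NULL` picks 3 for classical and 1 for quantum models.
#' @return a `training_config` list.
#' @export
training_config <- function(lr = 0.01, beta1 = 0.9, beta2 = 0.999,
                            batch_size = 128L, epochs = 150L,
                            val_every = 10L, seed = 0L, n_restarts = NULL) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 val_every = as.integer(val_every),
                 seed = as.integer(seed), n_restarts = n_restarts),
            class = "training_config")
}

init_params_for <- function(spec, seed) {
  if (spec$type == "quantum") init_qgnn_params(spec$config, seed = seed)
  else init_classical_params(spec$config, seed = seed)
}

batch_loss <- function(spec, params, graphs) {
  preds <- vapply(graphs, function(g) predict_one(spec, params, g),
                  numeric(1))
  mse_loss(preds, vapply(graphs, function(g) g$target_ha, numeric(1)))
}

train_one_run <- function(spec, train_set, val_set, tc, run_seed) {
  params <- init_params_for(spec, seed = run_seed)
  vec <- flatten_params(params)
  state <- NULL
  n <- length(train_set)
  train_curve <- numeric(0)
  val_curve <- numeric(0)
  val_epochs <- integer(0)
  best <- list(val = Inf, params = params)
  if (tc$epochs == 0L) {
    if (length(val_set)) best$val <- batch_loss(spec, params, val_set)
    return(list(params = params, best = best, train_curve = train_curve,
                val_curve = val_curve, val_epochs = val_epochs))
  }
  for (epoch in seq_len(tc$epochs)) {
    set.seed(tc$seed * 10000L + run_seed * 1000L + epoch)
    ord <- sample(n)
    starts <- seq(1L, n, by = tc$batch_size)
    losses <- numeric(0)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + tc$batch_size - 1L, n)]
      lg <- loss_gradient(spec, unflatten_params(vec, params),
                          train_set[idx])
      losses <- c(losses, lg$loss)
      st <- adam_step(vec, flatten_params(lg$grads), state,
                      lr = tc$lr, beta1 = tc$beta1, beta2 = tc$beta2)
      vec <- st$vec
      state <- st$state
    }
    train_curve <- c(train_curve, mean(losses))
    if (length(val_set) &&
        (epoch %% tc$val_every == 0L || epoch == tc$epochs)) {
      p <- unflatten_params(vec, params)
      vl <- batch_loss(spec, p, val_set)
      val_curve <- c(val_curve, vl)
      val_epochs <- c(val_epochs, epoch)
      if (vl < best$val) best <- list(val = vl, params = p)
    }
  }
  if (!length(val_set)) best <- list(val = NA_real_,
                                     params = unflatten_params(vec, params))
  list(params = unflatten_params(vec, params), best = best,
       train_curve = train_curve, val_curve = val_curve,
       val_epochs = val_epochs)
}

#' Train a model
#'
#' Minibatch Adam over `data$train`, validating on `data$val` every
#' `val_every` epochs (and at the final epoch); the weights with the lowest
#' validation loss are selected.  Classical models run `n_restarts`
#' independent restarts (default 3) and keep the overall best-validation
#' weights; quantum/hybrid models run once with all quantum weights at 1.
#'
#' @param spec a [model_spec()].
#' @param data list with `train` and `val` lists of labelled `molgraph`
#'   (as from [split_dataset()]).
#' @param tc a [training_config()].
#' @return a `run_result` list: `train_curve` (mean minibatch loss per
#'   epoch, Hartree^2), `val_curve` and `val_epochs`, `best_params`,
#'   `best_val`, and `metrics` of the selected weights on the validation
#'   set (see [evaluate_model()]).
#' @export
train_model <- function(spec, data, tc = training_config()) {
  if (!length(data$train)) stop("empty training set")
  n_restarts <- tc$n_restarts
  if (is.null(n_restarts))
    n_restarts <- if (spec$type == "classical") 3L else 1L
  runs <- lapply(seq_len(n_restarts), function(r) {
    train_one_run(spec, data$train, data$val, tc,
                  run_seed = tc$seed + r - 1L)
  })
  best_run <- runs[[which.min(vapply(runs, function(r) {
    if (is.na(r$best$val)) Inf else r$best$val
  }, numeric(1)))]]
  best_params <- best_run$best$params
  metrics <- if (length(data$val))
    evaluate_model(spec, best_params, data$val) else NULL
  structure(list(train_curve = best_run$train_curve,
                 val_curve = best_run$val_curve,
                 val_epochs = best_run$val_epochs,
                 best_params = best_params,
                 best_val = best_run$best$val,
                 final_params = best_run$params,
                 metrics = metrics,
                 n_restarts = n_restarts),
            class = "run_result")
}

#' Evaluate a model on labelled molecules
#'
#' @param spec a [model_spec()].
#' @param params parameters for `spec`.
#' @param graphs non-empty list of labelled `molgraph`.
#' @return list with `mse` (Hartree^2), `rmse`, `mae` (Hartree), `n`, and
#'   `mae_aromatic` / `mae_non_aromatic` stratified by the presence of
#'   aromatic bonds (`NA` when a stratum is empty).
#' @export
evaluate_model <- function(spec, params, graphs) {
  if (!length(graphs)) stop("empty evaluation set")
  preds <- vapply(graphs, function(g) predict_one(spec, params, g),
                  numeric(1))
  targets <- vapply(graphs, function(g) g$target_ha, numeric(1))
  if (anyNA(targets)) stop("evaluation set contains unlabelled graphs")
  err <- preds - targets
  arom <- vapply(graphs, function(g) any(g$bonds$type == "aromatic"),
                 logical(1))
  list(mse = mean(err^2), rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       n = length(graphs),
       mae_aromatic = if (any(arom)) mean(abs(err[arom])) else NA_real_,
       mae_non_aromatic = if (any(!arom)) mean(abs(err[!arom])) else NA_real_)
}
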