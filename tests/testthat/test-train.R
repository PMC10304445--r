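# reference Adam, re-implemented from the update equations independently of
# the package's optimizer
reference_adam <- function(vec, grads_list, lr = 0.01, b1 = 0.9, b2 = 0.999,
                           eps = 1e-8) {
  m <- v <- rep(0, length(vec))
  for (t in seq_along(grads_list)) {
    g <- grads_list[[t]]
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    vec <- vec - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
  }
  vec
}

test_that("mse loss matches its definition", {
  x <- c(1, 2, 3)
  expect_equal(mse_loss(x, x), 0)
  expect_equal(mse_loss(x + 0.3, x), 0.09)
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(mse_loss(a, b), sum((a - b)^2) / 50)
  expect_error(mse_loss(1:3, 1:2))
})

test_that("parameter-shift recovers the closed-form derivative of cos", {
  # one carbon qubit under the tetrahedral encoding stays |0>; a single
  # simple node layer rotates it by theta, so the local readout with
  # r0 = 0, r1 = 1 is exactly cos(theta) and its gradient -sin(theta)
  g <- molgraph(data.frame(z = 6L, nh = 4L, aromatic = FALSE, hyb = "sp3"))
  cfg <- model_config(n_layers = 1, edu_variant = "simple",
                      encoding_method = "an")
  spec <- model_spec("quantum", cfg)
  for (theta in c(0.3, 1.1, -0.7)) {
    p <- init_qgnn_params(cfg)
    p <- unflatten_params(rep(0, length(flatten_params(p))), p)
    p$node_angles[1, 1] <- theta
    p$r1 <- 1
    gg <- g; gg$target_ha <- 0
    lg <- loss_gradient(spec, p, list(gg))
    # d/dtheta (cos(theta) - 0)^2 = -2 cos(theta) sin(theta)
    expect_equal(lg$grads$node_angles[1, 1],
                 -2 * cos(theta) * sin(theta), tolerance = 1e-10)
    expect_equal(lg$loss, cos(theta)^2, tolerance = 1e-12)
  }
})

test_that("gradients agree with central finite differences everywhere", {
  g <- Filter(function(g) n_nodes(g) == 4,
              generate_molecules(20, seed = 89, max_atoms = 4))[[1]]
  g$target_ha <- 0.3
  configs <- list(
    model_config(2, "default", "local"),
    model_config(1, "simple", "global"),
    model_config(2, "simple", "local", re_uploading = TRUE),
    model_config(1, "default", "local", master_node = TRUE),
    model_config(1, "default", "local", encoding_method = "net_an_nh"))
  for (cfg in configs) {
    spec <- model_spec("quantum", cfg)
    p <- random_params(cfg, seed = 97)
    lg <- loss_gradient(spec, p, list(g))
    vec <- flatten_params(p)
    h <- 1e-6
    fd <- vapply(seq_along(vec), function(k) {
      vp <- vec; vp[k] <- vp[k] + h
      vm <- vec; vm[k] <- vm[k] - h
      (mse_loss(predict_one(spec, unflatten_params(vp, p), g), 0.3) -
         mse_loss(predict_one(spec, unflatten_params(vm, p), g), 0.3)) /
        (2 * h)
    }, numeric(1))
    err <- mixed_err(flatten_params(lg$grads), fd)
    expect_lt(max(err), 1e-5)
  }
})

test_that("hybrid gradients flow through the angle extraction network", {
  g <- generate_molecules(3, seed = 101)[[2]]
  g$target_ha <- 0.1
  cfg <- model_config(1, "simple", "local",
                      encoding_method = "net_an_arom_hyb",
                      re_uploading = TRUE)
  spec <- model_spec("quantum", cfg)
  p <- random_params(cfg, seed = 103)
  lg <- loss_gradient(spec, p, list(g))
  net_idx <- grep("^net\\.", names(flatten_params(p)))
  expect_gt(max(abs(flatten_params(lg$grads)[net_idx])), 0)
})

test_that("adam_step reproduces a reference implementation", {
  vec <- c(0.5, -1, 2)
  # zero gradient: parameters unchanged
  st <- adam_step(vec, c(0, 0, 0))
  expect_equal(st$vec, vec)
  # first step moves each coordinate by about -lr * sign(g)
  st <- adam_step(vec, c(3, -0.2, 1e-4), lr = 0.01)
  expect_equal(st$vec, vec - 0.01 * sign(c(3, -0.2, 1e-4)), tolerance = 1e-3)
  # ten steps against the independent reference
  set.seed(5)
  grads <- lapply(1:10, function(i) rnorm(3))
  v <- vec; state <- NULL
  for (gd in grads) {
    st <- adam_step(v, gd, state)
    v <- st$vec; state <- st$state
  }
  expect_equal(v, reference_adam(vec, grads), tolerance = 1e-12)
})

test_that("dataset splitting is disjoint, seeded and exhaustive when asked", {
  gs <- generate_molecules(10, seed = 107)
  sp <- split_dataset(gs, c(8, 1, 1), seed = 1)
  ids <- c(vapply(sp$train, `[[`, "", "id"), vapply(sp$val, `[[`, "", "id"),
           vapply(sp$test, `[[`, "", "id"))
  expect_setequal(ids, vapply(gs, `[[`, "", "id"))
  expect_equal(split_dataset(gs, c(8, 1, 1), seed = 1), sp)
  # different seeds give different splits with high probability
  firsts <- vapply(1:100, function(s)
    split_dataset(gs, c(8, 1, 1), seed = s)$train[[1]]$id, "")
  expect_gt(length(unique(firsts)), 1)
  expect_error(split_dataset(gs, c(9, 1, 1)))
})

test_that("training returns initial params for 0 epochs and tracks curves", {
  cfg <- model_config(1, "simple")
  spec <- model_spec("quantum", cfg)
  gs <- teacher_label(generate_molecules(12, seed = 109), cfg,
                      init_qgnn_params(cfg), noise_sd = 0.01, seed = 3)
  sp <- split_dataset(gs, c(8, 4, 0), seed = 2)
  res0 <- train_model(spec, sp, training_config(epochs = 0, seed = 1))
  expect_equal(flatten_params(res0$best_params),
               flatten_params(init_qgnn_params(cfg)))
  res <- train_model(spec, sp, training_config(epochs = 6, val_every = 2,
                                               batch_size = 4, seed = 1))
  expect_length(res$train_curve, 6)
  expect_length(res$val_curve, 3)
  expect_equal(res$val_epochs, c(2L, 4L, 6L))
  expect_equal(res$best_val, min(res$val_curve))
  expect_error(train_model(spec, list(train = list(), val = list()),
                           training_config(epochs = 1)), "empty")
})

test_that("classical training with restarts keeps the best validation run", {
  cfg <- classical_config(c("ggnn", "gcn", "gcn"), "add")
  spec <- model_spec("classical", cfg)
  qcfg <- model_config(1, "simple")
  gs <- teacher_label(generate_molecules(16, seed = 113), qcfg,
                      init_qgnn_params(qcfg), noise_sd = 0.02, seed = 4)
  sp <- split_dataset(gs, c(12, 4, 0), seed = 3)
  res <- train_model(spec, sp, training_config(epochs = 4, val_every = 2,
                                               batch_size = 6, seed = 7,
                                               n_restarts = 2))
  expect_equal(res$n_restarts, 2)
  expect_true(is.finite(res$best_val))
  expect_equal(res$metrics$mse,
               evaluate_model(spec, res$best_params, sp$val)$mse)
})

test_that("evaluation metrics follow their definitions", {
  cfg <- model_config(1, "simple")
  spec <- model_spec("quantum", cfg)
  p <- init_qgnn_params(cfg)
  gs <- teacher_label(generate_molecules(15, seed = 127), cfg, p,
                      noise_sd = 0, seed = 5)
  m <- evaluate_model(spec, p, gs)
  expect_equal(m$mse, 0, tolerance = 1e-20)
  expect_equal(m$mae, 0, tolerance = 1e-10)
  # constant offset c: (c^2, |c|, |c|)
  off <- lapply(gs, function(g) { g$target_ha <- g$target_ha + 0.2; g })
  m2 <- evaluate_model(spec, p, off)
  expect_equal(m2$mse, 0.04, tolerance = 1e-12)
  expect_equal(m2$rmse, 0.2, tolerance = 1e-12)
  expect_equal(m2$mae, 0.2, tolerance = 1e-12)
  expect_equal(m2$rmse, sqrt(m2$mse))
  # stratified MAE covers the whole set
  arom <- vapply(gs, function(g) any(g$bonds$type == "aromatic"), logical(1))
  if (any(arom) && any(!arom)) {
    expect_equal(m2$mae,
                 (sum(arom) * m2$mae_aromatic +
                    sum(!arom) * m2$mae_non_aromatic) / length(gs),
                 tolerance = 1e-12)
  }
})
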