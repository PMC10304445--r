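test_that("edu_matrix satisfies its algebraic identities", {
  set.seed(3)
  SWAP <- matrix(0, 4, 4); SWAP[1, 1] <- SWAP[4, 4] <- 1
  SWAP[2, 3] <- SWAP[3, 2] <- 1
  for (r in 1:5) {
    v <- runif(3, -pi, pi); d <- runif(1, -pi, pi)
    for (variant in c("default", "simple")) {
      va <- if (variant == "default") v else v[1]
      E <- edu_matrix(va, d, variant)
      # unitary
      expect_lt(max(Mod(E %*% Conj(t(E)) - diag(4))), 1e-12)
      # symmetric under swapping its two qubits
      expect_lt(max(Mod(SWAP %*% E %*% SWAP - E)), 1e-12)
      # equals the explicit three-factor product computed independently
      V <- if (variant == "default") u3_matrix(v[1], v[2], v[3])
           else ry_matrix(v[1])
      ref <- kronecker(Conj(t(V)), Conj(t(V))) %*% rzz_matrix(d) %*%
        kronecker(V, V)
      expect_lt(max(Mod(E - ref)), 1e-12)
    }
  }
  # V = identity reduces the EDU to RZZ
  expect_lt(max(Mod(edu_matrix(c(0, 0, 0), 0.8, "default") -
                      rzz_matrix(0.8))), 1e-12)
  # d = 0 makes the EDU the identity
  expect_lt(max(Mod(edu_matrix(0.5, 0, "simple") - diag(4))), 1e-12)
  expect_error(edu_matrix(c(1, 2), 0.1, "default"))
})

test_that("node layer matches closed forms and the dense oracle", {
  g <- fixture_molecule()
  cfg <- model_config(n_layers = 1, edu_variant = "simple")
  p <- init_qgnn_params(cfg)
  # angle 0: state unchanged
  p0 <- p; p0$node_angles[1, 1] <- 0
  s <- random_state(4, seed = 8)
  expect_equal(apply_node_layer(s, g, cfg, p0, 1)$amplitudes, s$amplitudes)
  # default with angles (0, pi, 0) flips every qubit of |0...0>
  cfgd <- model_config(n_layers = 1, edu_variant = "default")
  pd <- init_qgnn_params(cfgd)
  pd$node_angles[1, ] <- c(0, pi, 0)
  s <- apply_node_layer(init_state(4), g, cfgd, pd, 1)
  for (q in 0:3) expect_equal(expval_z(s, q), -1, tolerance = 1e-12)
  # random angles match the dense oracle
  set.seed(9)
  pd$node_angles[1, ] <- runif(3, -pi, pi)
  s0 <- random_state(4, seed = 10)
  s <- apply_node_layer(s0, g, cfgd, pd, 1)
  gates <- lapply(0:3, function(q) gate_spec("U3", q, pd$node_angles[1, ]))
  expect_lt(max(Mod(s$amplitudes - dense_apply(s0$amplitudes, gates, 4))),
            1e-12)
})

test_that("link layer respects within-block commutation and block order", {
  cfg <- model_config(n_layers = 1, edu_variant = "default")
  p <- random_params(cfg, seed = 4)
  # no bonds: state unchanged
  g0 <- molgraph(data.frame(z = 6L, nh = 4L, aromatic = FALSE, hyb = "sp3"))
  s0 <- random_state(1, seed = 2)
  expect_equal(apply_link_layer(s0, g0, cfg, p, 1)$amplitudes, s0$amplitudes)

  # path A-B-C with two single bonds: the two same-type EDUs commute
  atoms <- data.frame(z = rep(6L, 3), nh = 2L, aromatic = FALSE, hyb = "sp3")
  gpath <- molgraph(atoms, data.frame(i = c(0L, 1L), j = c(1L, 2L),
                                      type = "single"))
  s0 <- random_state(3, seed = 3)
  v <- p$v_angles["single", ]; d <- p$d_angle[1]
  fwd <- apply_gates(s0, c(edu_seq(0, 1, v, d, "default"),
                           edu_seq(1, 2, v, d, "default")))
  rev_ <- apply_gates(s0, c(edu_seq(1, 2, v, d, "default"),
                            edu_seq(0, 1, v, d, "default")))
  expect_lt(max(Mod(fwd$amplitudes - rev_$amplitudes)), 1e-10)
  expect_lt(max(Mod(apply_link_layer(s0, gpath, cfg, p, 1)$amplitudes -
                      fwd$amplitudes)), 1e-10)

  # mixed types do NOT commute across blocks: the enforced order matters
  gmix <- molgraph(atoms, data.frame(i = c(0L, 1L), j = c(1L, 2L),
                                     type = c("single", "double")))
  v2 <- p$v_angles["double", ]
  in_order <- apply_gates(s0, c(edu_seq(0, 1, v, d, "default"),
                                edu_seq(1, 2, v2, d, "default")))
  swapped <- apply_gates(s0, c(edu_seq(1, 2, v2, d, "default"),
                               edu_seq(0, 1, v, d, "default")))
  expect_gt(max(Mod(in_order$amplitudes - swapped$amplitudes)), 1e-6)
  expect_lt(max(Mod(apply_link_layer(s0, gmix, cfg, p, 1)$amplitudes -
                      in_order$amplitudes)), 1e-10)
})

test_that("forward pass reproduces trivial closed forms and composition", {
  # single carbon atom, all angles 0, r0 = 0, r1 = 1, tetrahedral encoding
  g <- molgraph(data.frame(z = 6L, nh = 4L, aromatic = FALSE, hyb = "sp3"))
  cfg <- model_config(n_layers = 1, edu_variant = "default",
                      encoding_method = "an")
  p <- init_qgnn_params(cfg)
  p <- unflatten_params(rep(0, length(flatten_params(p))), p)
  p$r1 <- 1
  expect_equal(qgnn_forward(g, cfg, p), 1.0, tolerance = 1e-12)

  # one layer equals manual encode -> node -> link -> readout
  g <- fixture_molecule()
  cfg <- model_config(n_layers = 1, edu_variant = "default",
                      readout = "global", encoding_method = "an_nh")
  p <- random_params(cfg, seed = 6)
  s <- encode(g, encoding_spec("an_nh"))
  s <- apply_node_layer(s, g, cfg, p, 1)
  s <- apply_link_layer(s, g, cfg, p, 1)
  expect_equal(qgnn_forward(g, cfg, p), readout(s, p, "global"),
               tolerance = 1e-12)
})

test_that("forward is invariant under node permutations for all variants", {
  gs <- generate_molecules(8, seed = 13)
  g <- Filter(function(g) n_nodes(g) >= 6, gs)[[1]]
  for (variant in c("default", "simple")) {
    for (ro in c("local", "global")) {
      for (ru in c(FALSE, TRUE)) {
        cfg <- model_config(n_layers = 2, edu_variant = variant,
                            readout = ro, re_uploading = ru)
        p <- random_params(cfg, seed = 17)
        f0 <- qgnn_forward(g, cfg, p)
        set.seed(19)
        for (r in 1:5) {
          perm <- sample(n_nodes(g)) - 1L
          expect_lt(abs(qgnn_forward(permute_graph(g, perm), cfg, p) - f0),
                    1e-9)
        }
      }
    }
  }
  # with a master node: permute the atoms, master stays last
  cfg <- model_config(n_layers = 1, master_node = TRUE)
  p <- random_params(cfg, seed = 23)
  gm <- add_master_node(g)
  f0 <- qgnn_forward(gm, cfg, p)
  set.seed(29)
  for (r in 1:5) {
    perm <- sample(n_nodes(g)) - 1L
    gp <- add_master_node(permute_graph(g, perm))
    expect_lt(abs(qgnn_forward(gp, cfg, p) - f0), 1e-9)
  }
})

test_that("readout identities hold", {
  p <- list(r0 = 0.1, r1 = 0.5, r2 = 0)
  s <- init_state(3)
  expect_equal(readout(s, p, "local"), 0.6, tolerance = 1e-12)
  # global with r2 = 0 equals local on random states
  for (r in 1:20) {
    s <- random_state(3, seed = 200 + r)
    expect_equal(readout(s, p, "global"), readout(s, p, "local"),
                 tolerance = 1e-14)
  }
  # balanced two-qubit product state: only r0 survives
  s <- apply_gates(init_state(2), list(gate_spec("RY", 0, pi / 2),
                                       gate_spec("RY", 1, pi / 2)))
  p2 <- list(r0 = 0.3, r1 = 0.7, r2 = 0.9)
  expect_equal(readout(s, p2, "local"), 0.3, tolerance = 1e-12)
  expect_equal(readout(s, p2, "global"), 0.3, tolerance = 1e-12)
})

test_that("forward output is bounded by the readout coefficients", {
  gs <- generate_molecules(5, seed = 31)
  for (g in gs) {
    cfg <- model_config(n_layers = 2, readout = "global")
    p <- random_params(cfg, seed = 37)
    bound <- abs(p$r0) + abs(p$r1) + abs(p$r2)
    expect_lte(abs(qgnn_forward(g, cfg, p)), bound + 1e-12)
  }
})

test_that("trainable parameter counts enumerate the parameter shapes", {
  expect_equal(count_trainable_parameters(
    model_config(3, "default", "local")), 26)          # 9 + 3 + 12 + 2
  expect_equal(count_trainable_parameters(
    model_config(3, "default", "local", encoding_method = "net_an_nh")),
    76)                                                 # 26 + 50
  expect_equal(count_trainable_parameters(
    model_config(1, "simple", "local")), 8)             # 1 + 1 + 4 + 2
  # counts always match the flattened parameter vector
  for (cfg in list(model_config(2, "simple", "global", master_node = TRUE),
                   model_config(1, "default", "local",
                                encoding_method = "net_an_arom_hyb"),
                   model_config(3, "default", "global", re_uploading = TRUE))) {
    expect_equal(count_trainable_parameters(cfg),
                 length(flatten_params(init_qgnn_params(cfg))))
  }
})

test_that("single-qubit gate-layer counts follow the counting convention", {
  base <- model_config(3, "default", "local")
  reup <- model_config(3, "default", "local", re_uploading = TRUE)
  for (f in 0:4) {
    expect_equal(count_single_qubit_gate_layers(reup, f) -
                   count_single_qubit_gate_layers(base, f), 6)
  }
  expect_equal(count_single_qubit_gate_layers(
    model_config(1, "simple", "local"), 0), 3)   # 2 encoding + 1 node
  # nondecreasing in the number of layers
  for (L in 1:3) {
    expect_lte(count_single_qubit_gate_layers(model_config(L), 3),
               count_single_qubit_gate_layers(model_config(L + 1L), 3))
  }
})

test_that("link-layer schedule is an exact minimum edge coloring", {
  atoms <- function(n) data.frame(z = rep(6L, n), nh = 0L, aromatic = FALSE,
                                  hyb = "sp3")
  single <- molgraph(atoms(2), data.frame(i = 0L, j = 1L, type = "single"))
  expect_length(schedule_link_layer(single), 1)
  path <- molgraph(atoms(3), data.frame(i = c(0L, 1L), j = c(1L, 2L),
                                        type = "single"))
  expect_length(schedule_link_layer(path), 2)
  triangle <- molgraph(atoms(3), data.frame(i = c(0L, 0L, 1L),
                                            j = c(1L, 2L, 2L),
                                            type = "single"))
  expect_length(schedule_link_layer(triangle), 3)

  for (g in generate_molecules(15, seed = 41)) {
    sched <- schedule_link_layer(g)
    # every bond exactly once; no shared endpoint within a round
    seen <- character(0)
    for (r in sched) {
      ends <- c(r$bonds$i, r$bonds$j)
      expect_equal(anyDuplicated(ends), 0)
      seen <- c(seen, paste(r$bonds$i, r$bonds$j, r$type))
    }
    key <- with(g$bonds, paste(pmin(i, j), pmax(i, j), type))
    expect_setequal(seen, key)
    # per-block round counts: equal to the brute-force chromatic index,
    # hence within the Vizing window [Delta, Delta + 1]
    for (type in unique(g$bonds$type)) {
      b <- g$bonds[g$bonds$type == type, ]
      rounds <- sum(vapply(sched, function(r) r$type == type, logical(1)))
      edges <- cbind(b$i, b$j)
      if (nrow(edges) <= 6) {
        expect_equal(rounds, brute_chromatic_index(edges))
      }
      delta <- max(table(c(b$i, b$j)))
      expect_gte(rounds, delta)
      expect_lte(rounds, delta + 1)
    }
  }
})

test_that("executing schedule rounds reproduces the sequential link layer", {
  cfg <- model_config(n_layers = 1, edu_variant = "default")
  gs <- generate_molecules(6, seed = 43)
  for (g in Filter(function(g) nrow(g$bonds) >= 3, gs)) {
    p <- random_params(cfg, seed = 47)
    s0 <- random_state(n_nodes(g), seed = 53)
    seq_state <- apply_link_layer(s0, g, cfg, p, 1)
    st <- s0
    for (r in schedule_link_layer(g)) {
      t_row <- match(r$type, rownames(p$v_angles))
      for (k in seq_len(nrow(r$bonds))) {
        st <- apply_gates(st, edu_seq(r$bonds$i[k], r$bonds$j[k],
                                      p$v_angles[t_row, ], p$d_angle[1],
                                      "default"))
      }
    }
    expect_lt(max(Mod(st$amplitudes - seq_state$amplitudes)), 1e-10)
  }
})

test_that("checkpoints round-trip config and parameters", {
  cfg <- model_config(2, "default", "global", re_uploading = TRUE,
                      master_node = TRUE, encoding_method = "net_an_nh")
  p <- random_params(cfg, seed = 59)
  f <- tmpfile(".json")
  save_checkpoint(cfg, p, f)
  back <- load_checkpoint(f)
  expect_equal(unclass(back$config), unclass(cfg))
  expect_equal(flatten_params(back$params), flatten_params(p),
               tolerance = 1e-12)
  g <- generate_molecules(1, seed = 61)[[1]]
  expect_equal(qgnn_forward(add_master_node(g), back$config, back$params),
               qgnn_forward(add_master_node(g), cfg, p), tolerance = 1e-12)
})
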