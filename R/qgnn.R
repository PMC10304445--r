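# The EDU-QGC model.  A circuit alternates node layers (a shared single-qubit
# unitary on every atom qubit) and link layers (one EDU per bond).  An EDU is
# (V' (x) V') D (V (x) V) with node-local V and diagonal D = RZZ; it commutes
# with swapping its two qubits, so the circuit composed with a permutation-
# invariant readout is invariant under relabelling of the atoms.  EDUs of the
# same bond type share parameters and commute; across bond types a fixed
# application order (single, aromatic, double, triple, master) keeps the
# circuit well-defined.

EDU_VARIANTS <- c("default", "simple")
READOUT_MODES <- c("local", "global")

#' Model configuration for the quantum graph circuit
#'
#' @param n_layers number of EDU-QGC layers (node layer + link layer), >= 1.
#' @param edu_variant `"default"` (V and the node unitary are arbitrary
#'   single-qubit unitaries, ZYZ with 3 angles) or `"simple"` (RY, 1 angle).
#' @param readout `"local"` (affine in the mean single-qubit
#'   \eqn{\langle Z\rangle}) or `"global"` (adds the all-qubit
#'   \eqn{\langle\bigotimes Z\rangle} term).
#' @param re_uploading repeat the encoding after every layer?
#' @param master_node does the model expect master-augmented graphs (extra
#'   qubit with its own node-layer angles and a fifth EDU bond type)?
#' @param encoding_method one of the [encoding_spec()] method names.
#' @return a `model_config` list.
#' @export
model_config <- function(n_layers = 3L, edu_variant = "default",
                         readout = "local", re_uploading = FALSE,
                         master_node = FALSE, encoding_method = "an_nh") {
  stopifnot(n_layers >= 1)
  structure(list(
    n_layers = as.integer(n_layers),
    edu_variant = match.arg(edu_variant, EDU_VARIANTS),
    readout = match.arg(readout, READOUT_MODES),
    re_uploading = isTRUE(re_uploading),
    master_node = isTRUE(master_node),
    encoding_method = match.arg(encoding_method, ENCODING_METHODS)
  ), class = "model_config")
}

n_v_angles <- function(config) if (config$edu_variant == "default") 3L else 1L

bond_slots <- function(config) {
  if (config$master_node) BOND_TYPES else CHEM_BOND_TYPES
}

#' Initialize trainable parameters for a model configuration
#'
#' Quantum weights — node-layer angles, the per-layer RZZ angle, the per-bond
#' EDU angles and the readout coefficients — are all set to 1 by default.
#' When the configuration uses a `net_*` encoding, the angle extraction
#' network is initialized with seeded Glorot-uniform weights (zero biases).
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the network initialization (hybrid models only).
#' @return a `qgnn_params` list with fields `node_angles` (n_layers x 3 or
#'   x 1), `master_angles` (same shape, only if `master_node`), `d_angle`
#'   (length n_layers), `v_angles` (one row per bond type), `r0`, `r1`,
#'   `r2` (global readout only) and `net` (hybrid encodings only).
#' @export
init_qgnn_params <- function(config, seed = 0L) {
  k <- n_v_angles(config)
  L <- config$n_layers
  slots <- bond_slots(config)
  p <- list(
    node_angles = matrix(1, L, k),
    master_angles = if (config$master_node) matrix(1, L, k) else NULL,
    d_angle = rep(1, L),
    v_angles = matrix(1, length(slots), k,
                      dimnames = list(slots, NULL)),
    r0 = 1, r1 = 1,
    r2 = if (config$readout == "global") 1 else NULL,
    net = if (is_net_method(config$encoding_method))
      angle_extraction_net(net_input_dim(config$encoding_method),
                           init = "glorot", seed = seed) else NULL)
  structure(p, class = "qgnn_params")
}

check_params_shape <- function(config, params) {
  k <- n_v_angles(config)
  L <- config$n_layers
  ok <- is.matrix(params$node_angles) &&
    all(dim(params$node_angles) == c(L, k)) &&
    length(params$d_angle) == L &&
    is.matrix(params$v_angles) &&
    all(dim(params$v_angles) == c(length(bond_slots(config)), k)) &&
    is.numeric(params$r0) && is.numeric(params$r1) &&
    (config$readout == "global") == !is.null(params$r2) &&
    config$master_node == !is.null(params$master_angles) &&
    is_net_method(config$encoding_method) == !is.null(params$net)
  if (!ok) stop("parameter shapes do not match the model configuration")
  if (config$master_node && !all(dim(params$master_angles) == c(L, k)))
    stop("parameter shapes do not match the model configuration")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Circuit construction as a tape of gates.  Each tape gate carries, per
# angle, an optional reference to the trainable scalar it came from
# (param name + index + linear coefficient), which drives the
# parameter-shift gradient.

tape_gate <- function(kind, qubits, angles, refs = NULL) {
  if (is.null(refs)) refs <- vector("list", length(angles))
  stopifnot(length(refs) == length(angles))
  g <- gate_spec(kind, qubits, angles)
  g$refs <- refs
  g
}

ref <- function(param, index, coef = 1) list(param = param, index = index,
                                            coef = coef)

node_layer_gates <- function(g, config, params, layer) {
  gates <- list()
  for (k in seq_len(n_nodes(g))) {
    q <- k - 1L
    master <- isTRUE(g$atoms$is_master[k])
    if (master && is.null(params$master_angles))
      stop("graph has a master node but params carry no master_angles")
    nm <- if (master) "master_angles" else "node_angles"
    ang <- params[[nm]][layer, ]
    if (config$edu_variant == "default") {
      gates[[length(gates) + 1L]] <- tape_gate(
        "U3", q, ang,
        list(ref(nm, c(layer, 1L)), ref(nm, c(layer, 2L)),
             ref(nm, c(layer, 3L))))
    } else {
      gates[[length(gates) + 1L]] <- tape_gate("RY", q, ang[1],
                                               list(ref(nm, c(layer, 1L))))
    }
  }
  gates
}

# bonds of one type, ascending (min endpoint, max endpoint) order
bonds_of_type <- function(g, type) {
  b <- g$bonds[g$bonds$type == type, , drop = FALSE]
  if (!nrow(b)) return(b)
  lo <- pmin(b$i, b$j); hi <- pmax(b$i, b$j)
  b <- data.frame(i = lo, j = hi, type = b$type)
  b[order(b$i, b$j), , drop = FALSE]
}

edu_gates <- function(i, j, type_row, d_layer, config, params) {
  v <- params$v_angles[type_row, ]
  tr <- function(col, coef) ref("v_angles", c(type_row, col), coef)
  out <- list()
  if (config$edu_variant == "default") {
    vrefs <- list(tr(1L, 1), tr(2L, 1), tr(3L, 1))
    drefs <- list(tr(3L, -1), tr(2L, -1), tr(1L, -1))
    out <- c(out, list(
      tape_gate("U3", i, v, vrefs),
      tape_gate("U3", j, v, vrefs),
      tape_gate("RZZ", c(i, j), params$d_angle[d_layer],
                list(ref("d_angle", d_layer))),
      tape_gate("U3", i, -rev(v), drefs),
      tape_gate("U3", j, -rev(v), drefs)))
  } else {
    out <- c(out, list(
      tape_gate("RY", i, v[1], list(tr(1L, 1))),
      tape_gate("RY", j, v[1], list(tr(1L, 1))),
      tape_gate("RZZ", c(i, j), params$d_angle[d_layer],
                list(ref("d_angle", d_layer))),
      tape_gate("RY", i, -v[1], list(tr(1L, -1))),
      tape_gate("RY", j, -v[1], list(tr(1L, -1)))))
  }
  out
}

link_layer_gates <- function(g, config, params, layer) {
  gates <- list()
  slots <- bond_slots(config)
  for (t in seq_along(slots)) {
    b <- bonds_of_type(g, slots[t])
    for (r in seq_len(nrow(b))) {
      gates <- c(gates, edu_gates(b$i[r], b$j[r], t, layer, config, params))
    }
  }
  gates
}

build_circuit <- function(g, config, params) {
  spec <- encoding_spec(config$encoding_method, net = params$net)
  enc <- encoding_gates(g, spec)
  gates <- enc
  for (l in seq_len(config$n_layers)) {
    gates <- c(gates, node_layer_gates(g, config, params, l),
               link_layer_gates(g, config, params, l))
    if (config$re_uploading) gates <- c(gates, enc)
  }
  gates
}

# ---------------------------------------------------------------------------
# Compiled circuit representation used by the training hot path: index
# vectors and gate matrices are precomputed once so that replaying the
# circuit (and its parameter-shifted variants) is a tight loop of vector
# operations on the raw amplitude vector.

gate_matrix_of <- function(kind, angles) {
  switch(kind,
         RY = ry_matrix(angles[1]),
         RZ = rz_matrix(angles[1]),
         U3 = u3_matrix(angles[1], angles[2], angles[3]))
}

compile_circuit <- function(g, config, params) {
  tape <- build_circuit(g, config, params)
  n <- n_nodes(g)
  N <- 2^n
  i0s <- lapply(seq_len(n) - 1L, function(q) cached_i0(n, q))
  zsigns <- lapply(seq_len(n) - 1L, function(q) cached_zsign(n, q))
  gates <- lapply(tape, function(gt) {
    if (gt$kind == "RZZ") {
      sgn <- zsigns[[gt$qubits[1] + 1L]] * zsigns[[gt$qubits[2] + 1L]]
      list(zz = TRUE, sgn = sgn, ph = exp(-1i * gt$angles[1] / 2 * sgn))
    } else {
      q <- gt$qubits[1]
      list(zz = FALSE, i0 = i0s[[q + 1L]],
           i1 = i0s[[q + 1L]] + bitwShiftL(1L, n - 1L - q),
           U = gate_matrix_of(gt$kind, gt$angles))
    }
  })
  list(tape = tape, gates = gates, n = n, N = N, zsigns = zsigns)
}

run_compiled <- function(amps, cc, from = 1L, override = NULL,
                         override_at = 0L) {
  gates <- cc$gates
  for (k in from:length(gates)) {
    gt <- if (k == override_at) override else gates[[k]]
    if (gt$zz) {
      amps <- amps * gt$ph
    } else {
      a0 <- amps[gt$i0]; a1 <- amps[gt$i1]
      U <- gt$U
      amps[gt$i0] <- U[1, 1] * a0 + U[1, 2] * a1
      amps[gt$i1] <- U[2, 1] * a0 + U[2, 2] * a1
    }
  }
  amps
}

readout_amps <- function(amps, cc, params, mode) {
  probs <- Re(amps * Conj(amps))
  m1 <- 0
  for (q in seq_len(cc$n)) m1 <- m1 + sum(cc$zsigns[[q]] * probs)
  m1 <- m1 / cc$n
  out <- params$r0 + params$r1 * m1
  if (mode == "global") {
    par <- cc$zsigns[[1]]
    for (q in seq_len(cc$n)[-1]) par <- par * cc$zsigns[[q]]
    out <- out + params$r2 * sum(par * probs)
  }
  out
}

shifted_gate <- function(cc, i, ai, delta) {
  gt <- cc$tape[[i]]
  ang <- gt$angles
  ang[ai] <- ang[ai] + delta
  if (gt$kind == "RZZ") {
    sgn <- cc$gates[[i]]$sgn
    list(zz = TRUE, sgn = sgn, ph = exp(-1i * ang[1] / 2 * sgn))
  } else {
    g0 <- cc$gates[[i]]
    list(zz = FALSE, i0 = g0$i0, i1 = g0$i1,
         U = gate_matrix_of(gt$kind, ang))
  }
}

# ---------------------------------------------------------------------------
# Exposed layer operations

#' The dense 4x4 EDU matrix
#'
#' \eqn{(V^\dagger \otimes V^\dagger)\, RZZ(d)\, (V \otimes V)} with `V`
#' the arbitrary single-qubit ZYZ unitary (default variant, 3 angles) or an
#' RY rotation (simple variant, 1 angle).  Always unitary and symmetric
#' under exchange of its two qubits.
#'
#' @param v_angles numeric vector of length 3 (default) or 1 (simple).
#' @param d_angle RZZ rotation angle.
#' @param variant `"default"` or `"simple"`.
#' @return complex 4x4 matrix.
#' @export
edu_matrix <- function(v_angles, d_angle, variant = "default") {
  variant <- match.arg(variant, EDU_VARIANTS)
  if (variant == "default") {
    stopifnot(length(v_angles) == 3)
    V <- u3_matrix(v_angles[1], v_angles[2], v_angles[3])
  } else {
    stopifnot(length(v_angles) == 1)
    V <- ry_matrix(v_angles[1])
  }
  Vd <- Conj(t(V))
  kronecker(Vd, Vd) %*% rzz_matrix(d_angle) %*% kronecker(V, V)
}

#' Apply one node layer or link layer to a state
#'
#' `apply_node_layer` applies the layer's shared single-qubit unitary to
#' every atom qubit (and the master-specific unitary to the master qubit);
#' `apply_link_layer` applies one EDU per bond, grouped by bond type in the
#' order single, aromatic, double, triple, master.
#'
#' @param s a `statevector` over `n_nodes(g)` qubits.
#' @param g the `molgraph` supplying qubit assignment and bonds.
#' @param config a [model_config()].
#' @param params a `qgnn_params`.
#' @param layer 1-based layer index.
#' @return the updated `statevector`.
#' @export
apply_node_layer <- function(s, g, config, params, layer) {
  apply_gates(s, node_layer_gates(g, config, params, layer))
}

#' @rdname apply_node_layer
#' @export
apply_link_layer <- function(s, g, config, params, layer) {
  apply_gates(s, link_layer_gates(g, config, params, layer))
}

#' Permutation-invariant readout
#'
#' Local readout: \eqn{r_0 + (r_1/|V|) \sum_v \langle Z_v\rangle}; global
#' readout adds \eqn{r_2 \langle\bigotimes_v Z_v\rangle}.  The sums run over
#' all qubits, master included.
#'
#' @param s a `statevector`.
#' @param params a `qgnn_params` (uses `r0`, `r1` and, for global, `r2`).
#' @param mode `"local"` or `"global"`.
#' @return scalar prediction.
#' @export
readout <- function(s, params, mode = "local") {
  mode <- match.arg(mode, READOUT_MODES)
  n <- s$n_qubits
  probs <- Mod(s$amplitudes)^2
  m1 <- mean(vapply(seq_len(n) - 1L,
                    function(q) sum(cached_zsign(n, q) * probs), numeric(1)))
  out <- params$r0 + params$r1 * m1
  if (mode == "global") out <- out + params$r2 * expval_z_all(s)
  out
}

#' Forward pass of the quantum graph model
#'
#' Encodes the molecule, applies `n_layers` blocks of node layer + link
#' layer (re-encoding after each block when re-uploading is on), and reads
#' out the prediction.  A pure function of the graph and parameters, and
#' invariant under any relabelling of the graph's nodes.
#'
#' @param g a `molgraph`; must carry a master node iff
#'   `config$master_node`.
#' @param config a [model_config()].
#' @param params a `qgnn_params` shaped for `config`.
#' @return scalar prediction in Hartree.
#' @export
qgnn_forward <- function(g, config, params) {
  check_params_shape(config, params)
  if (config$master_node != has_master(g))
    stop("graph '", g$id, "' master-node status does not match the config")
  s <- apply_gates(init_state(n_nodes(g)), build_circuit(g, config, params))
  readout(s, params, config$readout)
}

# ---------------------------------------------------------------------------
# Structural accounting

#' Count the trainable parameters of a model configuration
#'
#' Node-layer angles per layer (3 default / 1 simple, doubled when a master
#' node adds its own set), one RZZ angle per layer, EDU angles per bond type
#' (4 chemical types, +1 master type when enabled), the readout coefficients
#' (2 local / 3 global), and the angle extraction network for `net_*`
#' encodings.
#'
#' @param config a [model_config()].
#' @return integer parameter count.
#' @export
count_trainable_parameters <- function(config) {
  k <- n_v_angles(config)
  L <- config$n_layers
  n <- L * k +                                  # node layers
    (if (config$master_node) L * k else 0L) +   # master node unitary
    L +                                         # RZZ angle per layer
    length(bond_slots(config)) * k +            # EDU per bond type
    2L + (config$readout == "global")           # r0, r1 (, r2)
  if (is_net_method(config$encoding_method))
    n <- n + 4L * net_input_dim(config$encoding_method) + 14L
  as.integer(n)
}

#' Count sequential single-qubit gate layers of the circuit
#'
#' Uses a fixed counting convention: each encoding application contributes 2
#' layers (RY then RZ, never merged with neighbouring blocks); a node layer
#' contributes 3 (default, ZYZ) or 1 (simple); each EDU bond-type block
#' contributes twice the single-qubit gate count of `V`; between consecutive
#' EDU blocks the trailing and leading RZ layers (same rotation axis) merge
#' into one.
#'
#' @param config a [model_config()].
#' @param n_bond_types_present number of distinct bond types `f` occurring in
#'   the input graphs (0--5).
#' @return integer layer count.
#' @export
count_single_qubit_gate_layers <- function(config, n_bond_types_present) {
  f <- as.integer(n_bond_types_present)
  stopifnot(f >= 0)
  enc_apps <- 1L + if (config$re_uploading) config$n_layers else 0L
  node <- if (config$edu_variant == "default") 3L else 1L
  link <- if (f == 0L) 0L
          else if (config$edu_variant == "default") 6L * f - (f - 1L)
          else 2L * f
  as.integer(2L * enc_apps + config$n_layers * (node + link))
}

# ---------------------------------------------------------------------------
# Link-layer scheduling (parallel EDU rounds via exact edge coloring)

# exact minimum proper edge coloring of the edge list (2-column matrix),
# by backtracking over k = Delta, Delta+1, ... (Vizing guarantees Delta+1)
min_edge_coloring <- function(edges) {
  m <- nrow(edges)
  if (m == 0L) return(integer())
  deg <- table(c(edges[, 1], edges[, 2]))
  delta <- max(deg)
  for (k in delta:(delta + 1L)) {
    col <- rep(NA_integer_, m)
    assign_edge <- function(e) {
      if (e > m) return(TRUE)
      for (c in seq_len(k)) {
        clash <- any(!is.na(col[seq_len(e - 1L)]) &
                       col[seq_len(e - 1L)] == c &
                       (edges[seq_len(e - 1L), 1] %in% edges[e, ] |
                          edges[seq_len(e - 1L), 2] %in% edges[e, ]))
        if (!clash) {
          col[e] <<- c
          if (assign_edge(e + 1L)) return(TRUE)
          col[e] <<- NA_integer_
        }
      }
      FALSE
    }
    if (assign_edge(1L)) return(col)
  }
  stop("edge coloring failed")  # unreachable by Vizing's theorem
}

#' Schedule a link layer into parallel EDU rounds
#'
#' Within each bond-type block (in the enforced order single, aromatic,
#' double, triple, master) the bonds are partitioned into a minimum number
#' of rounds such that no two bonds in a round share an endpoint — an exact
#' minimum edge coloring, so the number of rounds per block is the block's
#' chromatic index (between \eqn{\Delta} and \eqn{\Delta + 1}).
#' Rounds of different blocks never interleave; same-type EDUs share
#' parameters and commute, so executing rounds in order reproduces the
#' sequential link layer exactly.
#'
#' @param g a `molgraph`.
#' @return list of rounds; each round is a list with `type` (bond type) and
#'   `bonds` (data.frame of `i`, `j`).  Every bond of `g` appears in exactly
#'   one round.
#' @export
schedule_link_layer <- function(g) {
  rounds <- list()
  for (type in BOND_TYPES) {
    b <- bonds_of_type(g, type)
    if (!nrow(b)) next
    col <- min_edge_coloring(cbind(b$i, b$j))
    for (c in sort(unique(col))) {
      rounds[[length(rounds) + 1L]] <-
        list(type = type, bonds = b[col == c, c("i", "j"), drop = FALSE])
    }
  }
  rounds
}

# ---------------------------------------------------------------------------
# Checkpoints: flat key -> array JSON with the config embedded

#' Save / load a model checkpoint
#'
#' Checkpoints are plain JSON: the configuration under `"config"` and every
#' parameter array flattened (column-major, with dimensions recorded) under
#' `"params"`.  Works for quantum/hybrid (`model_config`) and classical
#' (`classical_config`) models.
#'
#' @param config the model configuration.
#' @param params the parameter list.
#' @param path file path.
#' @return `save_checkpoint`: `path` invisibly. `load_checkpoint`: list with
#'   `config` and `params`.
#' @export
save_checkpoint <- function(config, params, path) {
  flat <- lapply(params, function(p) {
    if (inherits(p, "angle_extraction_net")) {
      lapply(unclass(p), as_flat_array)
    } else if (is.null(p)) NULL else as_flat_array(p)
  })
  flat <- flat[!vapply(flat, is.null, logical(1))]
  doc <- list(kind = if (inherits(config, "model_config")) "quantum"
                     else "classical",
              config = unclass(config), params = flat)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

as_flat_array <- function(p) {
  list(dim = if (is.matrix(p)) dim(p) else length(p),
       data = as.numeric(p),
       rows = if (is.matrix(p)) rownames(p) else NULL)
}

from_flat_array <- function(f) {
  if (length(f$dim) == 2L) {
    m <- matrix(unlist(f$data), unlist(f$dim)[1], unlist(f$dim)[2])
    if (!is.null(f$rows)) rownames(m) <- unlist(f$rows)
    m
  } else {
    v <- unlist(f$data)
    if (length(v) == 1L) v else v
  }
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cfg <- doc$config
  if (doc$kind == "quantum") {
    config <- model_config(cfg$n_layers, cfg$edu_variant, cfg$readout,
                           cfg$re_uploading, cfg$master_node,
                           cfg$encoding_method)
    params <- list(
      node_angles = from_flat_array(doc$params$node_angles),
      master_angles = if (!is.null(doc$params$master_angles))
        from_flat_array(doc$params$master_angles) else NULL,
      d_angle = from_flat_array(doc$params$d_angle),
      v_angles = from_flat_array(doc$params$v_angles),
      r0 = from_flat_array(doc$params$r0),
      r1 = from_flat_array(doc$params$r1),
      r2 = if (!is.null(doc$params$r2)) from_flat_array(doc$params$r2)
           else NULL,
      net = if (!is.null(doc$params$net))
        structure(lapply(doc$params$net, from_flat_array),
                  class = "angle_extraction_net") else NULL)
    params <- structure(params, class = "qgnn_params")
  } else {
    config <- classical_config(unlist(cfg$layer_sequence), cfg$aggregation,
                               cfg$encoding_method)
    params <- classical_params_from_flat(doc$params)
  }
  list(config = config, params = params)
}
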