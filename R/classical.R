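# Matched classical message-passing baselines.  Node features are the same
# two encoding angles the quantum model consumes (feature dimension 2),
# three message-passing layers chosen from a gated-graph-network style
# convolution (with an edge network producing a 2x2 matrix per bond type)
# and a GCN layer, then a mean readout with a scalar head.

CLASSICAL_LAYERS <- c("ggnn", "gcn")
# bond-order weights entering the GCN adjacency
GCN_BOND_WEIGHT <- c(single = 1, aromatic = 1.5, double = 2, triple = 3)

#' Classical baseline configuration
#'
#' @param layer_sequence character vector of length 3 over `"ggnn"` /
#'   `"gcn"`, e.g. `c("ggnn","ggnn","gcn")`.
#' @param aggregation neighbourhood aggregation for the GGNN layers:
#'   `"add"`, `"mean"` or `"max"`.
#' @param encoding_method fixed encoding scheme supplying the initial
#'   2-dimensional node features (same information as the quantum model).
#' @return a `classical_config` list.
#' @export
classical_config <- function(layer_sequence = c("ggnn", "ggnn", "ggnn"),
                             aggregation = "mean",
                             encoding_method = "an_nh") {
  layer_sequence <- match.arg(layer_sequence, CLASSICAL_LAYERS,
                              several.ok = TRUE)
  if (length(layer_sequence) != 3L)
    stop("layer_sequence must have length 3")
  encoding_method <- match.arg(encoding_method,
                               c("an", "an_nh", "an_arom_hyb"))
  structure(list(layer_sequence = layer_sequence,
                 aggregation = match.arg(aggregation, c("add", "mean", "max")),
                 encoding_method = encoding_method),
            class = "classical_config")
}

#' Initialize classical baseline parameters
#'
#' Glorot-uniform weights, zero biases, seeded.  Parameters are stored as a
#' flat named list: per layer `L<k>_Phi`, `L<k>_Ew1`, `L<k>_Eb1`,
#' `L<k>_Ew2`, `L<k>_Eb2` (GGNN) or `L<k>_W` (GCN), plus `head_w` and
#' `head_b` for the scalar head applied to the mean node feature.
#'
#' @param config a [classical_config()].
#' @param seed RNG seed.
#' @return a `classical_params` named list of numeric arrays.
#' @export
init_classical_params <- function(config, seed = 0L) {
  set.seed(as.integer(seed))
  glorot <- function(nout, nin) {
    a <- sqrt(6 / (nin + nout))
    matrix(runif(nout * nin, -a, a), nout, nin)
  }
  p <- list()
  for (l in seq_along(config$layer_sequence)) {
    if (config$layer_sequence[l] == "ggnn") {
      p[[paste0("L", l, "_Phi")]] <- glorot(2L, 2L)
      p[[paste0("L", l, "_Ew1")]] <- glorot(2L, 4L)
      p[[paste0("L", l, "_Eb1")]] <- numeric(2)
      p[[paste0("L", l, "_Ew2")]] <- glorot(4L, 2L)
      p[[paste0("L", l, "_Eb2")]] <- numeric(4)
    } else {
      p[[paste0("L", l, "_W")]] <- glorot(2L, 2L)
    }
  }
  p$head_w <- drop(glorot(1L, 2L))
  p$head_b <- 0
  structure(p, class = "classical_params")
}

classical_params_from_flat <- function(flat) {
  structure(lapply(flat, from_flat_array), class = "classical_params")
}

#' Edge network: bond type to a 2x2 message matrix
#'
#' One-hot bond type (4 chemical types) through a hidden layer of dimension
#' 2 with ReLU, then a linear output of dimension 4 reshaped row-major to a
#' 2x2 matrix.
#'
#' @param bond_type one of `"single"`, `"aromatic"`, `"double"`, `"triple"`.
#' @param Ew1,Eb1,Ew2,Eb2 edge-network weights (2x4, 2, 4x2, 4).
#' @return numeric 2x2 matrix.
#' @export
edge_network <- function(bond_type, Ew1, Eb1, Ew2, Eb2) {
  k <- match(bond_type, CHEM_BOND_TYPES)
  if (is.na(k)) stop("classical models do not process '", bond_type, "' bonds")
  x <- as.numeric(seq_len(4L) == k)
  h <- pmax(drop(Ew1 %*% x + Eb1), 0)
  matrix(drop(Ew2 %*% h + Eb2), 2, 2, byrow = TRUE)
}

no_master <- function(g) {
  if (has_master(g))
    stop("classical models expect graphs without a master node")
  invisible(g)
}

neighbors_of <- function(g) {
  n <- n_nodes(g)
  nb <- lapply(seq_len(n), function(k) list())
  for (r in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[r]; j <- g$bonds$j[r]; t <- g$bonds$type[r]
    nb[[i + 1L]][[length(nb[[i + 1L]]) + 1L]] <- list(j = j, type = t)
    nb[[j + 1L]][[length(nb[[j + 1L]]) + 1L]] <- list(j = i, type = t)
  }
  nb
}

#' GGNN-style convolution layer
#'
#' Updates every node feature as
#' \eqn{x_i' = \Phi x_i + \mathrm{aggr}_{j \in N(i)} NN(e_{ij})\, x_j},
#' where `NN` is the [edge_network()].  The aggregation over an empty
#' neighbourhood is the zero vector for all aggregation modes.
#'
#' @param x numeric `|V| x 2` node-feature matrix.
#' @param g a `molgraph` without master node.
#' @param Phi 2x2 self-connection matrix.
#' @param Ew1,Eb1,Ew2,Eb2 edge-network weights.
#' @param aggr `"add"`, `"mean"` or `"max"` (componentwise).
#' @return updated `|V| x 2` matrix.
#' @export
ggnn_layer <- function(x, g, Phi, Ew1, Eb1, Ew2, Eb2, aggr = "add") {
  no_master(g)
  aggr <- match.arg(aggr, c("add", "mean", "max"))
  nb <- neighbors_of(g)
  n <- nrow(x)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    msgs <- lapply(nb[[i]], function(e) {
      drop(edge_network(e$type, Ew1, Eb1, Ew2, Eb2) %*% x[e$j + 1L, ])
    })
    agg <- if (!length(msgs)) c(0, 0) else {
      M <- do.call(rbind, msgs)
      switch(aggr, add = colSums(M), mean = colMeans(M),
             max = apply(M, 2, max))
    }
    out[i, ] <- drop(Phi %*% x[i, ]) + agg
  }
  out
}

#' GCN convolution layer
#'
#' \eqn{x' = \mathrm{ReLU}(\tilde D^{-1/2} (A + I) \tilde D^{-1/2}\, x\,
#' W^\top)}, where the adjacency entries carry the bond order (single 1,
#' aromatic 1.5, double 2, triple 3) and \eqn{\tilde D} is the diagonal of
#' row sums of \eqn{A + I}.
#'
#' @param x numeric `|V| x 2` node-feature matrix.
#' @param g a `molgraph` without master node.
#' @param W 2x2 weight matrix.
#' @return updated `|V| x 2` matrix.
#' @export
gcn_layer <- function(x, g, W) {
  no_master(g)
  n <- nrow(x)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(g$bonds))) {
    w <- GCN_BOND_WEIGHT[[g$bonds$type[r]]]
    A[g$bonds$i[r] + 1L, g$bonds$j[r] + 1L] <- w
    A[g$bonds$j[r] + 1L, g$bonds$i[r] + 1L] <- w
  }
  Ahat <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(Ahat))
  P <- (dinv %o% dinv) * Ahat
  pmax(P %*% x %*% t(W), 0)
}

#' Forward pass of a classical baseline
#'
#' Initial node features are the two fixed-encoding angles of
#' `config$encoding_method`; the three configured layers are applied in
#' order; the readout is the mean over nodes followed by the scalar head
#' `head_w . mean + head_b`.
#'
#' @param g a `molgraph` without master node.
#' @param config a [classical_config()].
#' @param params a `classical_params`.
#' @return scalar prediction in Hartree.
#' @export
classical_forward <- function(g, config, params) {
  no_master(g)
  x <- t(vapply(seq_len(n_nodes(g)), function(k) {
    fixed_angles(g$atoms[k, , drop = FALSE], config$encoding_method)
  }, numeric(2)))
  for (l in seq_along(config$layer_sequence)) {
    if (config$layer_sequence[l] == "ggnn") {
      x <- ggnn_layer(x, g,
                      params[[paste0("L", l, "_Phi")]],
                      params[[paste0("L", l, "_Ew1")]],
                      params[[paste0("L", l, "_Eb1")]],
                      params[[paste0("L", l, "_Ew2")]],
                      params[[paste0("L", l, "_Eb2")]],
                      aggr = config$aggregation)
    } else {
      x <- gcn_layer(x, g, params[[paste0("L", l, "_W")]])
    }
  }
  sum(params$head_w * colMeans(x)) + params$head_b
}
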