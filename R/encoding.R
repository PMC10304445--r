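# Atom-feature -> rotation-angle encodings.  Every node gets one qubit,
# prepared from |0> by RY(theta_ry) then RZ(theta_rz).  Three fixed schemes
# map the discrete features directly to angles; two hybrid schemes obtain
# the angles from a small trainable network on one-hot features.

ENCODING_METHODS <- c("an", "an_nh", "an_arom_hyb", "net_an_nh",
                      "net_an_arom_hyb")

#' Encoding specification
#'
#' Selects how atom features become the two encoding angles.  Fixed schemes:
#' * `"an"` — atomic number only; the four elements are placed at the
#'   vertices of a tetrahedron inscribed in the Bloch sphere (the four
#'   single-qubit states furthest from each other).
#' * `"an_nh"` — atomic number on RY, hydrogen count on RZ, each evenly
#'   spaced: \eqn{\theta_{RY} = (2z-7)\pi/4}, \eqn{\theta_{RZ} = 2\pi n_h/5}.
#' * `"an_arom_hyb"` — atomic number on RY as above; aromaticity `a` and
#'   hybridization `h` (sp:1, sp2:2, sp3:3) jointly on RZ as
#'   \eqn{(-1)^a (2h-1)\pi/6}.
#'
#' Hybrid schemes `"net_an_nh"` and `"net_an_arom_hyb"` feed the one-hot
#' features through an [angle_extraction_net()].
#'
#' @param method one of `"an"`, `"an_nh"`, `"an_arom_hyb"`, `"net_an_nh"`,
#'   `"net_an_arom_hyb"`.
#' @param net an `angle_extraction_net`, required for (and only allowed
#'   with) the `net_*` methods.
#' @return an `encoding_spec` list.
#' @export
encoding_spec <- function(method = "an_nh", net = NULL) {
  method <- match.arg(method, ENCODING_METHODS)
  if (is_net_method(method)) {
    if (is.null(net)) stop("method '", method, "' requires an angle extraction net")
    d <- net_input_dim(method)
    if (ncol(net$W1) != d)
      stop("net input_dim ", ncol(net$W1), " does not match method '", method,
           "' (needs ", d, ")")
  } else if (!is.null(net)) {
    stop("fixed encoding '", method, "' must not carry a net")
  }
  structure(list(method = method, net = net), class = "encoding_spec")
}

is_net_method <- function(method) startsWith(method, "net_")

net_input_dim <- function(method) {
  switch(method, net_an_nh = 9L, net_an_arom_hyb = 8L,
         stop("not a net encoding: ", method))
}

# tetrahedral polar angle: the four Bloch vectors pairwise at dot product -1/3
TETRA_POLAR <- acos(-1 / 3)

#' Fixed encoding angles for one atom
#'
#' @param atom one row of a `molgraph`'s `atoms` table (a non-master atom).
#' @param method a fixed encoding method name.
#' @return numeric `c(theta_ry, theta_rz)` in radians; `theta_ry` acts as the
#'   Bloch polar angle and `theta_rz` as the azimuth of the prepared state.
#' @export
fixed_angles <- function(atom, method) {
  method <- match.arg(method, c("an", "an_nh", "an_arom_hyb"))
  if (isTRUE(atom$is_master)) stop("master node has no feature encoding")
  z <- as.integer(atom$z)
  switch(method,
    an = {
      k <- match(z, ELEMENTS)           # 1..4 for C,N,O,F
      ry <- c(0, TETRA_POLAR, TETRA_POLAR, TETRA_POLAR)[k]
      rz <- c(0, 0, 2 * pi / 3, -2 * pi / 3)[k]
      c(ry, rz)
    },
    an_nh = c((2 * z - 7) * pi / 4, 2 * pi * atom$nh / 5),
    an_arom_hyb = {
      h <- match(atom$hyb, HYBRIDIZATIONS)  # sp:1, sp2:2, sp3:3
      a <- as.integer(isTRUE(atom$aromatic))
      c((2 * z - 7) * pi / 4, (-1)^a * (2 * h - 1) * pi / 6)
    })
}

#' One-hot feature vector for the hybrid encodings
#'
#' `net_an_nh`: one-hot atomic number over C/N/O/F followed by one-hot
#' hydrogen count over 0..4 (length 9).  `net_an_arom_hyb`: one-hot atomic
#' number, a single 0/1 aromaticity entry, then one-hot hybridization over
#' sp/sp2/sp3 (length 8).
#'
#' @param atom one row of a `molgraph`'s `atoms` table (non-master).
#' @param method `"net_an_nh"` or `"net_an_arom_hyb"`.
#' @return numeric 0/1 vector.
#' @export
one_hot <- function(atom, method) {
  method <- match.arg(method, c("net_an_nh", "net_an_arom_hyb"))
  if (isTRUE(atom$is_master)) stop("master node has no feature encoding")
  z_oh <- as.numeric(ELEMENTS == as.integer(atom$z))
  if (method == "net_an_nh") {
    nh_oh <- as.numeric(0:4 == as.integer(atom$nh))
    c(z_oh, nh_oh)
  } else {
    hyb_oh <- as.numeric(HYBRIDIZATIONS == atom$hyb)
    c(z_oh, as.numeric(isTRUE(atom$aromatic)), hyb_oh)
  }
}

#' Create an angle extraction network
#'
#' A fully connected network with one hidden layer of dimension 4 (ReLU) and
#' an output layer of dimension 2 squashed by \eqn{2\pi \cdot
#' \mathrm{sigmoid}}, so both output angles lie in \eqn{(0, 2\pi)}.  The
#' first output drives the encoding RY gate, the second the RZ gate.  The
#' same network is shared across all nodes of a graph.
#'
#' @param input_dim length of the one-hot feature vector (9 or 8).
#' @param init `"glorot"` for seeded uniform Glorot initialization or
#'   `"zero"`.
#' @param seed RNG seed for `"glorot"`.
#' @return an `angle_extraction_net`: list of `W1` (4 x input_dim), `b1`
#'   (4), `W2` (2 x 4), `b2` (2).
#' @export
angle_extraction_net <- function(input_dim, init = c("glorot", "zero"),
                                 seed = 0L) {
  init <- match.arg(init)
  d <- as.integer(input_dim)
  if (init == "zero") {
    net <- list(W1 = matrix(0, 4, d), b1 = numeric(4),
                W2 = matrix(0, 2, 4), b2 = numeric(2))
  } else {
    set.seed(as.integer(seed))
    glorot <- function(nout, nin) {
      a <- sqrt(6 / (nin + nout))
      matrix(runif(nout * nin, -a, a), nout, nin)
    }
    net <- list(W1 = glorot(4L, d), b1 = numeric(4),
                W2 = glorot(2L, 4L), b2 = numeric(2))
  }
  structure(net, class = "angle_extraction_net")
}

#' Forward pass of the angle extraction network
#'
#' @param net an [angle_extraction_net()].
#' @param atom one row of the `atoms` table (non-master), or a precomputed
#'   one-hot vector via `x`.
#' @param method the `net_*` method naming the one-hot layout.
#' @param x optional raw input vector overriding `atom`/`method`.
#' @return numeric `c(theta_ry, theta_rz)`, each in \eqn{(0, 2\pi)}.
#' @export
extract_angles <- function(net, atom = NULL, method = NULL, x = NULL) {
  if (is.null(x)) x <- one_hot(atom, method)
  if (length(x) != ncol(net$W1))
    stop("input length ", length(x), " does not match net input_dim ",
         ncol(net$W1))
  h <- pmax(drop(net$W1 %*% x + net$b1), 0)
  z2 <- drop(net$W2 %*% h + net$b2)
  2 * pi * plogis_(z2)
}

plogis_ <- function(x) 1 / (1 + exp(-x))

#' Count the trainable parameters of an angle extraction network
#'
#' All weight and bias entries: `4 * input_dim + 4 + 8 + 2`.
#'
#' @param net an [angle_extraction_net()].
#' @return integer.
#' @export
count_net_parameters <- function(net) {
  length(net$W1) + length(net$b1) + length(net$W2) + length(net$b2)
}

#' Encoding angles for every node of a graph
#'
#' @param g a `molgraph`.
#' @param spec an [encoding_spec()].
#' @return matrix `n_nodes x 2` of `(theta_ry, theta_rz)`; the master row, if
#'   any, is `c(pi/2, NA)` — the master qubit is prepared in the fixed
#'   \eqn{|+\rangle} state by a single RY(\eqn{\pi/2}) and gets no RZ.
#' @export
encoding_angles <- function(g, spec) {
  n <- n_nodes(g)
  out <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    atom <- g$atoms[k, , drop = FALSE]
    if (isTRUE(atom$is_master)) {
      out[k, ] <- c(pi / 2, NA_real_)
    } else if (is_net_method(spec$method)) {
      out[k, ] <- extract_angles(spec$net, atom, spec$method)
    } else {
      out[k, ] <- fixed_angles(atom, spec$method)
    }
  }
  out
}

#' Prepare the encoded register state of a molecular graph
#'
#' Starts from \eqn{|0\ldots0\rangle} on one qubit per node and applies, for
#' every non-master node, RY(\eqn{\theta_{RY}}) followed by
#' RZ(\eqn{\theta_{RZ}}) on its qubit; the master qubit (if present) is set
#' to \eqn{|+\rangle} with RY(\eqn{\pi/2}).
#'
#' @param g a `molgraph`.
#' @param spec an [encoding_spec()].
#' @return a `statevector` over `n_nodes(g)` qubits.
#' @export
encode <- function(g, spec) {
  apply_gates(init_state(n_nodes(g)), encoding_gates(g, spec))
}

# gate list of one encoding application (used by the circuit builder; the
# pref field ties net-generated angles to their node for backpropagation)
encoding_gates <- function(g, spec) {
  ang <- encoding_angles(g, spec)
  gates <- list()
  for (k in seq_len(n_nodes(g))) {
    q <- k - 1L
    if (isTRUE(g$atoms$is_master[k])) {
      gates[[length(gates) + 1L]] <- tape_gate("RY", q, pi / 2)
    } else {
      refs <- if (is_net_method(spec$method)) list(
        list(param = "net_angle", index = c(k, 1L), coef = 1),
        list(param = "net_angle", index = c(k, 2L), coef = 1)) else list(NULL, NULL)
      gates[[length(gates) + 1L]] <- tape_gate("RY", q, ang[k, 1], refs[1])
      gates[[length(gates) + 1L]] <- tape_gate("RZ", q, ang[k, 2], refs[2])
    }
  }
  gates
}
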