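# Dense statevector simulator for the gate set used by the circuit models:
# RY, RZ, RZZ and the ZYZ-decomposed arbitrary single-qubit unitary U3.
# Rotation gates follow the convention exp(-i * theta * P / 2) for Pauli
# word P.  Qubit 0 is the MOST significant bit of the basis index.

#' Initialize the all-zero computational basis state
#'
#' @param n_qubits number of qubits, between 1 and 12 (dense simulation).
#' @return a `statevector`: list with `n_qubits` and complex `amplitudes` of
#'   length `2^n_qubits`, currently \eqn{|0...0\rangle}.
#' @export
init_state <- function(n_qubits) {
  if (n_qubits < 1 || n_qubits > 12) stop("n_qubits must be in 1..12")
  amps <- complex(2^n_qubits)
  amps[1] <- 1 + 0i
  structure(list(n_qubits = as.integer(n_qubits), amplitudes = amps),
            class = "statevector")
}

#' @export
print.statevector <- function(x, ...) {
  cat(sprintf("<statevector on %d qubits>\n", x$n_qubits))
  invisible(x)
}

#' Dense 2x2 rotation matrices
#'
#' `ry_matrix`/`rz_matrix` return the single-qubit rotations
#' \eqn{\exp(-i\theta Y/2)} and \eqn{\exp(-i\theta Z/2)}; `u3_matrix(a,b,c)`
#' is the ZYZ product `RZ(a) %*% RY(b) %*% RZ(c)` (rightmost factor acts
#' first), an arbitrary single-qubit unitary up to global phase.
#'
#' @param theta,a,b,c rotation angles in radians.
#' @return complex 2x2 matrix.
#' @export
ry_matrix <- function(theta) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  matrix(c(c2, s2, -s2, c2), 2, 2) + 0i
}

#' @rdname ry_matrix
#' @export
rz_matrix <- function(theta) {
  diag(c(exp(-1i * theta / 2), exp(1i * theta / 2)))
}

#' @rdname ry_matrix
#' @export
u3_matrix <- function(a, b, c) {
  rz_matrix(a) %*% ry_matrix(b) %*% rz_matrix(c)
}

#' Dense RZZ matrix
#'
#' Two-qubit diagonal rotation \eqn{\exp(-i\theta Z\otimes Z/2)}; symmetric
#' under exchange of its qubits, which is what makes it a valid diagonal
#' unitary for undirected links.
#'
#' @param theta rotation angle in radians.
#' @return complex 4x4 diagonal matrix.
#' @export
rzz_matrix <- function(theta) {
  ph <- exp(-1i * theta / 2 * c(1, -1, -1, 1))
  diag(ph)
}

#' A gate application instruction
#'
#' @param kind one of `"RY"`, `"RZ"`, `"RZZ"`, `"U3"`.
#' @param qubits 0-based qubit index (one for RY/RZ/U3, two distinct for RZZ).
#' @param angles one angle (RY/RZ/RZZ) or three (U3, ZYZ order).
#' @return a `gate_spec` list.
#' @export
gate_spec <- function(kind, qubits, angles) {
  kind <- match.arg(kind, c("RY", "RZ", "RZZ", "U3"))
  n_ang <- if (kind == "U3") 3L else 1L
  n_q <- if (kind == "RZZ") 2L else 1L
  stopifnot(length(angles) == n_ang, length(qubits) == n_q)
  if (kind == "RZZ" && qubits[1] == qubits[2])
    stop("RZZ qubits must be distinct")
  list(kind = kind, qubits = as.integer(qubits), angles = as.numeric(angles))
}

bit_mask <- function(n_qubits, qubit) {
  bitwShiftL(1L, n_qubits - 1L - as.integer(qubit))
}

# index sets recur constantly during training; memoise them per
# (n_qubits, qubit) combination
.mask_cache <- new.env(parent = emptyenv())

cached_i0 <- function(n_qubits, qubit) {
  key <- paste0("i0.", n_qubits, ".", qubit)
  v <- .mask_cache[[key]]
  if (is.null(v)) {
    m <- bit_mask(n_qubits, qubit)
    v <- which(bitwAnd(0:(2^n_qubits - 1L), m) == 0L)
    .mask_cache[[key]] <- v
  }
  v
}

cached_zsign <- function(n_qubits, qubit) {
  key <- paste0("zs.", n_qubits, ".", qubit)
  v <- .mask_cache[[key]]
  if (is.null(v)) {
    m <- bit_mask(n_qubits, qubit)
    v <- ifelse(bitwAnd(0:(2^n_qubits - 1L), m) == 0L, 1, -1)
    .mask_cache[[key]] <- v
  }
  v
}

cached_zzsign <- function(n_qubits, q1, q2) {
  key <- paste0("zz.", n_qubits, ".", q1, ".", q2)
  v <- .mask_cache[[key]]
  if (is.null(v)) {
    v <- cached_zsign(n_qubits, q1) * cached_zsign(n_qubits, q2)
    .mask_cache[[key]] <- v
  }
  v
}

apply_1q_matrix <- function(s, U, qubit) {
  if (qubit < 0 || qubit >= s$n_qubits) stop("qubit index out of range")
  m <- bit_mask(s$n_qubits, qubit)
  i0 <- cached_i0(s$n_qubits, qubit)
  i1 <- i0 + m
  a0 <- s$amplitudes[i0]; a1 <- s$amplitudes[i1]
  s$amplitudes[i0] <- U[1, 1] * a0 + U[1, 2] * a1
  s$amplitudes[i1] <- U[2, 1] * a0 + U[2, 2] * a1
  s
}

#' Apply a gate to a statevector
#'
#' @param s a `statevector`.
#' @param g a [gate_spec()].
#' @return the updated `statevector` (norm preserved to machine precision).
#' @export
apply_gate <- function(s, g) {
  switch(g$kind,
    RY = apply_1q_matrix(s, ry_matrix(g$angles[1]), g$qubits[1]),
    RZ = apply_1q_matrix(s, rz_matrix(g$angles[1]), g$qubits[1]),
    U3 = apply_1q_matrix(s, u3_matrix(g$angles[1], g$angles[2], g$angles[3]),
                         g$qubits[1]),
    RZZ = {
      q <- g$qubits
      if (any(q < 0 | q >= s$n_qubits)) stop("qubit index out of range")
      sgn <- cached_zzsign(s$n_qubits, q[1], q[2])
      s$amplitudes <- s$amplitudes * exp(-1i * g$angles[1] / 2 * sgn)
      s
    })
}

#' Apply a list of gates in order
#' @param s a `statevector`.
#' @param gates list of [gate_spec()] objects.
#' @return the updated `statevector`.
#' @export
apply_gates <- function(s, gates) {
  for (g in gates) s <- apply_gate(s, g)
  s
}

#' Pauli-Z expectation value of one qubit
#'
#' @param s a `statevector`.
#' @param qubit 0-based qubit index.
#' @return \eqn{\langle Z_q \rangle \in [-1, 1]}.
#' @export
expval_z <- function(s, qubit) {
  if (qubit < 0 || qubit >= s$n_qubits) stop("qubit index out of range")
  sum(cached_zsign(s$n_qubits, qubit) * Mod(s$amplitudes)^2)
}

#' Expectation of the tensor product of Z over all qubits
#'
#' @param s a `statevector`.
#' @return \eqn{\langle \bigotimes_q Z_q \rangle \in [-1, 1]}.
#' @export
expval_z_all <- function(s) {
  key <- paste0("par.", s$n_qubits)
  sgn <- .mask_cache[[key]]
  if (is.null(sgn)) {
    idx <- 0:(length(s$amplitudes) - 1L)
    pop <- integer(length(idx))
    for (b in seq_len(s$n_qubits) - 1L)
      pop <- pop + (bitwAnd(idx, bitwShiftL(1L, b)) > 0L)
    sgn <- (-1)^pop
    .mask_cache[[key]] <- sgn
  }
  sum(sgn * Mod(s$amplitudes)^2)
}

#' Squared-norm of a statevector
#' @param s a `statevector`.
#' @return scalar; 1 for any physical state.
#' @export
state_norm <- function(s) sqrt(sum(Mod(s$amplitudes)^2))
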