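# Independent oracles used across the suite.  These deliberately avoid the
# package's statevector engine: gates are embedded as dense 2^n x 2^n
# matrices via Kronecker products and applied by plain matrix-vector
# multiplication.

# qubit 0 is the most significant bit, so the embedding is
# I (x) ... (x) U (x) ... (x) I with U at position `qubit` counting from the
# left
dense_embed_1q <- function(U, qubit, n) {
  M <- matrix(1, 1, 1)
  for (q in seq_len(n) - 1L) {
    M <- kronecker(M, if (q == qubit) U else diag(2))
  }
  M
}

dense_rzz <- function(theta, q1, q2, n) {
  N <- 2^n
  idx <- 0:(N - 1L)
  b1 <- bitwAnd(idx, bitwShiftL(1L, n - 1L - q1)) > 0L
  b2 <- bitwAnd(idx, bitwShiftL(1L, n - 1L - q2)) > 0L
  diag(exp(-1i * theta / 2 * ifelse(b1 == b2, 1, -1)))
}

dense_gate_matrix <- function(g, n) {
  switch(g$kind,
         RY = dense_embed_1q(ry_matrix(g$angles[1]), g$qubits[1], n),
         RZ = dense_embed_1q(rz_matrix(g$angles[1]), g$qubits[1], n),
         U3 = dense_embed_1q(u3_matrix(g$angles[1], g$angles[2], g$angles[3]),
                             g$qubits[1], n),
         RZZ = dense_rzz(g$angles[1], g$qubits[1], g$qubits[2], n))
}

dense_apply <- function(amps, gates, n) {
  for (g in gates) amps <- dense_gate_matrix(g, n) %*% amps
  drop(amps)
}

dense_expval_z <- function(amps, qubit, n) {
  Z <- dense_embed_1q(diag(c(1, -1)), qubit, n)
  Re(Conj(amps) %*% Z %*% amps)[1]
}

dense_expval_z_all <- function(amps, n) {
  Z <- diag(c(1, -1))
  M <- matrix(1, 1, 1)
  for (q in seq_len(n)) M <- kronecker(M, Z)
  Re(Conj(amps) %*% M %*% amps)[1]
}

random_state <- function(n, seed) {
  set.seed(seed)
  a <- complex(real = rnorm(2^n), imaginary = rnorm(2^n))
  a <- a / sqrt(sum(Mod(a)^2))
  s <- init_state(n)
  s$amplitudes <- a
  s
}

# brute-force minimum proper edge coloring: smallest k such that some
# assignment in k^m is proper (feasible for m <= 6 edges)
brute_chromatic_index <- function(edges) {
  m <- nrow(edges)
  if (m == 0L) return(0L)
  for (k in 1:m) {
    grid <- do.call(expand.grid, rep(list(seq_len(k)), m))
    for (r in seq_len(nrow(grid))) {
      col <- as.integer(grid[r, ])
      ok <- TRUE
      for (e1 in seq_len(m - 1L)) for (e2 in (e1 + 1L):m) {
        if (col[e1] == col[e2] &&
            length(intersect(edges[e1, ], edges[e2, ]))) ok <- FALSE
      }
      if (ok) return(k)
    }
  }
  m
}

# a small fixed molecule: propene-like C=C-C skeleton plus an O
fixture_molecule <- function() {
  molgraph(
    atoms = data.frame(
      z = c(6L, 6L, 6L, 8L),
      nh = c(2L, 1L, 2L, 1L),
      aromatic = FALSE,
      hyb = c("sp2", "sp2", "sp3", "sp3")),
    bonds = data.frame(i = c(0L, 1L, 2L), j = c(1L, 2L, 3L),
                       type = c("double", "single", "single")),
    id = "fixture")
}

random_params <- function(config, seed) {
  p <- init_qgnn_params(config, seed = seed)
  set.seed(seed)
  v <- flatten_params(p)
  unflatten_params(v + runif(length(v), -1, 1), p)
}

mixed_err <- function(a, b) pmin(abs(a - b), abs(a - b) / pmax(abs(b), 1e-12))

# naive double-loop re-implementation of the GGNN update, kept deliberately
# independent of the package's layer code
naive_ggnn <- function(x, g, Phi, Ew1, Eb1, Ew2, Eb2, aggr) {
  n <- nrow(x)
  out <- matrix(0, n, 2)
  for (i in seq_len(n) - 1L) {
    msgs <- NULL
    for (r in seq_len(nrow(g$bonds))) {
      other <- if (g$bonds$i[r] == i) g$bonds$j[r]
               else if (g$bonds$j[r] == i) g$bonds$i[r] else NA
      if (is.na(other)) next
      oh <- as.numeric(seq_len(4) == match(g$bonds$type[r],
                                           c("single", "aromatic", "double",
                                             "triple")))
      M <- matrix(drop(Ew2 %*% pmax(drop(Ew1 %*% oh + Eb1), 0) + Eb2),
                  2, 2, byrow = TRUE)
      msgs <- rbind(msgs, drop(M %*% x[other + 1L, ]))
    }
    agg <- if (is.null(msgs)) c(0, 0)
           else switch(aggr, add = colSums(msgs), mean = colMeans(msgs),
                       max = apply(msgs, 2, max))
    out[i + 1L, ] <- drop(Phi %*% x[i + 1L, ]) + agg
  }
  out
}

tmpfile <- function(ext = ".jsonl") {
  f <- tempfile(fileext = ext)
  withr::defer(unlink(f), envir = parent.frame())
  f
}

# gate sequence realizing one EDU on qubits (i, j); independent of the
# package's link-layer builder
edu_seq <- function(i, j, v, d, variant) {
  if (variant == "default") {
    list(gate_spec("U3", i, v), gate_spec("U3", j, v),
         gate_spec("RZZ", c(i, j), d),
         gate_spec("U3", i, -rev(v)), gate_spec("U3", j, -rev(v)))
  } else {
    list(gate_spec("RY", i, v), gate_spec("RY", j, v),
         gate_spec("RZZ", c(i, j), d),
         gate_spec("RY", i, -v), gate_spec("RY", j, -v))
  }
}

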