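#' @importFrom stats rnorm runif setNames
#' @importFrom utils head
NULL

# Chemical vocabulary shared across the package.  Heavy atoms only; hydrogens
# enter as a node feature (count of bonded H).
ELEMENTS <- c(C = 6L, N = 7L, O = 8L, F = 9L)
VALENCE <- c(`6` = 4, `7` = 3, `8` = 2, `9` = 1)
HYBRIDIZATIONS <- c("sp", "sp2", "sp3")
BOND_TYPES <- c("single", "aromatic", "double", "triple", "master")
CHEM_BOND_TYPES <- c("single", "aromatic", "double", "triple")
# Bond order used against the valence budget (aromatic counts 1.5).
BOND_ORDER <- c(single = 1, aromatic = 1.5, double = 2, triple = 3)

#' Construct a molecular graph
#'
#' A molecular graph is an undirected attributed graph whose nodes are heavy
#' atoms (C, N, O, F) and whose links are typed bonds.  An optional master
#' node, connected to every atom by bonds of type `"master"`, can be appended
#' with [add_master_node()].  Node indices are 0-based throughout the package
#' (they double as qubit indices in the simulator).
#'
#' @param atoms data.frame with columns `z` (atomic number, one of 6/7/8/9),
#'   `nh` (bonded hydrogens, 0--4), `aromatic` (logical), `hyb` (one of
#'   `"sp"`, `"sp2"`, `"sp3"`), and optionally `is_master` (logical).  Master
#'   rows may carry `NA` in the chemical columns.
#' @param bonds data.frame with columns `i`, `j` (0-based node indices) and
#'   `type` (one of `r paste0('"', BOND_TYPES, '"', collapse = ", ")`).  May
#'   have zero rows.
#' @param target_ha optional scalar regression target in Hartree (`NA` if
#'   unlabelled).
#' @param id character label for the graph.
#' @param validate run [validate_molgraph()] on the result (default `TRUE`).
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds = empty_bonds(), target_ha = NA_real_,
                     id = "mol", validate = TRUE) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$is_master)) atoms$is_master <- FALSE
  atoms$is_master[is.na(atoms$is_master)] <- FALSE
  atoms <- atoms[, c("z", "nh", "aromatic", "hyb", "is_master")]
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) == 0L) bonds <- empty_bonds()
  bonds <- bonds[, c("i", "j", "type")]
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  bonds$type <- as.character(bonds$type)
  g <- structure(
    list(atoms = atoms, bonds = bonds,
         target_ha = as.numeric(target_ha)[1], id = as.character(id)[1]),
    class = "molgraph")
  if (validate) validate_molgraph(g)
  g
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), type = character(),
             stringsAsFactors = FALSE)
}

#' Number of nodes of a molecular graph
#'
#' @param g a `molgraph`.
#' @param master include the master node in the count (default `TRUE`).
#' @return integer node count.
#' @export
n_nodes <- function(g, master = TRUE) {
  if (master) nrow(g$atoms) else sum(!g$atoms$is_master)
}

#' Does the graph carry a master node?
#' @param g a `molgraph`.
#' @return logical.
#' @export
has_master <- function(g) any(g$atoms$is_master)

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph '%s': %d atoms%s, %d bonds, target %s Ha>\n",
              x$id, n_nodes(x, master = FALSE),
              if (has_master(x)) " + master" else "",
              nrow(x$bonds),
              if (is.na(x$target_ha)) "NA" else format(x$target_ha)))
  invisible(x)
}

#' Validate molecular-graph invariants
#'
#' Checks the structural invariants of the data model: element and hydrogen
#' ranges, hybridization labels, bond endpoint sanity (no self loops, no
#' duplicated unordered pairs, indices in range), master-node rules (at most
#' one; bonded to every other node; master bond type exactly on master
#' incident bonds), connectivity, and the 9-heavy-atom size cap.
#'
#' @param g a `molgraph`.
#' @return `g` invisibly; signals a classed error `eduqgc_validation_error`
#'   naming the graph id on the first violated invariant.
#' @export
validate_molgraph <- function(g) {
  fail <- function(msg) {
    stop(errorCondition(sprintf("graph '%s': %s", g$id, msg),
                        class = c("eduqgc_validation_error", "error")))
  }
  a <- g$atoms
  b <- g$bonds
  n <- nrow(a)
  if (n < 1L) fail("graph has no nodes")
  if (sum(a$is_master) > 1L) fail("more than one master node")
  if (sum(!a$is_master) > 9L) fail("more than 9 heavy atoms")
  reg <- !a$is_master
  if (any(!(a$z[reg] %in% ELEMENTS))) fail("atomic number outside {6,7,8,9}")
  if (any(is.na(a$nh[reg]) | a$nh[reg] < 0 | a$nh[reg] > 4))
    fail("hydrogen count outside 0..4")
  if (any(!(a$hyb[reg] %in% HYBRIDIZATIONS))) fail("unknown hybridization")
  if (any(!is.logical(a$aromatic[reg]) & !(a$aromatic[reg] %in% c(TRUE, FALSE))))
    fail("aromatic flag must be boolean")
  if (nrow(b) > 0L) {
    if (any(!(b$type %in% BOND_TYPES))) fail("unknown bond type")
    if (any(b$i < 0L | b$i >= n | b$j < 0L | b$j >= n))
      fail("bond index out of range")
    if (any(b$i == b$j)) fail("self loop")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) fail("duplicate bond")
    m_end <- a$is_master[b$i + 1L] | a$is_master[b$j + 1L]
    if (any(m_end & b$type != "master"))
      fail("bond incident to master must have type 'master'")
    if (any(!m_end & b$type == "master"))
      fail("'master' bond between two regular atoms")
  }
  if (has_master(g)) {
    m <- which(a$is_master) - 1L
    others <- setdiff(seq_len(n) - 1L, m)
    touched <- unique(c(b$j[b$i == m], b$i[b$j == m]))
    if (!setequal(touched, others))
      fail("master node must be bonded to every other node")
  }
  if (n > 1L) {
    # connectivity by traversal over the undirected edge set
    adj <- lapply(seq_len(n), function(k) integer())
    for (r in seq_len(nrow(b))) {
      adj[[b$i[r] + 1L]] <- c(adj[[b$i[r] + 1L]], b$j[r])
      adj[[b$j[r] + 1L]] <- c(adj[[b$j[r] + 1L]], b$i[r])
    }
    seen <- logical(n)
    stack <- 0L
    seen[1L] <- TRUE
    while (length(stack)) {
      v <- stack[[1L]]
      stack <- stack[-1L]
      for (w in adj[[v + 1L]]) {
        if (!seen[w + 1L]) {
          seen[w + 1L] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    if (!all(seen)) fail("graph is not connected")
  }
  invisible(g)
}

#' Append a master node
#'
#' Returns a copy of `g` with one extra node, flagged as master, bonded to
#' every prior node with bonds of type `"master"`.  The master node is always
#' the last node index, which pins its qubit assignment.  The master node
#' carries no chemical features.
#'
#' @param g a `molgraph` without a master node.
#' @return a new `molgraph`.
#' @export
add_master_node <- function(g) {
  if (has_master(g)) stop("graph '", g$id, "' already has a master node")
  n <- n_nodes(g)
  atoms <- rbind(g$atoms,
                 data.frame(z = NA_integer_, nh = NA_integer_, aromatic = NA,
                            hyb = NA_character_, is_master = TRUE))
  bonds <- rbind(g$bonds,
                 data.frame(i = seq_len(n) - 1L, j = n,
                            type = "master", stringsAsFactors = FALSE))
  molgraph(atoms, bonds, target_ha = g$target_ha, id = g$id)
}

#' Apply a node permutation to a molecular graph
#'
#' Relabels nodes so that old node `k` becomes `perm[k + 1] `(0-based values).
#' Used by the permutation-invariance checks of the circuit models.
#'
#' @param g a `molgraph`.
#' @param perm integer vector of length `n_nodes(g)`: a permutation of
#'   `0:(n-1)`; entry `k+1` is the new index of old node `k`.
#' @return the relabelled `molgraph`.
#' @export
permute_graph <- function(g, perm) {
  n <- n_nodes(g)
  stopifnot(length(perm) == n, setequal(perm, seq_len(n) - 1L))
  inv <- integer(n)
  inv[perm + 1L] <- seq_len(n) - 1L        # inv[new+1] = old
  atoms <- g$atoms[inv + 1L, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- g$bonds
  if (nrow(bonds)) {
    bonds$i <- perm[bonds$i + 1L]
    bonds$j <- perm[bonds$j + 1L]
  }
  molgraph(atoms, bonds, target_ha = g$target_ha, id = g$id)
}

# ---------------------------------------------------------------------------
# JSON-lines interchange

atom_to_list <- function(row) {
  if (isTRUE(row$is_master)) return(list(master = TRUE))
  list(z = as.integer(row$z), nh = as.integer(row$nh),
       aromatic = isTRUE(row$aromatic), hyb = row$hyb)
}

#' Write molecular graphs to a JSON-lines file
#'
#' One graph per line, UTF-8, LF line endings:
#' `{"id": str, "atoms": [{"z","nh","aromatic","hyb"} | {"master":true}],
#'   "bonds": [[i, j, type]], "y_gap_ha": float|null}`.
#'
#' @param graphs list of `molgraph`.
#' @param path output file path.
#' @return `path` invisibly.
#' @seealso [read_graphs()]
#' @export
write_graphs <- function(graphs, path) {
  lines <- vapply(graphs, function(g) {
    atoms <- lapply(seq_len(nrow(g$atoms)),
                    function(k) atom_to_list(g$atoms[k, , drop = FALSE]))
    bonds <- lapply(seq_len(nrow(g$bonds)), function(k) {
      list(g$bonds$i[k], g$bonds$j[k], g$bonds$type[k])
    })
    rec <- list(id = g$id, atoms = atoms, bonds = bonds,
                y_gap_ha = if (is.na(g$target_ha)) NULL else g$target_ha)
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read molecular graphs from a JSON-lines file
#'
#' Parses and validates the interchange dialect written by [write_graphs()].
#' Malformed JSON raises a parse error naming the line number; a record that
#' violates a graph invariant raises a validation error naming the graph id.
#'
#' @param path input file path.
#' @return list of validated `molgraph`, in file order.
#' @export
read_graphs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(ln) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[ln]], simplifyVector = FALSE),
                    error = function(e) {
                      stop(errorCondition(
                        sprintf("parse error at line %d: %s", ln,
                                conditionMessage(e)),
                        class = c("eduqgc_parse_error", "error")))
                    })
    record_to_graph(rec, ln)
  })
}

record_to_graph <- function(rec, ln) {
  perr <- function(msg) {
    stop(errorCondition(sprintf("parse error at line %d: %s", ln, msg),
                        class = c("eduqgc_parse_error", "error")))
  }
  if (is.null(rec$id) || is.null(rec$atoms)) perr("missing 'id' or 'atoms'")
  atoms <- do.call(rbind, lapply(rec$atoms, function(a) {
    if (isTRUE(a$master)) {
      data.frame(z = NA_integer_, nh = NA_integer_, aromatic = NA,
                 hyb = NA_character_, is_master = TRUE)
    } else {
      if (is.null(a$z) || is.null(a$nh) || is.null(a$aromatic) || is.null(a$hyb))
        perr("atom record missing a feature field")
      data.frame(z = as.integer(a$z), nh = as.integer(a$nh),
                 aromatic = as.logical(a$aromatic), hyb = as.character(a$hyb),
                 is_master = FALSE)
    }
  }))
  bonds <- if (length(rec$bonds)) {
    do.call(rbind, lapply(rec$bonds, function(b) {
      if (length(b) != 3L) perr("bond record must be [i, j, type]")
      data.frame(i = as.integer(b[[1]]), j = as.integer(b[[2]]),
                 type = as.character(b[[3]]), stringsAsFactors = FALSE)
    }))
  } else empty_bonds()
  y <- if (is.null(rec$y_gap_ha)) NA_real_ else as.numeric(rec$y_gap_ha)
  molgraph(atoms, bonds, target_ha = y, id = as.character(rec$id))
}

# ---------------------------------------------------------------------------
# Synthetic molecule generator

#' Generate synthetic QM9-like molecules
#'
#' Samples connected heavy-atom graphs emulating the small-organic-molecule
#' regime: up to `max_atoms` atoms drawn from C/N/O/F, bonds assigned under a
#' simplified valence budget (C:4, N:3, O:2, F:1; an aromatic bond consumes
#' 1.5), occasional benzene-like aromatic six-rings, and hydrogen counts set
#' to the leftover valence (clipped to 0--4).  Hybridization is `sp` for atoms
#' in a triple bond, `sp2` for aromatic or doubly bonded atoms, else `sp3`.
#' The composition leans heavily on carbon, as small organic datasets do.
#'
#' The sampler retries internally until a valid graph is drawn, so the output
#' always passes [validate_molgraph()].  Deterministic for a fixed seed.
#'
#' @param n number of molecules.
#' @param seed integer RNG seed.
#' @param max_atoms maximum heavy-atom count (default 9, the QM9 cap).
#' @return list of `n` unlabelled `molgraph` objects with ids `"m0"`,
#'   `"m1"`, ...
#' @export
generate_molecules <- function(n, seed, max_atoms = 9L) {
  stopifnot(n >= 0, max_atoms >= 1, max_atoms <= 9)
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(k) {
    repeat {
      g <- try(sample_molecule(max_atoms, id = paste0("m", k - 1L)),
               silent = TRUE)
      if (!inherits(g, "try-error")) return(g)
    }
  })
}

sample_molecule <- function(max_atoms, id) {
  # size distribution tilted toward larger molecules, as in QM9
  sizes <- seq_len(max_atoms)
  n <- sample(sizes, 1L, prob = sizes)
  elem_prob <- c(0.70, 0.12, 0.16, 0.02)  # C, N, O, F
  aromatic_ring <- n >= 6 && runif(1) < 0.2
  if (aromatic_ring) {
    z <- c(rep(6L, 6L), sample(ELEMENTS, n - 6L, replace = TRUE,
                               prob = elem_prob))
  } else {
    z <- sample(ELEMENTS, n, replace = TRUE, prob = elem_prob)
    # a lone heavy atom must be able to exist (F alone would be HF; fine),
    # but a 2+-atom molecule needs a first atom with valence >= 1 (always true)
  }
  budget <- VALENCE[as.character(z)]
  bonds <- empty_bonds()
  used <- numeric(n)
  add_bond <- function(i, j, type) {
    bonds <<- rbind(bonds, data.frame(i = i, j = j, type = type,
                                      stringsAsFactors = FALSE))
    used[i + 1L] <<- used[i + 1L] + BOND_ORDER[[type]]
    used[j + 1L] <<- used[j + 1L] + BOND_ORDER[[type]]
  }
  first_free <- 0L
  if (aromatic_ring) {
    for (k in 0:5) add_bond(k, (k + 1L) %% 6L, "aromatic")
    first_free <- 6L
    # attach remaining atoms to the ring or to each other via a spanning tree
    for (k in seq_len(n - 6L) + 5L) {
      cand <- which(used[seq_len(k)] < budget[seq_len(k)] &
                      budget[seq_len(k)] - used[seq_len(k)] >= 1) - 1L
      if (!length(cand)) stop("dead end")
      add_bond(sample(cand, 1L), k, "single")
    }
  } else if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      free <- budget[seq_len(k)] - used[seq_len(k)]
      cand <- which(free >= 1) - 1L
      if (!length(cand)) stop("dead end")
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      avail <- min(free[p + 1L], budget[k + 1L])
      type <- "single"
      if (avail >= 3 && runif(1) < 0.05) type <- "triple"
      else if (avail >= 2 && runif(1) < 0.15) type <- "double"
      add_bond(p, k, type)
    }
  }
  # a few extra single bonds to create rings
  if (n >= 4L) {
    for (t in seq_len(2L)) {
      if (runif(1) > 0.25) next
      free <- which(budget - used >= 1) - 1L
      if (length(free) < 2L) next
      pair <- sample(free, 2L)
      key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
      if (paste(min(pair), max(pair)) %in% key) next
      add_bond(pair[1], pair[2], "single")
    }
  }
  in_type <- function(k, type) {
    any((bonds$i == k | bonds$j == k) & bonds$type == type)
  }
  aromatic <- vapply(seq_len(n) - 1L, function(k) in_type(k, "aromatic"),
                     logical(1))
  hyb <- vapply(seq_len(n) - 1L, function(k) {
    if (in_type(k, "triple")) "sp"
    else if (aromatic[k + 1L] || in_type(k, "double")) "sp2"
    else "sp3"
  }, character(1))
  nh <- pmin(pmax(floor(budget - used), 0), 4)
  molgraph(data.frame(z = z, nh = as.integer(nh), aromatic = aromatic,
                      hyb = hyb, is_master = FALSE),
           bonds, id = id)
}

#' Label molecules with a frozen teacher model
#'
#' Sets each graph's target to the forward pass of a fixed ("teacher")
#' quantum model plus i.i.d. Gaussian noise, which gives a ground-truth
#' function that the trainable model can provably represent — the basis of
#' the parameter-recovery checks.
#'
#' @param graphs list of `molgraph`.
#' @param teacher_config a [model_config()] for the teacher.
#' @param teacher_params parameters valid for `teacher_config` (see
#'   [init_qgnn_params()]).
#' @param noise_sd Gaussian noise standard deviation in Hartree.
#' @param seed integer RNG seed for the noise.
#' @return the graphs with `target_ha` filled in.
#' @export
teacher_label <- function(graphs, teacher_config, teacher_params,
                          noise_sd = 0, seed = 0L) {
  check_params_shape(teacher_config, teacher_params)
  set.seed(as.integer(seed))
  noise <- rnorm(length(graphs), 0, noise_sd)
  Map(function(g, eps) {
    gg <- if (teacher_config$master_node && !has_master(g))
      add_master_node(g) else g
    g$target_ha <- qgnn_forward(gg, teacher_config, teacher_params) + eps
    g
  }, graphs, noise)
}
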