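# Fixed-size categorical graph representation G = <A, C, E>.
#
# A mol_graph stores one-hot matrices over the full vocabulary (ordinary
# categories plus <MASK>):
#   A: n x (K_A + 1) atom types, C: n x (K_C + 1) charges,
#   E: n x n x (K_E + 1) bond types, symmetric with a "none" diagonal.
# Internally most algorithms work on the equivalent integer index form
# (graph_indices / graph_from_indices); the one-hot form is the public
# container and the shape the denoiser consumes.

new_mol_graph <- function(A, C, E, n_real) {
  structure(list(A = A, C = C, E = E, n = nrow(A), n_real = as.integer(n_real)),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("mol_graph: n =", x$n, "(", x$n_real, "real atoms ),",
      "channels", ncol(x$A), "/", ncol(x$C), "/", dim(x$E)[3], "\n")
  invisible(x)
}

onehot_matrix <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Integer index form of a graph
#'
#' @param g a `mol_graph`.
#' @return list with `a`, `c` (integer vectors of length n) and `e`
#'   (n x n integer matrix) of category indices.
#' @export
graph_indices <- function(g) {
  n <- g$n
  e <- matrix(max.col(matrix(g$E, nrow = n * n), ties.method = "first"),
              n, n)
  list(a = max.col(g$A, ties.method = "first"),
       c = max.col(g$C, ties.method = "first"),
       e = e)
}

#' Build a graph from integer category indices
#'
#' @param a,c integer vectors of length `n` (atom / charge categories).
#' @param e n x n integer matrix of bond categories (must be symmetric).
#' @param vocab the vocabulary fixing channel widths.
#' @param n_real number of non-padding atoms (defaults to the count of
#'   rows whose atom category is not `<PAD>`).
#' @return a `mol_graph`.
#' @export
graph_from_indices <- function(a, c, e, vocab, n_real = NULL) {
  n <- length(a)
  stopifnot(length(c) == n, all(dim(e) == c(n, n)))
  if (!isTRUE(all(e == t(e)))) stop("bond index matrix must be symmetric")
  dE <- vocab$K_E + 1L
  E <- array(0, dim = c(n, n, dE))
  E[cbind(rep(seq_len(n), n), rep(seq_len(n), each = n), as.vector(e))] <- 1
  if (is.null(n_real)) n_real <- sum(a != pad_index(vocab))
  new_mol_graph(onehot_matrix(a, vocab$K_A + 1L),
                onehot_matrix(c, vocab$K_C + 1L), E, n_real)
}

#' Encode a SMILES string as a fixed-size categorical graph
#'
#' Heavy atoms occupy the first rows (hydrogens stay implicit); the remaining
#' rows are `<PAD>` atoms with neutral charge and no bonds. Stereochemistry is
#' stripped on encode.
#'
#' @param s a single SMILES string.
#' @param vocab vocabulary from [build_vocabulary()].
#' @param n target graph size (must be at least the heavy-atom count).
#' @return a `mol_graph` with `n_real` heavy atoms.
#' @export
smiles_to_graph <- function(s, vocab, n) {
  stopifnot(is.character(s), length(s) == 1)
  tab <- molecule_tables(s)[[1]]
  encode_molecule_table(tab, vocab, n)
}

# shared encoder for pre-parsed atom/bond tables (batch path)
encode_molecule_table <- function(tab, vocab, n) {
  n_real <- nrow(tab$atoms)
  if (n_real > n) {
    stop("molecule '", tab$smiles, "' has ", n_real,
         " heavy atoms, larger than graph size n = ", n)
  }
  a_idx <- match(tab$atoms$el, vocab$atom_types)
  if (anyNA(a_idx)) {
    stop("element(s) not in vocabulary: ",
         paste(unique(tab$atoms$el[is.na(a_idx)]), collapse = ", "))
  }
  c_idx <- match(tab$atoms$chg, vocab$charges)
  if (anyNA(c_idx)) {
    stop("formal charge(s) not in vocabulary: ",
         paste(unique(tab$atoms$chg[is.na(c_idx)]), collapse = ", "))
  }
  a <- c(a_idx, rep(pad_index(vocab), n - n_real))
  ch <- c(c_idx, rep(neutral_charge_index(vocab), n - n_real))
  e <- matrix(1L, n, n)  # "none"
  if (nrow(tab$bonds)) {
    i <- tab$bonds[, "i"]; j <- tab$bonds[, "j"]
    e[cbind(i, j)] <- e[cbind(j, i)] <- tab$bonds[, "code"] + 1L
  }
  graph_from_indices(a, ch, e, vocab, n_real = n_real)
}

# connected components of a tiny undirected adjacency (logical) matrix
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# index-form decode: returns list(elements, charges, bonds) or NULL when no
# real atoms survive. Used by graph_to_smiles and the batched sampler decode.
decode_indices <- function(a, ch, e, vocab) {
  if (any(a == mask_index(vocab, "A")) || any(ch == mask_index(vocab, "C")) ||
      any(e == mask_index(vocab, "E"))) {
    stop("graph contains <MASK> categories; decoding requires a clean graph")
  }
  keep <- which(a != pad_index(vocab))
  if (length(keep) == 0) return(NULL)
  e <- e[keep, keep, drop = FALSE]
  diag(e) <- 1L
  adj <- e != 1L
  comp <- components_of(adj)
  # largest component; ties broken by the lowest original node index
  sizes <- tabulate(comp)
  cand <- which(sizes == max(sizes))
  first_idx <- vapply(cand, function(k) min(keep[comp == k]), integer(1))
  sel <- comp == cand[which.min(first_idx)]
  keep2 <- which(sel)
  esub <- e[keep2, keep2, drop = FALSE]
  bonds <- which(upper.tri(esub) & esub != 1L, arr.ind = TRUE)
  list(elements = vocab$atom_types[a[keep[keep2]]],
       charges = vocab$charges[ch[keep[keep2]]],
       bonds = cbind(i = bonds[, 1], j = bonds[, 2],
                     code = esub[bonds] - 1L))
}

#' Decode a categorical graph back to SMILES
#'
#' Padding nodes are dropped, the largest connected component under
#' non-"none" edges is kept (ties broken by lowest node index), and the
#' resulting molecule is sanitized by RDKit. Chemically impossible graphs
#' (e.g. valence violations) yield the failure flag `NA_character_`, which
#' counts as an invalid generation, not an error.
#'
#' @param g a `mol_graph` free of `<MASK>` categories.
#' @param vocab the vocabulary used to encode `g`.
#' @return canonical SMILES, or `NA_character_` on sanitization failure.
#' @export
graph_to_smiles <- function(g, vocab) {
  graphs_to_smiles(list(g), vocab)[[1]]
}

#' Decode a batch of graphs in one sanitization call
#'
#' @param graphs list of `mol_graph` objects.
#' @param vocab shared vocabulary.
#' @return character vector, `NA_character_` for failed decodes.
#' @export
graphs_to_smiles <- function(graphs, vocab) {
  if (length(graphs) == 0) return(character(0))
  specs <- lapply(graphs, function(g) {
    idx <- graph_indices(g)
    decode_indices(idx$a, idx$c, idx$e, vocab)
  })
  out <- rep(NA_character_, length(graphs))
  todo <- which(!vapply(specs, is.null, logical(1)))
  if (length(todo)) out[todo] <- assemble_molecules(specs[todo])
  out
}

#' Apply a node permutation to a graph
#'
#' Row `i` of the result is row `perm[i]` of the input; both axes of the bond
#' array are permuted consistently. Decoding is invariant under permutation.
#'
#' @param g a `mol_graph`.
#' @param perm a permutation of `1:n`.
#' @return the permuted `mol_graph`.
#' @export
permute_graph <- function(g, perm) {
  n <- g$n
  if (length(perm) != n || !setequal(perm, seq_len(n))) {
    stop("perm must be a permutation of 1..", n)
  }
  new_mol_graph(g$A[perm, , drop = FALSE], g$C[perm, , drop = FALSE],
                g$E[perm, perm, , drop = FALSE], g$n_real)
}

# structural validity check used by tests and as a debugging aid
check_graph <- function(g, vocab, clean = FALSE) {
  stopifnot(all(abs(rowSums(g$A) - 1) < 1e-12),
            all(abs(rowSums(g$C) - 1) < 1e-12),
            all(abs(apply(g$E, c(1, 2), sum) - 1) < 1e-12))
  idx <- graph_indices(g)
  stopifnot(all(idx$e == t(idx$e)), all(diag(idx$e) == 1L))
  if (clean) {
    stopifnot(all(idx$a <= vocab$K_A), all(idx$c <= vocab$K_C),
              all(idx$e <= vocab$K_E))
    padded <- idx$a == pad_index(vocab)
    stopifnot(all(idx$e[padded, ] == 1L), all(idx$e[, padded] == 1L))
  }
  invisible(TRUE)
}
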