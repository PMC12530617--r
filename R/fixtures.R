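# Enumerated small-molecule fixtures with exact reference distributions.
#
# Real training corpora (MOSES, ZINC-250K) are replaced at desk scale by
# enumerations with closed-form frequencies, so distribution-recovery tests
# have an exact target. "enumerated_chains" produces all unbranched
# heavy-atom chains over the allowed elements (no two adjacent heteroatoms,
# bounded heteroatom count), deduplicated by canonical SMILES; "ring_mix"
# adds plain carbon rings.

#' Fixture specification
#'
#' @param generator `"enumerated_chains"` or `"ring_mix"`.
#' @param max_heavy_atoms chain/ring size bound (<= 9, CPU scale).
#' @param elements allowed elements, a subset of C, N, O (carbon is always
#'   included).
#' @param max_heteroatoms cap on non-carbon atoms per molecule.
#' @param n_molecules size of the emitted training corpus.
#' @param seed recorded seed (corpus assembly is deterministic).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(generator = c("enumerated_chains", "ring_mix"),
                         max_heavy_atoms = 4, elements = c("C", "O"),
                         max_heteroatoms = 1, n_molecules = 200, seed = 1) {
  generator <- match.arg(generator)
  stopifnot(max_heavy_atoms >= 2, max_heavy_atoms <= 9,
            all(elements %in% c("C", "N", "O")), n_molecules >= 1)
  structure(list(generator = generator,
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 elements = unique(c("C", elements)),
                 max_heteroatoms = as.integer(max_heteroatoms),
                 n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

enumerate_chain_strings <- function(max_len, elements, max_het) {
  out <- character(0)
  for (len in 2:max_len) {
    seqs <- do.call(expand.grid,
                    c(rep(list(elements), len), stringsAsFactors = FALSE))
    for (r in seq_len(nrow(seqs))) {
      atoms <- unlist(seqs[r, ], use.names = FALSE)
      het <- atoms != "C"
      if (sum(het) > max_het) next
      if (len > 1 && any(het[-1] & het[-len])) next  # no adjacent heteroatoms
      out <- c(out, paste(atoms, collapse = ""))
    }
  }
  out
}

ring_strings <- function(max_len) {
  if (max_len < 3) return(character(0))
  vapply(3:max_len, function(k) {
    paste0("C1", paste(rep("C", k - 2), collapse = ""), "C1")
  }, character(1))
}

#' Build an enumerated fixture corpus
#'
#' Enumerates the generator's molecule set, canonicalizes and deduplicates
#' it, attaches uniform reference weights, apportions `n_molecules` corpus
#' entries to the molecules by largest remainder (so corpus frequencies
#' match the reference distribution exactly up to integer rounding), and
#' computes an RDKit property table.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `fixture` with `molecules` (distinct canonical
#'   SMILES), `weights` (reference probabilities, summing to 1), `corpus`
#'   (character vector of length `n_molecules`), and `properties`
#'   (data.frame: smiles, qed, sas, logp, tpsa for the distinct molecules).
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  raw <- enumerate_chain_strings(spec$max_heavy_atoms, spec$elements,
                                 spec$max_heteroatoms)
  if (spec$generator == "ring_mix") {
    raw <- c(raw, ring_strings(spec$max_heavy_atoms))
  }
  if (length(raw) == 0) stop("empty enumeration for this fixture spec")
  molecules <- sort(unique(canonical_smiles(raw)))
  m <- length(molecules)
  weights <- rep(1 / m, m)
  # largest-remainder apportionment of the corpus counts
  exact <- spec$n_molecules * weights
  counts <- floor(exact)
  rem <- spec$n_molecules - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  corpus <- rep(molecules, times = counts)
  panel <- property_panel(molecules)
  structure(list(spec = spec, molecules = molecules, weights = weights,
                 corpus = corpus, properties = panel$values),
            class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  cat("fixture (", x$spec$generator, "):", length(x$molecules),
      "distinct molecules, corpus of", length(x$corpus), "\n")
  cat(" ", paste(x$molecules, collapse = " "), "\n")
  invisible(x)
}

#' Empirical vs reference total-variation distance
#'
#' @param generated character vector of generated canonical SMILES (invalid
#'   `NA` entries allowed; they contribute their probability mass to the
#'   distance as out-of-support draws).
#' @param molecules reference support (canonical SMILES).
#' @param weights reference probabilities.
#' @return TV distance in `[0, 1]`.
#' @export
tv_distance <- function(generated, molecules, weights) {
  stopifnot(length(molecules) == length(weights))
  emp <- table(factor(generated, levels = molecules)) / length(generated)
  out_mass <- 1 - sum(emp)
  0.5 * (sum(abs(as.numeric(emp) - weights)) + out_mass)
}
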