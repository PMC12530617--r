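# Categorical vocabulary shared by the three graph channels.
#
# Conventions (fixed across the package):
#   * atom channel: observed elements (sorted), then "<PAD>", then "<MASK>".
#     "<PAD>" is an ordinary category - it is corrupted and predicted like any
#     element, which is how the model learns the molecule-size distribution.
#   * charge channel: observed formal charges (sorted, always containing 0),
#     then "<MASK>".
#   * bond channel: "none" (index 1), "single", "double", "triple",
#     "aromatic", then "<MASK>". "none" is an ordinary category.
#   * "<MASK>" is always the last index of its channel; K_* counts the
#     ordinary (non-mask) categories, so the mask index is K + 1.

MASK_LABEL <- "<MASK>"
PAD_LABEL <- "<PAD>"
BOND_LABELS <- c("none", "single", "double", "triple", "aromatic")

#' Build the categorical vocabulary from a training corpus
#'
#' Scans a set of molecules and fixes the ordered category lists for the atom,
#' charge and bond channels, including the `<PAD>` and `<MASK>` bookkeeping
#' categories. The vocabulary (together with the graph size `n`) fully
#' determines the one-hot encoding used by the diffusion model.
#'
#' @param smiles_list non-empty character vector of valid SMILES.
#' @return object of class `mol_vocabulary` with fields `atom_types`,
#'   `charges` (integer vector), `charge_types`, `bond_types`, and ordinary
#'   category counts `K_A`, `K_C`, `K_E`.
#' @examples \dontrun{
#' build_vocabulary(c("CCO", "c1ccccc1N"))
#' }
#' @export
build_vocabulary <- function(smiles_list) {
  stopifnot(is.character(smiles_list), length(smiles_list) >= 1)
  tabs <- molecule_tables(smiles_list)  # errors name any unparsable SMILES
  elements <- sort(unique(unlist(lapply(tabs, function(m) m$atoms$el))))
  charges <- sort(unique(c(0L, unlist(lapply(tabs, function(m) m$atoms$chg)))))
  vocab <- list(
    atom_types = c(elements, PAD_LABEL, MASK_LABEL),
    charges = as.integer(charges),
    charge_types = c(as.character(charges), MASK_LABEL),
    bond_types = c(BOND_LABELS, MASK_LABEL),
    K_A = length(elements) + 1L,   # elements + <PAD>
    K_C = length(charges),
    K_E = length(BOND_LABELS))
  class(vocab) <- "mol_vocabulary"
  vocab
}

#' @export
print.mol_vocabulary <- function(x, ...) {
  cat("Molecular graph vocabulary\n")
  cat("  atoms  (K =", x$K_A, "):", paste(x$atom_types, collapse = " "), "\n")
  cat("  charges(K =", x$K_C, "):", paste(x$charge_types, collapse = " "), "\n")
  cat("  bonds  (K =", x$K_E, "):", paste(x$bond_types, collapse = " "), "\n")
  invisible(x)
}

# index helpers -------------------------------------------------------------

mask_index <- function(vocab, channel) {
  switch(channel, A = vocab$K_A + 1L, C = vocab$K_C + 1L, E = vocab$K_E + 1L,
         stop("unknown channel: ", channel))
}

pad_index <- function(vocab) vocab$K_A  # <PAD> sits just before <MASK>

neutral_charge_index <- function(vocab) {
  idx <- match(0L, vocab$charges)
  if (is.na(idx)) stop("vocabulary has no neutral charge category")
  idx
}

ordinary_count <- function(vocab, channel) {
  switch(channel, A = vocab$K_A, C = vocab$K_C, E = vocab$K_E,
         stop("unknown channel: ", channel))
}

#' Ordinary category counts per channel
#'
#' Convenience accessor giving the `K` vector expected by
#' [make_schedule()].
#'
#' @param vocab a `mol_vocabulary`.
#' @return named integer vector `c(A=, C=, E=)`.
#' @export
channel_K <- function(vocab) {
  c(A = vocab$K_A, C = vocab$K_C, E = vocab$K_E)
}
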