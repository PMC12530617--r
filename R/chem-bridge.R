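#' @keywords internal
"_PACKAGE"

# Batched RDKit bridge. All chemistry primitives (SMILES parsing and
# canonicalization, molecule assembly + sanitization, descriptor panels,
# circular fingerprints) run in one Python subprocess call per batch so the
# interpreter/RDKit startup cost is paid once per request, not per molecule.

.moldiff_env <- new.env(parent = emptyenv())

bridge_script <- function() {
  path <- system.file("python", "chem_bridge.py", package = "moldiff")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is mapped directly
    path <- system.file("inst", "python", "chem_bridge.py", package = "moldiff")
  }
  if (!nzchar(path)) stop("chem_bridge.py not found in the installed package")
  path
}

python_binary <- function() {
  bin <- getOption("moldiff.python", "")
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) stop("no 'python' interpreter found on the PATH")
  unname(bin)
}

#' Call the bundled RDKit helper
#'
#' Low-level entry point to the batched Python/RDKit subprocess used for all
#' chemistry primitives. Exported mainly for tests and debugging; the
#' higher-level wrappers ([canonical_smiles()], [molecule_tables()],
#' [property_panel()], [morgan_fingerprints()]) are the intended interface.
#'
#' @param task one of `"parse"`, `"assemble"`, `"descriptors"`,
#'   `"fingerprints"`.
#' @param payload named list forming the rest of the JSON request.
#' @return list of per-molecule result lists, each with an `ok` flag.
#' @export
chem_bridge <- function(task, payload) {
  req <- c(list(task = task), payload)
  json <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(python_binary(), shQuote(bridge_script()),
                                  input = json, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chem_bridge call failed (task '", task, "'): ",
         paste(out, collapse = "\n"))
  }
  # stderr noise (if any) precedes the single-line JSON response
  jsonlite::fromJSON(out[length(out)], simplifyVector = FALSE)
}

#' Parse SMILES into atom/bond tables
#'
#' Runs each SMILES through RDKit sanitization, strips stereochemistry and
#' isotopes, and returns per-molecule element/charge/bond tables in the
#' encoding used throughout the package (bond codes 1 = single, 2 = double,
#' 3 = triple, 4 = aromatic; atom indices 1-based).
#'
#' @param smiles character vector.
#' @return list with one entry per molecule: `canonical`, `atoms`
#'   (data.frame of `el`, `chg`), `bonds` (matrix `i`, `j`, `code`).
#'   Unparsable input raises an error naming the offending string.
#' @export
molecule_tables <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  res <- chem_bridge("parse", list(smiles = as.list(smiles)))
  lapply(seq_along(res), function(k) {
    r <- res[[k]]
    if (!isTRUE(r$ok)) stop(r$error)
    atoms <- data.frame(
      el  = vapply(r$atoms, function(a) a$el, character(1)),
      chg = vapply(r$atoms, function(a) as.integer(a$chg), integer(1)),
      stringsAsFactors = FALSE)
    bonds <- if (length(r$bonds)) {
      do.call(rbind, lapply(r$bonds, function(b) as.integer(unlist(b))))
    } else {
      matrix(integer(0), ncol = 3)
    }
    colnames(bonds) <- c("i", "j", "code")
    list(smiles = smiles[[k]], canonical = r$canonical,
         atoms = atoms, bonds = bonds)
  })
}

#' Canonicalize SMILES
#'
#' @param smiles character vector.
#' @param strict error on unparsable input (default) instead of returning
#'   `NA_character_` for it.
#' @return character vector of RDKit canonical SMILES (stereo stripped).
#' @export
canonical_smiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  cache <- .moldiff_env$canon_cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .moldiff_env$canon_cache <- cache
  }
  out <- rep(NA_character_, length(smiles))
  known <- vapply(smiles, function(s) !is.null(cache[[s]]), logical(1))
  out[known] <- vapply(smiles[known], function(s) cache[[s]], character(1))
  todo <- unique(smiles[!known])
  if (length(todo)) {
    res <- chem_bridge("parse", list(smiles = as.list(todo)))
    for (k in seq_along(todo)) {
      r <- res[[k]]
      if (isTRUE(r$ok)) {
        cache[[todo[k]]] <- r$canonical
      } else if (strict) {
        stop(r$error)
      } else {
        cache[[todo[k]]] <- NA_character_
      }
    }
    idx <- which(!known)
    out[idx] <- vapply(smiles[idx], function(s) cache[[s]], character(1))
  }
  out
}

# Assemble explicit atom/bond lists into sanitized molecules.
# mols: list of list(elements=chr, charges=int, bonds=matrix i,j,code).
# Returns character vector, NA where sanitization rejected the molecule.
assemble_molecules <- function(mols) {
  if (length(mols) == 0) return(character(0))
  payload <- list(mols = lapply(mols, function(m) {
    bonds <- m$bonds
    list(elements = as.list(m$elements),
         charges = as.list(as.integer(m$charges)),
         bonds = if (is.null(bonds) || nrow(bonds) == 0) list() else
           lapply(seq_len(nrow(bonds)), function(r) as.list(unname(bonds[r, ]))))
  }))
  res <- chem_bridge("assemble", payload)
  vapply(res, function(r) if (isTRUE(r$ok)) r$canonical else NA_character_,
         character(1))
}

#' Morgan fingerprints as on-bit index lists
#'
#' Circular (Morgan/ECFP-like) substructure fingerprints computed by RDKit.
#'
#' @param smiles character vector of valid SMILES.
#' @param radius neighborhood radius (default 2).
#' @param nbits folded length (default 2048).
#' @return list of integer vectors of on-bit positions (0-based).
#' @export
morgan_fingerprints <- function(smiles, radius = 2, nbits = 2048) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  res <- chem_bridge("fingerprints",
                     list(smiles = as.list(smiles),
                          radius = radius, nbits = nbits))
  lapply(res, function(r) {
    if (!isTRUE(r$ok)) stop(r$error)
    as.integer(unlist(r$bits))
  })
}
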