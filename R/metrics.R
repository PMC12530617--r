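# Generation-quality metrics following the MOSES benchmark conventions:
# canonical-SMILES identity for uniqueness/novelty, Morgan-fingerprint
# internal diversity, RDKit property panels.

#' Fraction of generations that decoded to a valid molecule
#'
#' @param outputs character vector of decode results (`NA_character_` marks
#'   a failed/invalid generation).
#' @return fraction in `[0, 1]`.
#' @export
validity <- function(outputs) {
  if (length(outputs) == 0) stop("empty output list")
  mean(!is.na(outputs))
}

#' Uniqueness and novelty of the valid generations
#'
#' Uniqueness is the fraction of distinct canonical SMILES among the valid
#' ones; novelty is the fraction of those distinct molecules absent from the
#' training set (computed over distinct molecules, not with multiplicity).
#'
#' @param valid character vector of canonical SMILES of valid generations.
#' @param train character vector (or set) of canonical training SMILES.
#' @return named numeric `c(uniqueness=, novelty=)`; both `NA` (with a
#'   warning) when `valid` is empty.
#' @export
uniqueness_novelty <- function(valid, train) {
  if (length(valid) == 0) {
    warning("no valid molecules: uniqueness/novelty undefined")
    return(c(uniqueness = NA_real_, novelty = NA_real_))
  }
  distinct <- unique(valid)
  c(uniqueness = length(distinct) / length(valid),
    novelty = mean(!distinct %in% train))
}

tanimoto_matrix <- function(fps, nbits) {
  m <- length(fps)
  M <- matrix(0, m, nbits)
  for (k in seq_len(m)) M[k, fps[[k]] + 1L] <- 1
  inter <- M %*% t(M)
  sizes <- rowSums(M)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- inter / uni
  sim[uni == 0] <- 1  # two empty fingerprints count as identical
  sim
}

#' Internal diversity of a molecule set
#'
#' `IntDiv_p = 1 - (mean over all ordered pairs, self-pairs included, of
#' Tanimoto(fp_i, fp_j)^p)^(1/p)` on Morgan fingerprints (radius 2,
#' 2048 bits).
#'
#' @param valid character vector of valid SMILES (>= 2).
#' @param p power (1 or 2 in the standard reports).
#' @param radius,nbits fingerprint parameters.
#' @return diversity score in `[0, 1]`; `NA` with a warning for fewer than
#'   two molecules.
#' @export
internal_diversity <- function(valid, p = 1, radius = 2, nbits = 2048) {
  if (length(valid) < 2) {
    warning("internal diversity undefined for fewer than 2 molecules")
    return(NA_real_)
  }
  fps <- morgan_fingerprints(valid, radius = radius, nbits = nbits)
  sim <- tanimoto_matrix(fps, nbits)
  1 - mean(sim^p)^(1 / p)
}

#' Per-molecule property panel (QED, SAS, logP, TPSA)
#'
#' Descriptors are computed by RDKit (synthetic accessibility via the
#' standard fragment-contribution SA score). Molecules whose descriptor
#' computation fails are excluded with a warning.
#'
#' @param valid character vector of valid SMILES.
#' @return list with `values` (data.frame `smiles`, `qed`, `sas`, `logp`,
#'   `tpsa`) and `summary` (per-property mean and sd).
#' @export
property_panel <- function(valid) {
  stopifnot(length(valid) >= 1)
  res <- chem_bridge("descriptors", list(smiles = as.list(valid)))
  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " molecule(s) excluded from the property panel: ",
            paste(vapply(res[!ok], function(r) r$error, character(1)),
                  collapse = "; "))
  }
  values <- data.frame(
    smiles = valid[ok],
    qed = vapply(res[ok], function(r) r$qed, numeric(1)),
    sas = vapply(res[ok], function(r) r$sas, numeric(1)),
    logp = vapply(res[ok], function(r) r$logp, numeric(1)),
    tpsa = vapply(res[ok], function(r) r$tpsa, numeric(1)),
    stringsAsFactors = FALSE)
  num <- values[, c("qed", "sas", "logp", "tpsa")]
  summary <- data.frame(property = names(num),
                        mean = vapply(num, mean, numeric(1)),
                        sd = vapply(num, function(x) {
                          if (length(x) > 1) stats::sd(x) else 0
                        }, numeric(1)),
                        row.names = NULL)
  list(values = values, summary = summary)
}

#' Mean absolute deviation from a conditioning target
#'
#' @param values per-molecule property values (non-empty).
#' @param target the conditioning value.
#' @return `mean(|values - target|)`.
#' @export
mean_abs_deviation <- function(values, target) {
  if (length(values) == 0) stop("empty value vector")
  mean(abs(values - target))
}

#' Full generation report
#'
#' @param outputs raw decode results (`NA_character_` for invalid).
#' @param train_smiles canonical training set for novelty.
#' @param target optional conditioning value; adds MAD on
#'   `target_property`.
#' @param target_property property column used for MAD (`"qed"`, `"sas"`,
#'   `"logp"` or `"tpsa"`).
#' @return list of class `generation_report` (validity, uniqueness,
#'   novelty, IntDiv1/2, property summary, optional MAD).
#' @export
generation_report <- function(outputs, train_smiles, target = NULL,
                              target_property = NULL) {
  valid <- outputs[!is.na(outputs)]
  un <- if (length(valid)) uniqueness_novelty(valid, train_smiles) else
    c(uniqueness = NA_real_, novelty = NA_real_)
  panel <- if (length(valid)) property_panel(valid) else NULL
  rep <- list(n_requested = length(outputs), n_valid = length(valid),
              validity = validity(outputs),
              uniqueness = unname(un["uniqueness"]),
              novelty = unname(un["novelty"]),
              intdiv1 = if (length(valid) >= 2)
                internal_diversity(valid, p = 1) else NA_real_,
              intdiv2 = if (length(valid) >= 2)
                internal_diversity(valid, p = 2) else NA_real_,
              property_stats = panel$summary)
  if (!is.null(target) && !is.null(target_property) && !is.null(panel)) {
    rep$target <- target
    rep$target_property <- target_property
    rep$mad <- mean_abs_deviation(panel$values[[target_property]], target)
  }
  class(rep) <- "generation_report"
  rep
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf("generation report: %d requested, %d valid\n",
              x$n_requested, x$n_valid))
  cat(sprintf("  validity %.3f | uniqueness %.3f | novelty %.3f\n",
              x$validity, x$uniqueness, x$novelty))
  cat(sprintf("  IntDiv1 %.3f | IntDiv2 %.3f\n", x$intdiv1, x$intdiv2))
  if (!is.null(x$property_stats)) {
    for (k in seq_len(nrow(x$property_stats))) {
      cat(sprintf("  %s %.3f +/- %.3f\n", x$property_stats$property[k],
                  x$property_stats$mean[k], x$property_stats$sd[k]))
    }
  }
  if (!is.null(x$mad)) {
    cat(sprintf("  MAD(%s -> %.3g) = %.4f\n", x$target_property, x$target,
                x$mad))
  }
  invisible(x)
}
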