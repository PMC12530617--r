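# Reading and writing molecule lists and reports.

#' Read molecules from a SMILES or CSV file
#'
#' Plain-text files hold one SMILES per line; CSV files must carry a
#' `smiles` column and may carry numeric property columns used for
#' conditioning.
#'
#' @param path file path (`.csv` is dispatched on extension).
#' @return data.frame with a `smiles` column plus any property columns.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(df$smiles)) stop("CSV file must have a 'smiles' column: ", path)
    return(df)
  }
  lines <- readLines(path, warn = FALSE)
  data.frame(smiles = lines[nzchar(trimws(lines))], stringsAsFactors = FALSE)
}

#' Write molecules to a SMILES or CSV file
#'
#' @param x character vector of SMILES, or a data.frame with a `smiles`
#'   column (written as CSV).
#' @param path output path.
#' @export
write_smiles <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    writeLines(x[!is.na(x)], path)
  }
  invisible(path)
}

#' Write a generation report as JSON
#'
#' @param report a `generation_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' Serializes the full training configuration (including schedule and
#' denoiser settings) so a run is reproducible from its config file.
#'
#' @param config a [train_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$denoiser <- unclass(x$denoiser)
  x$loss_weights <- as.list(x$loss_weights)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$denoiser <- do.call(denoiser_config, x$denoiser)
  x$loss_weights <- unlist(x$loss_weights)
  do.call(train_config, x)
}
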