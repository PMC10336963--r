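# Plain-text interchange: dataset CSV (SMILES + targets + metadata columns),
# group-model JSON, and prediction-matrix CSV. Writers prepend a single
# comment line recording the provenance/config string so files are
# self-describing; readers skip comment lines.

#' Write / read a dataset CSV
#'
#' Columns: `smiles`, `target`, and any of `noisy_target`, `temperature`,
#' `regime`, `split`, `leaked` that are present. A `#`-prefixed header
#' comment carries the `config` string.
#'
#' @param ds a [property_dataset()].
#' @param path file path.
#' @param config one-line provenance string stored in the header comment.
#' @export
write_dataset_csv <- function(ds, path, config = "adduq dataset") {
  df <- as.data.frame(ds)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @return `read_dataset_csv()` returns a [property_dataset()] (molecules
#'   re-parsed from SMILES).
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("smiles", "target") %in% names(df)))
  mols <- lapply(df$smiles, parse_smiles)
  property_dataset(mols, df$target,
                   noisy_target = df$noisy_target,
                   temperature = df$temperature,
                   regime = df$regime,
                   split = df$split,
                   leaked = if (!is.null(df$leaked)) as.logical(df$leaked),
                   smiles = df$smiles)
}

#' Write / read a group model as JSON
#'
#' @param gm a [group_model()].
#' @param path file path.
#' @export
write_group_model <- function(gm, path) {
  jsonlite::write_json(list(coefficients = as.list(gm$coefficients),
                            min_count = gm$min_count,
                            rounding = gm$rounding),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_group_model
#' @export
read_group_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  group_model(unlist(x$coefficients),
              min_count = x$min_count %||% NA_integer_,
              rounding = x$rounding %||% 3L)
}

#' Write / read an ensemble prediction matrix as CSV
#'
#' Rows are submodels, columns are records; the targets are stored as the
#' first row, labeled `target`.
#'
#' @param b an [ensemble_block()].
#' @param path file path.
#' @param config provenance comment string.
#' @export
write_ensemble_csv <- function(b, path, config = "adduq ensemble block") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", config), con)
  df <- as.data.frame(rbind(target = b$targets, b$predictions))
  names(df) <- paste0("r", seq_len(b$n_test))
  utils::write.csv(cbind(row = c("target",
                                 paste0("submodel", seq_len(b$n_ens))), df),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(df$row[1L] == "target")
  m <- as.matrix(df[, -1L, drop = FALSE])
  ensemble_block(m[-1L, , drop = FALSE], as.numeric(m[1L, ]))
}

#' Load an external SMILES + target CSV
#'
#' Optional loader for full-scale replication data (for example a published
#' artificial-enthalpy table with columns `smiles` and a kcal/mol target).
#' Molecules outside the package's restricted SMILES dialect (aromatic
#' lowercase, charges, stereo) are skipped with a count reported via a
#' warning, which is a documented caveat of the external path.
#'
#' @param path CSV path with columns `smiles` and `target` (or the target
#'   column named by `target_col`).
#' @param target_col name of the target column.
#' @return a [property_dataset()] of the parseable molecules.
#' @export
read_external_enthalpy_csv <- function(path, target_col = "target") {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot("smiles" %in% names(df), target_col %in% names(df))
  mols <- lapply(df$smiles, function(s)
    tryCatch(parse_smiles(s), error = function(e) NULL))
  ok <- !vapply(mols, is.null, logical(1))
  if (!all(ok))
    warning(sum(!ok), " of ", length(ok),
            " molecules outside the supported SMILES dialect were skipped")
  property_dataset(mols[ok], df[[target_col]][ok])
}
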