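# Batch interface and file I/O: data-frame-first wrappers that run the
# consensus calculation over a table of records and return one tidy row per
# record, plus readers for SMILES lists and FASTA files and writers for CSV
# and JSON reports.

.result_row <- function(id, res) {
  row <- glance(res)
  per <- stats::setNames(res$per_set$pi, paste0("pi_", res$per_set$set))
  dplyr::bind_cols(tibble(id = id), row["pi_mean"], row["pi_sd"],
                   tibble::as_tibble_row(per), row[c("interval_low", "interval_high",
                                                     "q_at_ph", "status")],
                   tibble(error = NA_character_))
}

.error_row <- function(id, msg) {
  tibble(id = id, pi_mean = NA_real_, pi_sd = NA_real_,
         interval_low = NA_real_, interval_high = NA_real_,
         q_at_ph = NA_real_, status = "error", error = msg)
}

.batch <- function(data, values, ids, fun, sets, ph_charge) {
  rows <- list()
  results <- list()
  for (i in seq_along(values)) {
    res <- tryCatch(fun(values[i], sets = sets, ph_charge = ph_charge), error = identity)
    if (inherits(res, "error")) {
      rows[[i]] <- .error_row(ids[i], sprintf("record '%s': %s", ids[i], conditionMessage(res)))
      results[[i]] <- list(NULL)
    } else {
      rows[[i]] <- .result_row(ids[i], res)
      results[[i]] <- list(res)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$result <- unlist(results, recursive = FALSE)
  out
}

#' Consensus pI for a table of structures
#'
#' @param data A data frame with one row per molecule.
#' @param smiles Column (tidy-eval) holding SMILES strings.
#' @param id Optional column holding record identifiers.
#' @param sets,ph_charge Passed to [pi_consensus()].
#' @return A tibble with one row per record: consensus mean/SD, per-set pI
#'   columns, isoelectric interval, charge at the reporting pH, status, an
#'   `error` column (`NA` on success; parse failures do not abort the run)
#'   and the full `pi_result` in the `result` list-column.
#' @export
pi_structures <- function(data, smiles = smiles, id = NULL, sets = NULL, ph_charge = 7.4) {
  values <- as.character(dplyr::pull(data, {{ smiles }}))
  idq <- rlang::enquo(id)
  ids <- if (rlang::quo_is_null(idq)) sprintf("mol%d", seq_along(values))
         else as.character(dplyr::pull(data, !!idq))
  .batch(data, values, ids, pi_consensus, sets, ph_charge)
}

#' Consensus pI for a table of sequences
#'
#' @param data A data frame with one row per peptide.
#' @param sequence Column (tidy-eval) holding one-letter sequences.
#' @inheritParams pi_structures
#' @return As [pi_structures()], using the sequence-based calculator.
#' @export
pi_sequences <- function(data, sequence = sequence, id = NULL, sets = NULL, ph_charge = 7.4) {
  values <- as.character(dplyr::pull(data, {{ sequence }}))
  idq <- rlang::enquo(id)
  ids <- if (rlang::quo_is_null(idq)) sprintf("seq%d", seq_along(values))
         else as.character(dplyr::pull(data, !!idq))
  .batch(data, values, ids, sequence_consensus, sets, ph_charge)
}

#' Read a SMILES file (one record per line)
#'
#' Each non-empty line holds a SMILES string optionally followed by
#' whitespace and a name; lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return A tibble with columns `id` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(tibble(id = character(), smiles = character()))
  toks <- stringr::str_split_fixed(lines, "\\s+", 2)
  ids <- ifelse(nzchar(toks[, 2]), toks[, 2], sprintf("mol%d", seq_along(lines)))
  tibble(id = ids, smiles = toks[, 1])
}

#' Read peptide sequences from a FASTA file
#'
#' @param path File path.
#' @return A tibble with columns `id` and `sequence`. An empty file yields
#'   an empty tibble with a warning.
#' @export
read_fasta <- function(path) {
  recs <- Biostrings::readAAStringSet(path)
  if (!length(recs)) {
    warning(sprintf("no FASTA records in '%s'", path))
    return(tibble(id = character(), sequence = character()))
  }
  tibble(id = names(recs), sequence = unname(as.character(recs)))
}

#' Write a batch result table to CSV or JSON
#'
#' The `result` list-column is dropped; remaining columns are written in a
#' stable order so identical runs produce byte-identical files.
#'
#' @param results A tibble from [pi_structures()] or [pi_sequences()].
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- dplyr::select(results, -dplyr::any_of("result"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
  } else {
    readr::write_csv(out, path, na = "")
  }
  invisible(path)
}
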