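#' Measurement tables
#'
#' A measurement table holds one omics layer of differential measurements:
#' transcripts, proteins, or phosphosites.  Each row is one analyte with a
#' log2 fold-change (treated over control) and, optionally, per-replicate
#' log2 intensities for the two groups, a p-value and a BH-adjusted FDR.
#'
#' Phosphosite analytes use the key `"<PROTEIN>_<RES><POS>"` with a
#' one-letter residue code (e.g. `"CDK1_Y15"`); multiple residues on one
#' record are joined by `";"`.  The host protein and residue string are
#' parsed from the key so sites can be joined to regulatory-site
#' annotations and normalized against protein abundance.
#'
#' @param data A data frame with at least `analyte_id` and `log2fc`
#'   columns.  Optional columns: `p_value`, `fdr`, `reps_control`,
#'   `reps_treated` (list columns of numeric replicate vectors).
#' @param layer One of `"transcript"`, `"protein"`, `"phosphosite"`.
#' @param condition_label Free-text label of the contrast (e.g.
#'   `"TKI_24h"`).
#'
#' @return A tibble of class `measurement_table` with attributes `layer`
#'   and `condition_label`.
#' @export
measurement_table <- function(data, layer = c("transcript", "protein", "phosphosite"),
                              condition_label = NA_character_) {
  layer <- match.arg(layer)
  data <- tibble::as_tibble(data)
  if (!all(c("analyte_id", "log2fc") %in% names(data))) {
    sc_abort("measurement_table needs 'analyte_id' and 'log2fc' columns")
  }
  data$analyte_id <- as.character(data$analyte_id)
  if (any(is.na(data$analyte_id) | data$analyte_id == "")) {
    sc_abort("analyte_id must be non-empty for every record")
  }
  dup <- unique(data$analyte_id[duplicated(data$analyte_id)])
  if (length(dup) > 0) {
    sc_abort("duplicate analyte_id in %s table: %s", layer,
             paste(head(dup, 10), collapse = ", "))
  }
  data$log2fc <- as.numeric(data$log2fc)
  if (!"p_value" %in% names(data)) data$p_value <- NA_real_
  if (!"fdr" %in% names(data)) data$fdr <- NA_real_
  if (!"significant" %in% names(data)) data$significant <- NA
  if (!"flags" %in% names(data)) data$flags <- NA_character_
  bad_p <- !is.na(data$p_value) & (data$p_value < 0 | data$p_value > 1)
  bad_q <- !is.na(data$fdr) & (data$fdr < 0 | data$fdr > 1)
  if (any(bad_p) || any(bad_q)) sc_abort("p_value/fdr outside [0,1]")

  if (layer == "phosphosite") {
    parsed <- parse_site_key(data$analyte_id)
    if (any(is.na(parsed$residue))) {
      sc_abort("phosphosite analyte_id not in '<PROTEIN>_<RES><POS>' form: %s",
               paste(head(data$analyte_id[is.na(parsed$residue)], 5), collapse = ", "))
    }
    data$host_protein <- parsed$protein
    data$residue <- parsed$residue
  } else {
    if ("residue" %in% names(data) && any(!is.na(data$residue))) {
      sc_abort("residue column only allowed on the phosphosite layer")
    }
    data$residue <- NA_character_
    data$host_protein <- NA_character_
  }
  structure(data,
            class = c("measurement_table", class(tibble::tibble())),
            layer = layer, condition_label = condition_label)
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("<measurement_table> layer=%s condition=%s (%d analytes)\n",
              attr(x, "layer"), attr(x, "condition_label"), nrow(x)))
  NextMethod()
}

mt_layer <- function(x) attr(x, "layer")

# "WEE1_S139" -> protein "WEE1", residue "S139"; multi-site "P_S10;T20"
parse_site_key <- function(keys) {
  m <- stringr::str_match(keys, "^(.+)_([A-Z]\\d+(?:;[A-Z]\\d+)*)$")
  tibble::tibble(protein = m[, 2], residue = m[, 3])
}

default_col_map <- function() {
  list(analyte_id = "analyte_id", log2fc = "log2fc", p_value = "p_value",
       control_prefix = "control_", treated_prefix = "treated_")
}

#' Read a differential-measurement table from TSV
#'
#' Reads a UTF-8, header-rowed, tab-separated table and validates it as a
#' [measurement_table()].  Column names can be remapped with `col_map`
#' (a list or the path of a YAML file) so exported tables from other
#' pipelines can be adapted without code changes.  Rows whose fold-change
#' does not parse as a number are dropped and counted in the log.
#' Per-replicate intensity columns are picked up by prefix
#' (`control_1, control_2, ...`, `treated_1, ...` by default).
#'
#' @param path Path of the TSV file.
#' @param layer Omics layer of the table (see [measurement_table()]).
#' @param col_map Optional list or YAML file path overriding the default
#'   column mapping: entries `analyte_id`, `log2fc`, `p_value`,
#'   `control_prefix`, `treated_prefix`.
#' @param condition_label Optional condition label.
#' @param dialect Only `"tsv"` is supported.
#' @return A [measurement_table()].
#' @export
read_measurement_table <- function(path, layer, col_map = NULL,
                                   condition_label = NA_character_,
                                   dialect = "tsv") {
  dialect <- match.arg(dialect, "tsv")
  if (!file.exists(path)) sc_abort("file not found: %s", path)
  if (is.character(col_map) && length(col_map) == 1) {
    col_map <- yaml::read_yaml(col_map)
  }
  cm <- modifyList(default_col_map(), col_map %||% list())
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (need in c("analyte_id", "log2fc")) {
    if (!cm[[need]] %in% names(raw)) {
      sc_abort("missing mandatory column '%s' in %s", cm[[need]], path)
    }
  }
  out <- tibble::tibble(
    analyte_id = raw[[cm$analyte_id]],
    log2fc = suppressWarnings(as.numeric(raw[[cm$log2fc]]))
  )
  if (cm$p_value %in% names(raw)) {
    out$p_value <- suppressWarnings(as.numeric(raw[[cm$p_value]]))
  }
  rep_cols <- function(prefix) {
    nm <- names(raw)[startsWith(names(raw), prefix)]
    nm[order(suppressWarnings(as.numeric(sub(prefix, "", nm, fixed = TRUE))))]
  }
  ctrl <- rep_cols(cm$control_prefix)
  trt <- rep_cols(cm$treated_prefix)
  if (length(ctrl) > 0 && length(trt) > 0) {
    num <- function(cols) {
      m <- vapply(cols, function(cl) suppressWarnings(as.numeric(raw[[cl]])),
                  numeric(nrow(raw)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
    }
    out$reps_control <- num(ctrl)
    out$reps_treated <- num(trt)
  }
  keep <- !is.na(out$log2fc)
  if (any(!keep)) {
    sc_log("%s: dropped %d row(s) with unparsable log2fc", path, sum(!keep))
    out <- out[keep, , drop = FALSE]
  }
  measurement_table(out, layer = layer, condition_label = condition_label)
}

#' Write a measurement table to canonical TSV
#'
#' Inverse of [read_measurement_table()]: replicate list-columns are
#' expanded back into `control_i` / `treated_i` columns, numbers are
#' written at full precision so a read/write round trip reproduces every
#' field.
#'
#' @param table A [measurement_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  out <- tibble::as_tibble(table)
  for (side in c("reps_control", "reps_treated")) {
    if (side %in% names(out)) {
      reps <- out[[side]]
      k <- max(lengths(reps))
      prefix <- if (side == "reps_control") "control_" else "treated_"
      for (i in seq_len(k)) {
        out[[paste0(prefix, i)]] <-
          vapply(reps, function(v) if (length(v) >= i) v[[i]] else NA_real_, 1)
      }
      out[[side]] <- NULL
    }
  }
  out$residue <- NULL
  out$host_protein <- NULL
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
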