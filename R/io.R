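# CSV readers/writers ----------------------------------------------------------
#
# Interchange format: a voltage matrix CSV (time points as rows, experiments
# as columns, header row of experiment ids, exactly 1511 data rows) plus a
# metadata CSV with columns experiment_id, bod5_mg, volume_ml,
# resistance_ohm, water_type, role. Trailing zeros in a column are padding.

#' Read an experiment set from a voltage matrix CSV and a metadata CSV
#'
#' @param matrix_csv path to the 1511-row voltage matrix (experiments as
#'   columns; set `transpose = TRUE` if experiments are rows).
#' @param metadata_csv path to the metadata table.
#' @param transpose whether the matrix is stored experiments-as-rows.
#' @return an [experiment_set()].
#' @export
read_dataset <- function(matrix_csv, metadata_csv, transpose = FALSE) {
  m <- as.matrix(utils::read.csv(matrix_csv, check.names = FALSE))
  if (transpose) m <- t(m)
  if (nrow(m) != CANONICAL_LENGTH) {
    stop("voltage matrix must have ", CANONICAL_LENGTH, " rows, found ",
         nrow(m))
  }
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  need <- c("experiment_id", "bod5_mg", "volume_ml", "resistance_ohm",
            "water_type", "role")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  }
  ids <- colnames(m)
  if (is.null(ids) || !setequal(ids, meta$experiment_id)) {
    stop("experiment ids in the matrix header do not match the metadata")
  }
  meta <- meta[match(ids, meta$experiment_id), ]
  traces <- lapply(seq_along(ids), function(j) {
    v <- m[, j]
    nz <- which(v != 0)
    n_obs <- if (length(nz)) max(nz) else 1L  # trailing zeros are padding
    voltage_trace(ids[j], v[seq_len(n_obs)], meta$bod5_mg[j],
                  sample_volume = meta$volume_ml[j],
                  external_resistance = meta$resistance_ohm[j],
                  water_type = meta$water_type[j])
  })
  experiment_set(traces, meta$role)
}

#' Write an experiment set as a voltage matrix CSV and a metadata CSV
#'
#' The inverse of [read_dataset()]: traces are zero-padded into the
#' 1511-row frame, experiments as columns.
#'
#' @param set an [experiment_set()].
#' @param matrix_csv,metadata_csv output paths.
#' @export
write_dataset <- function(set, matrix_csv, metadata_csv) {
  stopifnot(inherits(set, "experiment_set"))
  m <- t(canonical_matrix(set))          # time points as rows
  colnames(m) <- set_ids(set)
  utils::write.csv(m, matrix_csv, row.names = FALSE)
  meta <- data.frame(
    experiment_id = set_ids(set),
    bod5_mg = set_masses(set),
    volume_ml = vapply(set$traces, `[[`, numeric(1), "sample_volume"),
    resistance_ohm = vapply(set$traces, `[[`, numeric(1),
                            "external_resistance"),
    water_type = vapply(set$traces, `[[`, character(1), "water_type"),
    role = unname(set$roles),
    row.names = NULL
  )
  utils::write.csv(meta, metadata_csv, row.names = FALSE)
  invisible(c(matrix_csv, metadata_csv))
}
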