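# Loading, validating and writing lifespan-record datasets.
#
# A dataset is a tibble with one row per strain-cohort observation and the
# external columns
#   organism, genes (";"-joined), alleles (";"-joined), intervention_types
#   (";"-joined), lifespan_days, lifespan_metric, temperature_c, diet,
#   study_id
# plus the derived columns canonical_name, n and experiment_key. ";" is
# reserved as the list separator inside the genes/alleles/types fields.

DATASET_COLUMNS <- c(
  "organism", "genes", "alleles", "intervention_types", "lifespan_days",
  "lifespan_metric", "temperature_c", "diet", "study_id"
)

DEFAULT_EXPERIMENT_KEY_FIELDS <- c("study_id", "temperature_c", "diet")

split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(character(0))
  }
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

key_part <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

#' Build a validated lifespan dataset from a raw data frame
#'
#' Applies the row-level curation checks (known organism, positive lifespan,
#' controlled intervention vocabulary), derives the canonical strain name,
#' the intervention count `n` and the experiment grouping key, and attaches
#' a load report (rows read / kept / rejected with per-row reasons).
#'
#' Strains are identified at the gene level: the canonical name uses gene
#' symbols only, so observations of the same gene set with different alleles
#' map to one model (alleles are recorded but not distinguishing).
#'
#' @param df Data frame with the columns named in the package's dump
#'   dialect (see [read_lifespan_data()]); extra columns are dropped.
#' @param experiment_key_fields Columns whose combination defines
#'   "same experiment" for epistasis comparisons. Default
#'   `c("study_id", "temperature_c", "diet")`; all epistasis maths is
#'   restricted to observations sharing this key.
#' @return A tibble of class `lifespan_dataset` with attribute
#'   `load_report`.
#' @export
as_lifespan_dataset <- function(df,
                                experiment_key_fields = DEFAULT_EXPERIMENT_KEY_FIELDS) {
  df <- as_tibble(df)
  missing_cols <- setdiff(DATASET_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Dataset schema mismatch; missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad_key <- setdiff(experiment_key_fields, DATASET_COLUMNS)
  if (length(bad_key) > 0) {
    abort(paste0("Unknown experiment_key field(s): ", paste(bad_key, collapse = ", ")))
  }

  df <- df[DATASET_COLUMNS]
  for (col in c("organism", "genes", "alleles", "intervention_types",
                "lifespan_metric", "diet", "study_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$lifespan_days <- suppressWarnings(as.numeric(df$lifespan_days))
  df$temperature_c <- suppressWarnings(as.numeric(df$temperature_c))
  df$lifespan_metric[is.na(df$lifespan_metric) | !nzchar(df$lifespan_metric)] <- "mean"

  n_read <- nrow(df)
  reasons <- rep(NA_character_, n_read)
  reject <- function(i, why) {
    if (is.na(reasons[i])) reasons[i] <<- why
  }

  for (i in seq_len(n_read)) {
    org <- df$organism[i]
    if (is.na(org) || !nzchar(org)) {
      reject(i, "missing organism")
    } else if (!org %in% ORGANISMS) {
      reject(i, "unknown organism")
    }
    ls <- df$lifespan_days[i]
    if (is.na(ls)) {
      reject(i, "missing lifespan")
    } else if (ls <= 0) {
      reject(i, "non-positive lifespan")
    }
    if (!df$lifespan_metric[i] %in% c("mean", "median")) {
      reject(i, "unknown lifespan metric")
    }
    g <- split_field(if (is.na(df$genes[i])) "" else df$genes[i])
    it <- split_field(if (is.na(df$intervention_types[i])) "" else df$intervention_types[i])
    if (length(it) > 0) {
      if (!all(it %in% names(INTERVENTION_DIRECTIONS))) {
        reject(i, "unknown intervention type")
      } else if (length(it) != length(g)) {
        reject(i, "intervention type count mismatch")
      }
    }
    if (is.na(df$study_id[i]) || !nzchar(df$study_id[i])) {
      reject(i, "missing study id")
    }
  }

  kept <- is.na(reasons)
  rejections <- tibble(
    row = which(!kept),
    reason = reasons[!kept]
  )
  out <- df[kept, , drop = FALSE]
  out$canonical_name <- vapply(
    out$genes, function(g) canonical_name(split_field(key_part(g))), character(1),
    USE.NAMES = FALSE
  )
  out$n <- vapply(
    out$canonical_name, function(nm) length(gene_set(nm)), integer(1),
    USE.NAMES = FALSE
  )
  out$experiment_key <- experiment_key_of(out, experiment_key_fields)

  structure(
    out,
    class = c("lifespan_dataset", class(out)),
    load_report = list(
      rows_read = n_read,
      rows_kept = nrow(out),
      rows_rejected = nrow(rejections),
      rejections = rejections,
      experiment_key_fields = experiment_key_fields
    )
  )
}

experiment_key_of <- function(df, fields = DEFAULT_EXPERIMENT_KEY_FIELDS) {
  parts <- lapply(fields, function(f) key_part(df[[f]]))
  do.call(paste, c(parts, sep = "|"))
}

#' Load report of a dataset
#'
#' @param x A `lifespan_dataset`.
#' @return The load report list (rows read / kept / rejected, per-row
#'   rejection reasons, experiment-key fields).
#' @export
load_report <- function(x) {
  attr(x, "load_report")
}

#' Read lifespan records from a database dump
#'
#' Reads the CSV or JSON dump dialect (one object/row per strain-cohort
#' observation) and validates it via [as_lifespan_dataset()]. The SQL dump
#' dialect is not supported.
#'
#' @param path File to read.
#' @param format `"csv"` (UTF-8, comma-separated, mandatory header) or
#'   `"json"` (array of objects with the same keys as the CSV columns).
#' @param column_map Optional named character vector adapting foreign
#'   column names: names are the package's canonical columns, values the
#'   names found in the file.
#' @inheritParams as_lifespan_dataset
#' @return A `lifespan_dataset`; see [load_report()] for the row
#'   accounting.
#' @export
read_lifespan_data <- function(path,
                               format = c("csv", "json"),
                               column_map = NULL,
                               experiment_key_fields = DEFAULT_EXPERIMENT_KEY_FIELDS) {
  format <- arg_match(format)
  if (!file.exists(path)) {
    abort(paste0("Input file not found: ", path))
  }
  raw <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE),
    json = {
      parsed <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (length(parsed) == 0) {
        tibble()
      } else {
        as_tibble(parsed)
      }
    }
  )
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    raw <- as_tibble(setNames(
      rep(list(character(0)), length(DATASET_COLUMNS)), DATASET_COLUMNS
    ))
  }
  if (!is.null(column_map)) {
    for (ours in names(column_map)) {
      theirs <- column_map[[ours]]
      if (!theirs %in% names(raw)) {
        abort(paste0("column_map points at absent column: ", theirs))
      }
      raw[[ours]] <- raw[[theirs]]
    }
  }
  as_lifespan_dataset(raw, experiment_key_fields = experiment_key_fields)
}

#' Write lifespan records in a dump dialect
#'
#' Serialises the external columns under a fixed row ordering (organism,
#' experiment key, intervention count, canonical name) so that re-writing a
#' loaded file is byte-stable, and `read_lifespan_data(write_lifespan_data(x))`
#' reproduces `x` up to observation order.
#'
#' @param x A `lifespan_dataset` (or data frame with the dump columns).
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_lifespan_data <- function(x, path, format = c("csv", "json")) {
  format <- arg_match(format)
  df <- as_tibble(x)
  if (!all(DATASET_COLUMNS %in% names(df))) {
    abort("Not a lifespan dataset: external columns missing.")
  }
  if (nrow(df) > 0) {
    if (!"canonical_name" %in% names(df)) {
      df <- as_lifespan_dataset(df)
    }
    ord <- order(df$organism, experiment_key_of(df), df$n, df$canonical_name,
                 df$lifespan_days, method = "radix")
    df <- df[ord, ]
  }
  df <- df[DATASET_COLUMNS]
  switch(format,
    csv = readr::write_csv(df, path, na = "", progress = FALSE),
    json = jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                                digits = NA, pretty = TRUE)
  )
  invisible(path)
}

#' Split a dataset into experiment groups
#'
#' All epistasis definitions refer to data generated in the same experiment;
#' this splits the observations on the experiment key (by default study,
#' temperature and diet).
#'
#' @param x A `lifespan_dataset`.
#' @return Named list of tibbles, one per experiment key.
#' @export
experiment_groups <- function(x) {
  split(as_tibble(x), x$experiment_key)
}

#' Mean lifespan per strain within one experiment group
#'
#' Multiple cohorts of the same strain within one experiment are averaged
#' (arithmetic mean) before any epistasis computation.
#'
#' @param group Tibble of observations sharing one experiment key.
#' @return Tibble with columns organism, canonical_name, n, lifespan_days.
#' @keywords internal
model_lifespans <- function(group) {
  # base aggregation: this sits on the hot path of dataset-wide classification
  idx <- split(seq_len(nrow(group)), group$canonical_name)
  first <- vapply(idx, function(i) i[[1]], integer(1))
  tibble::new_tibble(list(
    organism = group$organism[first],
    canonical_name = names(idx),
    n = group$n[first],
    lifespan_days = vapply(idx, function(i) mean(group$lifespan_days[i]),
                           numeric(1))
  ), nrow = length(idx))
}

#' Curation inclusion filter for an experiment group
#'
#' A group passes when (a) at least one multi-gene mutant in the group has
#' an assayed (n-1)-mutant (or wild type, for doubles built stepwise) whose
#' gene set is a subset of its own — i.e. a strain from which it was
#' incrementally constructed — and (b) at least one mutant observation
#' exceeds the group's wild-type lifespan by strictly more than 10%.
#' `assume_prior_lag = TRUE` waives (b) for groups without a wild-type
#' control, asserting that one of the interventions was already shown to
#' modulate lifespan in prior work (a curator's call, not computed).
#'
#' @param group Tibble of observations sharing one experiment key.
#' @param assume_prior_lag Waive the 10% rule when the group has no WT.
#' @return List with elements `pass` (logical) and `reason` (`NA` on pass).
#' @export
inclusion_filter <- function(group, assume_prior_lag = FALSE) {
  fail <- function(reason) list(pass = FALSE, reason = reason)
  mutants <- group[group$n >= 1, , drop = FALSE]
  if (nrow(mutants) == 0) {
    return(fail("no mutants"))
  }
  multi <- unique(group$canonical_name[group$n >= 2])
  if (length(multi) == 0) {
    return(fail("no multi-gene mutant"))
  }
  present <- unique(group$canonical_name)
  has_predecessor <- any(vapply(multi, function(nm) {
    gs <- gene_set(nm)
    any(vapply(gs, function(g) canonical_name(setdiff(gs, g)) %in% present,
               logical(1)))
  }, logical(1)))
  if (!has_predecessor) {
    return(fail("no (n-1)-mutant comparison"))
  }
  wt_rows <- group$lifespan_days[group$n == 0]
  if (length(wt_rows) == 0) {
    if (assume_prior_lag) {
      return(list(pass = TRUE, reason = NA_character_))
    }
    return(fail("no wild-type control"))
  }
  # min over WT cohorts keeps the screen monotone in evidence: adding an
  # observation can extend but never revoke a pass.
  wt <- min(wt_rows)
  if (!any(mutants$lifespan_days > wt * 1.1)) {
    return(fail("no >10% increase"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Lifespan-distribution QC summary
#'
#' Per (organism, strain, temperature) summary of lifespan values, the
#' table used to eyeball outliers across studies. SD is reported only when
#' at least two observations exist.
#'
#' @param x A `lifespan_dataset` (or compatible tibble).
#' @return Tibble with columns organism, canonical_name, temperature_c,
#'   min, max, mean, sd, count (all lifespans in days).
#' @export
qc_lifespan_distributions <- function(x) {
  df <- as_tibble(x)
  if (nrow(df) == 0) {
    return(tibble(
      organism = character(0), canonical_name = character(0),
      temperature_c = numeric(0), min = numeric(0), max = numeric(0),
      mean = numeric(0), sd = numeric(0), count = integer(0)
    ))
  }
  df |>
    group_by(organism, canonical_name, temperature_c) |>
    summarise(
      min = min(lifespan_days),
      max = max(lifespan_days),
      mean = mean(lifespan_days),
      sd = if (dplyr::n() >= 2) sd(lifespan_days) else NA_real_,
      count = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(organism, canonical_name, temperature_c)
}
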