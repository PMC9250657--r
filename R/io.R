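SEVEN_CLASS_COLS <- c("locus_id", paste0("n_", GENOTYPE_LABELS))
THREE_CLASS_COLS <- c("locus_id", paste0("n_", COLLAPSED_LABELS))

#' Read a per-locus genotype count table
#'
#' Reads a TSV of per-locus counts, either seven-class
#' (`locus_id, n_6A, n_5A1a, n_4A2a, n_3A3a, n_2A4a, n_1A5a, n_6a`) or
#' three-class collapsed (`locus_id, n_6A, n_A_a, n_6a`). Class columns are
#' ordered by descending A-dosage. Rows whose class values sum to ~1 are
#' auto-detected as frequency rows and flagged (`is_frequency`); tests run
#' on them default to the frequency scale with a configurable pseudo-N.
#' Schema violations (missing columns, negative values, duplicated locus
#' ids, non-numeric cells) are errors with line numbers.
#'
#' @param path TSV file.
#' @param format `"seven_class"` or `"three_class"`.
#' @return list of locus records, each with `locus_id`, `counts`,
#'   `is_frequency`, `line`.
#' @export
read_counts_table <- function(path, format = c("seven_class", "three_class")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- if (format == "seven_class") SEVEN_CLASS_COLS else THREE_CLASS_COLS
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  ids <- as.character(df$locus_id)
  dup <- which(duplicated(ids))
  if (length(dup) > 0) {
    stop("duplicate locus_id '", ids[dup[1]], "' at line ", dup[1] + 1L,
         " of ", path)
  }
  if (any(!nzchar(ids))) {
    stop("empty locus_id at line ", which(!nzchar(ids))[1] + 1L, " of ", path)
  }
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    vals <- suppressWarnings(as.numeric(df[i, cols[-1]]))
    line <- i + 1L
    if (any(is.na(vals))) {
      stop("non-numeric count at line ", line, " of ", path)
    }
    if (any(vals < 0)) {
      stop("negative count at line ", line, " of ", path)
    }
    counts <- if (format == "seven_class") {
      stats::setNames(vals, GENOTYPE_LABELS)
    } else {
      stats::setNames(vals, COLLAPSED_LABELS)
    }
    records[[i]] <- list(locus_id = ids[i], counts = counts,
                         format = format,
                         is_frequency = is_frequency_triple(vals, tol = 1e-3),
                         line = line)
  }
  records
}

#' Write a per-locus genotype count table
#'
#' Inverse of [read_counts_table()]; used by the fixture writer and for
#' round-tripping results.
#'
#' @param records list of locus records (`locus_id`, `counts`).
#' @param path output TSV path.
#' @param format `"seven_class"` or `"three_class"`.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(records, path,
                               format = c("seven_class", "three_class")) {
  format <- match.arg(format)
  cols <- if (format == "seven_class") SEVEN_CLASS_COLS else THREE_CLASS_COLS
  rows <- lapply(records, function(r) {
    out <- data.frame(locus_id = r$locus_id, stringsAsFactors = FALSE)
    for (k in seq_along(r$counts)) out[[cols[k + 1L]]] <- unname(r$counts[k])
    out
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an individual-by-locus dosage matrix
#'
#' CSV with one row per individual: first column `individual`, remaining
#' columns one per locus holding integer A-dosages 0..6 (missing coded NA).
#' Tallies per-locus seven-class genotype counts, excluding missing calls.
#'
#' @param path CSV file.
#' @return list of locus records with `locus_id`, `counts`, `n_missing`,
#'   `all_missing` (such loci carry no counts and are excluded from
#'   testing).
#' @export
read_dosage_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"individual" %in% names(df)) {
    stop("dosage matrix needs an 'individual' first column: ", path)
  }
  loci <- setdiff(names(df), "individual")
  if (length(loci) == 0) stop("no locus columns in ", path)
  lapply(loci, function(lc) {
    v <- df[[lc]]
    bad <- which(!is.na(v) & (v < 0 | v > 6 | v != round(v)))
    if (length(bad) > 0) {
      stop("dosage outside 0..6 for locus '", lc, "' at data line ",
           bad[1] + 1L, " of ", path)
    }
    obs <- v[!is.na(v)]
    counts <- stats::setNames(
      vapply(6:0, function(d) sum(obs == d), numeric(1)), GENOTYPE_LABELS)
    list(locus_id = lc, counts = counts, format = "seven_class",
         is_frequency = FALSE, n_missing = sum(is.na(v)),
         all_missing = length(obs) == 0)
  })
}

#' Write a batch of test results
#'
#' One row per (locus, test): `locus_id, method, statistic, df, p_value,
#' n, scale` plus one `exp_*` column per expected class frequency. A JSON
#' mirror is written when `json_path` is given.
#'
#' @param results named list of `hex_test` objects (names = locus ids).
#' @param path output TSV path.
#' @param json_path optional JSON path.
#' @return `path`, invisibly.
#' @export
write_test_results <- function(results, path, json_path = NULL) {
  rows <- lapply(names(results), function(id) {
    t <- results[[id]]
    out <- data.frame(locus_id = id, method = t$method,
                      statistic = t$statistic, df = t$df,
                      p_value = t$p_value, n = t$n, scale = t$scale,
                      stringsAsFactors = FALSE)
    for (k in seq_along(t$expected)) {
      out[[paste0("exp_", names(t$expected)[k])]] <- unname(t$expected[k])
    }
    out
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- lapply(results, function(t) {
      list(method = t$method, statistic = t$statistic, df = t$df,
           p_value = t$p_value, n = t$n, scale = t$scale,
           observed = as.list(t$observed), expected = as.list(t$expected))
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Path to a packaged fixture
#'
#' Packaged plain-text fixtures: `worked_example.tsv` (the seven-class
#' example counts), `chrysanthemum_ahwe.tsv` and `chrysanthemum_dr.tsv`
#' (collapsed observed frequencies for the published chrysanthemum marker
#' examples).
#'
#' @param name fixture file name; with no argument, lists available names.
#' @return file path (or character vector of names).
#' @export
hex_fixture_path <- function(name = NULL) {
  dir <- system.file("extdata", package = "hexaHWE")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    stop("no packaged fixture '", name, "'; available: ",
         paste(list.files(dir), collapse = ", "))
  }
  path
}
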