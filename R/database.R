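#' Construct a TF-target database object
#'
#' The central data structure: a mapping from each transcription factor's
#' locus ID to the set of genes it binds (its cistrome-derived target set).
#' Per-TF target-set size supplies `X` in the over-representation test.
#'
#' @param entries Named list; names are TF locus IDs, elements character
#'   vectors of target locus IDs. IDs are normalized, targets deduplicated.
#' @param source_label Free-text provenance string.
#' @return Object of class `tf_target_db`.
#' @export
tf_target_db <- function(entries, source_label = "") {
  if (!is.list(entries) || is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("entries must be a named list of target-ID vectors", call. = FALSE)
  }
  names(entries) <- normalize_gene_id(names(entries))
  if (anyDuplicated(names(entries))) {
    stop("duplicate TF identifiers after normalization", call. = FALSE)
  }
  entries <- lapply(entries, function(v) unique(normalize_gene_id(v)))
  if (any(lengths(entries) == 0L)) {
    stop("every TF must have a non-empty target set", call. = FALSE)
  }
  structure(list(entries = entries, source_label = source_label),
            class = "tf_target_db")
}

#' Number of TFs in a database
#' @param db A `tf_target_db`.
#' @return Integer TF count.
#' @export
tf_count <- function(db) length(db$entries)

#' @export
print.tf_target_db <- function(x, ...) {
  cat("<tf_target_db> ", tf_count(x), " TFs, ",
      sum(lengths(x$entries)), " TF-target pairs\n", sep = "")
  if (nzchar(x$source_label)) cat("  source: ", x$source_label, "\n", sep = "")
  invisible(x)
}

#' Load a TF-target database from long-format TSV
#'
#' Canonical exchange format: one `TF_ID<TAB>TARGET_ID` pair per line, no
#' header, `#` comments and blank lines tolerated. Duplicate pairs collapse
#' to one (target sets have set semantics).
#'
#' @param path Path to the TSV file.
#' @param source_label Provenance recorded on the returned object; defaults
#'   to the file path.
#' @return A `tf_target_db`.
#' @export
load_database <- function(path, source_label = path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop("parse error in ", path, " line ", lineno[bad[1]],
         ": expected 2 tab-separated fields, found ", lengths(fields)[bad[1]],
         call. = FALSE)
  }
  if (!length(fields)) stop("empty database file: ", path, call. = FALSE)
  tf <- normalize_gene_id(vapply(fields, `[`, "", 1L))
  tg <- normalize_gene_id(vapply(fields, `[`, "", 2L))
  tf_target_db(split(tg, factor(tf, levels = unique(tf))), source_label)
}

#' Load a database from a directory of per-TF target lists
#'
#' Convenience loader for Plant-Cistrome-style distributions: one plain-text
#' target list per TF, filename stem (minus extension) taken as the TF locus
#' ID and normalized.
#'
#' @param dir Directory containing one gene-list file per TF.
#' @param pattern Filename filter passed to [list.files()].
#' @return A `tf_target_db`.
#' @export
load_database_dir <- function(dir, pattern = NULL) {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files found in ", dir, call. = FALSE)
  stems <- sub("\\.[^.]*$", "", basename(files))
  entries <- lapply(files, read_clean_lines)
  names(entries) <- stems
  entries <- entries[lengths(entries) > 0L]
  if (!length(entries)) stop("no non-empty target lists in ", dir, call. = FALSE)
  tf_target_db(entries, source_label = dir)
}

#' Write a TF-target database as long-format TSV
#'
#' Inverse of [load_database()]: the round trip reproduces the mapping
#' exactly. TFs and targets are written in lexicographic order so output is
#' byte-deterministic.
#'
#' @param db A `tf_target_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "tf_target_db"))
  if (tf_count(db) == 0L) stop("refusing to write a database with zero TFs", call. = FALSE)
  tfs <- sort(names(db$entries), method = "radix")
  con <- file(path, "w")
  on.exit(close(con))
  for (tf in tfs) {
    tg <- sort(db$entries[[tf]], method = "radix")
    writeLines(paste(tf, tg, sep = "\t"), con)
  }
  invisible(path)
}
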