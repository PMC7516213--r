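#' Normalize a locus identifier
#'
#' Gene identifiers arriving from transcript-level pipelines frequently carry
#' an isoform suffix (`AT1G01060.1`) and inconsistent case. Cistrome target
#' tables are gene-level, so identifiers are upper-cased and a single trailing
#' `.<digits>` transcript suffix is stripped before any lookup. The operation
#' is idempotent and vectorized.
#'
#' @param raw Character vector of raw identifiers.
#' @return Character vector of normalized locus IDs.
#' @examples
#' normalize_gene_id("at1g01060.1") # "AT1G01060"
#' @export
normalize_gene_id <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(trimws(raw))
  if (any(!nzchar(out))) {
    stop("malformed gene identifier: empty or whitespace-only input", call. = FALSE)
  }
  if (any(grepl("[[:space:]]", out))) {
    stop("malformed gene identifier: embedded whitespace", call. = FALSE)
  }
  sub("\\.[0-9]+$", "", out)
}

#' Construct a gene set
#'
#' A gene set is an unordered, duplicate-free character vector of normalized
#' locus IDs. Used for both the genes-of-interest (GOI) list (size `n`) and
#' the background universe (size `N`).
#'
#' @param ids Character vector of identifiers (normalized on entry).
#' @return Character vector of class `gene_set`.
#' @export
gene_set <- function(ids) {
  ids <- if (length(ids)) unique(normalize_gene_id(ids)) else character(0)
  structure(ids, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", length(x), " genes\n", sep = "")
  if (length(x)) cat("  ", paste(utils::head(unclass(x), 6), collapse = ", "),
                     if (length(x) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Read non-comment, non-blank lines from a plain-text file.
read_clean_lines <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Load a gene list from a plain-text file
#'
#' One locus ID per line; blank lines and `#` comments are ignored. IDs are
#' normalized and deduplicated. When a background `universe` is supplied,
#' members absent from the universe are dropped with a warning (the
#' over-representation test is only defined over the reference population)
#' and returned in the `dropped` component.
#'
#' @param path Path to the gene-list file (UTF-8, one ID per line).
#' @param universe Optional `gene_set` background; members outside it are dropped.
#' @return List with components `genes` (a `gene_set`) and `dropped`
#'   (character vector of normalized IDs excluded by the universe filter).
#' @export
load_gene_list <- function(path, universe = NULL) {
  ids <- read_clean_lines(path)
  if (!length(ids)) stop("empty input: no gene identifiers in ", path, call. = FALSE)
  ids <- unique(normalize_gene_id(ids))
  dropped <- character(0)
  if (!is.null(universe)) {
    keep <- ids %in% universe
    dropped <- ids[!keep]
    ids <- ids[keep]
    if (length(dropped)) {
      warning(length(dropped), " gene(s) absent from the universe were dropped",
              call. = FALSE)
    }
  }
  if (!length(ids)) {
    stop("empty input: no gene identifiers remain after universe filtering",
         call. = FALSE)
  }
  list(genes = gene_set(ids), dropped = dropped)
}

#' Load a gene alias table
#'
#' Tab-separated file with a header and columns `gene_id`, `symbols`, `names`
#' (symbols and full names comma-joined within a cell). Used to decorate
#' enrichment results with familiar gene symbols.
#'
#' @param path Path to the alias TSV.
#' @return data.frame with columns `gene_id`, `symbols`, `names`.
#' @export
load_aliases <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "#")
  need <- c("gene_id", "symbols", "names")
  if (!all(need %in% names(tab))) {
    stop("alias table must have header columns gene_id, symbols, names",
         call. = FALSE)
  }
  tab <- tab[, need]
  tab$gene_id <- normalize_gene_id(tab$gene_id)
  tab
}

#' Annotate enrichment records with gene symbols and names
#'
#' Joins each record's TF identifier against an alias table. Annotation is
#' best-effort: TFs without an alias entry get empty symbol/name fields, and
#' record order is unchanged.
#'
#' @param records data.frame of enrichment records (column `tf_id`), or an
#'   `uptf_enrichment` result.
#' @param aliases Alias data.frame as returned by [load_aliases()].
#' @return Input with `symbols` and `names` columns filled.
#' @export
annotate <- function(records, aliases) {
  if (inherits(records, "uptf_enrichment")) {
    records$records <- annotate(records$records, aliases)
    return(records)
  }
  idx <- match(records$tf_id, aliases$gene_id)
  records$symbols <- ifelse(is.na(idx), "", aliases$symbols[idx])
  records$names <- ifelse(is.na(idx), "", aliases$names[idx])
  records
}
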