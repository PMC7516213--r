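#' Peak-to-gene assignment rule
#'
#' Defines the regulatory interval of a gene: the gene body (optional) plus a
#' fixed window upstream of the transcription start site (TSS), strand-aware.
#' The default — 1,000 bp upstream plus the gene body — is the conventional
#' promoter definition for compact plant genomes and is configurable.
#'
#' @param upstream_window Base pairs upstream of the TSS to include (>= 0).
#' @param include_gene_body Whether the gene body itself counts.
#' @return Object of class `assignment_rule`.
#' @export
assignment_rule <- function(upstream_window = 1000L, include_gene_body = TRUE) {
  upstream_window <- as.integer(upstream_window)
  if (is.na(upstream_window) || upstream_window < 0L) {
    stop("upstream_window must be >= 0", call. = FALSE)
  }
  structure(list(upstream_window = upstream_window,
                 include_gene_body = isTRUE(include_gene_body)),
            class = "assignment_rule")
}

#' Parse a BED3+ peak file
#'
#' Coordinates are kept in BED semantics: 0-based, half-open. `track`,
#' `browser` and `#` lines are skipped; columns beyond the sixth are ignored;
#' the fifth column, when present and numeric, is captured as the peak score.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `score`
#'   (`NA` when absent), one row per peak, input order preserved.
#' @export
parse_bed <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  skip <- !nzchar(trimws(lines)) | grepl("^(#|track\\b|browser\\b)", lines)
  lineno <- which(!skip)
  fields <- strsplit(lines[!skip], "\t", fixed = TRUE)
  n <- length(fields)
  if (!n) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  }
  if (any(lengths(fields) < 3L)) {
    i <- which(lengths(fields) < 3L)[1]
    stop("parse error in ", path, " line ", lineno[i],
         ": BED needs at least 3 tab-separated fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    stop("parse error in ", path, " line ", lineno[bad[1]],
         ": invalid interval (need numeric 0 <= start < end)", call. = FALSE)
  }
  score <- rep(NA_real_, n)
  has5 <- lengths(fields) >= 5L
  score[has5] <- suppressWarnings(as.numeric(vapply(fields[has5], `[`, "", 5L)))
  data.frame(chrom = chrom, start = start, end = end, score = score)
}

#' Parse gene models from a GFF3 annotation
#'
#' Only features of type `gene` are used; the locus ID is taken from the `ID`
#' attribute and normalized. GFF3 1-based inclusive coordinates are preserved.
#' Genes on an unknown strand (`.`) are skipped with a warning; duplicate
#' gene IDs make the annotation ambiguous and are an error.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
parse_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop("parse error in ", path, ": ", conditionMessage(e),
                        call. = FALSE)
                 })
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) & S4Vectors::mcols(gr)$type == "gene"]
  if (!length(gr)) {
    warning("no gene features found in ", path, call. = FALSE)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0), end = integer(0)))
  }
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("parse error in ", path, ": gene feature lacking an ID attribute",
         call. = FALSE)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  known <- strand %in% c("+", "-")
  if (any(!known)) {
    warning(sum(!known), " gene(s) on unknown strand '.' skipped", call. = FALSE)
  }
  gene_id <- normalize_gene_id(as.character(ids))[known]
  if (anyDuplicated(gene_id)) {
    stop("ambiguous annotation: duplicate gene ID ",
         gene_id[duplicated(gene_id)][1], " in ", path, call. = FALSE)
  }
  data.frame(gene_id = gene_id,
             chrom = as.character(GenomicRanges::seqnames(gr))[known],
             strand = strand[known],
             start = BiocGenerics::start(gr)[known],
             end = BiocGenerics::end(gr)[known])
}

# Regulatory interval of each gene in 0-based half-open coordinates:
# gene body (optional) plus `upstream_window` bp 5' of the TSS, strand-aware.
# Returns a data.frame(gene_id, chrom, start0, end0); empty intervals dropped.
regulatory_intervals <- function(genes, rule) {
  w <- rule$upstream_window
  body_s <- genes$start - 1L  # 0-based half-open gene body [start-1, end)
  body_e <- genes$end
  plus <- genes$strand == "+"
  if (rule$include_gene_body) {
    s <- ifelse(plus, body_s - w, body_s)
    e <- ifelse(plus, body_e, body_e + w)
  } else {
    s <- ifelse(plus, body_s - w, body_e)
    e <- ifelse(plus, body_s, body_e + w)
  }
  s <- pmax(s, 0L)
  keep <- s < e
  data.frame(gene_id = genes$gene_id[keep], chrom = genes$chrom[keep],
             start0 = as.integer(s[keep]), end0 = as.integer(e[keep]))
}

#' Assign peaks to genes
#'
#' A gene is assigned when at least one peak overlaps (>= 1 bp) its
#' regulatory interval under the given rule. All interval arithmetic is done
#' in 0-based half-open space (GFF3 coordinates converted on entry); overlap
#' detection uses `GenomicRanges::findOverlaps`. Peaks on chromosomes absent
#' from the annotation are ignored with a message.
#'
#' @param peaks data.frame from [parse_bed()].
#' @param genes data.frame from [parse_gff3_genes()].
#' @param rule An [assignment_rule()].
#' @return `gene_set` of assigned gene IDs.
#' @export
assign_peaks_to_genes <- function(peaks, genes, rule = assignment_rule()) {
  if (!nrow(peaks) || !nrow(genes)) return(gene_set(character(0)))
  reg <- regulatory_intervals(genes, rule)
  if (!nrow(reg)) return(gene_set(character(0)))
  off <- sum(!(peaks$chrom %in% reg$chrom))
  if (off > 0) {
    message(off, " peak(s) on chromosomes absent from the annotation ignored")
  }
  lv <- unique(c(reg$chrom, peaks$chrom))
  # 0-based half-open [s, e) maps to 1-based inclusive [s+1, e]
  pk <- GenomicRanges::GRanges(factor(peaks$chrom, levels = lv),
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  rg <- GenomicRanges::GRanges(factor(reg$chrom, levels = lv),
                               IRanges::IRanges(reg$start0 + 1L, reg$end0))
  hits <- GenomicRanges::findOverlaps(pk, rg, ignore.strand = TRUE)
  gene_set(reg$gene_id[unique(S4Vectors::subjectHits(hits))])
}

#' Build a TF-target database from a directory of per-TF peak files
#'
#' Each BED filename stem is taken as a TF locus ID (normalized); that TF's
#' target set is every gene whose regulatory interval is hit by at least one
#' of its peaks. TFs with no assigned gene are omitted with a warning.
#'
#' @param peak_dir Directory of per-TF BED files (`*.bed`).
#' @param genes Gene models from [parse_gff3_genes()].
#' @param rule An [assignment_rule()].
#' @return A `tf_target_db`.
#' @export
build_database <- function(peak_dir, genes, rule = assignment_rule()) {
  files <- list.files(peak_dir, pattern = "\\.bed$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no BED files found in ", peak_dir, call. = FALSE)
  entries <- list()
  for (f in files) {
    tf <- normalize_gene_id(sub("\\.[^.]*$", "", basename(f)))
    targets <- assign_peaks_to_genes(parse_bed(f), genes, rule)
    if (!length(targets)) {
      warning("TF ", tf, " has no assigned target genes; omitted", call. = FALSE)
      next
    }
    entries[[tf]] <- unclass(targets)
  }
  if (!length(entries)) stop("no TF produced any target genes", call. = FALSE)
  tf_target_db(entries, source_label = peak_dir)
}
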