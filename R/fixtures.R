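#' Generate a synthetic gene universe
#'
#' Produces `N` unique locus IDs in AGI-like syntax (`AT<chrom>G<5 digits>`,
#' chromosomes 1-5) so that identifier-normalization code paths are exercised
#' by synthetic data exactly as by real Arabidopsis input. Order is shuffled
#' under the seed; the set itself is a deterministic function of `N`.
#'
#' @param N Universe size (>= 1).
#' @param seed Integer seed; all fixture generators take an explicit seed so
#'   outputs are byte-reproducible.
#' @return `gene_set` of size `N`.
#' @export
make_universe <- function(N, seed = 1L) {
  if (!is.numeric(N) || length(N) != 1L || N < 1) stop("N must be >= 1", call. = FALSE)
  N <- as.integer(N)
  i <- seq_len(N) - 1L
  ids <- sprintf("AT%dG%05d", i %% 5L + 1L, (i %/% 5L + 1L) * 10L)
  withr::with_seed(seed, ids <- sample(ids))
  gene_set(ids)
}

#' Generate a synthetic TF-target database
#'
#' Each TF's target-set size is a fraction of the universe drawn uniformly
#' from `target_fraction_range`; targets are sampled without replacement from
#' the universe. TF identifiers are drawn from the universe (TFs are genes).
#'
#' @param universe `gene_set` to sample targets from.
#' @param num_tfs Number of TFs (>= 1).
#' @param target_fraction_range Length-2 numeric, `X/N` range per TF; the
#'   upper bound must be positive (empty target sets are disallowed).
#' @param seed Integer seed.
#' @param tf_ids Optional explicit TF identifiers (length `num_tfs`).
#' @return A `tf_target_db`.
#' @export
make_database <- function(universe, num_tfs, target_fraction_range = c(0.05, 0.5),
                          seed = 1L, tf_ids = NULL) {
  if (num_tfs < 1) stop("num_tfs must be >= 1", call. = FALSE)
  r <- target_fraction_range
  if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < 0 || r[2] > 1) {
    stop("target_fraction_range must be an increasing pair within [0, 1]",
         call. = FALSE)
  }
  if (r[2] <= 0) stop("target fraction of 0: empty target sets disallowed", call. = FALSE)
  u <- unclass(universe)
  N <- length(u)
  withr::with_seed(seed, {
    if (is.null(tf_ids)) tf_ids <- sample(u, num_tfs)
    frac <- stats::runif(num_tfs, r[1], r[2])
    X <- pmax(1L, as.integer(round(frac * N)))
    entries <- lapply(X, function(k) sample(u, k))
  })
  names(entries) <- tf_ids
  tf_target_db(entries, source_label = sprintf("synthetic (seed %d)", seed))
}

#' Generate a GOI list, optionally with planted enrichment
#'
#' With `targets` supplied, exactly `round(overlap_fraction * n)` genes are
#' sampled from the target set and the remainder from the rest of the
#' universe, so the planted overlap count `x` is hit exactly — the generator
#' and the analyzer agree by construction. With `targets = NULL` the GOI list
#' is a uniform draw from the universe (a null scenario for calibration).
#'
#' @param universe `gene_set` background.
#' @param n GOI list size.
#' @param seed Integer seed.
#' @param targets Target `gene_set` of the enriched TF, or `NULL` for a null draw.
#' @param overlap_fraction Share of the GOI list drawn from `targets`.
#' @return `gene_set` of size `n`.
#' @export
make_goi <- function(universe, n, seed = 1L, targets = NULL,
                     overlap_fraction = NULL) {
  u <- unclass(universe)
  if (n < 1 || n > length(u)) stop("n must lie in [1, |universe|]", call. = FALSE)
  if (is.null(targets)) {
    withr::with_seed(seed, ids <- sample(u, n))
    return(gene_set(ids))
  }
  if (is.null(overlap_fraction) || overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  }
  tg <- intersect(unclass(targets), u)
  bg <- setdiff(u, tg)
  k <- as.integer(round(overlap_fraction * n))
  if (k > length(tg) || (n - k) > length(bg)) {
    stop("infeasible scenario: requested overlap exceeds available targets ",
         "or background", call. = FALSE)
  }
  withr::with_seed(seed, ids <- c(sample(tg, k), sample(bg, n - k)))
  gene_set(ids)
}

#' Describe a planted-enrichment scenario
#'
#' Bundles the parameters of a synthetic study: a universe of `universe_size`
#' genes, `num_tfs` TFs with target fractions in `target_fraction_range`, and
#' a GOI list of `goi_size` in which a share `planted_overlap_fraction` is
#' drawn from the first TF's targets. The first TF's target fraction is
#' pinned to `enriched_target_fraction` so the planted signal has a known
#' `X`.
#'
#' @param universe_size,goi_size Universe (`N`) and GOI (`n`) sizes.
#' @param num_tfs Total TFs including the enriched one.
#' @param target_fraction_range `X/N` range for the decoy TFs.
#' @param enriched_target_fraction `X/N` of the enriched TF.
#' @param planted_overlap_fraction Share of GOI drawn from enriched targets.
#' @param seed Integer seed.
#' @return Object of class `planted_scenario`.
#' @export
planted_scenario <- function(universe_size = 27206, goi_size = 722,
                             num_tfs = 49, target_fraction_range = c(0.05, 0.5),
                             enriched_target_fraction = 11896 / 27206,
                             planted_overlap_fraction = 0.716, seed = 1L) {
  sc <- list(universe_size = as.integer(universe_size),
             goi_size = as.integer(goi_size), num_tfs = as.integer(num_tfs),
             target_fraction_range = target_fraction_range,
             enriched_target_fraction = enriched_target_fraction,
             planted_overlap_fraction = planted_overlap_fraction,
             seed = as.integer(seed))
  fr <- c(sc$enriched_target_fraction, sc$planted_overlap_fraction,
          sc$target_fraction_range)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]", call. = FALSE)
  if (sc$goi_size > sc$universe_size) {
    stop("goi_size must not exceed universe_size", call. = FALSE)
  }
  if (sc$num_tfs < 1) stop("num_tfs must be >= 1", call. = FALSE)
  structure(sc, class = "planted_scenario")
}

#' Realize a planted scenario as data
#'
#' Generates universe, database and GOI list from a [planted_scenario()].
#' The enriched TF is the first database entry; its overlap with the GOI list
#' equals `round(planted_overlap_fraction * goi_size)` exactly.
#'
#' @param scenario A `planted_scenario`.
#' @return List with `universe`, `db`, `goi`, `enriched_tf` (its locus ID).
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "planted_scenario"))
  s <- scenario$seed
  universe <- make_universe(scenario$universe_size, seed = s)
  f <- scenario$enriched_target_fraction
  db1 <- make_database(universe, 1L, c(f, f), seed = s + 1L)
  enriched_tf <- names(db1$entries)[1]
  if (scenario$num_tfs > 1L) {
    decoys <- make_database(universe, scenario$num_tfs - 1L,
                            scenario$target_fraction_range, seed = s + 2L)
    # regenerate any decoy that collided with the enriched TF id
    if (enriched_tf %in% names(decoys$entries)) {
      names(decoys$entries)[names(decoys$entries) == enriched_tf] <-
        setdiff(unclass(universe), c(enriched_tf, names(decoys$entries)))[1]
    }
    db <- tf_target_db(c(db1$entries, decoys$entries),
                       source_label = sprintf("planted scenario (seed %d)", s))
  } else {
    db <- db1
  }
  goi <- make_goi(universe, scenario$goi_size, seed = s + 3L,
                  targets = gene_set(db$entries[[enriched_tf]]),
                  overlap_fraction = scenario$planted_overlap_fraction)
  list(universe = universe, db = db, goi = goi, enriched_tf = enriched_tf)
}

#' Generate synthetic gene models
#'
#' Lays non-overlapping genes along chromosomes with intergenic gaps wide
#' enough that a default 1 kb promoter never reaches into a neighboring gene
#' body. Strands alternate randomly.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param chroms Chromosome names to distribute genes over.
#' @return data.frame in the layout of [parse_gff3_genes()].
#' @export
make_gene_models <- function(n_genes, seed = 1L, chroms = c("Chr1", "Chr2")) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  ids <- unclass(make_universe(n_genes, seed = seed))
  withr::with_seed(seed, {
    chrom <- sample(chroms, n_genes, replace = TRUE)
    len <- sample(500:3000, n_genes, replace = TRUE)
    gap <- sample(2500:4000, n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  })
  start <- integer(n_genes)
  cursor <- setNames(rep(1L, length(chroms)), chroms)
  for (i in seq_len(n_genes)) {
    start[i] <- cursor[chrom[i]] + gap[i]
    cursor[chrom[i]] <- start[i] + len[i]
  }
  data.frame(gene_id = ids, chrom = chrom, strand = strand,
             start = start, end = start + len - 1L)
}

#' Generate peaks hitting exactly a requested gene set
#'
#' For each gene in `hit_gene_ids`, emits one peak placed inside that gene's
#' regulatory interval under `rule` at a position overlapping no other gene's
#' regulatory interval, so [assign_peaks_to_genes()] recovers exactly the
#' requested set. Errors when the geometry makes that impossible.
#'
#' @param genes Gene models (layout of [parse_gff3_genes()]).
#' @param hit_gene_ids Character vector of gene IDs to hit (subset of `genes`).
#' @param rule An [assignment_rule()].
#' @param seed Integer seed (chooses among feasible peak placements).
#' @return data.frame in the layout of [parse_bed()].
#' @export
make_peak_fixture <- function(genes, hit_gene_ids, rule = assignment_rule(),
                              seed = 1L) {
  hit_gene_ids <- if (length(hit_gene_ids)) normalize_gene_id(hit_gene_ids) else character(0)
  if (!all(hit_gene_ids %in% genes$gene_id)) {
    stop("hit_gene_ids must be a subset of the supplied gene models", call. = FALSE)
  }
  reg <- regulatory_intervals(genes, rule)
  peaks <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0))
  if (!length(hit_gene_ids)) return(peaks)
  withr::with_seed(seed, {
    for (g in hit_gene_ids) {
      i <- match(g, reg$gene_id)
      if (is.na(i)) {
        stop("infeasible geometry: gene ", g, " has an empty regulatory ",
             "interval under this rule", call. = FALSE)
      }
      s <- reg$start0[i]; e <- reg$end0[i]
      w <- min(50L, e - s)
      cand <- seq.int(s, e - w)
      other <- reg[-i, , drop = FALSE]
      other <- other[other$chrom == reg$chrom[i], , drop = FALSE]
      free <- vapply(cand, function(cs) {
        !any(cs < other$end0 & other$start0 < cs + w)
      }, logical(1))
      if (!any(free)) {
        stop("infeasible geometry: no peak position hits only ", g, call. = FALSE)
      }
      cs <- if (sum(free) == 1L) cand[free] else sample(cand[free], 1L)
      peaks <- rbind(peaks, data.frame(chrom = reg$chrom[i], start = cs,
                                       end = cs + w, score = NA_real_))
    }
  })
  peaks
}

#' Write a gene list file
#' @param ids Character vector or `gene_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(unclass(ids), path)
  invisible(path)
}

#' Write peaks as BED3 (+score)
#' @param peaks data.frame in the layout of [parse_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  if (nrow(peaks) && any(!is.na(peaks$score))) {
    sc <- ifelse(is.na(peaks$score), "0", format(peaks$score, trim = TRUE))
    writeLines(paste(peaks$chrom, peaks$start, peaks$end, ".", sc, sep = "\t"),
               path)
  } else {
    writeLines(paste(peaks$chrom, peaks$start, peaks$end, sep = "\t"), path)
  }
  invisible(path)
}

#' Write gene models as GFF3
#' @param genes data.frame in the layout of [parse_gff3_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(genes$chrom, "uptf", "gene", genes$start, genes$end, ".",
                   genes$strand, ".", paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
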