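#' Upper-tail hypergeometric test of target over-representation
#'
#' Probability of observing at least `x` TF-target genes among `n` sampled
#' genes (the GOI list) when `X` of the `N` universe genes are targets,
#' sampling without replacement: `P(K >= x)` for `K ~ Hypergeom(N, X, n)`.
#' Computed via the survival function of `stats::phyper`, numerically valid
#' down to the smallest representable doubles (~1e-300).
#'
#' @param x Overlap count, number of GOI genes that are targets.
#' @param n GOI list size.
#' @param X TF target-set size within the universe.
#' @param N Universe size.
#' @return Upper-tail p-value(s); arguments recycle as in [stats::phyper()].
#' @export
hypergeom_upper_tail <- function(x, n, X, N) {
  check_counts(x, n, X, N)
  stats::phyper(x - 1, X, N - X, n, lower.tail = FALSE)
}

#' Upper-tail binomial test of target over-representation
#'
#' Sampling-with-replacement analogue of [hypergeom_upper_tail()]:
#' `P(B >= x)` for `B ~ Binomial(n, X/N)`.
#'
#' @inheritParams hypergeom_upper_tail
#' @return Upper-tail p-value(s).
#' @export
binom_upper_tail <- function(x, n, X, N) {
  check_counts(x, n, X, N)
  stats::pbinom(x - 1, n, X / N, lower.tail = FALSE)
}

check_counts <- function(x, n, X, N) {
  ok <- is.finite(x) & is.finite(n) & is.finite(X) & is.finite(N) &
    x >= 0 & x <= n & n <= N & X >= 0 & X <= N
  if (!all(ok)) {
    stop("invalid counts: need 0 <= x <= n <= N and 0 <= X <= N", call. = FALSE)
  }
  invisible(TRUE)
}

#' Bonferroni family-wise error correction
#'
#' Adjusted p-value `min(1, p * m)`, controlling the family-wise error rate
#' when `m` hypotheses are tested at level `alpha/m`. `m` may exceed the
#' length of `p` when untested hypotheses count toward the family.
#'
#' @param p Vector of raw p-values in (0, 1].
#' @param m Number of tests performed (defaults to `length(p)`).
#' @return Adjusted p-values, input order preserved.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  check_adjust_args(p, m)
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Benjamini-Hochberg step-up false discovery rate correction
#'
#' With p-values sorted ascending and `k` the rank, the raw step-up value is
#' `p_(k) * m / k`; monotonicity is enforced by a running minimum from the
#' largest rank downward and the result capped at 1, returned in input order.
#' This is the adjusted-p formulation of testing rank `k` at level
#' `k * alpha / m`.
#'
#' @inheritParams bonferroni_adjust
#' @return Adjusted p-values, input order preserved.
#' @export
bh_adjust <- function(p, m = length(p)) {
  check_adjust_args(p, m)
  stats::p.adjust(p, method = "BH", n = m)
}

check_adjust_args <- function(p, m) {
  if (length(m) != 1L || is.na(m) || m < 1) stop("m must be >= 1", call. = FALSE)
  if (m < length(p)) stop("m must be at least length(p)", call. = FALSE)
  if (length(p) && (any(!is.finite(p)) || any(p <= 0 | p > 1))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Count GOI/target overlap
#'
#' @param goi,targets Gene sets (normalized ID vectors).
#' @return `x = |goi` \eqn{\cap} `targets|`.
#' @export
count_overlap <- function(goi, targets) {
  sum(unclass(goi) %in% unclass(targets))
}

#' Enrichment configuration
#'
#' @param test `"hypergeometric"` (sampling without replacement; the default,
#'   appropriate for drawing a gene list from a finite genome) or
#'   `"binomial"` (with replacement).
#' @param correction `"fdr_bh"` (Benjamini-Hochberg, default), `"bonferroni"`,
#'   or `"none"`.
#' @param alpha Significance level in (0, 1], default 0.05.
#' @param m Number of tests for the correction; `NULL` (default) means the
#'   number of TFs actually tested.
#' @return Object of class `enrichment_config`.
#' @export
enrichment_config <- function(test = c("hypergeometric", "binomial"),
                              correction = c("fdr_bh", "bonferroni", "none"),
                              alpha = 0.05, m = NULL) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(m) && (length(m) != 1L || m < 1)) stop("m must be >= 1", call. = FALSE)
  structure(list(test = test, correction = correction, alpha = alpha, m = m),
            class = "enrichment_config")
}

#' Run upstream-TF over-representation analysis
#'
#' For every TF in the database, counts the overlap `x` between the GOI list
#' (size `n`) and that TF's target set restricted to the universe (size `X`
#' out of `N`), computes the configured upper-tail p-value, applies the
#' configured multiple-testing correction with `m` equal to the number of TFs
#' tested (unless overridden in the config), and returns records ranked by
#' raw p-value (ties broken by TF ID). TFs with zero overlap are retained
#' (`p = 1`) so the record count and `m` stay interpretable; TFs whose target
#' set is disjoint from the universe (`X = 0`) are dropped with a warning and
#' do not count toward the default `m`.
#'
#' @param goi `gene_set` of genes of interest (must be within `universe`).
#' @param db A `tf_target_db`.
#' @param universe `gene_set` background population.
#' @param config An [enrichment_config()].
#' @return Object of class `uptf_enrichment`: list with `records` (data.frame
#'   with columns `tf_id, x, n, observed_pct, X, N, expected_pct, p_raw,
#'   p_adj, rank, symbols, names`), `config`, `n`, `N`, `m`.
#' @export
run_enrichment <- function(goi, db, universe, config = enrichment_config()) {
  stopifnot(inherits(db, "tf_target_db"))
  goi <- unclass(goi)
  universe <- unclass(universe)
  if (!length(goi)) stop("empty GOI set", call. = FALSE)
  if (tf_count(db) == 0L) stop("empty database", call. = FALSE)
  outside <- setdiff(goi, universe)
  if (length(outside)) {
    stop(length(outside), " GOI gene(s) are not in the universe; ",
         "filter the GOI list against the universe first", call. = FALSE)
  }
  n <- length(goi)
  N <- length(universe)

  targets <- lapply(db$entries, function(tg) tg[tg %in% universe])
  X <- lengths(targets)
  if (any(X == 0L)) {
    warning(sum(X == 0L), " TF(s) with no targets in the universe dropped ",
            "from testing", call. = FALSE)
    targets <- targets[X > 0L]
    X <- X[X > 0L]
  }
  if (!length(targets)) stop("no TF has targets within the universe", call. = FALSE)
  x <- vapply(targets, function(tg) sum(goi %in% tg), integer(1))

  p_raw <- switch(config$test,
                  hypergeometric = hypergeom_upper_tail(x, n, X, N),
                  binomial = binom_upper_tail(x, n, X, N))
  m <- if (is.null(config$m)) length(p_raw) else as.integer(config$m)
  p_adj <- switch(config$correction,
                  fdr_bh = bh_adjust(p_raw, m),
                  bonferroni = bonferroni_adjust(p_raw, m),
                  none = p_raw)

  rec <- data.frame(tf_id = names(targets), x = as.integer(x), n = n,
                    observed_pct = 100 * x / n,
                    X = as.integer(X), N = N,
                    expected_pct = 100 * X / N,
                    p_raw = p_raw, p_adj = p_adj,
                    row.names = NULL)
  ord <- order(rec$p_raw, rec$tf_id, method = "radix")
  rec <- rec[ord, , drop = FALSE]
  rec$rank <- seq_len(nrow(rec))
  rec$symbols <- ""
  rec$names <- ""
  rownames(rec) <- NULL
  structure(list(records = rec, config = config, n = n, N = N, m = m),
            class = "uptf_enrichment")
}

#' @export
print.uptf_enrichment <- function(x, ...) {
  cat("<uptf_enrichment> ", nrow(x$records), " TFs tested (",
      x$config$test, ", ", x$config$correction, ", m = ", x$m,
      "); n = ", x$n, ", N = ", x$N, "\n", sep = "")
  top <- utils::head(x$records, 5)
  top$observed_pct <- sprintf("%.1f", top$observed_pct)
  top$expected_pct <- sprintf("%.1f", top$expected_pct)
  top$p_raw <- sprintf("%.3g", top$p_raw)
  top$p_adj <- sprintf("%.3g", top$p_adj)
  print(top[, c("rank", "tf_id", "x", "n", "observed_pct", "X", "N",
                "expected_pct", "p_raw", "p_adj")], row.names = FALSE)
  if (nrow(x$records) > 5) cat("  ... ", nrow(x$records) - 5, " more\n", sep = "")
  invisible(x)
}

#' Keep significant records
#'
#' Filters an enrichment result to records with `p_adj <= alpha`. Rank values
#' are preserved from the unfiltered ranking.
#'
#' @param result An `uptf_enrichment`.
#' @param alpha Significance threshold.
#' @return Filtered `uptf_enrichment`.
#' @export
filter_significant <- function(result, alpha = result$config$alpha) {
  stopifnot(inherits(result, "uptf_enrichment"))
  result$records <- result$records[result$records$p_adj <= alpha, , drop = FALSE]
  rownames(result$records) <- NULL
  result
}

#' Write an enrichment result as TSV
#'
#' One row per TF with header columns `TF_ID, x, n, observed_pct, X, N,
#' expected_pct, pvalue, adj_pvalue, gene_symbols, gene_names`. Percentages
#' are printed to one decimal and p-values to three significant figures in
#' scientific notation; full-precision values live on the result object.
#'
#' @param result An `uptf_enrichment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  stopifnot(inherits(result, "uptf_enrichment"))
  r <- result$records
  out <- data.frame(TF_ID = r$tf_id, x = r$x, n = r$n,
                    observed_pct = sprintf("%.1f", r$observed_pct),
                    X = r$X, N = r$N,
                    expected_pct = sprintf("%.1f", r$expected_pct),
                    pvalue = sprintf("%.3g", r$p_raw),
                    adj_pvalue = sprintf("%.3g", r$p_adj),
                    gene_symbols = r$symbols, gene_names = r$names)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
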