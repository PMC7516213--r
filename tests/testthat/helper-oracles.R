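# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: tail probabilities by explicit combinatorial
# enumeration (never phyper/pbinom), peak assignment by pairwise interval
# intersection in plain 0-based arithmetic (never GenomicRanges).

# P(K >= x) for K ~ Hypergeom(N, X, n) by summing choose-products.
# choose() returns 0 outside the support, so the naive sum is exact.
hyper_tail_enum <- function(x, n, X, N) {
  if (x > min(n, X)) return(0)
  k <- seq.int(x, min(n, X))
  sum(choose(X, k) * choose(N - X, n - k)) / choose(N, n)
}

# Brute-force peak-to-gene assignment: tests every (peak, gene) pair.
# Genes are 1-based inclusive; peaks 0-based half-open; all comparison in
# 0-based half-open space per the documented rule.
assign_oracle <- function(peaks, genes, rule) {
  overlaps <- function(s1, e1, s2, e2) max(s1, s2) < min(e1, e2)
  hit <- logical(nrow(genes))
  w <- rule$upstream_window
  for (gi in seq_len(nrow(genes))) {
    bs <- genes$start[gi] - 1L; be <- genes$end[gi]
    if (genes$strand[gi] == "+") {
      ps <- max(0L, bs - w); pe <- bs
    } else {
      ps <- be; pe <- be + w
    }
    for (pi in seq_len(nrow(peaks))) {
      if (peaks$chrom[pi] != genes$chrom[gi]) next
      s <- peaks$start[pi]; e <- peaks$end[pi]
      if ((rule$include_gene_body && overlaps(s, e, bs, be)) ||
          (w > 0L && overlaps(s, e, ps, pe))) {
        hit[gi] <- TRUE
        break
      }
    }
  }
  sort(genes$gene_id[hit])
}

# Published summary statistics used as fixed expectations: one row per TF,
# columns x, X, observed/expected percentages, raw and corrected p-values.
# GOI sizes: LHY-bound set n = 722 (BH-corrected), cca1 lhy DEGs n = 824
# (BH), auxin up-regulated n = 789 (Bonferroni), auxin down-regulated
# n = 659 (Bonferroni); universe N = 27206, m = 349 TFs in all runs.
lhy_table <- data.frame(
  x = c(287L, 426L, 275L, 318L, 517L, 274L, 327L, 619L, 585L, 357L, 381L,
        224L, 336L, 178L, 339L, 579L, 165L, 132L, 269L, 137L),
  X = c(4110L, 8276L, 3936L, 5255L, 11896L, 4188L, 5764L, 16878L, 15403L,
        6979L, 7781L, 3280L, 6440L, 2268L, 6654L, 15664L, 2112L, 1469L,
        4944L, 1630L),
  obs = c(39.8, 59.0, 38.1, 44.0, 71.6, 38.0, 45.3, 85.7, 81.0, 49.4, 52.8,
          31.0, 46.5, 24.7, 47.0, 80.2, 22.9, 18.3, 37.3, 19.0),
  exp = c(15.1, 30.4, 14.5, 19.3, 43.7, 15.4, 21.2, 62.0, 56.6, 25.7, 28.6,
          12.1, 23.7, 8.3, 24.5, 57.6, 7.8, 5.4, 18.2, 6.0),
  p = c(5.84e-60, 2.59e-58, 6.43e-57, 2.09e-53, 3.01e-53, 8.13e-51,
        7.54e-49, 3.63e-46, 6.78e-45, 6.05e-44, 1.94e-43, 6.20e-43,
        2.94e-42, 4.60e-41, 1.88e-40, 6.91e-39, 1.45e-37, 7.86e-36,
        1.02e-34, 3.89e-34),
  padj = c(2.04e-57, 4.52e-56, 7.48e-55, 1.82e-51, 2.10e-51, 4.73e-49,
           3.76e-47, 1.58e-44, 2.63e-43, 2.11e-42, 6.15e-42, 1.80e-41,
           7.88e-41, 1.15e-39, 4.38e-39, 1.51e-37, 2.98e-36, 1.52e-34,
           1.88e-33, 6.79e-33))

cca1lhy_table <- data.frame(
  x = c(267L, 329L, 196L, 374L, 479L, 275L, 344L, 250L, 610L, 194L, 560L,
        297L, 126L, 278L, 119L, 198L, 97L, 559L, 127L, 82L),
  X = c(4110L, 6654L, 3280L, 8276L, 11896L, 5764L, 7781L, 5255L, 16878L,
        3936L, 15403L, 6979L, 2268L, 6440L, 2112L, 4188L, 1630L, 15664L,
        2485L, 1469L),
  p = c(9.65e-37, 1.75e-23, 1.71e-21, 3.27e-20, 2.47e-17, 1.20e-16,
        1.75e-16, 9.54e-15, 9.71e-14, 1.39e-12, 8.36e-12, 1.37e-11,
        1.78e-11, 2.02e-11, 2.95e-11, 3.38e-11, 1.44e-10, 5.25e-10,
        2.97e-9, 7.24e-8),
  padj = c(3.37e-34, 3.05e-21, 1.98e-19, 2.85e-18, 1.72e-15, 6.99e-15,
           8.70e-15, 4.16e-13, 3.76e-12, 4.86e-11, 2.65e-10, 3.97e-10,
           4.77e-10, 5.03e-10, 6.87e-10, 7.38e-10, 2.96e-9, 1.02e-8,
           5.46e-8, 1.26e-6))

auxin_up_table <- data.frame(
  x = c(172L, 303L, 215L, 49L, 33L, 221L, 136L, 269L, 83L, 249L, 42L, 102L,
        179L, 231L, 97L, 181L, 205L, 161L, 76L, 31L),
  X = c(2924L, 6835L, 4503L, 563L, 363L, 5446L, 3086L, 7322L, 1732L, 6794L,
        751L, 2422L, 4758L, 6448L, 2334L, 4895L, 5657L, 4281L, 1742L, 540L),
  obs = c(21.8, 38.4, 27.2, 6.2, 4.2, 28.0, 17.2, 34.1, 10.5, 31.6, 5.3,
          12.9, 22.7, 29.3, 12.3, 22.9, 26.0, 20.4, 9.6, 3.9),
  exp = c(10.7, 25.1, 16.6, 2.1, 1.3, 20.0, 11.3, 26.9, 6.4, 25.0, 2.8, 8.9,
          17.5, 23.7, 8.6, 18.0, 20.8, 15.7, 6.4, 2.0),
  p = c(5.21e-20, 4.78e-17, 1.11e-14, 9.88e-12, 8.56e-9, 2.85e-8, 3.89e-7,
        3.87e-6, 4.80e-6, 1.36e-5, 4.44e-5, 8.38e-5, 9.38e-5, 1.49e-4,
        2.04e-4, 2.13e-4, 2.21e-4, 2.38e-4, 2.54e-4, 2.75e-4),
  padj = c(1.82e-17, 1.67e-14, 3.88e-12, 3.45e-9, 2.99e-6, 9.94e-6,
           1.36e-4, 1.35e-3, 1.68e-3, 4.75e-3, 1.55e-2, 2.93e-2, 3.28e-2,
           5.20e-2, 7.11e-2, 7.44e-2, 7.72e-2, 8.32e-2, 8.87e-2, 9.60e-2))

auxin_down_table <- data.frame(
  x = c(238L, 289L, 451L, 460L, 283L, 381L, 244L, 393L, 169L, 422L),
  X = c(5764L, 7781L, 14295L, 14742L, 7658L, 11605L, 6440L, 12176L, 3936L,
        13486L),
  obs = c(36.1, 43.9, 68.4, 69.8, 42.9, 57.8, 37.0, 59.6, 25.6, 64.0),
  exp = c(21.2, 28.6, 52.5, 54.2, 28.1, 42.7, 23.7, 44.8, 14.5, 49.6),
  p = c(3.78e-19, 2.33e-17, 3.52e-17, 8.29e-17, 1.44e-16, 1.77e-15,
        5.41e-15, 6.05e-15, 1.84e-14, 2.64e-14),
  padj = c(1.32e-16, 8.12e-15, 1.23e-14, 2.89e-14, 5.03e-14, 6.17e-13,
           1.89e-12, 2.11e-12, 6.42e-12, 9.22e-12))

UNIVERSE_N <- 27206L
TF_FAMILY_M <- 349L

# Small toy inputs written to a temp dir; returns the paths.
write_toy_inputs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  u <- make_universe(200, seed = 11)
  db <- make_database(u, 4, c(0.2, 0.4), seed = 12)
  goi <- make_goi(u, 40, seed = 13,
                  targets = gene_set(db$entries[[1]]), overlap_fraction = 0.7)
  paths <- list(universe = file.path(dir, "universe.txt"),
                db = file.path(dir, "db.tsv"),
                goi = file.path(dir, "goi.txt"), dir = dir)
  write_gene_list(u, paths$universe)
  write_database(db, paths$db)
  write_gene_list(goi, paths$goi)
  paths
}
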