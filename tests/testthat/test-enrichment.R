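test_that("hypergeometric upper tail matches enumeration on small cases", {
  expect_equal(hypergeom_upper_tail(3, 4, 5, 10), 11 / 42, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(4, 4, 4, 10), 1 / choose(10, 4),
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(0, 7, 3, 20), 1)
  expect_error(hypergeom_upper_tail(5, 4, 3, 10), "invalid counts")
  expect_error(hypergeom_upper_tail(1, 4, 11, 10), "invalid counts")

  withr::with_seed(7, {
    for (i in 1:200) {
      N <- sample(2:50, 1); n <- sample(0:N, 1); X <- sample(0:N, 1)
      x <- sample(0:n, 1)
      expect_equal(hypergeom_upper_tail(x, n, X, N),
                   hyper_tail_enum(x, n, X, N), tolerance = 1e-10)
    }
  })
})

test_that("binomial upper tail matches closed forms", {
  expect_equal(binom_upper_tail(0, 5, 100, 1000), 1)
  expect_equal(binom_upper_tail(2, 2, 5, 10), 0.25, tolerance = 1e-12)
  expect_equal(binom_upper_tail(1, 2, 5, 10), 0.75, tolerance = 1e-12)
})

test_that("both tests are strictly decreasing in the overlap count", {
  for (case in list(c(40, 12, 100), c(722, 4110, 27206), c(10, 5, 20))) {
    n <- case[1]; X <- case[2]; N <- case[3]
    xs <- max(0, n - (N - X)):min(n, X)  # the support of the overlap count
    # strict decrease except where doubles saturate: ties allowed only at
    # exactly 1 (tail mass indistinguishable from total) or underflow to 0
    strict_dec <- function(p) {
      all(diff(p) < 0 | p[-length(p)] == 0 | p[-1] == 1)
    }
    expect_true(strict_dec(hypergeom_upper_tail(xs, n, X, N)))
    expect_true(strict_dec(binom_upper_tail(xs, n, X, N)))
  }
})

test_that("hypergeometric mass sums to one over the support", {
  withr::with_seed(3, {
    for (i in 1:20) {
      N <- sample(10:1000, 1); n <- sample(1:N, 1); X <- sample(1:N, 1)
      xs <- max(0, n - (N - X)):min(n, X)
      mass <- dhyper(xs, X, N - X, n)
      expect_equal(sum(mass), 1, tolerance = 1e-12)
      # tail at the support minimum is the whole mass
      expect_equal(hypergeom_upper_tail(xs[1], n, X, N), 1, tolerance = 1e-12)
    }
  })
})

test_that("corrections follow the step-up / FWER rules with external m", {
  expect_equal(bonferroni_adjust(0.5, m = 3), 1)
  expect_equal(bonferroni_adjust(3.78e-19, m = 349), 1.32e-16, tolerance = 5e-3)
  expect_equal(bonferroni_adjust(4.78e-17, m = 349), 1.67e-14, tolerance = 5e-3)

  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  # input order is restored after the sorted step-up pass
  expect_equal(bh_adjust(c(0.04, 0.01)), c(0.04, 0.02))

  expect_error(bh_adjust(c(0.1, 0.2), m = 0), "m must be")
  expect_error(bonferroni_adjust(c(0.1, 1.2)), "0, 1")

  withr::with_seed(8, {
    for (i in 1:20) {
      p <- runif(sample(1:30, 1))
      m <- length(p) + sample(0:300, 1)
      bon <- bonferroni_adjust(p, m)
      bh <- bh_adjust(p, m)
      expect_equal(bon, pmin(1, p * m))
      expect_true(all(bon >= p))
      expect_true(all(bh <= bon + 1e-15))
      expect_true(all(diff(bh[order(p)]) >= -1e-15))
      expect_true(all(bh <= 1))
    }
  })
})

test_that("overlap counting is plain set intersection", {
  expect_equal(count_overlap(gene_set(c("g1", "g2", "g3")),
                             gene_set(c("g2", "g3", "g4"))), 2L)
  expect_equal(count_overlap(gene_set(c("a1", "a2")), gene_set(c("b1"))), 0L)
  g <- gene_set(c("g1", "g2"))
  expect_equal(count_overlap(g, gene_set(c("g1", "g2", "g3"))), length(g))
})

test_that("a full run chains counting, testing and ranking as hand-derived", {
  universe <- gene_set(sprintf("G%02d", 1:10))
  db <- tf_target_db(list(TFA = sprintf("G%02d", 1:5)))
  goi <- gene_set(c("G01", "G02", "G03", "G06"))
  res <- run_enrichment(goi, db, universe,
                        enrichment_config(correction = "none"))
  r <- res$records
  expect_equal(nrow(r), 1L)
  expect_equal(r$x, 3L)
  expect_equal(r$n, 4L)
  expect_equal(r$X, 5L)
  expect_equal(r$N, 10L)
  expect_equal(r$p_raw, 11 / 42, tolerance = 1e-12)
  expect_equal(r$p_adj, r$p_raw)
  expect_equal(r$observed_pct, 75)
  expect_equal(r$expected_pct, 50)
})

test_that("zero-overlap TFs are retained, X=0 TFs dropped, ties broken by TF ID", {
  universe <- gene_set(sprintf("G%02d", 1:20))
  db <- tf_target_db(list(
    TFB = sprintf("G%02d", 1:4), TFA = sprintf("G%02d", 1:4),
    TFZ = sprintf("G%02d", 15:18), TFOUT = c("H1", "H2")))
  goi <- gene_set(sprintf("G%02d", 1:5))
  expect_warning(
    res <- run_enrichment(goi, db, universe,
                          enrichment_config(correction = "bonferroni")),
    "dropped")
  r <- res$records
  expect_equal(nrow(r), 3L)      # TFOUT gone
  expect_equal(res$m, 3L)        # and not counted toward m
  expect_equal(r$tf_id[1:2], c("TFA", "TFB"))  # identical p, lexicographic
  expect_equal(r$rank, 1:3)
  expect_equal(r$p_raw[r$tf_id == "TFZ"], 1)   # x = 0 retained with p = 1
  # records sorted ascending by p_raw
  expect_true(!is.unsorted(r$p_raw))
})

test_that("GOI genes outside the universe are refused at run time", {
  universe <- gene_set(c("G1", "G2"))
  db <- tf_target_db(list(TFA = c("G1")))
  expect_error(run_enrichment(gene_set(c("G1", "ZZ")), db, universe),
               "not in the universe")
})

test_that("significance filtering keeps ranks from the unfiltered list", {
  universe <- make_universe(500, seed = 1)
  db <- make_database(universe, 8, c(0.1, 0.3), seed = 2)
  goi <- make_goi(universe, 60, seed = 3,
                  targets = gene_set(db$entries[[1]]), overlap_fraction = 0.8)
  res <- run_enrichment(goi, db, universe)
  all_kept <- filter_significant(res, alpha = 1.0)
  expect_identical(all_kept$records, res$records)
  sig <- filter_significant(res, alpha = 0.05)
  expect_true(all(sig$records$p_adj <= 0.05))
  expect_true(all(sig$records$rank %in% res$records$rank))
  none <- filter_significant(res, alpha = 0)
  expect_equal(nrow(none$records), 0L)
})

test_that("result TSV carries the documented header and formatted columns", {
  paths <- write_toy_inputs()
  universe <- load_gene_list(paths$universe)$genes
  goi <- load_gene_list(paths$goi, universe = universe)$genes
  db <- load_database(paths$db)
  res <- run_enrichment(goi, db, universe)
  out <- file.path(paths$dir, "result.tsv")
  write_enrichment(res, out)
  tab <- read.delim(out, colClasses = "character")
  expect_identical(names(tab),
                   c("TF_ID", "x", "n", "observed_pct", "X", "N",
                     "expected_pct", "pvalue", "adj_pvalue", "gene_symbols",
                     "gene_names"))
  expect_equal(nrow(tab), nrow(res$records))
  expect_true(all(grepl("^[0-9]+\\.[0-9]$", tab$observed_pct)))
})
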