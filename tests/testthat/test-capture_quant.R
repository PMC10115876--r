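make_capture_fixture <- function(freqs, depth, error_rate, seed,
                                 strands = NULL) {
  spec <- test_spec()
  n <- length(freqs)
  if (is.null(strands)) strands <- rep("+", n)
  gg <- gen_genome_with_offtargets(
    max(6000, (n + 1) * 1500), spec,
    data.frame(mismatch_count = rep(0L, n), strand = strands), seed = seed)
  sites <- enumerate_offtargets(gg$genome, spec, 0)
  bam <- gen_capture_bam(sites, freqs, depth = depth,
                         error_rate = error_rate, seed = seed + 100,
                         genome = gg$genome, spec = spec,
                         out_dir = tempfile())
  list(spec = spec, genome = gg$genome, sites = sites, bam = bam)
}

test_that("an unedited error-free pileup is all reference A", {
  fx <- make_capture_fixture(0, depth = 100, error_rate = 0, seed = 1)
  pu <- pileup_deamination(fx$bam$bam, fx$sites[1, ], fx$spec)
  a_pos <- pu$editable
  expect_true(all(pu$depth == 100))
  expect_true(all(pu$count_A[a_pos] == 100))
  expect_true(all(pu$count_G[a_pos] == 0))
  expect_true(all(pu$freq[a_pos] == 0))
})

test_that("pileup counts conserve depth and recover planted editing", {
  fx <- make_capture_fixture(0.5, depth = 5000, error_rate = 0, seed = 2)
  pu <- pileup_deamination(fx$bam$bam, fx$sites[1, ], fx$spec)
  expect_true(all(pu$count_A + pu$count_G + pu$count_other == pu$depth))
  n_edited <- fx$bam$truth$sites$n_edited[1]
  # at error 0, G counts at editable positions equal planted edited reads
  expect_true(all(pu$count_G[pu$editable] == n_edited))
  # and the frequency is within 3 binomial SE of the planted 0.5
  se <- sqrt(0.5 * 0.5 / 5000)
  expect_true(all(abs(pu$freq[pu$editable] - 0.5) <= 3 * se))
})

test_that("minus-strand sites yield the same planted frequency as plus", {
  fx_p <- make_capture_fixture(0.2, depth = 3000, error_rate = 0, seed = 3,
                               strands = "+")
  fx_m <- make_capture_fixture(0.2, depth = 3000, error_rate = 0, seed = 3,
                               strands = "-")
  pu_p <- pileup_deamination(fx_p$bam$bam, fx_p$sites[1, ], fx_p$spec)
  pu_m <- pileup_deamination(fx_m$bam$bam, fx_m$sites[1, ], fx_m$spec)
  # same seed, same depth: identical planted edited-read counts
  expect_identical(fx_p$bam$truth$sites$n_edited,
                   fx_m$bam$truth$sites$n_edited)
  expect_identical(pu_p$count_G[pu_p$editable],
                   pu_m$count_G[pu_m$editable])
})

test_that("a missing contig is rejected by name", {
  fx <- make_capture_fixture(0, depth = 50, error_rate = 0, seed = 4)
  bad <- fx$sites[1, ]
  bad$contig <- "chrMissing"
  expect_error(pileup_deamination(fx$bam$bam, bad, fx$spec), "chrMissing")
})

test_that("identical edited and control tables are never called", {
  spec <- test_spec()
  counts <- with_seed(5, gen_capture_counts(spec, spec$spacer, 0.01, 10000))
  res <- call_offtarget_editing(counts, counts)
  expect_false(res$called)
})

test_that("site p-values match the exact hypergeometric oracle", {
  mk <- function(g_e, n_e, g_c, n_c) {
    e <- data.frame(position = 5L, editable = TRUE, depth = n_e,
                    count_A = n_e - g_e, count_G = g_e, count_other = 0L,
                    freq = g_e / n_e)
    c <- data.frame(position = 5L, editable = TRUE, depth = n_c,
                    count_A = n_c - g_c, count_G = g_c, count_other = 0L,
                    freq = g_c / n_c)
    list(e = e, c = c)
  }
  # the worked deep-capture example
  tb <- mk(10, 50000, 5, 50000)
  res <- call_offtarget_editing(tb$e, tb$c)
  expect_equal(res$p_value, oracle_fisher_greater(10, 50000, 5, 50000),
               tolerance = 1e-10)
  # random small tables, against both the enumeration oracle and fisher.test
  set.seed(6)
  for (i in 1:20) {
    n_e <- sample(50:500, 1); n_c <- sample(50:500, 1)
    g_e <- rbinom(1, n_e, 0.1); g_c <- rbinom(1, n_c, 0.05)
    tb <- mk(g_e, n_e, g_c, n_c)
    res <- call_offtarget_editing(tb$e, tb$c)
    expect_equal(res$p_value, oracle_fisher_greater(g_e, n_e, g_c, n_c),
                 tolerance = 1e-10)
    ft <- stats::fisher.test(matrix(c(g_e, n_e - g_e, g_c, n_c - g_c), 2,
                                    byrow = TRUE),
                             alternative = "greater")
    expect_equal(res$p_value, ft$p.value, tolerance = 1e-8)
  }
})

test_that("planted high-level editing over background error is called", {
  spec <- test_spec()
  res <- with_seed(7, {
    e <- gen_capture_counts(spec, spec$spacer, 0.01, 50000,
                            error_rate = 0.003)
    c <- gen_capture_counts(spec, spec$spacer, 0, 50000,
                            error_rate = 0.003)
    call_offtarget_editing(e, c)
  })
  expect_true(res$called)
  expect_lt(res$p_value, 1e-10)
})

test_that("all-zero depth is flagged uncallable", {
  spec <- test_spec()
  z <- data.frame(position = 4:8, editable = TRUE, depth = 0L,
                  count_A = 0L, count_G = 0L, count_other = 0L,
                  freq = NA_real_)
  res <- call_offtarget_editing(z, z)
  expect_true(res$uncallable)
  expect_false(res$called)
})

test_that("BH adjustment matches the step-up oracle and clips to [0,1]", {
  expect_identical(bh_adjust(0.01), 0.01)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:5) {
    p <- runif(sample(2:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= 0 & adj <= 1))
    expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("capture summaries aggregate calls and depth", {
  expect_identical(summarize_capture(NULL)$n_called, 0L)
  s0 <- summarize_capture(data.frame(p_value = numeric(0),
                                     max_deam_freq = numeric(0),
                                     mean_depth = numeric(0),
                                     called = logical(0)))
  expect_true(is.na(s0$mean_depth))
  df <- data.frame(p_value = c(1e-5, 1e-4, 0.5, 0.9, 0.2),
                   max_deam_freq = c(0.001, 0.003, 0.0001, 0.0002, 0.0001),
                   mean_depth = rep(1000, 5),
                   called = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  s <- summarize_capture(df)
  expect_identical(s$n_called, 2L)
  expect_identical(s$median_called_freq, 0.002)
  expect_identical(s$mean_depth, 1000)
})

test_that("end-to-end capture calls recover strongly edited sites", {
  freqs <- c(0.05, 0, 0.02, 0, 0)
  fx <- make_capture_fixture(freqs, depth = 3000, error_rate = 0.001,
                             seed = 9)
  ctrl <- gen_capture_bam(fx$sites, rep(0, 5), depth = 3000,
                          error_rate = 0.001, seed = 999,
                          genome = fx$genome, spec = fx$spec,
                          out_dir = tempfile())
  ed <- lapply(seq_len(nrow(fx$sites)), function(i)
    pileup_deamination(fx$bam$bam, fx$sites[i, ], fx$spec))
  co <- lapply(seq_len(nrow(fx$sites)), function(i)
    pileup_deamination(ctrl$bam, fx$sites[i, ], fx$spec))
  calls <- call_offtarget_sites(ed, co, alpha = 0.05)
  expect_identical(calls$called, freqs > 0)
  out <- write_capture_results(calls, fx$sites,
                               tsv_path = tempfile(fileext = ".tsv"),
                               vcf_path = tempfile(fileext = ".vcf"))
  expect_identical(sum(out$called), 2L)
})
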