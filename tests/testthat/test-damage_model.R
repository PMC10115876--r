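small_training_run <- function(n = 1200, seed = 7) {
  ds <- gen_accessibility_dataset(n = n, seed = seed)
  idx <- with_seed(seed + 1, sample(n))
  split <- floor(0.75 * n)
  list(ds = ds, train = idx[1:split], test = idx[(split + 1):n])
}

test_that("apply_edit converts only the requested window adenines", {
  spec <- test_spec()
  ctx <- paste0(strrep("C", 40), spec$spacer, "TGG", strrep("C", 37))
  # empty edit set is the identity
  expect_identical(apply_edit(ctx, spec, integer(0), 40L), ctx)
  # A5 -> G at the mapped offset on the plus strand
  ed <- apply_edit(ctx, spec, 5, 40L)
  expect_identical(substr(ed, 45, 45), "G")
  expect_identical(nchar(ed), nchar(ctx))
  # everything else unchanged
  expect_identical(substr(ed, 1, 44), substr(ctx, 1, 44))
  expect_identical(substr(ed, 46, nchar(ed)), substr(ctx, 46, nchar(ctx)))
  # a position not carrying A is rejected by name
  expect_error(apply_edit(ctx, spec, 4, 40L), "position 4")
})

test_that("minus-strand edits appear as T->C and round-trip to A->G", {
  spec <- test_spec()
  plus_ctx <- paste0(strrep("C", 40), spec$spacer, "TGG", strrep("C", 37))
  minus_ctx <- reverse_complement(plus_ctx)
  # protospacer span within the minus context (0-based)
  proto_start <- nchar(minus_ctx) - 40L - 20L
  ed <- apply_edit(minus_ctx, spec, c(5, 6), proto_start, strand = "-")
  diff_pos <- which(strsplit(ed, "")[[1]] != strsplit(minus_ctx, "")[[1]])
  expect_length(diff_pos, 2)
  expect_true(all(substring(minus_ctx, diff_pos, diff_pos) == "T"))
  expect_true(all(substring(ed, diff_pos, diff_pos) == "C"))
  # re-deriving the protospacer strand shows the A->G edits
  expect_identical(reverse_complement(ed),
                   apply_edit(plus_ctx, spec, c(5, 6), 40L))
})

test_that("predictions respect the contract: range, length, determinism", {
  cp <- constant_predictor(c(t1 = 0.4, t2 = 0.9), input_length = 50)
  seqs <- with_seed(1, c(random_seq(50), random_seq(50)))
  p <- predict_accessibility(seqs, cp)
  expect_identical(dim(p), c(2L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_accessibility(seqs, cp))
  expect_error(predict_accessibility("ACGT", cp), "expects 50")
})

test_that("the reference model learns the synthetic task", {
  run <- small_training_run()
  model <- train_reference_predictor(
    list(sequences = run$ds$sequences[run$train],
         labels = run$ds$labels[run$train]), seed = 7)
  p <- predict_accessibility(run$ds$sequences[run$test], model)[, 1]
  expect_gte(auroc(p, run$ds$labels[run$test]), 0.9)
  # motif-bearing sequences outscore their shuffled controls
  pos <- run$ds$sequences[run$ds$labels == 1][1:50]
  shuf <- vapply(pos, function(s) {
    paste(with_seed(nchar(s), sample(strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_gt(mean(predict_accessibility(pos, model)[, 1]),
            mean(predict_accessibility(shuf, model)[, 1]))
})

test_that("label permutation destroys the signal", {
  # default generator settings: smaller sets leave enough sampling
  # imbalance in the permuted labels for the motif detector to amplify
  ds <- gen_accessibility_dataset(n = 4000, seed = 7)
  idx <- with_seed(8, sample(4000))
  tr <- idx[1:3000]; te <- idx[3001:4000]
  perm <- with_seed(12, sample(ds$labels[tr]))
  model <- train_reference_predictor(
    list(sequences = ds$sequences[tr], labels = perm), seed = 7)
  a <- auroc(predict_accessibility(ds$sequences[te], model)[, 1],
             ds$labels[te])
  expect_gte(a, 0.4)
  expect_lte(a, 0.6)
})

test_that("training is reproducible for a fixed seed", {
  run <- small_training_run(n = 400, seed = 21)
  ds <- list(sequences = run$ds$sequences[run$train],
             labels = run$ds$labels[run$train])
  m1 <- train_reference_predictor(ds, seed = 5, epochs = 3)
  m2 <- train_reference_predictor(ds, seed = 5, epochs = 3)
  probe <- run$ds$sequences[run$test][1:40]
  expect_identical(predict_accessibility(probe, m1),
                   predict_accessibility(probe, m2))
})

test_that("the rank-based AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  labels <- rbinom(200, 1, 0.4)
  scores <- labels + rnorm(200)
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("a single-class dataset is rejected", {
  expect_error(
    train_reference_predictor(list(sequences = c("ACGT", "AAAA"),
                                   labels = c(1, 1))),
    "both classes")
})

test_that("a constant model never flags and gives zero damage", {
  spec <- test_spec()
  dg <- gen_damage_genome(spec, n_sites = 6, n_damaging = 2, seed = 31)
  cp <- constant_predictor(c(track = 0.9), input_length = 200)
  sc <- score_sites(dg$sites, dg$genome, spec, cp)
  expect_true(all(sc$max_damage == 0))
  expect_false(any(sc$flagged))
})

test_that("threshold logic follows the control/damage rule", {
  spec <- test_spec()
  dg <- gen_damage_genome(spec, n_sites = 1, n_damaging = 0, seed = 32)
  ctx_of <- function(site) {
    mid <- (site$start + site$end) %/% 2
    substr(dg$genome[[1]], mid - 100 + 1, mid + 100)
  }
  control_seq <- ctx_of(dg$sites[1, ])
  # a stub keyed on the exact control sequence: 0.5 for control, 0.3 edited
  stub <- structure(list(input_length = 200L, tracks = "t",
                         predict = function(seqs) {
                           matrix(ifelse(seqs == control_seq, 0.5, 0.3),
                                  ncol = 1)
                         }),
                    class = "accessibility_predictor")
  sc <- score_site(dg$sites[1, ], dg$genome, spec, stub)
  expect_equal(sc$max_damage, 0.2)
  expect_true(sc$flagged)  # 0.5 > 0.2 and 0.2 > 0.1
  # same damage but inaccessible control: not flagged
  stub_low <- structure(list(input_length = 200L, tracks = "t",
                             predict = function(seqs) {
                               matrix(ifelse(seqs == control_seq, 0.15,
                                             0.01), ncol = 1)
                             }),
                        class = "accessibility_predictor")
  expect_false(score_site(dg$sites[1, ], dg$genome, spec, stub_low)$flagged)
  # damage below threshold at accessible control: not flagged
  stub_small <- structure(list(input_length = 200L, tracks = "t",
                               predict = function(seqs) {
                                 matrix(ifelse(seqs == control_seq, 0.5,
                                               0.45), ncol = 1)
                               }),
                          class = "accessibility_predictor")
  expect_false(score_site(dg$sites[1, ], dg$genome, spec,
                          stub_small)$flagged)
})

test_that("flagging is invariant under strand representation", {
  spec <- test_spec()
  dg <- gen_damage_genome(spec, n_sites = 4, n_damaging = 2, seed = 33)
  run <- small_training_run(n = 800, seed = 34)
  model <- train_reference_predictor(
    list(sequences = run$ds$sequences[run$train],
         labels = run$ds$labels[run$train]), seed = 7, epochs = 8)
  # the same loci described from the minus strand
  L <- nchar(dg$genome[[1]])
  flipped <- dg$sites
  flipped$strand <- "-"
  flipped$start <- L - dg$sites$end
  flipped$end <- L - dg$sites$start
  flipped$protospacer <- dg$sites$protospacer
  genome_rc <- stats::setNames(reverse_complement(dg$genome[[1]]),
                               names(dg$genome))
  sc_fwd <- score_sites(dg$sites, dg$genome, spec, model)
  sc_rev <- score_sites(flipped, genome_rc, spec, model)
  expect_identical(sc_fwd$flagged, sc_rev$flagged)
  expect_equal(sc_fwd$max_damage, sc_rev$max_damage, tolerance = 1e-12)
})

test_that("sites without a window adenine are rejected for scoring", {
  spec <- test_spec()
  dg <- gen_damage_genome(spec, n_sites = 1, n_damaging = 0, seed = 35)
  bad <- dg$sites[1, ]
  bad$protospacer <- strrep("G", 20)
  expect_error(score_site(bad, dg$genome, spec,
                          constant_predictor(c(t = 0.5), 200)),
               "no adenine")
})
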