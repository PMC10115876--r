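test_that("a planted exact site in a clean background is found alone", {
  spec <- test_spec()
  gg <- gen_genome_with_offtargets(5000, spec,
                                   data.frame(mismatch_count = 0L,
                                              strand = "+"), seed = 1)
  sites <- enumerate_offtargets(gg$genome, spec, max_mismatches = 4)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$mismatch_count, 0L)
  expect_identical(sites$start, gg$truth$planted_sites$start)
  expect_identical(sites$protospacer, spec$spacer)
})

test_that("a genome without the PAM yields no sites", {
  spec <- test_spec()
  set.seed(2)
  # A/C alphabet cannot contain an NGG PAM on either strand except via
  # the spacer itself; no spacer is planted
  genome <- c(chrA = random_seq(3000, alphabet = c("A", "C")))
  sites <- enumerate_offtargets(genome, spec, max_mismatches = 2)
  expect_identical(nrow(sites), 0L)
})

test_that("enumeration equals the brute-force oracle on a random genome", {
  spec <- test_spec()
  gg <- gen_genome_with_offtargets(
    30000, spec, data.frame(mismatch_count = c(0L, 2L, 3L),
                            strand = c("+", "-", "+")), seed = 3)
  got <- enumerate_offtargets(gg$genome, spec, max_mismatches = 3)
  want <- oracle_offtargets(gg$genome, spec$spacer, spec$pam_pattern, 3)
  cols <- c("contig", "start", "end", "strand", "mismatch_count")
  got <- as.data.frame(got)[, cols]; rownames(got) <- NULL
  want$mismatch_count <- as.integer(want$mismatch_count)
  rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("a spacer containing N is rejected for enumeration", {
  spec <- test_spec()
  spec$spacer <- paste0("N", substr(spec$spacer, 2, 20))
  expect_error(enumerate_offtargets(c(c1 = "ACGT"), spec), "must not contain N")
})

test_that("overlapping sites from different sources unify", {
  spec <- test_spec()
  a <- hand_site(start = 100L, protospacer = spec$spacer,
                 sources = "insilico", mismatch_count = 2L)
  b <- hand_site(start = 105L, protospacer = spec$spacer,
                 sources = "circleseq", mismatch_count = 1L,
                 circleseq_read_count = 77)
  m <- merge_candidates(a, b)
  expect_identical(nrow(m), 1L)
  expect_identical(m$sources, "circleseq,insilico")
  expect_identical(m$circleseq_read_count, 77)
  expect_identical(m$mismatch_count, 1L)

  c <- hand_site(start = 500L, protospacer = spec$spacer)
  expect_identical(nrow(merge_candidates(a, c)), 2L)
})

test_that("merging agrees with an exhaustive overlap-closure oracle", {
  spec <- test_spec()
  set.seed(4)
  for (rep in 1:5) {
    n <- 30
    sites <- do.call(rbind, lapply(1:n, function(i) {
      hand_site(start = sample(0:300, 1),
                strand = sample(c("+", "-"), 1),
                protospacer = spec$spacer,
                mismatch_count = sample(0:4, 1))
    }))
    class(sites) <- c("candidate_sites", "data.frame")
    m <- merge_candidates(sites)
    # oracle: transitive closure of pairwise overlap on the same strand
    adj <- outer(1:n, 1:n, function(i, j) {
      sites$strand[i] == sites$strand[j] &
        sites$start[i] < sites$end[j] & sites$start[j] < sites$end[i]
    })
    reach <- adj
    for (k in 1:n) reach <- reach | (reach[, k] %o% reach[k, ] > 0)
    n_components <- length(unique(apply(reach, 1, function(r)
      min(which(r)))))
    expect_identical(nrow(m), n_components)
    expect_lte(nrow(m), n)
    # commutativity under input split
    half <- sites[1:15, ]; rest <- sites[16:30, ]
    class(half) <- class(rest) <- c("candidate_sites", "data.frame")
    m2 <- merge_candidates(half, rest)
    m3 <- merge_candidates(rest, half)
    expect_equal(m2, m3)
  }
})

test_that("the adenine-window filter keeps exactly protospacer-A sites", {
  spec <- test_spec()  # window 4..8
  with_a <- hand_site(protospacer = "GGGGAGGGGGGGGGGGGGGG")  # A at 5
  without <- hand_site(protospacer = "GGGGGGGGGGGGGGGGGGGG")
  tail_a <- hand_site(protospacer = "GGGGGGGGGGGGGGGGGGGA")  # A outside window
  sites <- rbind(with_a, without, tail_a)
  class(sites) <- c("candidate_sites", "data.frame")
  kept <- filter_adenine_window(sites, spec)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$protospacer, with_a$protospacer)
  expect_true(all(kept$has_adenine_in_window))
  # idempotent and a subset
  expect_identical(filter_adenine_window(kept, spec), kept)
})

test_that("minus-strand sites show window adenines as reference T", {
  spec <- test_spec()
  gg <- gen_genome_with_offtargets(5000, spec,
                                   data.frame(mismatch_count = 0L,
                                              strand = "-"), seed = 6)
  sites <- enumerate_offtargets(gg$genome, spec, max_mismatches = 0)
  expect_identical(sites$strand, "-")
  # the spacer has A5/A6, so the site must be retained
  expect_identical(nrow(filter_adenine_window(sites, spec)), 1L)
  # and the reference plus strand shows T at the mirrored coordinates
  ref05 <- protospacer_to_ref(genomic_interval(sites$contig, sites$start,
                                               sites$end, "-"), 5)
  plus_base <- substr(gg$genome[[1]], ref05 + 1, ref05 + 1)
  expect_identical(plus_base, "T")
  expect_identical(reverse_complement(plus_base), "A")
})

test_that("ranking is deterministic and follows the documented key", {
  spec <- test_spec()
  mk <- function(start, rc, mm, contig = "chr_t") {
    s <- hand_site(start = start, protospacer = spec$spacer,
                   mismatch_count = mm, circleseq_read_count = rc)
    s$contig <- contig
    s
  }
  sites <- rbind(mk(10, 5, 3), mk(200, 100, 4), mk(400, NA, 0),
                 mk(600, 5, 1), mk(800, 5, 1, contig = "chr_a"))
  class(sites) <- c("candidate_sites", "data.frame")
  top <- rank_sites(sites, 250)
  expect_identical(nrow(top), 5L)  # n beyond the list returns everything
  expect_identical(top$circleseq_read_count[1], 100)
  # ties on (count, mismatch) break by contig then start
  expect_identical(top$contig[2:3], c("chr_a", "chr_t"))
  expect_identical(top$start[2:3], c(800L, 600L))
  # absent CIRCLE-seq evidence ranks as zero reads
  expect_identical(top$start[5], 400L)
  set.seed(8)
  shuffled <- sites[sample(nrow(sites)), ]
  class(shuffled) <- c("candidate_sites", "data.frame")
  expect_equal(rank_sites(shuffled, 3),
               rank_sites(sites, 3))
})

test_that("CIRCLE-seq BED reading fills sequence fields from the genome", {
  spec <- test_spec()
  gg <- gen_genome_with_offtargets(8000, spec,
                                   data.frame(mismatch_count = c(1L, 0L),
                                              strand = c("+", "-")),
                                   seed = 9)
  planted <- gg$truth$planted_sites
  bed <- tempfile(fileext = ".bed")
  write_bed(data.frame(contig = planted$contig, start = planted$start,
                       end = planted$end, name = c("s1", "s2"),
                       score = c(1000L, 250L), strand = planted$strand),
            bed)
  circ <- read_circleseq_sites(bed, gg$genome, spec)
  expect_identical(circ$sources, c("circleseq", "circleseq"))
  expect_setequal(circ$circleseq_read_count, c(1000, 250))
  expect_setequal(circ$protospacer, planted$protospacer)
  expect_setequal(circ$mismatch_count, planted$mismatch_count)
})

test_that("capture probes are fixed-width and contain the protospacer", {
  spec <- test_spec()
  gg <- gen_genome_with_offtargets(8000, spec,
                                   data.frame(mismatch_count = 0L,
                                              strand = "+"), seed = 10)
  sites <- enumerate_offtargets(gg$genome, spec, 0)
  probes <- design_capture_probes(sites, gg$genome)
  expect_identical(unique(nchar(probes$sequences)), 120L)
  expect_true(grepl(spec$spacer, probes$sequences[[1]], fixed = TRUE))
})
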