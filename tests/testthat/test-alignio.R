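test_that("parse_mapview maps fields, filters on mapq and counts malformed lines", {
  lines <- c(
    "# header to be ignored",
    "r1\tchr1\t101\t+\t200\t60\t35",
    "r2\tchr1\t250\t-\t-200\t60\t35\textra\tcols",
    "r3\tchr1\t400\t+\t190\t5\t35",
    "broken line without tabs"
  )
  expect_warning(reads <- parse_mapview(lines, mapq_min = 10), "malformed")
  expect_s3_class(reads, "aligned_reads")
  expect_equal(nrow(reads), 2)  # r3 below mapq, broken line skipped
  expect_equal(attr(reads, "n_malformed"), 1L)
  expect_equal(reads$pos, c(101L, 250L))
  expect_equal(reads$strand, c("+", "-"))
  expect_equal(reads$outer_dist, c(200L, -200L))
  expect_equal(reads$read_len, c(35L, 35L))

  empty <- parse_mapview(character(0))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_malformed"), 0L)
})

test_that("outer_distance is E - S, signed", {
  expect_equal(outer_distance(100, 300), 200)
  expect_equal(outer_distance(100, 100), 0)
  expect_equal(outer_distance(100, 50), -50)
  expect_equal(outer_distance(c(1, 10), c(5, 5)), c(4, -5))
})

test_that("position track counts all read starts but attaches each pair's distance once", {
  lines <- c(
    "p1\tchr1\t101\t+\t200\t60\t35",
    "p1\tchr1\t266\t-\t-200\t60\t35",
    "p2\tchr1\t150\t+\t7000\t60\t35",
    "p2\tchr1\t7115\t-\t-7000\t60\t35"
  )
  reads <- parse_mapview(lines)
  track <- build_position_track(reads, chrom_len = 10000, dist_cutoff = 6000)
  expect_equal(sum(track$n), 4)
  expect_equal(track$n[101], 1)
  expect_equal(track$n[266], 1)
  expect_equal(track_dists_at(track, 101), 200L)
  # beyond-cutoff pair: depth counted, distance dropped
  expect_equal(track$n[150], 1)
  expect_equal(length(track_dists_at(track, 150)), 0)
  expect_equal(length(track$dist_val), 1)

  empty <- build_position_track(empty_reads_fixture(), chrom_len = 100)
  expect_equal(sum(empty$n), 0)
  expect_equal(length(empty$dist_val), 0)

  off <- parse_mapview("r\tchr1\t500\t+\t100\t60\t35")
  expect_warning(t2 <- build_position_track(off, chrom_len = 200),
                 "beyond chromosome end")
  expect_equal(sum(t2$n), 0)
})


test_that("mapview round-trip preserves the observation track", {
  sim <- std_sim(ref_len = 5e4, n_del = 2, coverage = 2, seed = 3,
                 libraries = list(c(200, 20)))
  path <- withr::local_tempfile()
  write_mapview(sim$reads, path, header = "round-trip fixture")
  back <- parse_mapview(path)
  t1 <- build_position_track(sim$reads, 5e4)
  t2 <- build_position_track(back, 5e4)
  expect_identical(t1$n, t2$n)
  expect_identical(t1$dist_pos, t2$dist_pos)
  expect_identical(t1$dist_val, t2$dist_val)
  # conservation: one distance record per retained pair
  n_pairs <- sum(sim$reads$strand == "+" & sim$reads$outer_dist > 0 &
                   sim$reads$outer_dist <= 6000)
  expect_equal(length(t1$dist_val), n_pairs)
})

test_that("insert model recovers Gaussian library parameters", {
  set.seed(11)
  d <- as.integer(round(rnorm(10000, 1500, 200)))
  m <- fit_insert_model(d, dist_cutoff = 6000)
  expect_lt(abs(m$D - 1500), 10)
  expect_lt(abs(m$sigma - 200), 10)
  expect_equal(sum(m$pmf), 1, tolerance = 1e-12)
})

test_that("insert model handles degenerate and undersized inputs", {
  m <- fit_insert_model(rep(200L, 150), dist_cutoff = 500, pseudocount = 0)
  expect_equal(m$pmf[200], 1)
  expect_equal(m$sigma, 1)  # sd floor
  expect_error(fit_insert_model(rep(200L, 50)), "at least 100")
})

test_that("empirical insert fit converges in total variation", {
  # known discrete distribution on a small support
  support <- 90:110
  p <- dnorm(support, 100, 4)
  p <- p / sum(p)
  set.seed(5)
  d <- sample(support, 1e5, replace = TRUE, prob = p)
  m <- fit_insert_model(d, dist_cutoff = 1000)
  truth <- numeric(1000)
  truth[support] <- p
  tv <- 0.5 * sum(abs(m$pmf - truth))
  expect_lt(tv, 0.05)
})

test_that("shifted insert lookups translate the pmf and floor out-of-support values", {
  m <- insert_model_gaussian(50, 5, dist_cutoff = 200)
  expect_equal(insert_logpmf(m, 90, delta = 40), m$log_pmf[50])
  expect_equal(insert_logpmf(m, 10, delta = 40), m$log_floor)
})

test_that("GC model is near unity on unbiased uniform-GC data and scale invariant", {
  set.seed(21)
  L <- 200000
  ref <- random_reference(L)
  pos <- sample.int(L, 200000, replace = TRUE)
  reads <- data.frame(name = "r", chrom = "c", pos = pos, strand = "+",
                      outer_dist = 0L, mapq = 60L, read_len = 35L)
  class(reads) <- c("aligned_reads", "data.frame")
  track <- build_position_track(reads, L)
  dm <- fit_gc_model(track, ref, gc_window = 100, n_bins = 10)
  populated <- dm$bin_counts >= 5000
  expect_true(any(populated))
  expect_true(all(dm$G[populated] >= 0.9 & dm$G[populated] <= 1.1))
  expect_true(all(dm$G[dm$bin_counts == 0] == 1))  # empty-bin fallback
  # read-count-weighted mean of applied factors is ~1
  adj <- gc_adjust(dm, ref)
  expect_equal(sum(track$n * adj$G) / sum(track$n), 1, tolerance = 0.05)
  # doubling counts leaves G unchanged (ratio definition)
  track2 <- track
  track2$n <- track$n * 2L
  dm2 <- fit_gc_model(track2, ref, gc_window = 100, n_bins = 10)
  expect_equal(dm2$G, dm$G)
})

test_that("GC model refuses an all-N reference", {
  track <- build_position_track(empty_reads_fixture(), chrom_len = 2000)
  ref <- Biostrings::DNAString(strrep("N", 2000))
  expect_error(fit_gc_model(track, ref), "all N")
})
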