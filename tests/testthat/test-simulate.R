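test_that("planted events respect counts, sizes, separation and zygosity", {
  cfg <- sim_config(ref_len = 2e6, n_del = 100, del_sizes = c(400, 800),
                    coverage = 3, libraries = list(c(1500, 200)), seed = 5)
  set.seed(cfg$seed)
  planted <- plant_cnvs(cfg)
  tr <- planted$truth
  expect_equal(nrow(tr), 100)
  expect_equal(sort(unique(tr$size)), c(400, 800))
  expect_equal(as.vector(table(tr$size)), c(50L, 50L))  # balanced assignment
  expect_true(all(tr$end - tr$start == tr$size))
  gaps <- tr$start[-1] - tr$end[-nrow(tr)]
  expect_true(all(gaps >= cfg$min_sep))
  expect_true(all(tr$hap %in% c("1", "2")))
  # het events appear on exactly one haplotype
  n1 <- nrow(planted$hap_events[[1]])
  n2 <- nrow(planted$hap_events[[2]])
  expect_equal(n1 + n2, 100)

  cfg0 <- sim_config(ref_len = 1e5, n_del = 0, seed = 1)
  set.seed(1)
  expect_equal(nrow(plant_cnvs(cfg0)$truth), 0)

  cramped <- sim_config(ref_len = 50000, n_del = 40,
                        del_sizes = c(400), seed = 1,
                        libraries = list(c(1500, 200)))
  set.seed(1)
  expect_error(plant_cnvs(cramped), "longer genome|place")
})

test_that("event-free simulation reproduces library distance and depth", {
  sim <- std_sim(ref_len = 1e6, n_del = 0, coverage = 2, seed = 12)
  d <- sim$reads$outer_dist[sim$reads$strand == "+"]
  d <- d[d > 0]
  se <- 200 / sqrt(length(d))
  expect_lt(abs(mean(d) - 1500), 3 * se)
  # depth conservation: read starts per position ~ 2 * coverage / read_len
  track <- build_position_track(sim$reads, 1e6)
  expect_equal(sum(track$n) / 1e6, 2 * 2 / 35, tolerance = 0.02)
})

test_that("pairs spanning a heterozygous deletion shift by its size", {
  cfg <- sim_config(ref_len = 3e5, n_del = 1, del_sizes = c(800),
                    coverage = 4, libraries = list(c(1500, 200)), seed = 77)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  carrier <- paste0("h", tr$hap)
  plus <- sim$reads[sim$reads$strand == "+" & sim$reads$outer_dist > 0, ]
  span <- plus$pos - 1 < tr$start & plus$pos - 1 + plus$outer_dist > tr$end
  from_carrier <- startsWith(plus$name, carrier)
  shifted <- plus$outer_dist[span & from_carrier]
  normal <- plus$outer_dist[span & !from_carrier]
  expect_gte(length(shifted), 20)
  expect_lt(abs(mean(shifted) - (1500 + 800)), 3 * 200 / sqrt(length(shifted)))
  expect_lt(abs(mean(normal) - 1500), 3 * 200 / sqrt(length(normal)))
})

test_that("a homozygous deletion has no read starts inside it", {
  cfg <- sim_config(ref_len = 2e5, n_del = 1, del_sizes = c(800),
                    zygosity = "hom", coverage = 4,
                    libraries = list(c(200, 20)), seed = 19)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  track <- build_position_track(sim$reads, 2e5)
  inside <- (tr$start + cfg$min_anchor):(tr$end - cfg$min_anchor)
  expect_equal(sum(track$n[inside]), 0)
})

test_that("a tandem duplication doubles depth over the duplicated interval", {
  cfg <- sim_config(ref_len = 4e5, n_del = 0, n_dup = 1,
                    dup_sizes = c(20000), zygosity = "hom", coverage = 3,
                    libraries = list(c(200, 20)), seed = 23)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  track <- build_position_track(sim$reads, 4e5)
  inside <- mean(track$n[(tr$start + 500):(tr$end - 500)])
  outside <- mean(track$n[1:(tr$start - 500)])
  expect_equal(inside / outside, 2, tolerance = 0.1)
})

test_that("identical configurations give byte-identical outputs", {
  cfg <- sim_config(ref_len = 5e4, n_del = 3, del_sizes = c(400),
                    coverage = 2, libraries = list(c(200, 20)), seed = 33)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, out_prefix = file.path(d1, "a_"))
  simulate_dataset(cfg, out_prefix = file.path(d2, "a_"))
  for (f in c("a_ref.fa", "a_reads.tsv", "a_truth.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("truth BED round-trips, sorted, including the empty case", {
  cfg <- sim_config(ref_len = 2e5, n_del = 5, del_sizes = c(400, 800),
                    coverage = 1, seed = 3, libraries = list(c(200, 20)))
  set.seed(3)
  tr <- plant_cnvs(cfg)$truth
  path <- withr::local_tempfile()
  write_truth(tr, path)
  back <- read_truth(path)
  expect_equal(back$start, tr$start)
  expect_equal(back$end, tr$end)
  expect_equal(back$event, tr$event)
  expect_equal(back$zygosity, tr$zygosity)
  expect_true(!is.unsorted(back$start))

  write_truth(tr[0, ], path)
  expect_equal(nrow(read_truth(path)), 0)
  expect_true(startsWith(readLines(path)[1], "#"))
})

test_that("GC-biased sampling produces a detectable depth-GC trend", {
  cfg <- sim_config(ref_len = 3e5, n_del = 0, coverage = 4,
                    libraries = list(c(200, 20)), seed = 55, gc_bias = 0.8)
  sim <- simulate_dataset(cfg)
  track <- build_position_track(sim$reads, 3e5)
  dm <- fit_gc_model(track, sim$ref, gc_window = 100, n_bins = 10)
  fitted <- dm$bin_counts >= 1000
  bin_gc <- (seq_len(10) - 0.5) / 10
  expect_gt(cor(bin_gc[fitted], dm$G[fitted]), 0.8)
})
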