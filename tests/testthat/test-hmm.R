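test_that("state space has the expected states, durations and shifts", {
  st <- build_state_space(grid_sizes = seq(200, 1600, by = 200),
                          insert_D = 1500, genome_len = 3e6)
  expect_equal(nrow(st), 5 + 8 * 3)
  expect_equal(st$name[1:5], c("Normal", "Del1", "Del2", "Dup1", "Dup2"))
  expect_true(all(st$duration[st$role %in% c("f5", "f3")] == 1500))
  g400 <- st[st$name == "grid_del_400", ]
  expect_equal(g400$C, 1)
  expect_equal(g400$delta, 0)
  expect_equal(g400$duration, 400)
  f400 <- st[st$name == "f5_400", ]
  expect_equal(f400$C, 2)
  expect_equal(f400$delta, 400)

  expect_equal(nrow(build_state_space(c(400), 1500, 1e6)), 8)
  expect_equal(nrow(build_state_space(integer(0), 1500, 1e6)), 5)
  expect_error(build_state_space(c(400, 400), 1500, 1e6), "increasing")
})

test_that("transitions follow the geometric-duration heuristic and topology", {
  st <- build_state_space(seq(200, 1600, 200), insert_D = 1500,
                          genome_len = 12e6)  # 12 Mbp -> 4 expected events
  tr <- exp(build_transitions(st))
  expect_equal(unname(rowSums(tr)), rep(1, nrow(st)), tolerance = 1e-9)
  i5 <- which(st$name == "f5_400")
  ig <- which(st$name == "grid_del_400")
  expect_equal(tr[i5, i5], 1 - 1 / 1500)
  expect_equal(tr[i5, ig], 1 / 1500)
  expect_equal(sum(tr[i5, ] > 0), 2)  # self + single destination
  # Normal: duration 3e6, 12 destinations sharing the exit mass equally
  dests <- which(tr[1, ] > 0 & seq_len(nrow(st)) != 1)
  expect_equal(length(dests), 12)
  expect_equal(unname(tr[1, dests]), rep((1 / 3e6) / 12, 12))
  # no edges outside the declared topology
  if3 <- which(st$name == "f3_400")
  expect_equal(unname(which(tr[ig, ] > 0)), sort(c(ig, if3)))
  expect_equal(unname(which(tr[if3, ] > 0)), sort(c(1L, if3)))
})

test_that("topology and row-stochasticity hold over random grid configurations", {
  set.seed(8)
  for (i in 1:20) {
    gs <- sort(sample(100:2000, sample(0:6, 1)))
    st <- build_state_space(gs, insert_D = sample(200:2000, 1),
                            genome_len = 1e6,
                            cnv_duration = sample(1000:20000, 1))
    tr <- exp(build_transitions(st))
    expect_equal(unname(rowSums(tr)), rep(1, nrow(st)), tolerance = 1e-9)
    # allowed destination count per role
    for (j in seq_len(nrow(st))) {
      ndest <- sum(tr[j, ] > 0) - 1
      expected <- switch(st$role[j], normal = 4 + length(gs), f5 = 1,
                         grid_del = 1, f3 = 1, 1)
      expect_equal(ndest, expected)
    }
  }
})

test_that("emissions combine Poisson depth with (shifted) distance terms", {
  m <- tiny_hmm(D = 50, sigma = 5, lam = 0.2, grid_sizes = c(10, 20))
  # Normal with no distances is pure Poisson at lambda * G
  expect_equal(emission_logprob(m, 1, n_t = 2, G_t = 1.5),
               dpois(2, 0.2 * 1.5, log = TRUE))
  # copy-0 state under zero reads sits at the epsilon floor, close to 0
  i_del2 <- which(m$states$name == "Del2")
  expect_equal(emission_logprob(m, i_del2, n_t = 0),
               dpois(0, 0.01 * 0.2, log = TRUE))
  expect_gt(emission_logprob(m, i_del2, n_t = 0), -0.01)
  # purely shifted flank evaluates the pmf after an index shift
  m1 <- tiny_hmm(D = 50, sigma = 5, lam = 0.2, grid_sizes = c(10, 20),
                 het_mix_weight = 1)
  i_f5 <- which(m1$states$name == "f5_20")
  expect_equal(
    emission_logprob(m1, i_f5, n_t = 1, dists_t = 70L),
    dpois(1, 0.2, log = TRUE) + m1$insert_model$log_pmf[50]
  )
  # het mixture averages shifted and null pmfs
  i_f5h <- which(m$states$name == "f5_20")
  im <- m$insert_model
  expect_equal(
    emission_logprob(m, i_f5h, n_t = 0, dists_t = 70L),
    dpois(0, 0.2, log = TRUE) + log(0.5 * im$pmf[50] + 0.5 * im$pmf[70])
  )
})

test_that("Viterbi matches exhaustive enumeration on small random instances", {
  set.seed(13)
  for (i in 1:30) {
    S <- sample(2:4, 1)
    T_ <- sample(2:8, 1)
    logE <- matrix(log(runif(S * T_)), S, T_)
    P <- matrix(runif(S * S), S, S)
    P <- P / rowSums(P)
    init <- runif(S)
    init <- init / sum(init)
    vit <- viterbi_matrix(logE, log(P), log(init))
    expect_equal(vit$loglik, enumerate_best_path(logE, log(P), log(init)),
                 tolerance = 1e-12)
  }
})

test_that("track-level Viterbi agrees with the R emissions plus enumeration", {
  m <- tiny_hmm(D = 50, sigma = 5, cutoff = 100, lam = 0.5,
                grid_sizes = integer(0))  # 5 states, depth-only topology
  set.seed(4)
  L <- 7
  n <- as.integer(rpois(L, 0.5))
  track <- structure(
    list(chrom = "c", length = L, n = n,
         dist_pos = c(2L, 5L), dist_val = c(48L, 60L),
         dist_cutoff = 100L),
    class = "position_track")
  vit <- viterbi(track, m)
  logE <- vapply(seq_len(L), function(t) {
    vapply(seq_len(nrow(m$states)), function(s) {
      emission_logprob(m, s, n[t], track$dist_val[track$dist_pos == t])
    }, numeric(1))
  }, numeric(nrow(m$states)))
  expect_equal(vit$loglik,
               enumerate_best_path(logE, m$log_trans, m$log_init),
               tolerance = 1e-10)
  # and the generic decoder agrees with the track decoder
  expect_equal(viterbi_matrix(logE, m$log_trans, m$log_init)$path, vit$path)
})

test_that("scaling emissions at one position leaves the decoded path unchanged", {
  set.seed(17)
  S <- 4; T_ <- 30
  logE <- matrix(log(runif(S * T_)), S, T_)
  P <- matrix(runif(S * S), S, S); P <- P / rowSums(P)
  init <- rep(1 / S, S)
  p1 <- viterbi_matrix(logE, log(P), log(init))$path
  logE2 <- logE
  logE2[, 12] <- logE2[, 12] + 7.3  # constant factor at one position
  p2 <- viterbi_matrix(logE2, log(P), log(init))$path
  expect_identical(p1, p2)
})

test_that("decoding event-free data yields an all-Normal path", {
  sim <- std_sim(ref_len = 2e5, n_del = 0, coverage = 3, seed = 9)
  track <- build_position_track(sim$reads, 2e5)
  dm <- fit_gc_model(track, sim$ref)
  im <- fit_insert_model(track$dist_val)
  model <- build_hmm(im, dm, genome_len = 2e5)
  # chromosome ends lack mate support and are masked, as in the pipeline
  edge <- round(im$D + 4 * im$sigma)
  mask <- rep(FALSE, 2e5)
  mask[c(seq_len(edge), (2e5 - edge + 1):2e5)] <- TRUE
  vit <- viterbi(track, model, mask = mask)
  expect_equal(unique(vit$path), 1L)
})

test_that("a planted heterozygous deletion is decoded through its grid row", {
  sim <- std_sim(ref_len = 1e5, n_del = 1, coverage = 4, seed = 31)
  sim$truth <- sim$truth  # one event, size 400 or 800
  track <- build_position_track(sim$reads, 1e5)
  dm <- fit_gc_model(track, sim$ref)
  model <- build_hmm(fit_insert_model(track$dist_val), dm, genome_len = 1e5)
  vit <- viterbi(track, model)
  states <- model$states$role[vit$path]
  runs <- rle(states)
  i_del <- which(runs$values == "grid_del")
  expect_length(i_del, 1)
  # flanked by f5 before and f3 after
  expect_equal(runs$values[i_del - 1], "f5")
  expect_equal(runs$values[i_del + 1], "f3")
  ends <- cumsum(runs$lengths)
  del_start <- ends[i_del - 1]  # 0-based call start
  del_end <- ends[i_del]
  expect_gte(reciprocal_overlap(del_start, del_end,
                                sim$truth$start, sim$truth$end), 0.5)
})

test_that("calls are extracted from maximal runs with optional merging", {
  m <- tiny_hmm(grid_sizes = c(10))
  st <- m$states
  i_g <- which(st$name == "grid_del_10")
  i_f5 <- which(st$name == "f5_10")
  i_f3 <- which(st$name == "f3_10")
  i_d1 <- which(st$name == "Del1")
  path <- rep(1L, 60)
  path[11:20] <- i_f5
  path[21:30] <- i_g
  path[31:40] <- i_f3
  vit <- structure(list(path = path, loglik = 0), class = "viterbi_result")
  calls <- extract_calls(vit, m, "chrX")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 20)  # flanks excluded from the interval
  expect_equal(calls$end, 30)
  expect_equal(calls$event, "DEL")
  expect_equal(calls$copy_number, 1L)
  expect_equal(calls$source, "grid row 1")

  expect_equal(nrow(extract_calls(
    structure(list(path = rep(1L, 10), loglik = 0),
              class = "viterbi_result"), m, "chrX")), 0)

  # two Del1 runs separated by 5 Normal positions merge at merge_gap 10
  path2 <- rep(1L, 40)
  path2[5:10] <- i_d1
  path2[16:20] <- i_d1
  vit2 <- structure(list(path = path2, loglik = 0),
                    class = "viterbi_result")
  expect_equal(nrow(extract_calls(vit2, m, "c")), 2)
  merged <- extract_calls(vit2, m, "c", merge_gap = 10)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(4, 20))
})

test_that("planted deletions are recovered with perfect precision at 3x", {
  sim <- std_sim(ref_len = 5e5, n_del = 20, coverage = 3, seed = 42)
  res <- call_cnvs(sim$reads, sim$ref, chrom = "sim1")
  mr <- match_calls(res$calls, sim$truth)
  expect_gt(mr$sensitivity, 0.8)
  expect_equal(nrow(mr$false_calls), 0)
})
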