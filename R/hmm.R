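#' Build the CNV state space
#'
#' States are: Normal (copy 2), Del1 (copy 1) and Del2 (copy 0) for
#' large deletions, Dup1 (copy 3) and Dup2 (copy 4+) for duplications,
#' and one grid row per targeted medium deletion size `k`: a 5' flanking
#' state `f5_k` (copy 2, distance shift `k`), an interior deletion state
#' `grid_del_k`, and a 3' flanking state `f3_k` (copy 2, shift `k`).
#' The flanking states are where spanning pairs' outer-distances follow
#' the insert distribution shifted upward by the deletion size; the grid
#' gives a first-order chain a memory of deletion size.
#'
#' Expected durations (bp) set the transition heuristics: flanks last
#' one insert mean, a grid deletion state lasts its targeted size,
#' large-CNV states last `cnv_duration`, and Normal lasts
#' `genome_len / expected_events`.
#'
#' @param grid_sizes Targeted medium-deletion sizes in bp, strictly
#'   increasing. Default `seq(200, 1600, by = 200)`. Empty gives a
#'   depth-only model.
#' @param insert_D Insert-library mean outer-distance (bp).
#' @param genome_len Genome (chromosome) length in bp.
#' @param expected_events Expected number of CNVs in `genome_len`;
#'   default one per 3 Mbp.
#' @param cnv_duration Expected size of CNVs detectable from depth alone
#'   (duration of Del1/Del2/Dup1/Dup2), default 10 kbp.
#' @param grid_copy Copy number of the grid interior deletion state:
#'   1 (heterozygous, default) or 0 (homozygous).
#' @return A `data.frame` with columns `name`, `C`, `delta`, `duration`,
#'   `role`, `row` (grid row index or `NA`). Normal is row 1.
#' @export
build_state_space <- function(grid_sizes = seq(200, 1600, by = 200),
                              insert_D, genome_len,
                              expected_events = genome_len / 3e6,
                              cnv_duration = 10000, grid_copy = 1) {
  if (length(grid_sizes) > 0) {
    if (any(grid_sizes < 1) || is.unsorted(grid_sizes, strictly = TRUE)) {
      stop("grid_sizes must be strictly increasing and >= 1")
    }
  }
  normal_dur <- genome_len / expected_events
  base <- data.frame(
    name = c("Normal", "Del1", "Del2", "Dup1", "Dup2"),
    C = c(2, 1, 0, 3, 4),
    delta = 0,
    duration = c(normal_dur, rep(cnv_duration, 4)),
    role = c("normal", "del1", "del2", "dup1", "dup2"),
    row = NA_integer_,
    stringsAsFactors = FALSE
  )
  grids <- lapply(seq_along(grid_sizes), function(i) {
    k <- grid_sizes[i]
    data.frame(
      name = paste0(c("f5_", "grid_del_", "f3_"), k),
      C = c(2, grid_copy, 2),
      delta = c(k, 0, k),
      duration = c(insert_D, k, insert_D),
      role = c("f5", "grid_del", "f3"),
      row = i,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(list(base), grids))
  rownames(out) <- NULL
  out
}

#' Heuristic transition matrix from expected durations
#'
#' Each state's self-transition probability is `1 - 1/duration`, so the
#' expected (geometric) run length equals the stated duration; the exit
#' mass `1/duration` is split equally among the permitted destinations.
#' Topology: Normal connects to and from Del1, Del2, Dup1, Dup2 and
#' every `f5_k`; within a grid row, `f5_k -> grid_del_k -> f3_k ->
#' Normal`; every state has a self-loop; no other edges.
#'
#' @param states State table from [build_state_space()].
#' @return Matrix of log transition probabilities (`-Inf` where no edge),
#'   rows sum to 1 in probability space.
#' @export
build_transitions <- function(states) {
  if (any(states$duration < 1)) stop("state durations must be >= 1")
  S <- nrow(states)
  trans <- matrix(0, S, S, dimnames = list(states$name, states$name))
  idx <- stats::setNames(seq_len(S), states$name)
  dest <- function(i) {
    role <- states$role[i]
    switch(role,
      normal = c(idx[states$role %in% c("del1", "del2", "dup1", "dup2")],
                 idx[states$role == "f5"]),
      del1 = , del2 = , dup1 = , dup2 = idx["Normal"],
      f5 = idx[states$role == "grid_del" & states$row == states$row[i]],
      grid_del = idx[states$role == "f3" & states$row == states$row[i]],
      f3 = idx["Normal"]
    )
  }
  for (i in seq_len(S)) {
    self <- 1 - 1 / states$duration[i]
    d <- dest(i)
    trans[i, i] <- self
    if (length(d) > 0) trans[i, d] <- (1 - self) / length(d)
  }
  log(trans)
}

#' Assemble an HMM specification
#'
#' @param insert_model Empirical insert model ([fit_insert_model()]).
#' @param depth_model GC-adjusted depth model ([fit_gc_model()]).
#' @param genome_len Chromosome length (bp).
#' @param grid_sizes Targeted deletion sizes; see [build_state_space()].
#' @param het_mix_weight Weight of the shifted component in flanking-state
#'   distance emissions. For a heterozygous deletion only the carrier
#'   haplotype's spanning pairs are shifted, so the default 0.5 mixes the
#'   shifted and null distributions equally; 1.0 gives a purely shifted
#'   flank (appropriate for homozygous deletions).
#' @param expected_events,cnv_duration,grid_copy See [build_state_space()].
#' @param eps_frac Poisson-mean floor for copy-0 states, as a fraction of
#'   `lambda * G` (tolerates mismapped reads inside homozygous deletions).
#' @return A `cnv_hmm`: list with `states`, `log_trans`, `log_init`,
#'   `insert_model`, `depth_model`, `het_mix_weight`, `eps_frac`,
#'   `logPd` (per-state distance log-pmf table, support x states).
#' @export
build_hmm <- function(insert_model, depth_model, genome_len,
                      grid_sizes = seq(200, 1600, by = 200),
                      het_mix_weight = 0.5,
                      expected_events = genome_len / 3e6,
                      cnv_duration = 10000, grid_copy = 1,
                      eps_frac = 0.01) {
  states <- build_state_space(grid_sizes, insert_D = round(insert_model$D),
                              genome_len = genome_len,
                              expected_events = expected_events,
                              cnv_duration = cnv_duration,
                              grid_copy = grid_copy)
  log_init <- rep(-Inf, nrow(states))
  log_init[1] <- 0  # decoding starts in Normal
  model <- structure(
    list(states = states, log_trans = build_transitions(states),
         log_init = log_init, insert_model = insert_model,
         depth_model = depth_model, het_mix_weight = het_mix_weight,
         eps_frac = eps_frac),
    class = "cnv_hmm"
  )
  model$logPd <- state_logpmf_table(model)
  model
}

#' @export
print.cnv_hmm <- function(x, ...) {
  ngrid <- sum(x$states$role == "grid_del")
  cat(sprintf(
    "cnv_hmm: %d states (%d grid rows), lambda = %.4f, D = %.1f, sigma = %.1f\n",
    nrow(x$states), ngrid, x$depth_model$lam, x$insert_model$D,
    x$insert_model$sigma))
  invisible(x)
}

#' Per-state outer-distance log-pmf table
#'
#' Column `j` holds `log p(d | state j)` over the support
#' `1..dist_cutoff`: the empirical pmf for zero-shift states, and the
#' heterozygous mixture `w * pmf(d - delta) + (1 - w) * pmf(d)` for
#' flanking states.
#'
#' @param model A `cnv_hmm`.
#' @return Numeric matrix, `dist_cutoff` rows x number of states.
#' @export
state_logpmf_table <- function(model) {
  im <- model$insert_model
  w <- model$het_mix_weight
  d <- seq_len(im$dist_cutoff)
  vapply(seq_len(nrow(model$states)), function(j) {
    delta <- model$states$delta[j]
    if (delta == 0) return(im$log_pmf)
    shifted <- insert_logpmf(im, d, delta = delta)
    log(w * exp(shifted) + (1 - w) * im$pmf)
  }, numeric(im$dist_cutoff))
}

#' Joint emission log-probability at one position
#'
#' The reference (R-level) emission: `log Poisson(n_t; mu)` with
#' `mu = max((C/2) * lambda * G_t, eps_frac * lambda * G_t)`, plus the
#' sum over attached outer-distances of the state's distance log-pmf.
#' The chromosome-scale decoder computes the identical quantity in C++.
#'
#' @param model A `cnv_hmm`.
#' @param state State index (row of `model$states`).
#' @param n_t Read-start count at the position.
#' @param dists_t Integer vector of outer-distances attached there (may
#'   be empty).
#' @param G_t GC adjustment factor at the position.
#' @return Log probability.
#' @export
emission_logprob <- function(model, state, n_t, dists_t = integer(0),
                             G_t = 1) {
  C <- model$states$C[state]
  lam <- model$depth_model$lam
  mu <- max(C / 2 * lam * G_t, model$eps_frac * lam * G_t)
  lp <- stats::dpois(n_t, mu, log = TRUE)
  if (length(dists_t) > 0) {
    ok <- dists_t >= 1 & dists_t <= model$insert_model$dist_cutoff
    lp <- lp + sum(model$logPd[dists_t[ok], state])
  }
  lp
}

#' Viterbi decoding of a position track
#'
#' Max-product dynamic program in log space over the joint depth +
#' mate-pair emissions; the initial distribution puts all mass on
#' Normal, and ties break toward the lowest state index. Positions with
#' `mask = TRUE` (reference N) contribute no evidence (emission 0 for
#' every state).
#'
#' @param track A `position_track`.
#' @param model A `cnv_hmm`.
#' @param G Per-position GC adjustment factors (default all 1); see
#'   [gc_adjust()].
#' @param mask Logical per-position mask (default none).
#' @return A `viterbi_result`: list with integer `path` (state index per
#'   position) and `loglik` of the best path.
#' @export
viterbi <- function(track, model, G = NULL, mask = NULL) {
  L <- track$length
  if (L == 0) {
    return(structure(list(path = integer(0), loglik = 0),
                     class = "viterbi_result"))
  }
  if (is.null(G)) G <- rep(1, L)
  if (is.null(mask)) mask <- rep(FALSE, L)
  stopifnot(length(G) == L, length(mask) == L)
  gvals <- sort(unique(G))
  gbin <- match(G, gvals) - 1L
  res <- viterbi_track_cpp(
    n = track$n, gbin = gbin, gvals = gvals, mask = mask,
    dist_pos = track$dist_pos, dist_val = track$dist_val,
    logPd = model$logPd, stateC = model$states$C,
    lambda = model$depth_model$lam, eps_frac = model$eps_frac,
    logT = model$log_trans, logInit = model$log_init
  )
  structure(list(path = res$path, loglik = res$loglik),
            class = "viterbi_result")
}

#' Viterbi decoding of an explicit emission matrix
#'
#' Generic decoder for small models (also the unit under the exhaustive
#' enumeration oracle in the test suite).
#'
#' @param logE Log-emission matrix, states x positions.
#' @param logT Log transition matrix.
#' @param logInit Log initial distribution.
#' @return A `viterbi_result`.
#' @export
viterbi_matrix <- function(logE, logT, logInit) {
  res <- viterbi_mat_cpp(logE, logT, logInit)
  structure(list(path = res$path, loglik = res$loglik),
            class = "viterbi_result")
}

#' Extract CNV calls from a decoded path
#'
#' Maximal runs of non-Normal copy-number states become calls: grid
#' interior deletion runs become DEL calls attributed to their grid row
#' (flanking-state runs are not part of the reported interval), Del1 and
#' Del2 runs become DEL calls with copy number 1 and 0, Dup1 and Dup2
#' runs DUP calls with copy number 3 and 4. Adjacent same-type calls
#' closer than `merge_gap` are merged. Calls lying entirely inside
#' masked (reference N) runs are suppressed.
#'
#' Intervals are 0-based half-open (BED convention).
#'
#' @param result A `viterbi_result`.
#' @param model The `cnv_hmm` used for decoding.
#' @param chrom Chromosome name for the output.
#' @param merge_gap Merge same-type calls separated by fewer than this
#'   many positions (default 0: no merging).
#' @param track,G Optional: the decoded `position_track` and adjustment
#'   factors, used to annotate each call with a log-likelihood-ratio
#'   score vs the all-Normal path and the mean outer-distance deviation
#'   of nearby pairs.
#' @param mask Optional logical mask used during decoding.
#' @return A `data.frame` of calls: `chrom`, `start`, `end`, `event`,
#'   `copy_number`, `source`, `score`, `mean_shift_evidence`.
#' @export
extract_calls <- function(result, model, chrom, merge_gap = 0,
                          track = NULL, G = NULL, mask = NULL) {
  st <- model$states
  path <- result$path
  empty <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    event = character(0), copy_number = integer(0), source = character(0),
    score = numeric(0), mean_shift_evidence = numeric(0),
    stringsAsFactors = FALSE
  )
  if (length(path) == 0) return(empty)
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  call_roles <- c("del1", "del2", "dup1", "dup2", "grid_del")
  keep <- st$role[r$values] %in% call_roles
  if (!any(keep)) return(empty)
  role <- st$role[r$values[keep]]
  event <- ifelse(role %in% c("dup1", "dup2"), "DUP", "DEL")
  cn <- st$C[r$values[keep]]
  src <- ifelse(role == "grid_del",
                paste0("grid row ", st$row[r$values[keep]]), role)
  calls <- data.frame(
    chrom = chrom, start = starts[keep] - 1L, end = ends[keep],
    event = event, copy_number = as.integer(cn), source = src,
    stringsAsFactors = FALSE
  )
  if (merge_gap > 0 && nrow(calls) > 1) {
    merged <- calls[1, , drop = FALSE]
    for (i in 2:nrow(calls)) {
      last <- nrow(merged)
      if (calls$event[i] == merged$event[last] &&
          calls$start[i] - merged$end[last] < merge_gap) {
        merged$end[last] <- calls$end[i]
      } else {
        merged <- rbind(merged, calls[i, , drop = FALSE])
      }
    }
    calls <- merged
  }
  if (!is.null(mask) && nrow(calls) > 0) {
    inside_mask <- vapply(seq_len(nrow(calls)), function(i) {
      all(mask[(calls$start[i] + 1):calls$end[i]])
    }, logical(1))
    calls <- calls[!inside_mask, , drop = FALSE]
  }
  calls$score <- NA_real_
  calls$mean_shift_evidence <- NA_real_
  if (!is.null(track) && nrow(calls) > 0) {
    if (is.null(G)) G <- rep(1, track$length)
    D <- model$insert_model$D
    lam <- model$depth_model$lam
    eps <- model$eps_frac
    Cs <- model$states$C
    for (i in seq_len(nrow(calls))) {
      pos <- (calls$start[i] + 1):calls$end[i]
      mu_s <- pmax(Cs[path[pos]] / 2, eps) * lam * G[pos]
      mu_0 <- pmax(Cs[1] / 2, eps) * lam * G[pos]
      llr <- sum(stats::dpois(track$n[pos], mu_s, log = TRUE) -
                 stats::dpois(track$n[pos], mu_0, log = TRUE))
      # distance records inside the call (dist_pos is sorted)
      lo <- findInterval(calls$start[i], track$dist_pos) + 1L
      hi <- findInterval(calls$end[i], track$dist_pos)
      if (hi >= lo) {
        dd <- track$dist_val[lo:hi]
        ss <- path[track$dist_pos[lo:hi]]
        llr <- llr + sum(model$logPd[cbind(dd, ss)] - model$logPd[dd, 1])
      }
      calls$score[i] <- llr
      flo <- findInterval(calls$start[i] - round(D), track$dist_pos) + 1L
      if (hi >= flo) {
        calls$mean_shift_evidence[i] <-
          mean(track$dist_val[flo:hi]) - D
      }
    }
  }
  rownames(calls) <- NULL
  calls
}
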