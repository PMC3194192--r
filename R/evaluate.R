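#' Reciprocal (mutual) overlap of two intervals
#'
#' `min(ovl / len(a), ovl / len(b))` where `ovl` is the intersection
#' length (0 if disjoint). 50% reciprocal overlap is the standard
#' criterion for counting a CNV call as correct against truth.
#'
#' @param a_start,a_end,b_start,b_end Interval bounds, 0-based
#'   half-open (vectorised).
#' @return Fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  la <- a_end - a_start
  lb <- b_end - b_start
  if (any(la <= 0) || any(lb <= 0)) stop("zero-length interval")
  ovl <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  pmin(ovl / la, ovl / lb)
}

#' Match CNV calls against truth
#'
#' Greedy one-to-one matching: among same-chromosome, same-event-type
#' (DEL with DEL, DUP with DUP) pairs whose reciprocal overlap reaches
#' `threshold`, pairs are matched in descending overlap order, each call
#' and each truth interval at most once. Copy number is not compared
#' (detection, not genotyping).
#'
#' @param calls Data.frame of calls (`chrom`, `start`, `end`, `event`).
#' @param truth Data.frame of true events (same columns).
#' @param threshold Reciprocal-overlap threshold, default 0.5.
#' @return A `match_report`: list with `n_truth`, `n_calls`,
#'   `n_matched`, `sensitivity`, `matches` (data.frame of matched index
#'   pairs and overlaps), `false_calls` (unmatched calls),
#'   `missed_truth`, and `per_size` (sensitivity by truth event size).
#' @export
match_calls <- function(calls, truth, threshold = 0.5) {
  n_truth <- nrow(truth)
  n_calls <- nrow(calls)
  matches <- data.frame(call = integer(0), truth = integer(0),
                        overlap = numeric(0))
  if (n_truth > 0 && n_calls > 0) {
    cg <- GenomicRanges::GRanges(calls$chrom,
      IRanges::IRanges(calls$start + 1, calls$end))
    tg <- GenomicRanges::GRanges(truth$chrom,
      IRanges::IRanges(truth$start + 1, truth$end))
    hits <- GenomicRanges::findOverlaps(cg, tg)
    ci <- S4Vectors::queryHits(hits)
    ti <- S4Vectors::subjectHits(hits)
    same_type <- calls$event[ci] == truth$event[ti]
    ro <- reciprocal_overlap(calls$start[ci], calls$end[ci],
                             truth$start[ti], truth$end[ti])
    keep <- same_type & ro >= threshold
    ci <- ci[keep]; ti <- ti[keep]; ro <- ro[keep]
    o <- order(-ro, ti, ci)  # deterministic greedy order
    used_c <- logical(n_calls)
    used_t <- logical(n_truth)
    for (k in o) {
      if (!used_c[ci[k]] && !used_t[ti[k]]) {
        used_c[ci[k]] <- TRUE
        used_t[ti[k]] <- TRUE
        matches <- rbind(matches, data.frame(call = ci[k], truth = ti[k],
                                             overlap = ro[k]))
      }
    }
  }
  n_matched <- nrow(matches)
  sens <- if (n_truth > 0) n_matched / n_truth else NA_real_
  per_size <- NULL
  if (n_truth > 0) {
    size <- truth$end - truth$start
    matched_t <- logical(n_truth)
    matched_t[matches$truth] <- TRUE
    per_size <- stats::aggregate(
      list(n_truth = rep(1, n_truth), n_matched = as.integer(matched_t)),
      by = list(size = size, event = truth$event), FUN = sum)
    per_size$sensitivity <- per_size$n_matched / per_size$n_truth
  }
  structure(
    list(n_truth = n_truth, n_calls = n_calls, n_matched = n_matched,
         sensitivity = sens, matches = matches,
         false_calls = if (n_calls > 0) {
           fc <- rep(TRUE, n_calls); fc[matches$call] <- FALSE
           calls[fc, , drop = FALSE]
         } else calls,
         missed_truth = if (n_truth > 0) {
           mt <- rep(TRUE, n_truth); mt[matches$truth] <- FALSE
           truth[mt, , drop = FALSE]
         } else truth,
         per_size = per_size, threshold = threshold),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "match_report: %d/%d truth matched (sensitivity %.3f), %d calls, %d unmatched calls\n",
    x$n_matched, x$n_truth,
    ifelse(is.na(x$sensitivity), NaN, x$sensitivity),
    x$n_calls, nrow(x$false_calls)))
  invisible(x)
}

#' Empirical power curve of the caller on simulated data
#'
#' For each coverage (and optionally each insert library), simulates a
#' diploid genome with planted heterozygous deletions of the requested
#' sizes, runs the full calling pipeline, matches calls to truth at 50%
#' reciprocal overlap, and tabulates sensitivity per (coverage, size,
#' library) with binomial standard errors, side by side with the
#' theoretical multi-pair power for the same parameters.
#'
#' @param coverages Haploid fold coverages to scan.
#' @param sizes Deletion sizes (bp).
#' @param n_per_size Planted events per size per replicate.
#' @param ref_len Simulated genome length (bp).
#' @param libraries List of `c(mean, sd)` libraries, each simulated as
#'   its own run.
#' @param replicates Replicates per cell.
#' @param seed Base seed; each cell derives its own.
#' @param config Caller configuration ([caller_config()]).
#' @param threshold Reciprocal-overlap threshold.
#' @return Data.frame with one row per (coverage, size, library,
#'   replicate): `n_truth`, `n_matched`, `sensitivity`, `se`,
#'   `theory` (theoretical multi-pair power), `n_false_calls`.
#' @export
power_curve <- function(coverages, sizes = c(400, 800), n_per_size = 100,
                        ref_len = 2e6,
                        libraries = list(c(1500, 200)),
                        replicates = 1, seed = 1,
                        config = caller_config(), threshold = 0.5) {
  rows <- list()
  cell <- 0
  for (cov in coverages) {
    for (li in seq_along(libraries)) {
      for (rep_i in seq_len(replicates)) {
        cell <- cell + 1
        cfg <- sim_config(
          ref_len = ref_len, n_del = n_per_size * length(sizes),
          del_sizes = sizes, zygosity = "het", coverage = cov,
          read_len = 35, libraries = libraries[li],
          seed = (seed * 1000L + cell) %% .Machine$integer.max
        )
        sim <- simulate_dataset(cfg)
        res <- tryCatch(
          call_cnvs(sim$reads, sim$ref, chrom = cfg$chrom, config = config),
          error = function(e) {
            stop("power_curve cell failed (coverage=", cov, ", library=",
                 paste(libraries[[li]], collapse = "/"), ", replicate=",
                 rep_i, "): ", conditionMessage(e))
          })
        rep_match <- match_calls(res$calls, sim$truth, threshold)
        lam <- 2 * cov / cfg$read_len
        for (sz in sizes) {
          ps <- rep_match$per_size
          row <- ps[ps$size == sz, , drop = FALSE]
          n_t <- sum(row$n_truth)
          n_m <- sum(row$n_matched)
          sens <- if (n_t > 0) n_m / n_t else NA_real_
          rows[[length(rows) + 1]] <- data.frame(
            coverage = cov, size = sz, lib_mean = libraries[[li]][1],
            lib_sd = libraries[[li]][2], replicate = rep_i,
            n_truth = n_t, n_matched = n_m, sensitivity = sens,
            se = if (n_t > 0) sqrt(sens * (1 - sens) / n_t) else NA_real_,
            theory = multi_pair_power(sz, lam, D = libraries[[li]][1],
                                      sigma = libraries[[li]][2],
                                      zygosity = "het"),
            n_false_calls = nrow(rep_match$false_calls)
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
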