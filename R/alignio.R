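#' Parse mapview-style alignment records
#'
#' Reads the tab-delimited alignment dialect produced by maq's `mapview`
#' (and by [simulate_dataset()]). The columns consumed are: read name,
#' chromosome, 1-based leftmost position, strand (`+`/`-`), signed
#' outer-distance, mapping quality and read length; extra columns are
#' ignored, and lines starting with `#` are treated as headers.
#'
#' @param input Path to a file, or a character vector of lines.
#' @param mapq_min Minimum mapping quality; records below are dropped.
#'   Default 0 (no filter).
#' @param dist_cutoff Maximum outer-distance retained as mate-pair
#'   evidence downstream (bp); stored as an attribute, applied by
#'   [build_position_track()].
#' @return A `data.frame` with columns `name`, `chrom`, `pos`, `strand`,
#'   `outer_dist`, `mapq`, `read_len`, of class `aligned_reads`.
#'   Attribute `n_malformed` counts skipped lines (reported with a
#'   warning when nonzero).
#' @export
parse_mapview <- function(input, mapq_min = 0, dist_cutoff = 6000) {
  if (length(input) == 1 && !grepl("\t", input)) {
    if (!file.exists(input)) stop("cannot read alignment input: ", input)
    lines <- readLines(input)
  } else {
    lines <- input
  }
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- empty_reads()
    attr(out, "n_malformed") <- 0L
    attr(out, "dist_cutoff") <- dist_cutoff
    return(out)
  }
  cols <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  bad <- if (length(cols) < 7) rep(TRUE, length(lines)) else is.na(cols[[7]])
  pos <- suppressWarnings(as.integer(cols[[3]]))
  odist <- suppressWarnings(as.integer(cols[[5]]))
  mapq <- suppressWarnings(as.integer(cols[[6]]))
  rlen <- if (length(cols) >= 7) suppressWarnings(as.integer(cols[[7]])) else NA_integer_
  bad <- bad | is.na(pos) | is.na(mapq) | is.na(rlen) | pos < 1 | rlen < 1 |
    !(cols[[4]] %in% c("+", "-"))
  bad[is.na(bad)] <- TRUE
  n_malformed <- sum(bad)
  if (n_malformed > 0) {
    warning(n_malformed, " malformed mapview line(s) skipped")
  }
  keep <- !bad & mapq >= mapq_min
  keep[is.na(keep)] <- FALSE
  odist[is.na(odist)] <- 0L
  out <- data.frame(
    name = cols[[1]][keep], chrom = cols[[2]][keep], pos = pos[keep],
    strand = cols[[4]][keep], outer_dist = odist[keep], mapq = mapq[keep],
    read_len = rlen[keep], stringsAsFactors = FALSE
  )
  class(out) <- c("aligned_reads", "data.frame")
  attr(out, "n_malformed") <- n_malformed
  attr(out, "dist_cutoff") <- dist_cutoff
  out
}

empty_reads <- function() {
  out <- data.frame(
    name = character(0), chrom = character(0), pos = integer(0),
    strand = character(0), outer_dist = integer(0), mapq = integer(0),
    read_len = integer(0), stringsAsFactors = FALSE
  )
  class(out) <- c("aligned_reads", "data.frame")
  out
}

#' Write alignment records as mapview-dialect text
#'
#' @param reads An `aligned_reads` data.frame (see [parse_mapview()]).
#' @param path Output file path.
#' @param header Optional character vector of header lines (each will be
#'   prefixed with `#`).
#' @export
write_mapview <- function(reads, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(reads) > 0) {
    lines <- paste(reads$name, reads$chrom, reads$pos, reads$strand,
                   reads$outer_dist, reads$mapq, reads$read_len, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Outer-distance of a forward-reverse read pair
#'
#' Defined as `E - S`: the mapped 3'-most coordinate `E` of the
#' negative-strand read minus the 5' coordinate `S` of the
#' positive-strand read. A deletion contained in the insert inflates the
#' mapped outer-distance by its size, which is the signal the flanking
#' states of the HMM exploit. Negative values indicate everted or
#' otherwise aberrant pairs and are excluded from distance evidence
#' downstream.
#'
#' @param pos_plus 5' coordinate of the positive-strand read.
#' @param end3_minus 3'-most mapped coordinate of the negative-strand read.
#' @return Signed distance in bp (vectorised).
#' @export
outer_distance <- function(pos_plus, end3_minus) {
  end3_minus - pos_plus
}

#' Build the per-position observation track
#'
#' The HMM observes, at every reference position, the number of read
#' starts `n` (both strands) and the outer-distances of pairs whose
#' leftmost (positive-strand) mate starts there. Each pair contributes
#' its distance exactly once, at the leftmost mate, so a pair's evidence
#' is never double counted. Distances outside `(0, dist_cutoff]` are
#' discarded (the pair still contributes depth).
#'
#' @param reads `aligned_reads` records, all on one chromosome.
#' @param chrom_len Chromosome length in bp.
#' @param dist_cutoff Maximum retained outer-distance (bp).
#' @return A `position_track`: list with `chrom`, `length`, integer
#'   vector `n` (read starts per position, 1-based indexing), and
#'   parallel vectors `dist_pos`/`dist_val` (positions and values of
#'   retained outer-distances, sorted by position).
#' @export
build_position_track <- function(reads, chrom_len, dist_cutoff = 6000) {
  chrom <- if (nrow(reads) > 0) unique(reads$chrom) else NA_character_
  if (length(chrom) > 1) {
    stop("build_position_track expects reads from a single chromosome, got: ",
         paste(chrom, collapse = ", "))
  }
  off <- reads$pos > chrom_len
  if (any(off)) {
    warning(sum(off), " read(s) beyond chromosome end skipped")
    reads <- reads[!off, , drop = FALSE]
  }
  n <- tabulate(reads$pos, nbins = chrom_len)
  isplus <- reads$strand == "+" & reads$outer_dist > 0 &
    reads$outer_dist <= dist_cutoff
  dp <- reads$pos[isplus]
  dv <- reads$outer_dist[isplus]
  o <- order(dp)
  structure(
    list(chrom = chrom, length = as.integer(chrom_len), n = as.integer(n),
         dist_pos = as.integer(dp[o]), dist_val = as.integer(dv[o]),
         dist_cutoff = as.integer(dist_cutoff)),
    class = "position_track"
  )
}

#' @export
print.position_track <- function(x, ...) {
  cat(sprintf(
    "position_track: %s (%d bp), %d read starts, %d mate-pair distances\n",
    x$chrom, x$length, sum(x$n), length(x$dist_val)))
  invisible(x)
}

#' Outer-distances attached at a position
#' @param track A `position_track`.
#' @param pos 1-based position.
#' @return Integer vector of retained outer-distances at `pos`.
#' @export
track_dists_at <- function(track, pos) {
  track$dist_val[track$dist_pos == pos]
}

#' Fit the empirical insert-size (outer-distance) model
#'
#' The null distribution of mapped outer-distances is taken to be the
#' empirical distribution of all retained pairs from the same run,
#' Laplace-smoothed over the integer support `[1, dist_cutoff]` so that
#' mean-shifted evaluations never return zero. `D` and `sigma` are the
#' sample mean and standard deviation; `sigma` is floored at 1 bp to
#' keep power formulas defined on degenerate inputs.
#'
#' @param dists Integer vector of retained outer-distances (at least 100).
#' @param dist_cutoff Support upper bound (bp).
#' @param pseudocount Laplace pseudocount per support cell.
#' @return An `insert_model`: list with `D`, `sigma`, `pmf` (length
#'   `dist_cutoff`), `log_pmf`, `floor_p` (smoothing mass used outside
#'   the support for shifted lookups), `dist_cutoff`.
#' @export
fit_insert_model <- function(dists, dist_cutoff = 6000, pseudocount = 1) {
  dists <- as.integer(dists)
  if (length(dists) < 100) {
    stop("need at least 100 outer-distances to fit the insert model (got ",
         length(dists), "); simulate more pairs or supply D/sigma explicitly ",
         "via insert_model_gaussian()")
  }
  if (any(dists < 1 | dists > dist_cutoff)) {
    stop("distances outside [1, dist_cutoff] must be filtered before fitting")
  }
  counts <- tabulate(dists, nbins = dist_cutoff)
  tot <- sum(counts) + pseudocount * dist_cutoff
  pmf <- (counts + pseudocount) / tot
  floor_p <- if (pseudocount > 0) pseudocount / tot else .Machine$double.xmin
  new_insert_model(D = mean(dists), sigma = max(stats::sd(dists), 1),
                   pmf = pmf, floor_p = floor_p, dist_cutoff = dist_cutoff)
}

#' Gaussian insert model on an integer support
#'
#' Discretised Gaussian alternative to [fit_insert_model()], used when
#' the library parameters are known (or for closed-form cross-checks).
#'
#' @param D,sigma Library mean and sd (bp).
#' @param dist_cutoff Support upper bound (bp).
#' @return An `insert_model`.
#' @export
insert_model_gaussian <- function(D, sigma, dist_cutoff = 6000) {
  x <- seq_len(dist_cutoff)
  p <- stats::pnorm(x + 0.5, D, sigma) - stats::pnorm(x - 0.5, D, sigma)
  p <- pmax(p, .Machine$double.xmin)
  p <- p / sum(p)
  new_insert_model(D = D, sigma = sigma, pmf = p,
                   floor_p = .Machine$double.xmin, dist_cutoff = dist_cutoff)
}

new_insert_model <- function(D, sigma, pmf, floor_p, dist_cutoff) {
  structure(
    list(D = D, sigma = sigma, pmf = pmf, log_pmf = log(pmf),
         floor_p = floor_p, log_floor = log(floor_p),
         dist_cutoff = as.integer(dist_cutoff)),
    class = "insert_model"
  )
}

#' @export
print.insert_model <- function(x, ...) {
  cat(sprintf("insert_model: D = %.1f bp, sigma = %.1f bp, support [1, %d]\n",
              x$D, x$sigma, x$dist_cutoff))
  invisible(x)
}

#' Log probability of an outer-distance under a (shifted) insert model
#'
#' A state whose flanks contain a deletion of size `delta` sees the
#' empirical distribution translated by `delta` (same shape, mean
#' `D + delta`). Values falling outside the support return the smoothing
#' floor.
#'
#' @param model An `insert_model`.
#' @param d Integer distances (vectorised).
#' @param delta Mean shift in bp (0 for copy-number states without
#'   flanking-deletion distance signal).
#' @return Log probabilities.
#' @export
insert_logpmf <- function(model, d, delta = 0) {
  x <- as.integer(d) - as.integer(delta)
  ok <- x >= 1L & x <= model$dist_cutoff
  out <- rep(model$log_floor, length(x))
  out[ok] <- model$log_pmf[x[ok]]
  out
}

#' Per-position GC fraction and reference mask
#'
#' GC fraction of a centered window (truncated at chromosome ends);
#' positions whose reference base is `N` are masked.
#'
#' @param ref_seq A `DNAString`, or a character scalar sequence.
#' @param gc_window Window width in bp.
#' @return List with numeric `gc` (per position, in `[0,1]`) and logical
#'   `mask` (`TRUE` where the base is N).
#' @export
gc_profile <- function(ref_seq, gc_window = 100) {
  dna <- as_dna(ref_seq)
  L <- length(dna)
  mask <- as.integer(Biostrings::letterFrequencyInSlidingView(
    dna, 1, "N")) > 0
  if (L < gc_window) {
    f <- Biostrings::letterFrequency(dna, "GC", as.prob = FALSE)
    acgt <- L - sum(mask)
    gc <- rep(if (acgt > 0) f / acgt else 0.5, L)
    return(list(gc = as.numeric(gc), mask = mask))
  }
  slid <- Biostrings::letterFrequencyInSlidingView(dna, gc_window,
                                                  c("GC", "N"))
  denom <- gc_window - slid[, "N"]
  frac <- ifelse(denom > 0, slid[, "G|C"] / denom, 0.5)
  # view starting at i covers [i, i + w - 1]; center position i + w %/% 2
  starts <- pmin(pmax(seq_len(L) - gc_window %/% 2, 1L), L - gc_window + 1L)
  list(gc = as.numeric(frac[starts]), mask = mask)
}

as_dna <- function(ref_seq) {
  if (methods::is(ref_seq, "DNAString")) return(ref_seq)
  if (methods::is(ref_seq, "DNAStringSet")) {
    if (length(ref_seq) != 1) stop("expected a single sequence")
    return(ref_seq[[1]])
  }
  Biostrings::DNAString(ref_seq)
}

#' Fit the GC depth-adjustment model
#'
#' Systematic depth bias is dominated by local GC content; the model
#' bins positions by windowed GC fraction and assigns each bin an
#' adjustment factor `G` = (mean read starts in bin) / lambda, clipped
#' to `[0.1, 10]`. Bins with fewer than 1000 positions fall back to
#' `G = 1`. `lambda` is the genome-wide mean read-start rate over non-N
#' positions.
#'
#' @param track A `position_track`.
#' @param ref_seq Reference sequence for the same chromosome.
#' @param gc_window GC window width (bp).
#' @param n_bins Number of equal-width GC-fraction bins on `[0, 1]`.
#' @param min_bin_positions Bin occupancy below which `G` falls back to 1.
#' @return A `depth_model`: list with `lam`, `gc_window`, `n_bins`,
#'   `G` (per-bin factors), `bin_counts`.
#' @export
fit_gc_model <- function(track, ref_seq, gc_window = 100, n_bins = 20,
                         min_bin_positions = 1000) {
  prof <- gc_profile(ref_seq, gc_window)
  if (length(prof$gc) != track$length) {
    stop("reference length (", length(prof$gc),
         ") does not match track length (", track$length, ")")
  }
  ok <- !prof$mask
  if (!any(ok)) stop("reference is all N; cannot fit a depth model")
  lam <- sum(track$n[ok]) / sum(ok)
  if (lam <= 0) stop("no reads on non-N positions; cannot fit a depth model")
  bins <- gc_bin_index(prof$gc, n_bins)
  G <- rep(1, n_bins)
  cnt <- tabulate(bins[ok], nbins = n_bins)
  mean_n <- vapply(seq_len(n_bins), function(b) {
    sel <- ok & bins == b
    if (any(sel)) mean(track$n[sel]) else NA_real_
  }, numeric(1))
  fit <- cnt >= min_bin_positions & !is.na(mean_n)
  G[fit] <- pmin(pmax(mean_n[fit] / lam, 0.1), 10)
  structure(
    list(lam = lam, gc_window = as.integer(gc_window),
         n_bins = as.integer(n_bins), G = G, bin_counts = cnt),
    class = "depth_model"
  )
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf("depth_model: lambda = %.4f read starts/bp, %d GC bins (window %d bp)\n",
              x$lam, x$n_bins, x$gc_window))
  invisible(x)
}

#' GC-fraction bin index
#' @param gc Numeric GC fractions in `[0, 1]`.
#' @param n_bins Number of equal-width bins.
#' @return Integer bin index in `1..n_bins`.
#' @export
gc_bin_index <- function(gc, n_bins) {
  pmin(pmax(floor(gc * n_bins) + 1L, 1L), as.integer(n_bins))
}

#' Per-position GC adjustment factors
#' @param model A `depth_model`.
#' @param ref_seq Reference sequence (same chromosome as the data the
#'   factors will be applied to).
#' @return List with numeric `G` per position and logical `mask`.
#' @export
gc_adjust <- function(model, ref_seq) {
  prof <- gc_profile(ref_seq, model$gc_window)
  bins <- gc_bin_index(prof$gc, model$n_bins)
  list(G = model$G[bins], bin = bins, mask = prof$mask)
}

#' Read a reference FASTA
#' @param path FASTA file (records matched to chromosome names exactly).
#' @return A `DNAStringSet` with names truncated at the first whitespace.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
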