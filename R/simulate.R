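#' Simulation configuration
#'
#' Describes a diploid genome derived from a (synthetic or supplied)
#' reference by planting heterozygous or homozygous deletions and
#' tandem duplications, and a paired-end sequencing experiment over it:
#' fixed-length reads, one or more Gaussian insert-size libraries, and
#' uniform fragment sampling at a given fold coverage per haplotype.
#'
#' @param ref_len Reference length in bp (ignored if `ref_seq` given).
#' @param n_del,del_sizes Number and sizes (bp) of planted deletions;
#'   sizes are assigned in balanced rotation from `del_sizes` (equal
#'   counts per size, order shuffled).
#' @param n_dup,dup_sizes Ditto for tandem duplications.
#' @param zygosity `"het"` (each event on one random haplotype) or
#'   `"hom"` (both).
#' @param coverage Haploid fold coverage: each haplotype receives
#'   `coverage * hap_len / (2 * read_len)` pairs in total (split
#'   equally across libraries), i.e. `coverage` sequenced bases per
#'   haplotype base and a read-start rate of `2 * coverage / read_len`
#'   on the diploid sample.
#' @param read_len Read length (bp), default 35.
#' @param libraries List of `c(mean, sd)` insert libraries; defaults to
#'   a short-insert library (200, 20) and a long-insert library
#'   (1500, 200).
#' @param seed Integer seed; all randomness in [simulate_dataset()]
#'   derives from it.
#' @param min_anchor A read crossing a breakpoint junction is kept
#'   (mapped to the side holding most of it) only if the minor-side
#'   overhang is under this many bp; larger overhangs make the read
#'   unmappable. Default 5.
#' @param min_sep Minimum gap between planted events (bp); default
#'   twice the largest library mean, keeping flanking evidence of
#'   neighbouring events disjoint.
#' @param gc_bias Strength of an optional GC sampling bias in `[0, 1)`;
#'   0 (default) samples fragments uniformly, larger values accept
#'   fragments with probability `1 + gc_bias * 2 * (gc - 0.5)` (local
#'   GC of the fragment start), exercising the depth-adjustment model.
#' @param chrom Chromosome name used in all outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(ref_len = 1e6, n_del = 0, del_sizes = c(400, 800),
                       n_dup = 0, dup_sizes = c(5000),
                       zygosity = c("het", "hom"), coverage = 3,
                       read_len = 35,
                       libraries = list(c(200, 20), c(1500, 200)),
                       seed = 1, min_anchor = 5, min_sep = NULL,
                       gc_bias = 0, chrom = "sim1") {
  zygosity <- match.arg(zygosity)
  if (!is.list(libraries)) libraries <- list(libraries)
  stopifnot(ref_len >= 1000, coverage > 0, read_len > 0,
            all(vapply(libraries, length, 1L) == 2),
            n_del >= 0, n_dup >= 0, gc_bias >= 0, gc_bias < 1)
  if (n_del > 0 && any(del_sizes < read_len)) {
    stop("all event sizes must be >= read_len")
  }
  if (n_dup > 0 && any(dup_sizes < read_len)) {
    stop("all event sizes must be >= read_len")
  }
  max_mean <- max(vapply(libraries, `[`, numeric(1), 1))
  if (is.null(min_sep)) min_sep <- 2 * max_mean
  structure(
    list(ref_len = as.integer(ref_len), n_del = as.integer(n_del),
         del_sizes = as.integer(del_sizes), n_dup = as.integer(n_dup),
         dup_sizes = as.integer(dup_sizes), zygosity = zygosity,
         coverage = coverage, read_len = as.integer(read_len),
         libraries = libraries, seed = as.integer(seed),
         min_anchor = as.integer(min_anchor),
         min_sep = as.integer(min_sep),
         margin = as.integer(max_mean + max(c(del_sizes, dup_sizes, 0))),
         gc_bias = gc_bias, chrom = chrom),
    class = "sim_config"
  )
}

#' Uniform-GC synthetic reference sequence
#'
#' Bases drawn i.i.d. uniformly from A/C/G/T (expected GC 0.5, no N
#' runs), using the current RNG state.
#'
#' @param len Length in bp.
#' @return A `DNAString`.
#' @export
random_reference <- function(len) {
  Biostrings::DNAString(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
}

#' Plant CNVs on a diploid genome
#'
#' Places the configured deletions and duplications at random positions
#' by rejection sampling, keeping events at least `min_sep` bp apart
#' and `margin` bp from the chromosome ends. Heterozygous events land
#' on one haplotype chosen by a fair coin; homozygous events on both.
#' Uses the current RNG state ([simulate_dataset()] seeds it).
#'
#' @param cfg A `sim_config`.
#' @return List with `truth` (data.frame: `chrom`, `start`, `end`
#'   0-based half-open, `event`, `zygosity`, `size`, `hap` in
#'   `{"1","2","both"}`, sorted by start) and `hap_events` (per-haplotype
#'   event tables for coordinate lift-over).
#' @export
plant_cnvs <- function(cfg) {
  sizes <- integer(0)
  events <- character(0)
  if (cfg$n_del > 0) {
    # balanced rotation over the size list, order shuffled
    sizes <- c(sizes, rep_len(cfg$del_sizes, cfg$n_del)[sample.int(cfg$n_del)])
    events <- c(events, rep("DEL", cfg$n_del))
  }
  if (cfg$n_dup > 0) {
    sizes <- c(sizes, rep_len(cfg$dup_sizes, cfg$n_dup)[sample.int(cfg$n_dup)])
    events <- c(events, rep("DUP", cfg$n_dup))
  }
  n <- length(sizes)
  empty_truth <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    event = character(0), zygosity = character(0), size = integer(0),
    hap = character(0), stringsAsFactors = FALSE
  )
  if (n == 0) {
    return(list(truth = empty_truth,
                hap_events = list(empty_truth, empty_truth)))
  }
  lo <- cfg$margin
  starts <- integer(n)
  acc_s <- integer(0)
  acc_e <- integer(0)
  for (i in seq_len(n)) {
    hi <- cfg$ref_len - cfg$margin - sizes[i]
    if (hi <= lo) stop("genome too short to place events; increase ref_len")
    placed <- FALSE
    for (att in seq_len(1000)) {
      s <- lo + floor(stats::runif(1) * (hi - lo + 1))
      if (all(s >= acc_e + cfg$min_sep | s + sizes[i] + cfg$min_sep <= acc_s)) {
        starts[i] <- s
        acc_s <- c(acc_s, s)
        acc_e <- c(acc_e, s + sizes[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " events with ", cfg$min_sep,
           " bp separation after 1000 attempts; use a longer genome")
    }
  }
  hap <- if (cfg$zygosity == "hom") {
    rep("both", n)
  } else {
    as.character(1 + stats::rbinom(n, 1, 0.5))
  }
  truth <- data.frame(
    chrom = cfg$chrom, start = starts, end = starts + sizes,
    event = events, zygosity = cfg$zygosity, size = sizes, hap = hap,
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  hap_events <- lapply(c("1", "2"), function(h) {
    truth[truth$hap %in% c(h, "both"), , drop = FALSE]
  })
  list(truth = truth, hap_events = hap_events)
}

# Maximal reference-contiguous runs of a haplotype carrying the given
# events, in haplotype order. Block boundaries are breakpoint junctions.
hap_blocks <- function(events, ref_len) {
  ref_start <- integer(0)
  ref_end <- integer(0)
  cur <- 0L
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      if (events$event[i] == "DEL") {
        ref_start <- c(ref_start, cur)
        ref_end <- c(ref_end, events$start[i])
        cur <- events$end[i]
      } else {  # tandem DUP: run ends after the first copy, second copy
        ref_start <- c(ref_start, cur)  # restarts at the event start
        ref_end <- c(ref_end, events$end[i])
        cur <- events$start[i]
      }
    }
  }
  ref_start <- c(ref_start, cur)
  ref_end <- c(ref_end, ref_len)
  len <- ref_end - ref_start
  hap_start <- cumsum(c(0L, len[-length(len)]))
  data.frame(hap_start = hap_start, len = len, ref_start = ref_start)
}

# Map 0-based haplotype read starts to reference coordinates.
# Reads crossing a junction with minor-side overhang < min_anchor map to
# their major block; others return NA (unmappable).
lift_read_starts <- function(pos, read_len, blocks, min_anchor) {
  b1 <- findInterval(pos, blocks$hap_start)
  b2 <- findInterval(pos + read_len - 1L, blocks$hap_start)
  ref <- as.integer(blocks$ref_start[b1] + (pos - blocks$hap_start[b1]))
  cross <- which(b2 != b1)
  if (length(cross) > 0) {
    left_len <- blocks$hap_start[b1[cross] + 1L] - pos[cross]
    right_len <- read_len - left_len
    # reference start the read would have if anchored in its right block
    ref_right <- as.integer(blocks$ref_start[b2[cross]] +
      (pos[cross] - blocks$hap_start[b2[cross]]))
    res <- rep(NA_integer_, length(cross))
    one <- b2[cross] == b1[cross] + 1L
    keep_left <- one & left_len >= right_len & right_len < min_anchor
    keep_right <- one & right_len > left_len & left_len < min_anchor
    res[keep_left] <- ref[cross][keep_left]
    res[keep_right] <- ref_right[keep_right]
    ref[cross] <- res
  }
  ref
}

#' Simulate aligned read pairs over a diploid genome
#'
#' For each haplotype and insert library, draws fragments uniformly
#' (insert outer span from a rounded Gaussian, clamped at twice the
#' read length), places forward-reverse 35 bp-style read pairs, and
#' maps both reads back to reference coordinates through the
#' haplotype's deletion/duplication lift-over. Pairs spanning a planted
#' deletion on the carrier haplotype therefore map with outer-distance
#' inflated by the deletion size; reads over breakpoint junctions are
#' discarded or snapped per `min_anchor` (see [sim_config()]). Uses the
#' current RNG state.
#'
#' @param cfg A `sim_config`.
#' @param hap_events Per-haplotype event tables from [plant_cnvs()].
#' @param ref_seq Optional reference sequence; required when
#'   `cfg$gc_bias > 0`.
#' @return An `aligned_reads` data.frame (mapview dialect fields plus a
#'   `lib` column), sorted by position. The mate of a discarded read
#'   keeps `outer_dist = 0` (no pair evidence).
#' @export
simulate_pairs <- function(cfg, hap_events, ref_seq = NULL) {
  S <- cfg$read_len
  nlib <- length(cfg$libraries)
  gcw <- NULL
  if (cfg$gc_bias > 0) {
    if (is.null(ref_seq)) stop("gc_bias > 0 requires ref_seq")
    gcw <- gc_profile(ref_seq, 100)$gc
  }
  parts <- list()
  for (h in 1:2) {
    blocks <- hap_blocks(hap_events[[h]], cfg$ref_len)
    hapL <- sum(blocks$len)
    for (li in seq_len(nlib)) {
      lib <- cfg$libraries[[li]]
      n_pairs <- round(cfg$coverage * hapL / (2 * S) / nlib)
      if (n_pairs == 0) next
      d <- pmax(as.integer(round(stats::rnorm(n_pairs, lib[1], lib[2]))),
                2L * S)
      ok <- d <= hapL - 1L
      d <- d[ok]
      f <- as.integer(floor(stats::runif(length(d)) * (hapL - d)))
      ref_p <- lift_read_starts(f, S, blocks, cfg$min_anchor)
      ref_m <- lift_read_starts(f + d - S + 1L, S, blocks, cfg$min_anchor)
      if (!is.null(gcw)) {
        anchor <- ifelse(is.na(ref_p), ref_m, ref_p)
        u <- stats::runif(length(d))
        w <- 1 + cfg$gc_bias * 2 * (gcw[pmin(anchor + 1L, cfg$ref_len)] - 0.5)
        keep_pair <- !is.na(anchor) & u < w / (1 + cfg$gc_bias)
        ref_p[!keep_pair] <- NA_integer_
        ref_m[!keep_pair] <- NA_integer_
      }
      dmap <- (ref_m + S - 1L) - ref_p  # mapped outer-distance
      id <- paste0("h", h, "l", li, "p", seq_along(d))
      plus <- data.frame(
        name = id, chrom = cfg$chrom, pos = ref_p + 1L, strand = "+",
        outer_dist = ifelse(is.na(dmap), 0L, dmap), mapq = 99L,
        read_len = S, lib = li, stringsAsFactors = FALSE
      )[!is.na(ref_p), , drop = FALSE]
      minus <- data.frame(
        name = id, chrom = cfg$chrom, pos = ref_m + 1L, strand = "-",
        outer_dist = ifelse(is.na(dmap), 0L, -dmap), mapq = 99L,
        read_len = S, lib = li, stringsAsFactors = FALSE
      )[!is.na(ref_m), , drop = FALSE]
      parts[[length(parts) + 1]] <- plus
      parts[[length(parts) + 1]] <- minus
    }
  }
  out <- if (length(parts) > 0) do.call(rbind, parts) else {
    cbind(empty_reads(), lib = integer(0))
  }
  out <- out[order(out$pos, out$name, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("aligned_reads", "data.frame")
  out
}

#' Run a full simulation
#'
#' Seeds the RNG from `cfg$seed`, builds (or accepts) the reference,
#' plants CNVs, simulates read pairs, and optionally writes the three
#' artifacts: reference FASTA, mapview-dialect alignment TSV, and truth
#' BED. Identical configurations produce byte-identical files.
#'
#' @param cfg A `sim_config`.
#' @param ref_seq Optional `DNAString` reference; default is a uniform
#'   random sequence of `cfg$ref_len`.
#' @param out_prefix If non-NULL, write `<prefix>ref.fa`,
#'   `<prefix>reads.tsv` and `<prefix>truth.bed`.
#' @return List with `cfg`, `ref` (`DNAString`), `truth`, `reads`, and
#'   (if written) `paths`.
#' @export
simulate_dataset <- function(cfg, ref_seq = NULL, out_prefix = NULL) {
  set.seed(cfg$seed)
  if (is.null(ref_seq)) {
    ref_seq <- random_reference(cfg$ref_len)
  } else {
    ref_seq <- as_dna(ref_seq)
    cfg$ref_len <- length(ref_seq)
  }
  planted <- plant_cnvs(cfg)
  reads <- simulate_pairs(cfg, planted$hap_events, ref_seq = ref_seq)
  out <- list(cfg = cfg, ref = ref_seq, truth = planted$truth,
              reads = reads)
  if (!is.null(out_prefix)) {
    dir.create(dirname(paste0(out_prefix, "x")), recursive = TRUE,
               showWarnings = FALSE)
    paths <- list(ref = paste0(out_prefix, "ref.fa"),
                  reads = paste0(out_prefix, "reads.tsv"),
                  truth = paste0(out_prefix, "truth.bed"))
    refset <- Biostrings::DNAStringSet(ref_seq)
    names(refset) <- cfg$chrom
    Biostrings::writeXStringSet(refset, paths$ref)
    write_mapview(reads, paths$reads, header = sim_header(cfg))
    write_truth(planted$truth, paths$truth, header = sim_header(cfg))
    out$paths <- paths
  }
  out
}

sim_header <- function(cfg) {
  libs <- paste(vapply(cfg$libraries, function(l)
    paste0(l[1], "/", l[2]), character(1)), collapse = ",")
  c(paste0("cnvhmm ", utils::packageVersion("cnvhmm"), " simulate"),
    paste0("seed=", cfg$seed),
    paste0("config: ref_len=", cfg$ref_len, " n_del=", cfg$n_del,
           " del_sizes=", paste(cfg$del_sizes, collapse = ","),
           " n_dup=", cfg$n_dup, " zygosity=", cfg$zygosity,
           " coverage=", cfg$coverage, " read_len=", cfg$read_len,
           " libraries=", libs, " min_anchor=", cfg$min_anchor,
           " min_sep=", cfg$min_sep, " gc_bias=", cfg$gc_bias))
}

#' Write planted CNVs as a truth BED
#'
#' BED6 with `event:zygosity` in the name column, sorted by start, with
#' `#` header lines.
#'
#' @param truth Truth table from [plant_cnvs()].
#' @param path Output path.
#' @param header Optional extra header lines.
#' @export
write_truth <- function(truth, path, header = NULL) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write truth BED: ", path)
  on.exit(close(con))
  writeLines(paste0("# ", c("cnvhmm truth BED", header)), con)
  if (nrow(truth) > 0) {
    truth <- truth[order(truth$start), , drop = FALSE]
    writeLines(paste(truth$chrom, truth$start, truth$end,
                     paste0(truth$event, ":", truth$zygosity), 0, ".",
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a truth (or call) BED file
#' @param path BED path (`#` lines skipped).
#' @return Data.frame with `chrom`, `start`, `end`, `event`, `zygosity`.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), event = character(0),
                      zygosity = character(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  name <- vapply(f, `[`, character(1), 4)
  nm <- strsplit(name, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[`, character(1), 1),
    start = as.integer(vapply(f, `[`, character(1), 2)),
    end = as.integer(vapply(f, `[`, character(1), 3)),
    event = vapply(nm, `[`, character(1), 1),
    zygosity = vapply(nm, function(x) if (length(x) > 1) x[2] else NA_character_,
                      character(1)),
    stringsAsFactors = FALSE
  )
}
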