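#' Caller configuration
#'
#' Collects every tunable of the calling pipeline with its default.
#'
#' @param grid_sizes Targeted medium-deletion sizes (bp) for the state
#'   grid; default 200 to 1600 in 200 bp steps.
#' @param het_mix_weight Shifted-component weight in flanking-state
#'   distance emissions (0.5: heterozygous generative truth; 1.0:
#'   purely shifted flanks).
#' @param expected_events_per_bp Prior CNV rate; Normal-state duration
#'   is its reciprocal. Default one event per 3 Mbp.
#' @param cnv_duration Expected size (bp) of depth-detectable CNVs
#'   (duration of the Del1/Del2/Dup1/Dup2 states).
#' @param grid_copy Copy number of grid interior deletion states (1
#'   heterozygous, 0 homozygous).
#' @param eps_frac Poisson-mean floor fraction for copy-0 states.
#' @param merge_gap Merge same-type calls separated by fewer than this
#'   many bp (0: off).
#' @param dist_cutoff Maximum outer-distance used as pair evidence (bp).
#' @param mapq_min Mapping-quality filter at parse time (0: none).
#' @param gc_window,gc_bins GC adjustment window (bp) and bin count.
#' @param pseudocount Laplace pseudocount of the insert-size pmf.
#' @param chunk_len If non-NULL, decode the chromosome in chunks of
#'   this many bp (plus `chunk_overlap` on each side) and deduplicate
#'   calls by coordinates; calls are identical to an unchunked run away
#'   from chunk edges.
#' @param chunk_overlap Chunk overlap in bp (default 10 kbp, larger
#'   than the largest grid size plus the insert mean).
#' @param edge_mask Number of bp masked at each chromosome end, where
#'   depth and pair support are structurally incomplete (a position
#'   within one insert length of an end cannot receive minus-strand
#'   read starts, mimicking a deletion). `NULL` (default) uses
#'   `insert mean + 4 sd`; 0 disables.
#' @return A `caller_config` list.
#' @export
caller_config <- function(grid_sizes = seq(200, 1600, by = 200),
                          het_mix_weight = 0.5,
                          expected_events_per_bp = 1 / 3e6,
                          cnv_duration = 10000, grid_copy = 1,
                          eps_frac = 0.01, merge_gap = 0,
                          dist_cutoff = 6000, mapq_min = 0,
                          gc_window = 100, gc_bins = 20,
                          pseudocount = 1, chunk_len = NULL,
                          chunk_overlap = 10000, edge_mask = NULL) {
  structure(as.list(environment()), class = "caller_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (or `key=value`); `#` comments and
#' blank lines ignored. Comma-separated values become numeric vectors.
#' Unknown keys are an error.
#'
#' @param path Config file path.
#' @param base Configuration to override, default [caller_config()].
#' @return A `caller_config`.
#' @export
read_caller_config <- function(path, base = caller_config()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln)
    key <- trimws(kv[1])
    if (!key %in% names(base)) stop("unknown config key: ", key)
    val <- as.numeric(strsplit(trimws(kv[2]), ",")[[1]])
    if (anyNA(val)) stop("non-numeric config value for ", key)
    base[[key]] <- val
  }
  base
}

format_config <- function(config) {
  paste(vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, "=", if (is.null(v)) "NULL" else paste(v, collapse = ","))
  }, character(1)), collapse = " ")
}

# Subset a position track to 1-based positions [from, to]
track_window <- function(track, from, to) {
  lo <- findInterval(from - 1L, track$dist_pos) + 1L
  hi <- findInterval(to, track$dist_pos)
  sel <- if (hi >= lo) lo:hi else integer(0)
  structure(
    list(chrom = track$chrom, length = as.integer(to - from + 1L),
         n = track$n[from:to],
         dist_pos = track$dist_pos[sel] - (from - 1L),
         dist_val = track$dist_val[sel],
         dist_cutoff = track$dist_cutoff),
    class = "position_track"
  )
}

#' Call CNVs from alignments and a reference
#'
#' The full pipeline: parse (if given paths), build the per-position
#' observation track and the empirical insert model, fit the GC depth
#' adjustment, assemble the HMM, decode with Viterbi and extract calls.
#' Chromosomes are processed independently; within a chromosome,
#' decoding can be chunked with overlap (see [caller_config()]).
#'
#' @param reads An `aligned_reads` data.frame or a mapview-dialect file
#'   path.
#' @param ref A `DNAStringSet`/`DNAString` or FASTA path.
#' @param chrom Chromosome name when `ref` is a bare `DNAString`.
#' @param config A [caller_config()].
#' @param keep_path If TRUE, also return the decoded state path per
#'   chromosome.
#' @return List with `calls` (data.frame across chromosomes),
#'   `insert_model`, per-chromosome `depth_models`, `models` and
#'   (optionally) `paths`.
#' @export
call_cnvs <- function(reads, ref, chrom = NULL, config = caller_config(),
                      keep_path = FALSE) {
  if (is.character(reads)) {
    reads <- parse_mapview(reads, mapq_min = config$mapq_min,
                           dist_cutoff = config$dist_cutoff)
  }
  if (is.character(ref)) ref <- read_reference(ref)
  if (methods::is(ref, "DNAString")) {
    nm <- if (!is.null(chrom)) chrom else
      if (nrow(reads) > 0) reads$chrom[1] else "chr"
    ref <- stats::setNames(Biostrings::DNAStringSet(ref), nm)
  }
  empty_calls <- extract_calls(
    structure(list(path = integer(0), loglik = 0), class = "viterbi_result"),
    NULL, character(0))
  if (nrow(reads) == 0) {
    warning("no alignment records; returning no calls")
    return(list(calls = empty_calls, insert_model = NULL,
                depth_models = list(), models = list()))
  }
  chroms <- intersect(unique(reads$chrom), names(ref))
  if (length(chroms) == 0) {
    stop("no chromosome shared between alignments (",
         paste(unique(reads$chrom), collapse = ","), ") and reference (",
         paste(names(ref), collapse = ","), ")")
  }
  dd <- reads$outer_dist[reads$strand == "+" & reads$outer_dist > 0 &
                           reads$outer_dist <= config$dist_cutoff]
  im <- fit_insert_model(dd, dist_cutoff = config$dist_cutoff,
                         pseudocount = config$pseudocount)
  all_calls <- list()
  depth_models <- list()
  models <- list()
  paths <- list()
  for (cn in chroms) {
    seqc <- ref[[cn]]
    L <- length(seqc)
    track <- build_position_track(reads[reads$chrom == cn, , drop = FALSE],
                                  L, dist_cutoff = config$dist_cutoff)
    dm <- fit_gc_model(track, seqc, gc_window = config$gc_window,
                       n_bins = config$gc_bins)
    adj <- gc_adjust(dm, seqc)
    edge <- if (is.null(config$edge_mask)) {
      round(im$D + 4 * im$sigma)
    } else config$edge_mask
    edge <- min(edge, L %/% 2)
    if (edge > 0) {
      adj$mask[c(seq_len(edge), (L - edge + 1L):L)] <- TRUE
    }
    model <- build_hmm(
      im, dm, genome_len = L, grid_sizes = config$grid_sizes,
      het_mix_weight = config$het_mix_weight,
      expected_events = L * config$expected_events_per_bp,
      cnv_duration = config$cnv_duration, grid_copy = config$grid_copy,
      eps_frac = config$eps_frac
    )
    if (is.null(config$chunk_len) || config$chunk_len >= L) {
      vit <- viterbi(track, model, G = adj$G, mask = adj$mask)
      calls <- extract_calls(vit, model, cn, merge_gap = config$merge_gap,
                             track = track, G = adj$G, mask = adj$mask)
      if (keep_path) paths[[cn]] <- model$states$name[vit$path]
    } else {
      calls <- chunked_calls(track, model, cn, adj, config)
    }
    all_calls[[cn]] <- calls
    depth_models[[cn]] <- dm
    models[[cn]] <- model
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  out <- list(calls = calls, insert_model = im,
              depth_models = depth_models, models = models)
  if (keep_path) out$paths <- paths
  out
}

chunked_calls <- function(track, model, cn, adj, config) {
  L <- track$length
  ov <- config$chunk_overlap
  starts <- seq(1L, L, by = config$chunk_len)
  pieces <- list()
  for (s in starts) {
    e <- min(s + config$chunk_len - 1L, L)
    s0 <- max(1L, s - ov)
    e0 <- min(L, e + ov)
    tw <- track_window(track, s0, e0)
    vit <- viterbi(tw, model, G = adj$G[s0:e0], mask = adj$mask[s0:e0])
    calls <- extract_calls(vit, model, cn, merge_gap = config$merge_gap,
                           track = tw, G = adj$G[s0:e0],
                           mask = adj$mask[s0:e0])
    if (nrow(calls) > 0) {
      calls$start <- calls$start + (s0 - 1L)
      calls$end <- calls$end + (s0 - 1L)
      calls <- calls[calls$start >= s - 1L & calls$start < e, , drop = FALSE]
    }
    pieces[[length(pieces) + 1]] <- calls
  }
  out <- do.call(rbind, pieces)
  out <- out[!duplicated(out[, c("start", "end", "event")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write calls as BED6+
#'
#' Columns: chrom, start, end, name (`event:source`), score (rounded
#' log-likelihood ratio vs the all-Normal path over the call), strand
#' (`.`), copy_number, mean_shift_evidence. `#` header lines record
#' version, configuration and seed.
#'
#' @param calls Calls data.frame from [call_cnvs()].
#' @param path Output path.
#' @param header Optional extra header lines.
#' @export
write_calls_bed <- function(calls, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c("cnvhmm calls BED6+", header)), con)
  if (nrow(calls) > 0) {
    writeLines(paste(
      calls$chrom, calls$start, calls$end,
      paste0(calls$event, ":", gsub(" ", "_", calls$source)),
      ifelse(is.na(calls$score), 0, round(calls$score)), ".",
      calls$copy_number,
      ifelse(is.na(calls$mean_shift_evidence), "NA",
             sprintf("%.1f", calls$mean_shift_evidence)),
      sep = "\t"), con)
  }
  invisible(path)
}

#' Read a calls BED6+ file written by [write_calls_bed()]
#' @param path File path.
#' @return Calls data.frame (`chrom`, `start`, `end`, `event`, `source`,
#'   `score`, `copy_number`).
#' @export
read_calls_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), event = character(0),
                      source = character(0), score = numeric(0),
                      copy_number = integer(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nm <- strsplit(vapply(f, `[`, character(1), 4), ":", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[`, character(1), 1),
    start = as.integer(vapply(f, `[`, character(1), 2)),
    end = as.integer(vapply(f, `[`, character(1), 3)),
    event = vapply(nm, `[`, character(1), 1),
    source = vapply(nm, function(x) if (length(x) > 1) x[2] else NA_character_,
                    character(1)),
    score = as.numeric(vapply(f, `[`, character(1), 5)),
    copy_number = as.integer(vapply(f, function(x)
      if (length(x) >= 7) x[7] else NA_character_, character(1))),
    stringsAsFactors = FALSE
  )
}
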