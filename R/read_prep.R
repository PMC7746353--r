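#' Read-preparation configuration
#'
#' Settings for adapter trimming and the length filter applied to raw
#' small-RNA reads before alignment to tRNA space. The length filter keeps
#' reads strictly longer than `min_len` ("more than 15 nt": a 15-nt read
#' fails) and at most `max_len` (the upper end of the small-RNA size
#' selection, 50 nt).
#'
#' Adapter matching is a deterministic seed-prefix rule: the 3' adapter is
#' located at the earliest read window matching the first `seed_len` bases
#' of `adapter3` and the read is cut there. Reads without an exact seed
#' are rescued by two ordered fallbacks — an exact adapter-prefix match
#' (>= 3 nt) flush with the read's 3' end (adapters clipped by the
#' sequencer), then the earliest seed window with at most
#' `max_adapter_mismatch` substitutions (seeds hit by sequencing errors).
#' The 5' adapter is the suffix-anchored analogue (last window matching
#' the final `seed_len` bases of `adapter5`; the read is cut after it).
#' Reads without any 3'-adapter hit are kept untrimmed and flagged, not
#' dropped.
#'
#' @param adapter3,adapter5 Adapter sequences (DNA or RNA; `NULL` disables
#'   that side). No defaults are baked in: adapters are library-kit
#'   specific.
#' @param min_len Exclusive minimum insert length in nt (default 15).
#' @param max_len Inclusive maximum insert length in nt (default 50).
#' @param max_adapter_mismatch Substitutions tolerated in the adapter seed
#'   (default 1).
#' @param seed_len Length of the adapter seed window (default 8).
#' @return A `read_prep_config` list.
#' @export
read_prep_config <- function(adapter3 = NULL, adapter5 = NULL, min_len = 15L,
                             max_len = 50L, max_adapter_mismatch = 1L,
                             seed_len = 8L) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (!(min_len > 0L && min_len < max_len)) abort("need 0 < min_len < max_len")
  if (!is.null(adapter3) && !nzchar(adapter3)) abort("adapter3 must be nonempty when supplied")
  if (!is.null(adapter5) && !nzchar(adapter5)) abort("adapter5 must be nonempty when supplied")
  structure(
    list(
      adapter3 = if (is.null(adapter3)) NULL else norm_seq(adapter3),
      adapter5 = if (is.null(adapter5)) NULL else norm_seq(adapter5),
      min_len = min_len, max_len = max_len,
      max_adapter_mismatch = as.integer(max_adapter_mismatch),
      seed_len = as.integer(seed_len)
    ),
    class = "read_prep_config"
  )
}

#' Read a FASTQ file into a tibble
#'
#' Reads plain four-line FASTQ records. Structural violations (truncated
#' record, missing `@`/`+` markers, quality/sequence length mismatch) abort
#' with the index of the offending record.
#'
#' @param path FASTQ file path.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("malformed FASTQ: truncated record %d", length(lines) %/% 4L + 1L))
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(tibble(id = character(), seq = character(), qual = character()))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") | nchar(seqs) != nchar(qual))
  if (length(bad)) abort(sprintf("malformed FASTQ record %d", bad[1]))
  tibble(id = sub("^@", "", hdr), seq = toupper(seqs), qual = qual)
}

#' Write a tibble of reads as FASTQ
#'
#' @param reads Tibble with `id`, `seq`, `qual` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  writeLines(
    as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)),
    path
  )
  invisible(path)
}

#' Trim adapters and apply the length filter
#'
#' Removes 5' and 3' adapters per the seed-window rule in
#' [read_prep_config()], then keeps reads with `min_len < length <=
#' max_len`. Quality strings are sliced alongside the sequence and
#' otherwise untouched; no quality filtering is performed.
#'
#' @param reads A tibble from [read_fastq()] (columns `id`, `seq`, `qual`)
#'   or a FASTQ path.
#' @param cfg A [read_prep_config()].
#' @return A tibble of surviving reads (`id`, `seq`, `qual`,
#'   `adapter3_found` flag), with a `summary` attribute — a tibble of
#'   `stage`, `count` rows (`input`, `adapter3_trimmed`,
#'   `adapter5_trimmed`, `discarded_short`, `discarded_long`, `passed`)
#'   satisfying `input = passed + discarded`. Retrieve it with
#'   [prep_summary()].
#' @export
trim_and_filter <- function(reads, cfg) {
  stopifnot(inherits(cfg, "read_prep_config"))
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  n_in <- nrow(reads)
  all_seqs <- norm_seq(reads$seq)
  # Trim coordinates depend only on the sequence, so work on the distinct
  # sequences and broadcast back (small-RNA libraries are highly redundant).
  seqs <- unique(all_seqs)
  ridx <- match(all_seqs, seqs)
  nu <- length(seqs)
  off5 <- rep(0L, nu)  # bases removed from the 5' side, original coordinates
  trimmed5 <- rep(FALSE, nu)
  # 5' adapter: cut after the LAST window matching the adapter's suffix seed.
  if (!is.null(cfg$adapter5) && nu > 0L) {
    seed <- substr(cfg$adapter5, max(1L, nchar(cfg$adapter5) - cfg$seed_len + 1L), nchar(cfg$adapter5))
    ends <- last_seed_end(seqs, seed, cfg$max_adapter_mismatch)
    trimmed5 <- !is.na(ends)
    off5[trimmed5] <- ends[trimmed5]
    seqs[trimmed5] <- substr(seqs[trimmed5], ends[trimmed5] + 1L, nchar(seqs[trimmed5]))
  }
  a3_found <- rep(FALSE, nu)
  # 3' adapter, three deterministic passes of decreasing confidence:
  # (1) earliest EXACT occurrence of the adapter's prefix seed;
  # (2) longest exact adapter-prefix match (>= 3 nt) flush with the read's
  #     3' terminus, which rescues reads whose adapter was clipped by the
  #     sequencer to fewer than seed_len bases (read-through trimming);
  # (3) earliest seed occurrence with <= max_adapter_mismatch substitutions,
  #     which rescues reads whose adapter seed carries sequencing errors.
  # Ordering matters: running the tolerant scan first would false-trim at
  # near-matches inside genuine long inserts.
  if (!is.null(cfg$adapter3) && nu > 0L) {
    seed <- substr(cfg$adapter3, 1L, min(cfg$seed_len, nchar(cfg$adapter3)))
    starts <- first_seed_start(seqs, seed, 0L)
    a3_found <- !is.na(starts)
    seqs[a3_found] <- substr(seqs[a3_found], 1L, starts[a3_found] - 1L)
    for (L in seq(nchar(seed) - 1L, 3L)) {
      sel <- !a3_found & nchar(seqs) > L &
        substr(seqs, nchar(seqs) - L + 1L, nchar(seqs)) == substr(cfg$adapter3, 1L, L)
      if (any(sel)) {
        seqs[sel] <- substr(seqs[sel], 1L, nchar(seqs[sel]) - L)
        a3_found[sel] <- TRUE
      }
    }
    if (cfg$max_adapter_mismatch > 0L && !all(a3_found)) {
      miss <- !a3_found
      starts <- first_seed_start(seqs[miss], seed, cfg$max_adapter_mismatch)
      hit <- !is.na(starts)
      idx <- which(miss)[hit]
      seqs[idx] <- substr(seqs[idx], 1L, starts[hit] - 1L)
      a3_found[idx] <- TRUE
    }
  }
  len <- nchar(seqs)
  short <- len <= cfg$min_len
  long <- !short & len > cfg$max_len
  keep_u <- !short & !long
  keep <- keep_u[ridx]
  ki <- ridx[keep]
  out <- tibble(
    id = reads$id[keep],
    seq = seqs[ki],
    qual = substr(reads$qual[keep], off5[ki] + 1L, off5[ki] + len[ki]),
    adapter3_found = a3_found[ki]
  )
  attr(out, "summary") <- tibble(
    stage = c("input", "adapter3_trimmed", "adapter5_trimmed",
              "discarded_short", "discarded_long", "passed"),
    count = c(n_in, sum(a3_found[ridx]), sum(trimmed5[ridx]),
              sum(short[ridx]), sum(long[ridx]), sum(keep))
  )
  out
}

#' @rdname trim_and_filter
#' @param x Result of [trim_and_filter()].
#' @export
prep_summary <- function(x) attr(x, "summary")

# Earliest start of a <=mm-mismatch occurrence of `seed` per sequence (NA if none).
first_seed_start <- function(seqs, seed, mm) {
  m <- Biostrings::vmatchPattern(seed, Biostrings::DNAStringSet(seqs), max.mismatch = mm)
  s <- Biostrings::startIndex(m)
  vapply(s, function(v) if (length(v)) min(v) else NA_integer_, integer(1))
}

# Latest end of a <=mm-mismatch occurrence of `seed` per sequence (NA if none).
last_seed_end <- function(seqs, seed, mm) {
  m <- Biostrings::vmatchPattern(seed, Biostrings::DNAStringSet(seqs), max.mismatch = mm)
  e <- Biostrings::endIndex(m)
  vapply(e, function(v) if (length(v)) max(v) else NA_integer_, integer(1))
}
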