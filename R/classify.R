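#' Map read sequences to tRNA space
#'
#' Reports every forward-strand occurrence (with at most `max_mismatch`
#' substitutions, no indels) of each distinct read sequence in the mature
#' sequences and precursor 3' trailers of a reference set. Coordinates are
#' 1-based closed intervals on the hit region's own coordinate system
#' (mature sequence or trailer).
#'
#' @param reads Character vector of read sequences (duplicates are
#'   collapsed), or a tibble with a `seq` column.
#' @param ref Reference tibble from [parse_trna_reference()] or
#'   [simulate_references()].
#' @param max_mismatch Allowed substitutions, 0-2 (default 0).
#' @return A tibble of alignments: `read_seq`, `trna_id`, `region`
#'   (`"mature"` or `"trailer"`), `start`, `end`, `mismatches`. Sequences
#'   with no hit anywhere are recorded in `attr(, "unaligned")` (a
#'   character vector).
#' @export
map_reads <- function(reads, ref, max_mismatch = 0L) {
  if (is.data.frame(reads)) reads <- reads$seq
  if (nrow(ref) == 0L) abort("empty reference set")
  if (!max_mismatch %in% 0:2) abort("max_mismatch must be 0, 1 or 2")
  seqs <- unique(norm_seq(reads))
  subjects <- bind_rows(
    tibble(trna_id = ref$id, region = "mature", subject = ref$mature_seq),
    tibble(trna_id = ref$id, region = "trailer", subject = ref$trailer_seq)
  ) |> filter(!is.na(.data$subject))

  hits <- vector("list", nrow(subjects))
  if (max_mismatch == 0L) {
    for (i in seq_len(nrow(subjects))) {
      loc <- stringr::str_locate_all(subjects$subject[i], stringr::fixed(seqs))
      nh <- vapply(loc, nrow, integer(1))
      if (!any(nh > 0L)) next
      idx <- rep.int(seq_along(seqs), nh)
      m <- do.call(rbind, loc)
      hits[[i]] <- tibble(
        read_seq = seqs[idx], trna_id = subjects$trna_id[i],
        region = subjects$region[i],
        start = as.integer(m[, 1]), end = as.integer(m[, 2]),
        mismatches = 0L
      )
    }
  } else {
    for (i in seq_len(nrow(subjects))) {
      subj <- Biostrings::DNAString(subjects$subject[i])
      per <- purrr::map(seqs, function(s) {
        if (nchar(s) > length(subj)) return(NULL)
        m <- Biostrings::matchPattern(s, subj, max.mismatch = max_mismatch)
        if (!length(m)) return(NULL)
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(s), subj,
                                          starting.at = Biostrings::start(m))
        tibble(
          read_seq = s, trna_id = subjects$trna_id[i], region = subjects$region[i],
          start = Biostrings::start(m), end = Biostrings::end(m),
          mismatches = as.integer(mm)
        )
      })
      hits[[i]] <- bind_rows(per)
    }
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    out <- tibble(
      read_seq = character(), trna_id = character(), region = character(),
      start = integer(), end = integer(), mismatches = integer()
    )
  }
  attr(out, "unaligned") <- setdiff(seqs, out$read_seq)
  out
}

#' Classify aligned fragments into the six tsRNA types
#'
#' Applies the positional rules that define tsRNA types. Trailer hits that
#' begin within `trailer_slack` nt of the mature 3' boundary are tRF-1
#' (farther trailer hits are not tsRNAs and return `NA`). Mature hits are
#' classified by end anchoring: a fragment is 5'-anchored when `start <=
#' tol5` and 3'-anchored when `end >= L - tol3` (`L` = mature length
#' including the CCA tail; `tol3` defaults to 3 so the CCA terminus counts
#' as the 3' end). 5'-anchored fragments are tRF-5 when they stop before
#' the anticodon loop, tiRNA-5 when they reach into or beyond it;
#' 3'-anchored fragments are tRF-3 when they start after the anticodon
#' loop, tiRNA-3 otherwise; unanchored fragments are i-tRF; fragments
#' anchored at both ends are full-length tRNAs, not tsRNAs (`NA`).
#'
#' @param alignments Alignment tibble from [map_reads()].
#' @param ref Reference tibble (for mature lengths and loop coordinates).
#' @param tol5,tol3 Anchoring tolerances in nt (defaults 1 and 3).
#' @param trailer_slack Maximum trailer start position for tRF-1
#'   (default 2).
#' @return `alignments` with a `type` column (`"tRF-1"`, `"tRF-3"`,
#'   `"tRF-5"`, `"i-tRF"`, `"tiRNA-3"`, `"tiRNA-5"`, or `NA` for
#'   non-tsRNA hits) and an `amino_acid` column joined from the reference.
#' @export
classify_fragments <- function(alignments, ref, tol5 = 1L, tol3 = 3L,
                               trailer_slack = 2L) {
  aln <- alignments |>
    left_join(
      ref |> select("id", "amino_acid", "mature_seq", "ac_start", "ac_end",
                    "trailer_seq") |>
        mutate(
          mature_len = nchar(.data$mature_seq),
          trailer_len = ifelse(is.na(.data$trailer_seq), 0L, nchar(.data$trailer_seq))
        ) |>
        select(-"mature_seq", -"trailer_seq"),
      by = c(trna_id = "id")
    )
  if (anyNA(aln$mature_len)) abort("alignment refers to a tRNA absent from the reference")
  bound <- ifelse(aln$region == "mature", aln$mature_len, aln$trailer_len)
  if (any(aln$start < 1L | aln$end > bound)) {
    abort("alignment interval outside the bounds of its reference region")
  }
  a5 <- aln$region == "mature" & aln$start <= tol5
  a3 <- aln$region == "mature" & aln$end >= aln$mature_len - tol3
  type <- rep(NA_character_, nrow(aln))
  type[aln$region == "trailer" & aln$start <= trailer_slack] <- "tRF-1"
  m <- aln$region == "mature"
  type[m & a5 & !a3 & aln$end < aln$ac_start] <- "tRF-5"
  type[m & a5 & !a3 & aln$end >= aln$ac_start] <- "tiRNA-5"
  type[m & a3 & !a5 & aln$start > aln$ac_end] <- "tRF-3"
  type[m & a3 & !a5 & aln$start <= aln$ac_end] <- "tiRNA-3"
  type[m & !a5 & !a3] <- "i-tRF"
  alignments$type <- type
  alignments$amino_acid <- aln$amino_acid
  alignments
}

TSRNA_TYPES <- c("tRF-1", "tRF-3", "tRF-5", "i-tRF", "tiRNA-3", "tiRNA-5")
TYPE_CODES <- c(`tRF-1` = "tRF1", `tRF-3` = "tRF3", `tRF-5` = "tRF5",
                `i-tRF` = "tRFi", `tiRNA-3` = "tiR3", `tiRNA-5` = "tiR5")

#' Collapse classified alignments into named tsRNA fragments
#'
#' Distinct read sequences become fragments. Each fragment takes the
#' majority type and amino-acid family over its tRNA hits (alphabetical
#' tie-break) and a systematic name
#' `organism-typecode-AminoAcid-<length><variant>` (e.g.
#' `rno-tRFi-Ser-25a`). Within each (type, amino acid, length) group,
#' variant letters a, b, c, ... are assigned by descending total abundance
#' with ties broken by lexicographic sequence order.
#'
#' @param alignments Classified alignment tibble from
#'   [classify_fragments()].
#' @param organism Organism prefix for names (default `"rno"`).
#' @param abundance Named numeric vector of total counts per sequence
#'   (names are read sequences). Must cover every aligned sequence.
#' @return A tibble of fragments: `name`, `sequence`, `type`,
#'   `amino_acid`, `length`, `variant`, `source_trna_ids` (comma-joined),
#'   `abundance`.
#' @export
collapse_and_name <- function(alignments, organism = "rno", abundance = NULL) {
  aln <- alignments |> filter(!is.na(.data$type))
  if (nrow(aln) == 0L) {
    return(tibble(
      name = character(), sequence = character(), type = character(),
      amino_acid = character(), length = integer(), variant = character(),
      source_trna_ids = character(), abundance = numeric()
    ))
  }
  if (is.null(abundance)) {
    abundance <- stats::setNames(rep(1, length(unique(aln$read_seq))), unique(aln$read_seq))
  }
  missing <- setdiff(unique(aln$read_seq), names(abundance))
  if (length(missing)) abort("abundance does not cover every aligned sequence")

  majority <- function(x) {
    tb <- sort(table(x), decreasing = TRUE)
    nm <- names(tb)[tb == max(tb)]
    sort(nm)[1]  # alphabetical tie-break
  }
  frags <- aln |>
    group_by(sequence = .data$read_seq) |>
    summarise(
      type = majority(.data$type),
      amino_acid = majority(.data$amino_acid),
      source_trna_ids = paste(sort(unique(.data$trna_id)), collapse = ","),
      .groups = "drop"
    ) |>
    mutate(
      length = nchar(.data$sequence),
      abundance = unname(abundance[.data$sequence])
    ) |>
    group_by(.data$type, .data$amino_acid, .data$length) |>
    arrange(desc(.data$abundance), .data$sequence, .by_group = TRUE) |>
    mutate(variant = letters[dplyr::row_number()]) |>
    ungroup()
  if (anyNA(frags$variant)) {
    abort("more than 26 variants in one (type, amino acid, length) group; names would be ambiguous")
  }
  frags |>
    mutate(name = render_tsrna_name(organism, .data$type, .data$amino_acid,
                                    .data$length, .data$variant)) |>
    select("name", "sequence", "type", "amino_acid", "length", "variant",
           "source_trna_ids", "abundance") |>
    arrange(.data$name)
}

#' Render and parse systematic tsRNA names
#'
#' The naming grammar is `organism-typecode-AminoAcid-<length><variant>`
#' with type codes `tiR5`, `tiR3`, `tRF5`, `tRF3`, `tRFi`, `tRF1` for the
#' six tsRNA types. `parse_tsrna_name(render_tsrna_name(...))` is the
#' identity on valid components, and vice versa.
#'
#' @param organism Organism prefix, e.g. `"rno"`.
#' @param type tsRNA type (`"tiRNA-5"`, `"i-tRF"`, ...).
#' @param amino_acid Three-letter amino-acid code.
#' @param length Fragment length in nt.
#' @param variant Single lowercase variant letter.
#' @return `render_tsrna_name()`: character vector of names.
#'   `parse_tsrna_name()`: tibble with `organism`, `type_code`, `type`,
#'   `amino_acid`, `length`, `variant`.
#' @examples
#' render_tsrna_name("rno", "i-tRF", "Ser", 25, "a")
#' parse_tsrna_name("rno-tiR3-Met-42c")
#' @export
render_tsrna_name <- function(organism, type, amino_acid, length, variant) {
  code <- TYPE_CODES[type]
  if (anyNA(code)) {
    abort(sprintf("unknown tsRNA type: %s", paste(unique(type[is.na(code)]), collapse = ", ")))
  }
  paste0(organism, "-", code, "-", amino_acid, "-", length, variant)
}

#' @rdname render_tsrna_name
#' @param name Character vector of systematic tsRNA names.
#' @export
parse_tsrna_name <- function(name) {
  m <- stringr::str_match(name, "^([A-Za-z]+)-([A-Za-z0-9]+)-([A-Za-z][a-z]{2})-([0-9]+)([a-z])$")
  if (anyNA(m[, 1])) {
    abort(sprintf("malformed tsRNA name: %s", name[which(is.na(m[, 1]))[1]]))
  }
  codes <- m[, 3]
  known <- codes %in% TYPE_CODES
  if (!all(known)) {
    abort(sprintf("unknown type code '%s' in name %s", codes[!known][1], name[!known][1]))
  }
  tibble(
    organism = m[, 2], type_code = codes,
    type = names(TYPE_CODES)[match(codes, TYPE_CODES)],
    amino_acid = m[, 4], length = as.integer(m[, 5]), variant = m[, 6]
  )
}
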