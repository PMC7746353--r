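#' Parse a structure-annotated tRNA reference file
#'
#' Reads the three-line reference dialect used throughout the package:
#' a header line `">id amino_acid anticodon [precursor_trailer=SEQ]"`, a
#' mature sequence line (5'->3', conventionally with the CCA tail appended),
#' and a dot-bracket secondary-structure line of the same length. The three
#' hairpin loops of the cloverleaf (D, anticodon, T) are located from the
#' structure and stored as 1-based closed intervals on the mature sequence.
#'
#' Records whose structure cannot be interpreted (length mismatch with the
#' sequence, unbalanced brackets, fewer than three hairpin loops) are
#' rejected individually; parsing continues and the rejects are reported in
#' the `errors` attribute of the result (and as a warning).
#'
#' @param path Path to a reference file.
#' @return A tibble with one row per accepted tRNA: `id`, `amino_acid`,
#'   `anticodon`, `mature_seq`, `structure`, `cca` (logical, TRUE when the
#'   mature sequence ends in CCA), loop intervals `d_start`, `d_end`,
#'   `ac_start`, `ac_end`, `t_start`, `t_end`, and `trailer_seq` (the 3'
#'   precursor trailer, `NA` when absent). Rejected records are in
#'   `attr(, "errors")` as a tibble of `id`, `message`.
#' @seealso [write_trna_reference()], [locate_loops()]
#' @export
parse_trna_reference <- function(path) {
  if (!file.exists(path)) abort(sprintf("reference file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("reference file is empty")
  hdr_idx <- which(startsWith(lines, ">"))
  if (length(hdr_idx) == 0L) abort("reference file contains no records ('>' headers)")
  if (hdr_idx[1] != 1L) abort("reference file must start with a '>' header")

  recs <- list()
  errs <- list()
  for (i in seq_along(hdr_idx)) {
    h <- hdr_idx[i]
    last <- if (i < length(hdr_idx)) hdr_idx[i + 1] - 1L else length(lines)
    body <- lines[seq.int(h + 1L, length.out = max(0L, last - h))]
    hdr <- sub("^>", "", lines[h])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- toks[1] %||% "<unnamed>"
    push_err <- function(msg) errs[[length(errs) + 1L]] <<- tibble(id = id, message = msg)
    if (length(body) != 2L) {
      push_err(sprintf("expected a sequence line and a structure line, found %d lines", length(body)))
      next
    }
    if (length(toks) < 3L) {
      push_err("header must carry id, amino_acid and anticodon")
      next
    }
    trailer <- NA_character_
    attr_tok <- grep("^precursor_trailer=", toks, value = TRUE)
    if (length(attr_tok)) trailer <- norm_seq(sub("^precursor_trailer=", "", attr_tok[1]))
    mature <- norm_seq(body[1])
    struct <- chartr("><", "()", trimws(body[2]))
    if (nchar(struct) != nchar(mature)) {
      push_err(sprintf("structure length %d != sequence length %d", nchar(struct), nchar(mature)))
      next
    }
    loops <- tryCatch(locate_loops(struct), error = function(e) conditionMessage(e))
    if (is.character(loops)) {
      push_err(loops)
      next
    }
    recs[[length(recs) + 1L]] <- tibble(
      id = id, amino_acid = toks[2], anticodon = to_rna(toks[3]),
      mature_seq = mature, structure = struct,
      cca = endsWith(mature, "CCA"),
      d_start = loops$start[1], d_end = loops$end[1],
      ac_start = loops$start[2], ac_end = loops$end[2],
      t_start = loops$start[3], t_end = loops$end[3],
      trailer_seq = trailer
    )
  }
  errors <- if (length(errs)) bind_rows(errs) else tibble(id = character(), message = character())
  if (nrow(errors)) {
    warn(sprintf(
      "%d reference record(s) rejected: %s", nrow(errors),
      paste(sprintf("%s (%s)", errors$id, errors$message), collapse = "; ")
    ))
  }
  if (!length(recs)) abort("no reference record could be parsed")
  out <- bind_rows(recs)
  attr(out, "errors") <- errors
  out
}

#' Locate the hairpin loops of a tRNA dot-bracket structure
#'
#' A hairpin loop is a maximal run of unpaired positions whose immediate
#' flanks are paired with each other (the closing pair of a stem). For a
#' canonical cloverleaf these are, 5'->3', the D loop, the anticodon loop
#' and the T loop. tRNAs with a long variable arm (e.g. Ser, Leu) present a
#' fourth hairpin between the anticodon and T arms; the second loop is
#' still the anticodon loop and the last one the T loop.
#'
#' @param structure Dot-bracket string using `.`, `(`, `)` (`>` and `<` are
#'   accepted as aliases of `(` and `)`).
#' @param all If `TRUE`, return every hairpin loop found instead of the
#'   three named cloverleaf loops.
#' @return A tibble of 1-based closed intervals: `loop` (`"d"`,
#'   `"anticodon"`, `"t"`, or `loop1`, `loop2`, ... when `all = TRUE`),
#'   `start`, `end`.
#' @examples
#' locate_loops("..((((....)))).." , all = TRUE)
#' @export
locate_loops <- function(structure, all = FALSE) {
  pairs <- dotbracket_pairs(structure)
  n <- length(pairs)
  ch <- seq_chars(chartr("><", "()", structure))
  unpaired <- ch == "."
  loops <- list()
  i <- 1L
  while (i <= n) {
    if (unpaired[i]) {
      j <- i
      while (j < n && unpaired[j + 1L]) j <- j + 1L
      if (i > 1L && j < n && !is.na(pairs[i - 1L]) && pairs[i - 1L] == j + 1L) {
        loops[[length(loops) + 1L]] <- c(i, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  lt <- tibble(
    loop = paste0("loop", seq_along(loops)),
    start = vapply(loops, `[`, integer(1), 1L),
    end = vapply(loops, `[`, integer(1), 2L)
  )
  if (all) return(lt)
  if (nrow(lt) < 3L) {
    abort(sprintf("expected >= 3 hairpin loops in the cloverleaf, found %d", nrow(lt)))
  }
  # 1st = D, 2nd = anticodon, LAST = T (long-variable-arm tRNAs insert an
  # extra hairpin between the anticodon and T arms).
  lt <- lt[c(1L, 2L, nrow(lt)), ]
  lt$loop <- c("d", "anticodon", "t")
  lt
}

# Pairing partner of each position (NA if unpaired); errors on unbalanced
# brackets. Internal workhorse for locate_loops().
dotbracket_pairs <- function(structure) {
  ch <- seq_chars(chartr("><", "()", structure))
  bad <- setdiff(unique(ch), c(".", "(", ")"))
  if (length(bad)) abort(sprintf("invalid structure character(s): %s", paste(bad, collapse = " ")))
  n <- length(ch)
  pairs <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) abort("unbalanced dot-bracket string: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack)) abort("unbalanced dot-bracket string: unmatched '('")
  pairs
}

#' Write a tRNA reference in the three-line dialect
#'
#' Emits the same format [parse_trna_reference()] reads, bit-exactly, so
#' that write-out followed by re-parse is the identity.
#'
#' @param ref A reference tibble from [parse_trna_reference()] or
#'   [simulate_references()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trna_reference <- function(ref, path) {
  hdr <- paste0(
    ">", ref$id, " ", ref$amino_acid, " ", ref$anticodon,
    ifelse(is.na(ref$trailer_seq), "", paste0(" precursor_trailer=", ref$trailer_seq))
  )
  writeLines(as.vector(rbind(hdr, ref$mature_seq, ref$structure)), path)
  invisible(path)
}
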