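#' Target-prediction configuration
#'
#' Thresholds for the three-rule consensus: (1) a seed match — the 3'UTR
#' contains the reverse complement of a 7-nt window of the tsRNA (7mer) or
#' of its positions 2-7 followed by an A opposite position 1 (7mer-1a);
#' (2) strict 5'-end pairing — perfect Watson-Crick complementarity at
#' tsRNA positions 2-11 and at most `max_mismatches` non-complementary
#' bases at positions 12-21 (G:U counts as a mismatch here); (3) a duplex
#' minimum free energy below `mfe_threshold`. For tsRNAs shorter than 21
#' nt the 12-21 span is truncated to the available positions and
#' `max_mismatches` prorated as `floor(4 * span / 10)`.
#'
#' @param seed_len Seed window width (7 nt).
#' @param perfect_span tsRNA positions requiring perfect pairing
#'   (default 2-11).
#' @param mismatch_span tsRNA positions where mismatches are tolerated
#'   (default 12-21).
#' @param max_mismatches Mismatches tolerated in `mismatch_span`
#'   (default 4).
#' @param mfe_threshold Duplex free-energy cutoff in kcal/mol
#'   (default -20; a site passes when its MFE is strictly below it).
#' @return A `target_config` list.
#' @export
target_config <- function(seed_len = 7L, perfect_span = c(2L, 11L),
                          mismatch_span = c(12L, 21L), max_mismatches = 4L,
                          mfe_threshold = -20) {
  stopifnot(seed_len >= 2L, perfect_span[1] < perfect_span[2],
            mismatch_span[1] <= mismatch_span[2], is.finite(mfe_threshold))
  structure(
    list(seed_len = as.integer(seed_len),
         perfect_span = as.integer(perfect_span),
         mismatch_span = as.integer(mismatch_span),
         max_mismatches = as.integer(max_mismatches),
         mfe_threshold = mfe_threshold),
    class = "target_config"
  )
}

# Watson-Crick nearest-neighbor stack free energies (kcal/mol, 37 C) for
# RNA duplexes, Turner 2004 parameter set (Xia et al. 1998 / Mathews et
# al. 2004). Keyed by the 5'->3' doublet of one strand (DNA alphabet, U=T);
# the antiparallel partner is its complement, and the table is
# reverse-complement symmetric so either strand gives the same energy.
WC_STACK <- c(
  AA = -0.93, TT = -0.93, AT = -1.10, TA = -1.33,
  CT = -2.08, AG = -2.08, CA = -2.11, TG = -2.11,
  GT = -2.24, AC = -2.24, GA = -2.35, TC = -2.35,
  CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42
)

#' Nearest-neighbor duplex energy model
#'
#' A deterministic, ungapped stand-in for a full hybridization folder:
#' duplex free energy is the duplex-initiation penalty plus the sum of
#' nearest-neighbor stack energies over the best antiparallel
#' registration, with a fixed penalty per non-complementary opposing pair.
#' Watson-Crick stacks use published Turner-set constants; any stack
#' containing a G:U wobble is scored with a single weakly stabilising
#' value. No bulges or internal-loop geometries are modelled.
#'
#' @param init_penalty Duplex initiation penalty, kcal/mol (default 4.09,
#'   the Turner-set value).
#' @param mismatch_penalty Added per non-complementary opposing pair,
#'   kcal/mol (default +1.0).
#' @param gu_energy Stack energy when a G:U wobble participates, kcal/mol
#'   (default -0.5).
#' @param allow_gu Score G:U as a (weak) pair rather than a mismatch
#'   (default TRUE).
#' @param stack_table Named vector of Watson-Crick stack energies keyed by
#'   5'->3' doublet; defaults to the embedded Turner-set table.
#' @return A `duplex_model` list.
#' @export
duplex_model <- function(init_penalty = 4.09, mismatch_penalty = 1.0,
                         gu_energy = -0.5, allow_gu = TRUE,
                         stack_table = WC_STACK) {
  stopifnot(init_penalty > 0, all(stack_table < 0))
  structure(
    list(init_penalty = init_penalty, mismatch_penalty = mismatch_penalty,
         gu_energy = gu_energy, allow_gu = allow_gu, stack_table = stack_table),
    class = "duplex_model"
  )
}

#' Enumerate 7-nt sliding seed windows of a tsRNA
#'
#' Slides a window of `width` nt by one nt from the 5' to the 3' end,
#' yielding `length - width + 1` windows.
#'
#' @param tsrna_seq tsRNA sequence (RNA or DNA alphabet), at least `width`
#'   nt.
#' @param width Window width (default 7).
#' @return Tibble with `offset` (1-based start on the tsRNA) and `window`.
#' @export
enumerate_seed_windows <- function(tsrna_seq, width = 7L) {
  s <- norm_seq(tsrna_seq)
  L <- nchar(s)
  if (L < width) abort(sprintf("tsRNA is %d nt, shorter than the %d-nt seed window", L, width))
  off <- seq_len(L - width + 1L)
  tibble(offset = off, window = substring(s, off, off + width - 1L))
}

#' Find seed-match sites of a tsRNA on a 3'UTR
#'
#' Reports every UTR position where the reverse complement of a 7-nt
#' tsRNA window occurs (`7mer`), or where the reverse complement of the
#' window's positions 2-7 is followed by an A opposite window position 1
#' (`7mer-1a`). Sites are deduplicated by (window offset, UTR position),
#' preferring the full `7mer` evidence.
#'
#' @param tsrna_seq tsRNA sequence (>= 7 nt).
#' @param utr_seq 3'UTR sequence.
#' @param cfg A [target_config()].
#' @return Tibble with `offset` (window start on the tsRNA),
#'   `utr_position` (1-based site start on the UTR) and `seed_evidence`
#'   (`"7mer"` or `"7mer-1a"`). Empty when nothing matches.
#' @export
seed_match_sites <- function(tsrna_seq, utr_seq, cfg = target_config()) {
  utr <- norm_seq(utr_seq)
  win <- enumerate_seed_windows(tsrna_seq, cfg$seed_len)
  pat7 <- revcomp(win$window)
  pat1a <- paste0(revcomp(substr(win$window, 2L, cfg$seed_len)), "A")
  find_all <- function(pats, evid) {
    loc <- stringr::str_locate_all(utr, stringr::fixed(pats))
    nh <- vapply(loc, nrow, integer(1))
    if (!any(nh > 0L)) return(NULL)
    tibble(
      offset = rep.int(win$offset, nh),
      utr_position = as.integer(do.call(rbind, loc)[, 1]),
      seed_evidence = evid
    )
  }
  out <- bind_rows(find_all(pat7, "7mer"), find_all(pat1a, "7mer-1a"))
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(offset = integer(), utr_position = integer(),
                  seed_evidence = character()))
  }
  out |>
    arrange(.data$offset, .data$utr_position,
            match(.data$seed_evidence, c("7mer", "7mer-1a"))) |>
    distinct(.data$offset, .data$utr_position, .keep_all = TRUE)
}

#' Strict 5'-end pairing filter
#'
#' Checks a candidate duplex between a tsRNA and the UTR window opposing
#' its positions 1..K (K = min(21, tsRNA length)): pass requires perfect
#' Watson-Crick complementarity over positions 2-11 and at most the
#' configured number of mismatches over 12-21 (G:U wobble counts as a
#' mismatch). `utr_site_seq` is the opposing UTR window written 5'->3', so
#' its last base opposes tsRNA position 1; opposing positions missing from
#' a short site count as mismatches.
#'
#' @param tsrna_seq tsRNA sequence.
#' @param utr_site_seq Opposing UTR window, 5'->3'.
#' @param cfg A [target_config()].
#' @return One-row tibble: `pass`, `perfect_2_11`, `mismatches` (count in
#'   the tolerated span), `max_allowed`.
#' @export
pairing_filter <- function(tsrna_seq, utr_site_seq, cfg = target_config()) {
  pe <- pairing_eval(seq_chars(norm_seq(tsrna_seq)),
                     seq_chars(norm_seq(utr_site_seq)), cfg)
  tibble(pass = pe$pass, perfect_2_11 = pe$perfect,
         mismatches = pe$mismatches, max_allowed = pe$allowed)
}

# Scalar core of the pairing rule, on pre-split character vectors.
pairing_eval <- function(a, s, cfg) {
  K <- min(cfg$mismatch_span[2], length(a))
  ks <- seq_len(K)
  # tsRNA position k opposes site position length(s) - k + 1 (antiparallel).
  j <- length(s) - ks + 1L
  ok <- j >= 1L & j <= length(s)
  ob <- rep(NA_character_, K)
  ob[ok] <- s[j[ok]]
  paired <- !is.na(ob) & is_wc(a[ks], ob)
  pspan <- cfg$perfect_span[1]:min(cfg$perfect_span[2], K)
  perfect <- all(paired[pspan])
  mspan <- if (cfg$mismatch_span[1] <= K) cfg$mismatch_span[1]:K else integer(0)
  mism <- sum(!paired[mspan])
  span_full <- cfg$mismatch_span[2] - cfg$mismatch_span[1] + 1L
  allowed <- if (length(mspan) == span_full) cfg$max_mismatches
             else as.integer(floor(cfg$max_mismatches * length(mspan) / span_full))
  list(pass = perfect && mism <= allowed, perfect = perfect,
       mismatches = mism, allowed = allowed)
}

#' Duplex minimum free energy under the nearest-neighbor model
#'
#' Scores every ungapped antiparallel registration of the two strands and
#' returns the lowest energy: initiation penalty + stack energies over
#' adjacent paired positions + per-mismatch penalties. Deterministic;
#' more negative = more stable. Overhanging (non-opposed) bases are
#' neither scored nor penalised.
#'
#' @param seq_a,seq_b The two strands, each written 5'->3' (>= 4 nt).
#' @param model A [duplex_model()].
#' @return Energy in kcal/mol.
#' @export
duplex_mfe <- function(seq_a, seq_b, model = duplex_model()) {
  a <- seq_chars(norm_seq(seq_a))
  brev <- rev(seq_chars(norm_seq(seq_b)))
  la <- length(a); lb <- length(brev)
  if (la < 4L || lb < 4L) abort("duplex_mfe needs both strands >= 4 nt")
  best <- Inf
  for (s in seq.int(-(la - 4L), lb - 4L)) {
    i <- seq_len(la)
    j <- i + s
    keep <- j >= 1L & j <= lb
    ai <- a[i[keep]]; bj <- brev[j[keep]]
    wc <- is_wc(ai, bj)
    gu <- model$allow_gu & is_gu(ai, bj)
    paired <- wc | gu
    n <- length(ai)
    e <- model$init_penalty + model$mismatch_penalty * sum(!paired)
    if (n >= 2L) {
      both <- paired[-n] & paired[-1L]
      bothwc <- wc[-n] & wc[-1L]
      doublet <- paste0(ai[-n], ai[-1L])
      stack <- ifelse(bothwc, model$stack_table[doublet], model$gu_energy)
      e <- e + sum(ifelse(both, stack, 0))
    }
    if (e < best) best <- e
  }
  best
}

#' Three-rule consensus target prediction
#'
#' For every (tsRNA, gene) pair, candidate sites come from
#' [seed_match_sites()]; each site is then tested by the strict pairing
#' filter and the duplex free-energy threshold over the UTR window
#' opposing tsRNA positions 1..min(21, length). A site is a consensus
#' call only when all three rules agree; a gene is a consensus target of
#' a tsRNA when it carries at least one consensus site.
#'
#' @param tsrnas Tibble with `name` and `sequence` columns (e.g. from
#'   [collapse_and_name()]), or a named character vector of sequences.
#' @param utrs Named character vector of 3'UTR sequences keyed by gene id,
#'   or a tibble with `gene_id` and `utr_seq`.
#' @param cfg A [target_config()].
#' @param model A [duplex_model()].
#' @return A `tsrna_targets` tibble: `tsrna_name`, `gene_id`,
#'   `utr_position`, `seed_evidence`, `pairing_pass`,
#'   `pairing_mismatches`, `mfe`, `consensus`. The gene-level consensus
#'   sets are available via [consensus_genes()].
#' @export
consensus_targets <- function(tsrnas, utrs, cfg = target_config(),
                              model = duplex_model()) {
  if (is.character(tsrnas)) {
    tsrnas <- tibble(name = names(tsrnas) %||% paste0("tsrna", seq_along(tsrnas)),
                     sequence = unname(tsrnas))
  }
  if (is.data.frame(utrs)) utrs <- tibble::deframe(utrs[, c("gene_id", "utr_seq")])
  if (length(utrs) == 0L) abort("empty UTR collection")
  utrs <- vapply(utrs, norm_seq, character(1))

  rows <- list()
  for (t in seq_len(nrow(tsrnas))) {
    ts_seq <- norm_seq(tsrnas$sequence[t])
    K <- min(cfg$mismatch_span[2], nchar(ts_seq))
    ts_head <- substr(ts_seq, 1L, K)
    for (g in names(utrs)) {
      utr <- utrs[[g]]
      sites <- seed_match_sites(ts_seq, utr, cfg)
      if (nrow(sites) == 0L) next
      # UTR position opposing tsRNA position 1, per site geometry.
      q <- sites$utr_position + sites$offset + cfg$seed_len - 2L
      ns <- nrow(sites)
      ts_chars <- seq_chars(ts_seq)
      pass <- logical(ns); mism <- integer(ns); mfe <- numeric(ns)
      for (i in seq_len(ns)) {
        lo <- max(1L, q[i] - K + 1L)
        hi <- min(nchar(utr), q[i])
        site_seq <- substr(utr, lo, hi)
        # Pad with N when the site runs off the UTR 3' side so that the
        # last site base still opposes tsRNA position 1.
        if (hi < q[i]) site_seq <- paste0(site_seq, strrep("N", q[i] - hi))
        pe <- pairing_eval(ts_chars, seq_chars(site_seq), cfg)
        pass[i] <- pe$pass; mism[i] <- pe$mismatches
        mfe[i] <- duplex_mfe(ts_head, site_seq, model)
      }
      rows[[length(rows) + 1L]] <- tibble(
        tsrna_name = tsrnas$name[t], gene_id = g,
        utr_position = sites$utr_position,
        seed_evidence = sites$seed_evidence,
        pairing_pass = pass, pairing_mismatches = mism, mfe = mfe,
        consensus = pass & mfe < cfg$mfe_threshold
      )
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(tsrna_name = character(), gene_id = character(),
           utr_position = integer(), seed_evidence = character(),
           pairing_pass = logical(), pairing_mismatches = integer(),
           mfe = numeric(), consensus = logical())
  class(out) <- c("tsrna_targets", class(out))
  out
}

#' Gene-level consensus target sets
#'
#' @param calls A `tsrna_targets` tibble from [consensus_targets()].
#' @return Tibble of distinct (`tsrna_name`, `gene_id`) pairs with at
#'   least one consensus site.
#' @export
consensus_genes <- function(calls) {
  calls |>
    filter(.data$consensus) |>
    distinct(.data$tsrna_name, .data$gene_id) |>
    as_tibble()
}
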