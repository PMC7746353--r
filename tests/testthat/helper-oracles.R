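# Independent oracles and fixtures shared across the suite. Each oracle is a
# deliberately naive re-derivation, kept free of the package's own code paths.

# --- canonical 76-nt cloverleaf fixture ------------------------------------
# Acceptor stem 1-7/66-72, D arm 10-13/22-25 (loop 14-21), anticodon arm
# 27-31/39-43 (loop 32-38), variable loop 44-48, T arm 49-53/61-65
# (loop 54-60), discriminator + CCA 73-76.
fixture_structure <- paste0(
  "(((((((", "..", "((((", strrep(".", 8), "))))", ".",
  "(((((", strrep(".", 7), ")))))", ".....",
  "(((((", strrep(".", 7), ")))))", ")))))))", "...."
)

fixture_trna <- function() {
  set.seed(7001)
  pairs <- dotbracket_pairs_oracle(fixture_structure)
  base <- sample(c("A", "C", "G", "T"), 76, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in which(!is.na(pairs) & pairs > seq_len(76))) base[pairs[i]] <- comp[base[i]]
  base[34:36] <- c("G", "C", "C")
  base[74:76] <- c("C", "C", "A")
  seqs <- paste(base, collapse = "")
  trailer <- paste(c(rep("T", 10), sample(c("A", "C", "G"), 6, replace = TRUE)), collapse = "")
  tibble::tibble(
    id = "tRNA-Gly-GCC-1", amino_acid = "Gly", anticodon = "GCC",
    mature_seq = seqs, structure = fixture_structure, cca = TRUE,
    d_start = 14L, d_end = 21L, ac_start = 32L, ac_end = 38L,
    t_start = 54L, t_end = 60L, trailer_seq = trailer
  )
}

# --- dot-bracket oracles ----------------------------------------------------
# Stack-based pairing map, written independently of the package internals.
dotbracket_pairs_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  stack <- integer(0)
  pairs <- rep(NA_integer_, length(ch))
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      pairs[i] <- stack[length(stack)]
      pairs[stack[length(stack)]] <- i
      stack <- stack[-length(stack)]
    }
  }
  pairs
}

# Hairpin loops by direct definition: a "(" at i and its partner j with only
# dots strictly between them encloses the loop [i+1, j-1].
hairpin_loops_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  pairs <- dotbracket_pairs_oracle(s)
  out <- NULL
  for (i in seq_along(ch)) {
    j <- pairs[i]
    if (!is.na(j) && j > i + 1L && all(ch[(i + 1L):(j - 1L)] == ".")) {
      out <- rbind(out, c(i + 1L, j - 1L))
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out[order(out[, 1]), , drop = FALSE]
}

# Random valid dot-bracket string (balanced by construction).
random_dotbracket <- function(len) {
  out <- character(0)
  open <- 0L
  while (length(out) < len - open) {
    r <- stats::runif(1)
    if (r < 0.3) {
      out <- c(out, "(")
      open <- open + 1L
    } else if (r < 0.55 && open > 0L) {
      out <- c(out, ")")
      open <- open - 1L
    } else {
      out <- c(out, ".")
    }
  }
  paste(c(out, rep(")", open)), collapse = "")
}

# --- classifier oracle ------------------------------------------------------
# Exhaustive six-way case analysis on the fixture tRNA (L = 76, anticodon
# loop [32, 38], tol5 = 1, tol3 = 3), written as literal nested cases.
classify_oracle <- function(start, end, L = 76L, ac = c(32L, 38L)) {
  anchored5 <- start <= 1L
  anchored3 <- end >= L - 3L
  if (anchored5 && anchored3) return(NA_character_)
  if (anchored5) {
    if (end < ac[1]) return("tRF-5") else return("tiRNA-5")
  }
  if (anchored3) {
    if (start > ac[2]) return("tRF-3") else return("tiRNA-3")
  }
  "i-tRF"
}

# --- duplex free-energy oracle ----------------------------------------------
# Naive scalar summation over every antiparallel ungapped registration,
# using its own copy of the published Turner-set Watson-Crick constants.
oracle_wc_stack <- c(
  AA = -0.93, TT = -0.93, AT = -1.10, TA = -1.33,
  CT = -2.08, AG = -2.08, CA = -2.11, TG = -2.11,
  GT = -2.24, AC = -2.24, GA = -2.35, TC = -2.35,
  CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42
)

mfe_oracle <- function(a, b, init = 4.09, mismatch = 1.0, gu = -0.5,
                       allow_gu = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  av <- strsplit(gsub("U", "T", toupper(a)), "")[[1]]
  bv <- rev(strsplit(gsub("U", "T", toupper(b)), "")[[1]])
  la <- length(av); lb <- length(bv)
  best <- Inf
  for (s in (-(la - 4L)):(lb - 4L)) {
    e <- init
    state <- character(la)  # pair state per tsRNA position
    for (i in seq_len(la)) {
      j <- i + s
      if (j < 1L || j > lb) {
        state[i] <- "out"
      } else if (!is.na(comp[av[i]]) && comp[av[i]] == bv[j]) {
        state[i] <- "wc"
      } else if (allow_gu &&
                 ((av[i] == "G" && bv[j] == "T") || (av[i] == "T" && bv[j] == "G"))) {
        state[i] <- "gu"
      } else {
        state[i] <- "mm"
        e <- e + mismatch
      }
    }
    for (i in seq_len(la - 1L)) {
      if (state[i] %in% c("wc", "gu") && state[i + 1L] %in% c("wc", "gu")) {
        if (state[i] == "wc" && state[i + 1L] == "wc") {
          e <- e + oracle_wc_stack[paste0(av[i], av[i + 1L])]
        } else {
          e <- e + gu
        }
      }
    }
    if (e < best) best <- e
  }
  unname(best)
}

# --- seed-site oracle -------------------------------------------------------
# Brute-force scan: for every window and every UTR offset, compare characters.
seed_sites_oracle <- function(tsrna, utr) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ts <- strsplit(gsub("U", "T", toupper(tsrna)), "")[[1]]
  uv <- strsplit(gsub("U", "T", toupper(utr)), "")[[1]]
  out <- NULL
  for (o in seq_len(length(ts) - 6L)) {
    w <- ts[o:(o + 6L)]
    rc7 <- rev(unname(comp[w]))
    rc6a <- c(rev(unname(comp[w[2:7]])), "A")
    for (p in seq_len(length(uv) - 6L)) {
      piece <- uv[p:(p + 6L)]
      if (all(piece == rc7)) {
        out <- rbind(out, data.frame(offset = o, utr_position = p, seed_evidence = "7mer"))
      } else if (all(piece == rc6a)) {
        out <- rbind(out, data.frame(offset = o, utr_position = p, seed_evidence = "7mer-1a"))
      }
    }
  }
  if (is.null(out)) data.frame(offset = integer(), utr_position = integer(),
                               seed_evidence = character()) else out
}

# --- hypergeometric tail oracle ---------------------------------------------
# Exhaustive enumeration of the upper tail with choose().
hyper_tail_oracle <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  i <- max(k, 0):min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# --- misc -------------------------------------------------------------------
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_ref_fixture <- function(path, records) {
  writeLines(unlist(lapply(records, function(r) {
    c(sprintf(">%s %s %s%s", r$id, r$amino_acid, r$anticodon,
              if (is.null(r$trailer)) "" else paste0(" precursor_trailer=", r$trailer)),
      r$seq, r$struct)
  })), path)
  path
}
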