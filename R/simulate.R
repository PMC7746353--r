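#' Simulation configuration
#'
#' Defines the synthetic study: a small set of cloverleaf tRNAs per
#' amino-acid family, type-conditioned fragment reads in two groups of
#' `n_replicates` with planted fold changes, adapter-ligated reads, 3'UTRs
#' with planted consensus target sites, a DE-mRNA table and a
#' gene-pathway annotation. The default type mixture is calibrated to the
#' published sham-brain composition (tiRNA-5 38.36%, tRF-3 21.29%, tRF-1
#' 0.12%) with the remaining mass split evenly over tRF-5, i-tRF and
#' tiRNA-3; the default design is two groups of three replicates.
#'
#' Three independent RNG streams (references, reads, targets) are derived
#' from the master seed so perturbing one stage does not reshuffle the
#' others.
#'
#' @param seed Master RNG seed.
#' @param n_trnas_per_family tRNA genes per amino-acid family (default 2).
#' @param families Amino-acid families to simulate.
#' @param type_mixture Named probabilities over the six tsRNA types
#'   (must sum to 1).
#' @param n_fragments Distinct fragments in the catalog (default 150).
#' @param n_replicates Replicates per group (default 3).
#' @param depth Expected reads per sample (default 5e4).
#' @param groups The two group labels (default `c("sham", "ICH")`).
#' @param n_de Number of fragments with planted fold changes (default 10,
#'   alternating up/down).
#' @param de_log2fc Magnitude of the planted log2 fold change (default 2).
#' @param noise_cv Coefficient of variation of replicate counts; counts
#'   are negative-binomial with `size = 1/cv^2` (default 0.1).
#' @param adapter3 3' adapter ligated to every read (default: the
#'   Illumina TruSeq small-RNA 3' adapter).
#' @param error_rate Uniform per-base substitution error rate (default 0).
#' @param read_len Sequencer read length; reads are insert + adapter
#'   truncated to this many cycles (default 50).
#' @param n_genes Number of synthetic genes/3'UTRs (default 50).
#' @param n_planted_sites Consensus target sites planted in UTRs
#'   (default 10).
#' @param utr_len_range UTR length range in nt (default 200-2000).
#' @param n_de_genes Significant genes in the synthetic DE-mRNA table
#'   (default 15).
#' @param de_target_overlap How many significant DE genes are planted
#'   target genes (default 5).
#' @param pathway_sizes Term sizes of the synthetic annotation; the first
#'   term is the planted-enriched one, kept small (10) so the planted
#'   signal clears the P < 0.01 and enrichment-factor gates at the
#'   default list size (default c(10, 20, 15, 12, 10, 8)).
#' @param organism Organism prefix for names (default `"rno"`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_trnas_per_family = 2L,
                       families = c("Ala", "Arg", "Cys", "Gln", "Glu",
                                    "Gly", "Leu", "Lys", "Met", "Ser"),
                       type_mixture = c(`tiRNA-5` = 0.3836, `tRF-3` = 0.2129,
                                        `tRF-5` = 0.1341, `i-tRF` = 0.1341,
                                        `tiRNA-3` = 0.1341, `tRF-1` = 0.0012),
                       n_fragments = 150L, n_replicates = 3L, depth = 5e4,
                       groups = c("sham", "ICH"),
                       n_de = 10L, de_log2fc = 2, noise_cv = 0.1,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       error_rate = 0, read_len = 50L,
                       n_genes = 50L, n_planted_sites = 10L,
                       utr_len_range = c(200L, 2000L),
                       n_de_genes = 15L, de_target_overlap = 5L,
                       pathway_sizes = c(10L, 20L, 15L, 12L, 10L, 8L),
                       organism = "rno") {
  if (abs(sum(type_mixture) - 1) > 1e-9) abort("type_mixture must sum to 1")
  if (!all(names(type_mixture) %in% TSRNA_TYPES)) abort("unknown tsRNA type in type_mixture")
  if (depth <= 0) abort("depth must be positive")
  if (n_replicates < 1L) abort("need at least one replicate per group")
  cfg <- as.list(environment())
  # Independent per-artifact RNG streams derived from the master seed.
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  cfg$streams <- stats::setNames(sample.int(.Machine$integer.max - 1L, 3L),
                                 c("references", "reads", "targets"))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(cfg, class = "sim_config")
}

# Fixed 76-nt cloverleaf scaffold: acceptor stem 1-7/66-72, D arm
# 10-13/22-25 (loop 14-21), anticodon arm 27-31/39-43 (loop 32-38,
# anticodon 34-36), variable loop 44-48, T arm 49-53/61-65 (loop 54-60),
# discriminator + CCA 73-76.
CLOVERLEAF <- paste0(
  "(((((((", "..", "((((", strrep(".", 8), "))))", ".",
  "(((((", strrep(".", 7), ")))))", ".....",
  "(((((", strrep(".", 7), ")))))", ")))))))", "...."
)

ANTICODONS <- c(Ala = "AGC", Arg = "ACG", Cys = "GCA", Gln = "CTG",
                Glu = "CTC", Gly = "GCC", Leu = "CAA", Lys = "CTT",
                Met = "CAT", Ser = "AGA")

#' Simulate a structure-annotated tRNA reference
#'
#' Each tRNA is a 76-nt canonical cloverleaf on a fixed paired scaffold:
#' stem 5' sides and loop bases are randomised, stem 3' sides are their
#' complements, the anticodon occupies the centre of the anticodon loop,
#' and the sequence ends in CCA. A 16-20 nt uracil-rich 3' precursor
#' trailer (U fraction >= 0.6 by construction) is attached to every gene.
#'
#' @param cfg A [sim_config()].
#' @return A reference tibble in the same shape as
#'   [parse_trna_reference()].
#' @export
simulate_references <- function(cfg) {
  set.seed(cfg$streams[["references"]])
  pairs <- dotbracket_pairs(CLOVERLEAF)
  loops <- locate_loops(CLOVERLEAF)
  n <- length(pairs)
  rows <- list()
  for (fam in cfg$families) {
    ac <- ANTICODONS[fam]
    if (is.na(ac)) ac <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    for (k in seq_len(cfg$n_trnas_per_family)) {
      base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      for (i in which(!is.na(pairs) & pairs > seq_len(n))) {
        base[pairs[i]] <- comp_base[base[i]]
      }
      base[34:36] <- seq_chars(ac)
      base[74:76] <- c("C", "C", "A")
      tlen <- sample(16:20, 1)
      n_u <- ceiling(0.6 * tlen)
      trailer <- sample(c("A", "C", "G"), tlen, replace = TRUE)
      trailer[sample.int(tlen, n_u)] <- "T"
      rows[[length(rows) + 1L]] <- tibble(
        id = sprintf("tRNA-%s-%s-%d", fam, to_rna(unname(ac)), k),
        amino_acid = fam, anticodon = to_rna(unname(ac)),
        mature_seq = paste(base, collapse = ""), structure = CLOVERLEAF,
        cca = TRUE,
        d_start = loops$start[1], d_end = loops$end[1],
        ac_start = loops$start[2], ac_end = loops$end[2],
        t_start = loops$start[3], t_end = loops$end[3],
        trailer_seq = paste(trailer, collapse = "")
      )
    }
  }
  bind_rows(rows)
}

# sample() that never falls into the scalar-x trap
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

# Draw fragment endpoints for one tsRNA type on one reference record.
draw_fragment <- function(type, rec) {
  L <- nchar(rec$mature_seq)
  switch(type,
    "tRF-5" = {
      end <- sample(16:23, 1)
      list(region = "mature", start = 1L, end = end)
    },
    "tiRNA-5" = {
      list(region = "mature", start = 1L, end = sample(rec$ac_start:rec$ac_end, 1))
    },
    "tRF-3" = {
      len <- sample(16:23, 1)
      list(region = "mature", start = L - len + 1L, end = L)
    },
    "tiRNA-3" = {
      list(region = "mature", start = sample(rec$ac_start:rec$ac_end, 1), end = L)
    },
    "i-tRF" = {
      start <- sample(2:(rec$ac_start - 2L), 1)
      len <- sample(16:23, 1)
      list(region = "mature", start = start, end = start + len - 1L)
    },
    "tRF-1" = {
      tlen <- nchar(rec$trailer_seq)
      len <- resample(seq.int(16L, min(20L, tlen)))
      list(region = "trailer", start = 1L, end = len)
    }
  )
}

#' Simulate adapter-ligated small-RNA reads with planted ground truth
#'
#' Builds a catalog of distinct fragments whose endpoints are conditioned
#' on tsRNA type (e.g. tiRNA-5: start 1, end uniform in the anticodon
#' loop), with relative abundances drawn log-normally and rescaled within
#' each type so the expected type composition equals `cfg$type_mixture`.
#' `n_de` fragments get planted fold changes (`+/- de_log2fc`,
#' alternating). Replicate counts are negative-binomial
#' (`size = 1/noise_cv^2`); each read is insert + 3' adapter truncated to
#' `read_len` cycles, with optional uniform substitution errors, and
#' per-sample read order is shuffled deterministically.
#'
#' @param cfg A [sim_config()].
#' @param ref Reference tibble from [simulate_references()].
#' @return A list: `samples` (tibble `sample`, `group`), `reads` (named
#'   list of per-sample read tibbles `id`, `seq`, `qual`; ids embed the
#'   truth fragment index), and `truth` (tibble `fragment`, `sequence`,
#'   `type`, `source_trna`, `region`, `start`, `end`, `mean_sham`,
#'   `mean_ich`, `log2fc`, `planted_de`, the means being expected counts
#'   per replicate in each group).
#' @export
simulate_reads <- function(cfg, ref) {
  set.seed(cfg$streams[["reads"]])
  mix <- cfg$type_mixture
  n_type <- pmax(round(mix * cfg$n_fragments), 1L)
  # catalog of distinct fragments
  frags <- list()
  seen <- character()
  for (ty in names(mix)) {
    made <- 0L
    tries <- 0L
    while (made < n_type[[ty]] && tries < 200L * n_type[[ty]]) {
      tries <- tries + 1L
      rec <- ref[sample.int(nrow(ref), 1), ]
      fr <- draw_fragment(ty, rec)
      src <- if (fr$region == "mature") rec$mature_seq else rec$trailer_seq
      s <- substr(src, fr$start, fr$end)
      if (s %in% seen) next
      seen <- c(seen, s)
      made <- made + 1L
      frags[[length(frags) + 1L]] <- tibble(
        sequence = s, type = ty, source_trna = rec$id,
        region = fr$region, start = fr$start, end = fr$end
      )
    }
    if (made < n_type[[ty]]) {
      abort(sprintf("could not draw %d distinct fragments of type %s", n_type[[ty]], ty))
    }
  }
  truth <- bind_rows(frags)
  nf <- nrow(truth)
  w <- stats::rlnorm(nf, 0, 1)
  for (ty in names(mix)) {
    sel <- truth$type == ty
    w[sel] <- mix[[ty]] * w[sel] / sum(w[sel])
  }
  truth$fragment <- sprintf("frag%04d", seq_len(nf))
  truth$log2fc <- 0
  truth$planted_de <- FALSE
  if (cfg$n_de > 0L) {
    de_idx <- sample.int(nf, cfg$n_de)
    truth$planted_de[de_idx] <- TRUE
    truth$log2fc[de_idx] <- rep_len(c(cfg$de_log2fc, -cfg$de_log2fc), cfg$n_de)
  }
  truth$mean_sham <- w * cfg$depth
  truth$mean_ich <- truth$mean_sham * 2^truth$log2fc

  samples <- tibble(
    sample = paste0(rep(cfg$groups, each = cfg$n_replicates), "_",
                    rep(seq_len(cfg$n_replicates), 2)),
    group = rep(cfg$groups, each = cfg$n_replicates)
  )
  reads <- vector("list", nrow(samples))
  names(reads) <- samples$sample
  tmpl <- substr(paste0(truth$sequence, cfg$adapter3), 1L, cfg$read_len)
  for (i in seq_len(nrow(samples))) {
    mu <- if (samples$group[i] == cfg$groups[1]) truth$mean_sham else truth$mean_ich
    cnt <- stats::rnbinom(nf, mu = mu, size = 1 / cfg$noise_cv^2)
    seqs <- rep.int(tmpl, cnt)
    fidx <- rep.int(seq_len(nf), cnt)
    if (cfg$error_rate > 0 && length(seqs)) {
      nerr <- stats::rbinom(length(seqs), nchar(seqs), cfg$error_rate)
      hit <- which(nerr > 0L)
      for (r in hit) {
        ch <- seq_chars(seqs[r])
        pos <- sample.int(length(ch), nerr[r])
        ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        seqs[r] <- paste(ch, collapse = "")
      }
    }
    ord <- sample.int(length(seqs))
    reads[[i]] <- tibble(
      id = sprintf("%s_%s_%06d", samples$sample[i], truth$fragment[fidx[ord]],
                   seq_along(ord)),
      seq = seqs[ord],
      qual = strrep("I", nchar(seqs[ord]))
    )
  }
  list(samples = samples, reads = reads, truth = truth)
}

#' Simulate 3'UTRs with planted consensus sites, a DE-mRNA table and a
#' pathway annotation
#'
#' UTRs are random sequences of 200-2000 nt. Each planted site is the
#' reverse complement of the tsRNA's first min(21, length) nt with 0-2
#' substitutions confined to the tolerated 12-21 span, re-drawn (with a
#' warning, up to a bounded retry count) until it clears the duplex
#' free-energy threshold, then embedded at a random UTR position. The
#' DE-mRNA table marks `n_de_genes` genes significant, of which
#' `de_target_overlap` are planted target genes; the annotation groups
#' genes into terms of `pathway_sizes` with the planted-enriched term
#' first (seeded with the overlap genes).
#'
#' @param cfg A [sim_config()].
#' @param tsrnas Tibble with `name`, `sequence`, or a named character
#'   vector of tsRNA sequences.
#' @param target_cfg A [target_config()].
#' @param model A [duplex_model()].
#' @return A list: `utrs` (named character vector), `de_table`,
#'   `annotation` (tibble `gene_id`, `term_id`, `term_name`) and `truth`
#'   (list with `sites`, `validated_genes`, `enriched_term`).
#' @export
simulate_targets <- function(cfg, tsrnas, target_cfg = target_config(),
                             model = duplex_model()) {
  set.seed(cfg$streams[["targets"]])
  if (is.character(tsrnas)) {
    tsrnas <- tibble(name = names(tsrnas), sequence = unname(tsrnas))
  }
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  lens <- sample(cfg$utr_len_range[1]:cfg$utr_len_range[2], cfg$n_genes, replace = TRUE)
  utrs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  names(utrs) <- genes

  n_sites <- min(cfg$n_planted_sites, cfg$n_genes)
  site_genes <- sample(genes, n_sites)
  site_ts <- sample.int(nrow(tsrnas), n_sites, replace = TRUE)
  sites <- list()
  for (i in seq_len(n_sites)) {
    ts <- norm_seq(tsrnas$sequence[site_ts[i]])
    K <- min(target_cfg$mismatch_span[2], nchar(ts))
    head_seq <- substr(ts, 1L, K)
    span_lo <- target_cfg$mismatch_span[1]
    site <- NULL
    for (attempt in seq_len(20L)) {
      n_mm <- if (attempt <= 10L) sample(0:2, 1) else 0L
      sc <- rev(comp_base[seq_chars(head_seq)])  # perfect antiparallel complement
      if (n_mm > 0L && span_lo <= K) {
        mm_pos <- sample(span_lo:K, min(n_mm, K - span_lo + 1L))
        for (k in mm_pos) {
          j <- K - k + 1L
          sc[j] <- sample(setdiff(c("A", "C", "G", "T"), comp_base[substr(head_seq, k, k)]), 1)
        }
      }
      cand <- paste(sc, collapse = "")
      if (duplex_mfe(head_seq, cand, model) < target_cfg$mfe_threshold) {
        site <- cand
        break
      }
      warn(sprintf("planted site for %s failed the MFE threshold; regenerating",
                   tsrnas$name[site_ts[i]]))
    }
    if (is.null(site)) {
      abort(sprintf("could not plant an MFE-passing site for tsRNA %s", tsrnas$name[site_ts[i]]))
    }
    g <- site_genes[i]
    pos <- sample.int(nchar(utrs[[g]]) - nchar(site) + 1L, 1)
    utrs[[g]] <- paste0(substr(utrs[[g]], 1, pos - 1L), site,
                        substr(utrs[[g]], pos + nchar(site), nchar(utrs[[g]])))
    sites[[i]] <- tibble(
      gene_id = g, tsrna_name = tsrnas$name[site_ts[i]],
      utr_position = pos, site_seq = site
    )
  }
  sites <- bind_rows(sites)

  overlap <- sample(unique(sites$gene_id), min(cfg$de_target_overlap, length(unique(sites$gene_id))))
  other_sig <- sample(setdiff(genes, unique(sites$gene_id)),
                      max(0L, cfg$n_de_genes - length(overlap)))
  sig <- c(overlap, other_sig)
  de_table <- tibble(
    gene_id = genes,
    log2fc = ifelse(genes %in% sig,
                    sample(c(-1, 1), cfg$n_genes, replace = TRUE) * stats::runif(cfg$n_genes, 0.8, 3),
                    stats::runif(cfg$n_genes, -0.4, 0.4)),
    p = ifelse(genes %in% sig, stats::runif(cfg$n_genes, 0.0001, 0.04),
               stats::runif(cfg$n_genes, 0.1, 0.9))
  ) |> flag_de()

  ann <- list()
  for (t in seq_along(cfg$pathway_sizes)) {
    size <- min(cfg$pathway_sizes[t], cfg$n_genes)
    members <- if (t == 1L) {
      c(overlap, sample(setdiff(genes, overlap), size - length(overlap)))
    } else {
      sample(genes, size)
    }
    ann[[t]] <- tibble(gene_id = members, term_id = sprintf("term%02d", t),
                       term_name = sprintf("pathway_%02d", t))
  }
  list(
    utrs = utrs, de_table = de_table, annotation = bind_rows(ann),
    truth = list(sites = sites, validated_genes = sort(overlap),
                 enriched_term = "term01")
  )
}
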