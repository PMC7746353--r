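test_that("seed windows slide by one nt from 5' to 3'", {
  w <- enumerate_seed_windows("ACGTACGTACGTACGT")  # 16 nt
  expect_equal(nrow(w), 10L)
  expect_equal(w$offset, 1:10)
  # printed mimic sequence of a 16-nt internal Gln fragment
  w2 <- enumerate_seed_windows("TCTGGACTCTGAATCC")
  expect_equal(w2$window[1], "TCTGGAC")
  expect_equal(w2$window, substring("TCTGGACTCTGAATCC", 1:10, 7:16))
  expect_equal(w2$window[nrow(w2)], "TGAATCC")
  one <- enumerate_seed_windows("ACGTACG")
  expect_equal(one$window, "ACGTACG")
  expect_error(enumerate_seed_windows("ACGTAC"), "shorter")
})

test_that("seed matching finds planted 7mer and 7mer-1a sites", {
  set.seed(801)
  ts <- "TCTGGACTCTGAATCCATTGAACTG"
  rc7 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(substr(ts, 1, 7))))
  utr7 <- paste0(random_dna(50), rc7, random_dna(50))
  hits <- seed_match_sites(ts, utr7)
  expect_true(any(hits$offset == 1 & hits$utr_position == 51 & hits$seed_evidence == "7mer"))

  # position 1 must not be T here, or the 7mer-1a site would equal the 7mer
  ts2 <- "GCTGGACTCTGAATCCATTGAACTG"
  rc6 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(substr(ts2, 2, 7))))
  utr1a <- paste0(strrep("C", 40), rc6, "A", strrep("C", 40))
  hits1a <- seed_match_sites(ts2, utr1a)
  expect_true(any(hits1a$offset == 1 & hits1a$utr_position == 41 &
                    hits1a$seed_evidence == "7mer-1a"))
})

test_that("seed matching equals the brute-force scan on random pairs", {
  set.seed(802)
  for (i in 1:200) {
    ts <- random_dna(sample(16:30, 1))
    utr <- random_dna(sample(60:200, 1))
    got <- seed_match_sites(ts, utr)
    exp <- seed_sites_oracle(ts, utr)
    got_k <- paste(got$offset, got$utr_position, got$seed_evidence)
    exp_k <- paste(exp$offset, exp$utr_position, exp$seed_evidence)
    expect_setequal(got_k, exp_k)
  }
})

test_that("the pairing filter enforces perfect 2-11 and the 12-21 mismatch budget", {
  set.seed(803)
  ts <- random_dna(21)
  site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ts)))
  expect_true(pairing_filter(ts, site)$pass)
  expect_equal(pairing_filter(ts, site)$mismatches, 0L)

  flip <- function(site, ts, k) {
    # mutate the site base opposing tsRNA position k to a non-complement
    j <- nchar(site) - k + 1
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    cur <- substr(site, j, j)
    repl <- setdiff(c("A", "C", "G", "T"), c(cur, comp[substr(ts, k, k)]))[1]
    substr(site, j, j) <- repl
    site
  }
  expect_false(pairing_filter(ts, flip(site, ts, 3))$pass)  # breaks rule (i)
  s4 <- site
  for (k in 12:15) s4 <- flip(s4, ts, k)
  expect_true(pairing_filter(ts, s4)$pass)                  # 4 mismatches allowed
  s5 <- flip(s4, ts, 16)
  pf5 <- pairing_filter(ts, s5)
  expect_false(pf5$pass)                                    # 5 are not
  expect_equal(pf5$mismatches, 5L)
})

test_that("short tsRNAs truncate the mismatch span and prorate the budget", {
  set.seed(804)
  ts <- random_dna(16)  # span 12-16: 5 positions, floor(4 * 5/10) = 2 allowed
  site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ts)))
  pf <- pairing_filter(ts, site)
  expect_equal(pf$max_allowed, 2L)
  expect_true(pf$pass)
})

test_that("duplex MFE matches the independent summation oracle", {
  set.seed(805)
  for (i in 1:60) {
    a <- random_dna(sample(8:21, 1))
    b <- if (i %% 2 == 0) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
    } else {
      random_dna(sample(8:21, 1))
    }
    expect_equal(duplex_mfe(a, b), mfe_oracle(a, b), tolerance = 1e-9)
  }
})

test_that("MFE is monotone in duplex length, symmetric, and GC-rich duplexes pass -20", {
  gc <- paste(rep(c("G", "C"), 10), collapse = "")  # 20-nt GC-rich strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gc)))
  expect_lt(duplex_mfe(gc, rc), -20)
  set.seed(806)
  e_prev <- Inf
  base <- "GCGAGCTAGCCGTATGGCCA"
  for (N in 8:20) {
    a <- substr(base, 1, N)
    b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
    e <- duplex_mfe(a, b)
    expect_lte(e, e_prev + 1e-12)
    e_prev <- e
  }
  a <- random_dna(15); b <- random_dna(15)
  expect_equal(duplex_mfe(a, b), duplex_mfe(b, a), tolerance = 1e-12)
  expect_error(duplex_mfe("ACG", "ACGT"), ">= 4 nt")
})

test_that("consensus requires all three rules and planted sites are recovered exactly", {
  set.seed(807)
  cfgT <- target_config()
  ts <- tibble::tibble(name = "ts1", sequence = "GCCGGGAATCGAACCCGGGAC")  # GC-rich 21-mer
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ts$sequence)))
  # gene A: full consensus site; gene B: a bare 7mer seed with no pairing
  # support beyond it (positions 8-11 oppose random bases)
  seed_only <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ts$sequence, 1, 7))
  ))
  utrs <- c(
    geneA = paste0(random_dna(80), rc, random_dna(80)),
    geneB = paste0(random_dna(80), seed_only, random_dna(80)),
    geneC = random_dna(300)
  )
  calls <- consensus_targets(ts, utrs, cfgT)
  cons <- consensus_genes(calls)
  expect_true("geneA" %in% cons$gene_id)
  expect_false("geneB" %in% cons$gene_id)
  # the intersection property: consensus is a subset of every engine's passes
  cc <- calls[calls$consensus, ]
  expect_true(all(cc$seed_evidence != "none"))
  expect_true(all(cc$pairing_pass))
  expect_true(all(cc$mfe < cfgT$mfe_threshold))
  expect_error(consensus_targets(ts, character(0)), "empty UTR")
})

test_that("generator-planted consensus sites give sensitivity 1 and high specificity", {
  cfg <- sim_config(seed = 31, n_genes = 50, n_planted_sites = 10)
  set.seed(901)
  tsrnas <- tibble::tibble(
    name = paste0("ts", 1:6),
    sequence = replicate(6, random_dna(sample(20:30, 1)))
  )
  tg <- suppressWarnings(simulate_targets(cfg, tsrnas))
  calls <- consensus_targets(tsrnas, tg$utrs)
  cons <- consensus_genes(calls)
  truth_pairs <- paste(tg$truth$sites$tsrna_name, tg$truth$sites$gene_id)
  got_pairs <- paste(cons$tsrna_name, cons$gene_id)
  expect_true(all(truth_pairs %in% got_pairs))  # sensitivity 1.0
  # specificity over all (tsRNA, gene) pairs
  neg <- nrow(tsrnas) * length(tg$utrs) - length(unique(truth_pairs))
  fp <- length(setdiff(got_pairs, truth_pairs))
  expect_gte(1 - fp / neg, 0.99)
})
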