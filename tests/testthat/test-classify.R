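test_that("map_reads reports every forward-strand occurrence", {
  fx <- fixture_trna()
  # second Gly isodecoder sharing the first 30 nt
  set.seed(601)
  fx2 <- fx
  fx2$id <- "tRNA-Gly-GCC-2"
  fx2$mature_seq <- paste0(substr(fx$mature_seq, 1, 30), random_dna(46))
  ref <- dplyr::bind_rows(fx, fx2)
  r_shared <- substr(fx$mature_seq, 1, 30)
  r_one <- substr(fx$mature_seq, 40, 60)
  r_absent <- "CCCCCCCCCCCCCCCCCCCC"
  aln <- map_reads(c(r_shared, r_one, r_absent), ref, max_mismatch = 0)
  expect_equal(sum(aln$read_seq == r_shared), 2L)
  shared <- aln[aln$read_seq == r_shared, ]
  expect_setequal(shared$trna_id, c("tRNA-Gly-GCC-1", "tRNA-Gly-GCC-2"))
  expect_true(all(shared$start == 1L & shared$end == 30L & shared$region == "mature"))
  expect_equal(sum(aln$read_seq == r_one), 1L)
  expect_equal(attr(aln, "unaligned"), r_absent)
  expect_error(map_reads("ACGT", ref[0, ]), "empty reference")
})

test_that("trailer hits map in trailer coordinates and tolerate mismatches when asked", {
  fx <- fixture_trna()
  tr_frag <- substr(fx$trailer_seq, 1, 16)
  aln <- map_reads(tr_frag, fx, max_mismatch = 0)
  expect_equal(aln$region, "trailer")
  expect_equal(c(aln$start, aln$end), c(1L, 16L))

  mut <- substr(fx$mature_seq, 1, 25)
  b3 <- substr(mut, 3, 3)
  substr(mut, 3, 3) <- ifelse(b3 == "G", "C", "G")  # one substitution at pos 3
  a0 <- map_reads(mut, fx, max_mismatch = 0)
  a1 <- map_reads(mut, fx, max_mismatch = 1)
  expect_equal(nrow(a0[a0$region == "mature" & a0$start == 1, ]), 0L)
  hit <- a1[a1$region == "mature" & a1$start == 1, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mismatches, 1L)
})

test_that("the classifier reproduces the published type definitions", {
  fx <- fixture_trna()
  cases <- tibble::tribble(
    ~region, ~start, ~end, ~expected,
    "mature", 1L, 35L, "tiRNA-5",   # 5' half reaching the anticodon loop
    "mature", 1L, 20L, "tRF-5",     # 5' fragment stopping in the D arm
    "mature", 55L, 76L, "tRF-3",    # T-loop start to the CCA end
    "mature", 10L, 34L, "i-tRF",    # anchored at neither end
    "mature", 35L, 76L, "tiRNA-3",  # anticodon loop to the 3' end
    "trailer", 1L, 16L, "tRF-1"     # precursor trailer fragment
  )
  aln <- tibble::tibble(
    read_seq = vapply(seq_len(nrow(cases)), function(i) {
      src <- if (cases$region[i] == "mature") fx$mature_seq else fx$trailer_seq
      substr(src, cases$start[i], cases$end[i])
    }, character(1)),
    trna_id = fx$id, region = cases$region,
    start = cases$start, end = cases$end, mismatches = 0L
  )
  got <- classify_fragments(aln, fx)
  expect_equal(got$type, cases$expected)
})

test_that("the classifier matches an exhaustive six-way case oracle on all intervals", {
  fx <- fixture_trna()
  grid <- expand.grid(start = 1:76, end = 1:76)
  grid <- grid[grid$start <= grid$end, ]
  aln <- tibble::tibble(
    read_seq = substring(fx$mature_seq, grid$start, grid$end),
    trna_id = fx$id, region = "mature",
    start = as.integer(grid$start), end = as.integer(grid$end), mismatches = 0L
  )
  got <- classify_fragments(aln, fx)$type
  expected <- mapply(classify_oracle, grid$start, grid$end)
  expect_equal(got, unname(expected))
  # every mature interval is either excluded (full length) or exactly one type
  expect_true(all(is.na(got) | got %in% c("tRF-3", "tRF-5", "i-tRF", "tiRNA-3", "tiRNA-5")))
})

test_that("distant trailer hits are not tRF-1", {
  fx <- fixture_trna()
  aln <- tibble::tibble(read_seq = substr(fx$trailer_seq, 4, 16), trna_id = fx$id,
                        region = "trailer", start = 4L, end = 16L, mismatches = 0L)
  expect_true(is.na(classify_fragments(aln, fx)$type))
  bad <- tibble::tibble(read_seq = "A", trna_id = fx$id, region = "mature",
                        start = 70L, end = 80L, mismatches = 0L)
  expect_error(classify_fragments(bad, fx), "outside")
})

test_that("collapse_and_name assigns variants by abundance then sequence", {
  fx <- fixture_trna()
  s_a <- substr(fx$mature_seq, 5, 24)   # two distinct 20-nt i-tRFs
  s_b <- substr(fx$mature_seq, 6, 25)
  aln <- tibble::tibble(
    read_seq = c(s_a, s_b), trna_id = fx$id, region = "mature",
    start = c(5L, 6L), end = c(24L, 25L), mismatches = 0L
  ) |> classify_fragments(fx)
  frags <- collapse_and_name(aln, "rno", c(50, 10) |> stats::setNames(c(s_a, s_b)))
  expect_equal(frags$variant[match(c(s_a, s_b), frags$sequence)], c("a", "b"))
  expect_equal(sort(frags$name), sort(c("rno-tRFi-Gly-20a", "rno-tRFi-Gly-20b")))
  # swapped abundances swap the letters
  frags2 <- collapse_and_name(aln, "rno", c(10, 50) |> stats::setNames(c(s_a, s_b)))
  expect_equal(frags2$variant[match(c(s_a, s_b), frags2$sequence)], c("b", "a"))
})

test_that("name rendering follows the published grammar and round-trips", {
  expect_equal(render_tsrna_name("rno", "i-tRF", "Ser", 25, "a"), "rno-tRFi-Ser-25a")
  expect_equal(render_tsrna_name("rno", "tiRNA-5", "Lys", 35, "b"), "rno-tiR5-Lys-35b")
  p <- parse_tsrna_name("rno-tRFi-Gln-16a")
  expect_equal(p$organism, "rno")
  expect_equal(p$type, "i-tRF")
  expect_equal(p$amino_acid, "Gln")
  expect_equal(p$length, 16L)
  expect_equal(p$variant, "a")
  expect_equal(parse_tsrna_name("rno-tiR3-Met-42c")$type, "tiRNA-3")

  set.seed(602)
  types <- c("tRF-1", "tRF-3", "tRF-5", "i-tRF", "tiRNA-3", "tiRNA-5")
  for (i in 1:50) {
    ty <- sample(types, 1)
    aa <- sample(c("Gly", "Ser", "Met", "Lys"), 1)
    len <- sample(16:49, 1)
    v <- sample(letters, 1)
    nm <- render_tsrna_name("rno", ty, aa, len, v)
    back <- parse_tsrna_name(nm)
    expect_equal(back$type, ty)
    expect_equal(back$amino_acid, aa)
    expect_equal(back$length, len)
    expect_equal(back$variant, v)
    expect_equal(render_tsrna_name(back$organism, back$type, back$amino_acid,
                                   back$length, back$variant), nm)
  }
  expect_error(parse_tsrna_name("rno-tRFx-Gly-20a"), "type code")
  expect_error(parse_tsrna_name("rno-tRFi-Gly-20"), "malformed")
})

test_that("planted types are recovered perfectly at zero sequencing error", {
  cfg <- sim_config(seed = 21, depth = 8000, n_fragments = 90)
  ref <- simulate_references(cfg)
  sim <- simulate_reads(cfg, ref)
  pc <- read_prep_config(adapter3 = cfg$adapter3)
  seqs <- unlist(lapply(sim$reads, function(r) trim_and_filter(r, pc)$seq))
  aln <- classify_fragments(map_reads(unique(seqs), ref, 0), ref)
  ab <- table(seqs)
  frags <- collapse_and_name(aln, "rno", stats::setNames(as.numeric(ab), names(ab)))
  m <- dplyr::inner_join(frags, sim$truth, by = "sequence")
  # every fragment with at least one sequenced read is named, none invented
  expect_setequal(m$sequence, intersect(sim$truth$sequence, seqs))
  expect_gte(nrow(m), nrow(sim$truth) - 2)
  # confusion matrix is diagonal
  expect_equal(m$type.x, m$type.y)
  # parsed length always equals sequence length
  expect_equal(parse_tsrna_name(frags$name)$length, nchar(frags$sequence))
})
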