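make_expr <- function(mat, groups) {
  # mat: fragments x samples matrix of counts
  tibble::as_tibble(as.table(mat), .name_repair = ~ c("name", "sample", "count")) |>
    dplyr::mutate(group = groups[sample], count = as.numeric(count))
}

test_that("TPM is counts per million of the aligned total, per sample", {
  expr <- tibble::tibble(
    name = c("a", "b"), sample = "s1", group = "g1", count = c(2, 8)
  )
  out <- compute_tpm(expr)
  expect_equal(out$tpm, c(200000, 800000))
  one <- compute_tpm(tibble::tibble(name = "a", sample = "s1", group = "g1", count = 7))
  expect_equal(one$tpm, 1e6)
  zero <- tibble::tibble(name = "a", sample = "s1", group = "g1", count = 0)
  expect_error(compute_tpm(zero), "zero")
  # explicit denominators: zeros stay zero, totals respected
  out2 <- compute_tpm(expr, aligned_totals = c(s1 = 20))
  expect_equal(out2$tpm, c(100000, 400000))
})

test_that("TPM sums to one million in every sample of a simulated run", {
  set.seed(701)
  mat <- matrix(rpois(60, 50), nrow = 10,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  groups <- stats::setNames(rep(c("sham", "ICH"), each = 3), paste0("s", 1:6))
  expr <- compute_tpm(make_expr(mat, groups))
  sums <- tapply(expr$tpm, expr$sample, sum)
  expect_equal(as.vector(sums), rep(1e6, 6), tolerance = 1e-12)
})

test_that("composition fractions are TPM-weighted and sum to one per breakdown", {
  frags <- tibble::tibble(
    name = c("f1", "f2", "f3"), type = c("tRF-5", "tRF-5", "tiRNA-5"),
    amino_acid = c("Gly", "Ser", "Gly"), length = c(18L, 20L, 34L)
  )
  expr <- tibble::tibble(
    name = rep(c("f1", "f2", "f3"), 2),
    sample = rep(c("s1", "s2"), each = 3),
    group = rep(c("sham", "ICH"), each = 3),
    count = c(10, 30, 60, 5, 5, 0)
  ) |> compute_tpm()
  comp <- composition(expr, frags)
  ty <- comp[comp$group == "sham" & comp$dimension == "type", ]
  expect_equal(ty$fraction[ty$level == "tRF-5"], 0.4)
  expect_equal(ty$fraction[ty$level == "tiRNA-5"], 0.6)
  ich_ty <- comp[comp$group == "ICH" & comp$dimension == "type", ]
  expect_equal(ich_ty$fraction[ich_ty$level == "tRF-5"], 1)
  agg <- aggregate(fraction ~ group + dimension, comp, sum)
  expect_equal(agg$fraction, rep(1, nrow(agg)))
  expect_s3_class(plot_composition(comp), "ggplot")
  # empty matrix -> empty table
  expect_equal(nrow(composition(expr[0, ], frags)), 0L)
})

test_that("Venn counts respect inclusion-exclusion and the detection rule", {
  expr <- tibble::tibble(
    name = c("a", "b", "c", "a", "c", "d"),
    sample = c("s1", "s1", "s1", "s2", "s2", "s2"),
    group = c("g1", "g1", "g1", "g2", "g2", "g2"),
    count = c(1, 0, 3, 2, 1, 5)
  )
  v <- venn_counts(expr, "g1", "g2")
  expect_equal(v$n_a, 2L)  # b has zero counts: not detected
  expect_equal(v$n_b, 3L)
  expect_equal(v$n_union, v$n_a + v$n_b - v$n_intersection)
  expect_equal(v$n_intersection, 2L)
  # identical sets
  same <- tibble::tibble(
    name = rep(c("a", "b"), 2), sample = rep(c("s1", "s2"), each = 2),
    group = rep(c("g1", "g2"), each = 2), count = 1
  )
  v2 <- venn_counts(same, "g1", "g2")
  expect_equal(v2$n_intersection, v2$n_union)
  expect_equal(v2$n_intersection, v2$n_a)
  # disjoint sets
  disj <- same |> dplyr::mutate(name = c("a", "b", "c", "d"))
  expect_equal(venn_counts(disj, "g1", "g2")$n_intersection, 0L)
  # published set sizes recover the printed intersection by inclusion-exclusion
  expect_equal(venn_intersection(308, 309, 331), 286)
  expect_equal(venn_intersection(10, 7, 17), 0)
})

test_that("diff_test matches the pooled-variance t oracle on a textbook case", {
  expr <- tibble::tibble(
    name = "f", sample = paste0("s", 1:6),
    group = rep(c("sham", "ICH"), each = 3),
    count = 1, tpm = c(10, 11, 12, 20, 21, 22)
  )
  res <- diff_test(expr, ref = "sham", alt = "ICH")
  oracle <- t.test(c(20, 21, 22), c(10, 11, 12), var.equal = TRUE)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$mean_ref, 11)
  expect_equal(res$mean_alt, 21)
  expect_true(res$significant)
})

test_that("diff_test agrees with stats::t.test on 100 random matrices", {
  set.seed(702)
  for (i in 1:100) {
    n <- sample(2:5, 1)
    x <- matrix(stats::rlnorm(2 * n * 4, 5, 1), nrow = 4)
    expr <- tibble::tibble(
      name = rep(paste0("f", 1:4), 2 * n),
      sample = rep(paste0("s", 1:(2 * n)), each = 4),
      group = rep(rep(c("A", "B"), each = n), each = 4),
      count = 1, tpm = as.vector(x)
    )
    res <- diff_test(expr, ref = "A", alt = "B")
    for (f in paste0("f", 1:4)) {
      a <- x[as.integer(sub("f", "", f)), 1:n]
      b <- x[as.integer(sub("f", "", f)), (n + 1):(2 * n)]
      expect_equal(res$p[res$name == f], t.test(b, a, var.equal = TRUE)$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("degenerate and antisymmetric cases behave by convention", {
  expr <- tibble::tibble(
    name = "f", sample = paste0("s", 1:6),
    group = rep(c("A", "B"), each = 3), count = 1, tpm = rep(5, 6)
  )
  res <- diff_test(expr, ref = "A", alt = "B")
  expect_equal(res$p, 1)
  expect_equal(res$log2fc, 0)
  expect_false(res$significant)

  set.seed(703)
  expr2 <- tibble::tibble(
    name = rep(paste0("f", 1:5), 6),
    sample = rep(paste0("s", 1:6), each = 5),
    group = rep(rep(c("A", "B"), each = 3), each = 5),
    count = 1, tpm = stats::rlnorm(30, 4, 1)
  )
  fwd <- diff_test(expr2, ref = "A", alt = "B")
  rev <- diff_test(expr2, ref = "B", alt = "A")
  m <- match(fwd$name, rev$name)
  expect_equal(fwd$log2fc, -rev$log2fc[m])
  expect_equal(fwd$p, rev$p[m])
  expect_error(diff_test(expr2[!expr2$sample %in% c("s1", "s2"), ]), "replicates")
})

test_that("a planted four-fold change with 10% CV and n=3 is flagged", {
  set.seed(704)
  base <- 500
  expr <- tibble::tibble(
    name = "f", sample = paste0("s", 1:6),
    group = rep(c("A", "B"), each = 3), count = 1,
    tpm = c(stats::rnorm(3, base, 0.1 * base), stats::rnorm(3, 4 * base, 0.4 * base))
  )
  res <- diff_test(expr, ref = "A", alt = "B")
  expect_true(res$significant)
  expect_gt(res$log2fc, 1.5)
})

test_that("results are sorted by p and expose tidy/glance summaries", {
  set.seed(705)
  expr <- tibble::tibble(
    name = rep(paste0("f", 1:6), 6),
    sample = rep(paste0("s", 1:6), each = 6),
    group = rep(rep(c("A", "B"), each = 3), each = 6),
    count = 1, tpm = stats::rlnorm(36, 4, 1)
  )
  res <- diff_test(expr, ref = "A", alt = "B")
  expect_false(is.unsorted(res$p))
  g <- glance(res)
  expect_equal(g$n_tested, 6L)
  expect_equal(g$n_significant, sum(res$significant))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "tsrna_diff"))
  expect_s3_class(autoplot(res), "ggplot")
})
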