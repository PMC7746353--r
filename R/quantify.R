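#' Normalise fragment counts to tags per million (TPM)
#'
#' TPM here is tag counts per million of total aligned tRNA reads:
#' `tpm = count / aligned_total * 1e6`, computed per sample. With the
#' default denominators (the per-sample sum of the supplied counts) TPM
#' sums to exactly one million in every sample.
#'
#' @param counts Long tibble with columns `name` (fragment), `sample`,
#'   `group`, `count` (nonnegative integers).
#' @param aligned_totals Optional named numeric vector of aligned-read
#'   totals per sample; defaults to per-sample count sums. Every total
#'   must be positive.
#' @return The input tibble with a `tpm` column appended.
#' @export
compute_tpm <- function(counts, aligned_totals = NULL) {
  stopifnot(all(c("name", "sample", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("counts must be nonnegative")
  if (is.null(aligned_totals)) {
    aligned_totals <- counts |>
      group_by(.data$sample) |>
      summarise(total = sum(.data$count)) |>
      tibble::deframe()
  }
  miss <- setdiff(unique(counts$sample), names(aligned_totals))
  if (length(miss)) abort(sprintf("no aligned total for sample(s): %s", paste(miss, collapse = ", ")))
  if (any(aligned_totals[unique(counts$sample)] <= 0)) {
    bad <- names(which(aligned_totals[unique(counts$sample)] <= 0))
    abort(sprintf("aligned total is zero for sample(s): %s", paste(bad, collapse = ", ")))
  }
  counts |> mutate(tpm = .data$count / unname(aligned_totals[.data$sample]) * 1e6)
}

#' TPM-weighted composition of a tsRNA profile
#'
#' Per-group fractions of total TPM broken down by tsRNA type, amino-acid
#' family and fragment length. Each breakdown sums to 1 within a group.
#'
#' @param expr Expression tibble from [compute_tpm()] (needs `name`,
#'   `sample`, `group`, `tpm`).
#' @param fragments Fragment tibble from [collapse_and_name()] (needs
#'   `name`, `type`, `amino_acid`, `length`).
#' @return A tibble with columns `group`, `dimension` (`"type"`,
#'   `"amino_acid"`, `"length"`), `level`, `fraction`.
#' @export
composition <- function(expr, fragments) {
  joined <- expr |>
    inner_join(fragments |> select("name", "type", "amino_acid", "length"),
               by = "name")
  if (nrow(joined) == 0L) {
    return(tibble(group = character(), dimension = character(),
                  level = character(), fraction = numeric()))
  }
  one_dim <- function(col) {
    joined |>
      group_by(.data$group, level = as.character(.data[[col]])) |>
      summarise(w = sum(.data$tpm), .groups = "drop_last") |>
      mutate(dimension = col, fraction = .data$w / sum(.data$w)) |>
      ungroup() |>
      select("group", "dimension", "level", "fraction")
  }
  bind_rows(one_dim("type"), one_dim("amino_acid"), one_dim("length"))
}

#' Detected-fragment sets and Venn counts between two groups
#'
#' A fragment counts as detected in a group when it has a nonzero raw
#' count in at least one replicate of that group. `venn_counts()` reports
#' the per-group, union and intersection cardinalities of the two detected
#' sets; `venn_intersection()` recovers the intersection from printed
#' per-group and union totals by inclusion-exclusion
#' (`A + B - union`).
#'
#' @param expr Long counts tibble (`name`, `sample`, `group`, `count`).
#' @param group_a,group_b The two group labels to compare (defaults: the
#'   first two group levels).
#' @return `venn_counts()`: one-row tibble `n_a`, `n_b`, `n_union`,
#'   `n_intersection` plus the group labels.
#' @export
venn_counts <- function(expr, group_a = NULL, group_b = NULL) {
  groups <- unique(expr$group)
  group_a <- group_a %||% groups[1]
  group_b <- group_b %||% groups[2]
  det <- function(g) {
    unique(expr$name[expr$group == g & expr$count > 0])
  }
  a <- det(group_a); b <- det(group_b)
  tibble(
    group_a = group_a, group_b = group_b,
    n_a = length(a), n_b = length(b),
    n_union = length(union(a, b)),
    n_intersection = length(intersect(a, b))
  )
}

#' @rdname venn_counts
#' @param n_a,n_b,n_union Printed per-group and union set sizes.
#' @export
venn_intersection <- function(n_a, n_b, n_union) {
  n_a + n_b - n_union
}

#' Differential tsRNA expression between two groups
#'
#' Two-sided unpaired Student's t test with pooled variance on TPM values,
#' fragment by fragment, with fold change computed on group means after
#' adding a small pseudocount (fold-change only, never the test). A
#' fragment is flagged significant when `|log2fc| > log2(fc_thresh)` and
#' `p < alpha`. No multiple-testing correction is applied: the raw-P plus
#' fold-change gate is the published convention this pipeline mirrors.
#' When both groups are constant and equal the statistic is undefined and
#' p is set to 1 (no evidence of change) by convention.
#'
#' @param expr Expression tibble from [compute_tpm()].
#' @param ref,alt Reference and alternative group labels (fold change is
#'   `alt / ref`); default to the first two group levels.
#' @param fc_thresh Fold-change gate (default 1.5).
#' @param alpha P-value gate (default 0.05).
#' @param pseudocount Added to both group means for the fold change only
#'   (default 0.01 TPM).
#' @return A `tsrna_diff` tibble sorted by p: `name`, `mean_ref`,
#'   `mean_alt`, `fc`, `log2fc`, `p`, `significant`. The `ref`/`alt`
#'   labels and thresholds are carried in attributes.
#' @export
diff_test <- function(expr, ref = NULL, alt = NULL, fc_thresh = 1.5,
                      alpha = 0.05, pseudocount = 0.01) {
  groups <- unique(expr$group)
  ref <- ref %||% groups[1]
  alt <- alt %||% groups[2]
  nrep <- expr |> distinct(.data$sample, .data$group) |> count(.data$group)
  for (g in c(ref, alt)) {
    n <- nrep$n[nrep$group == g]
    if (length(n) == 0L || n < 2L) {
      abort(sprintf("group '%s' needs >= 2 replicates for the t test", g))
    }
  }
  stats_tbl <- expr |>
    filter(.data$group %in% c(ref, alt)) |>
    mutate(side = ifelse(.data$group == ref, "ref", "alt")) |>
    group_by(.data$name, .data$side) |>
    summarise(m = mean(.data$tpm), v = stats::var(.data$tpm), n = dplyr::n(),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side", values_from = c("m", "v", "n"))

  sp2 <- ((stats_tbl$n_ref - 1) * stats_tbl$v_ref +
            (stats_tbl$n_alt - 1) * stats_tbl$v_alt) /
    (stats_tbl$n_ref + stats_tbl$n_alt - 2)
  se <- sqrt(sp2 * (1 / stats_tbl$n_ref + 1 / stats_tbl$n_alt))
  tstat <- (stats_tbl$m_alt - stats_tbl$m_ref) / se
  df <- stats_tbl$n_ref + stats_tbl$n_alt - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- sp2 == 0
  p[degenerate] <- ifelse(stats_tbl$m_ref[degenerate] == stats_tbl$m_alt[degenerate], 1, 0)

  fc <- (stats_tbl$m_alt + pseudocount) / (stats_tbl$m_ref + pseudocount)
  out <- tibble(
    name = stats_tbl$name,
    mean_ref = stats_tbl$m_ref, mean_alt = stats_tbl$m_alt,
    fc = fc, log2fc = log2(fc), p = p,
    significant = abs(log2(fc)) > log2(fc_thresh) & p < alpha
  ) |> arrange(.data$p, .data$name)
  attr(out, "groups") <- c(ref = ref, alt = alt)
  attr(out, "fc_thresh") <- fc_thresh
  attr(out, "alpha") <- alpha
  class(out) <- c("tsrna_diff", class(out))
  out
}
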