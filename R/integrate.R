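#' Read a differential-mRNA table
#'
#' Expects a TSV with columns `gene`/`gene_id`, `log2fc` and `p`. The
#' significance flag is recomputed from the standard gates
#' `|log2fc| > log2(fc_thresh)` and `p < alpha`.
#'
#' @param path TSV path.
#' @param fc_thresh,alpha Significance gates (defaults 1.5 and 0.05).
#' @return Tibble `gene_id`, `log2fc`, `p`, `significant`.
#' @export
read_de_table <- function(path, fc_thresh = 1.5, alpha = 0.05) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  names(tb)[names(tb) == "gene"] <- "gene_id"
  stopifnot(all(c("gene_id", "log2fc", "p") %in% names(tb)))
  flag_de(tb, fc_thresh, alpha)
}

#' @rdname read_de_table
#' @param de_table Tibble with `gene_id`, `log2fc`, `p`.
#' @export
flag_de <- function(de_table, fc_thresh = 1.5, alpha = 0.05) {
  de_table |>
    mutate(significant = abs(.data$log2fc) > log2(fc_thresh) & .data$p < alpha) |>
    as_tibble()
}

#' Validate predicted targets against differentially expressed mRNAs
#'
#' The validated target set of each tsRNA is the intersection of its
#' consensus-predicted genes with the significantly changed mRNAs.
#'
#' @param consensus Tibble of predicted (`tsrna_name`, `gene_id`) pairs,
#'   e.g. from [consensus_genes()].
#' @param de_table DE-mRNA tibble with `gene_id` and `significant`
#'   columns (see [read_de_table()]).
#' @return Tibble of validated (`tsrna_name`, `gene_id`) pairs; the
#'   pooled validated gene set is in `attr(, "validated_genes")`. Warns
#'   when the intersection is empty.
#' @export
intersect_targets <- function(consensus, de_table) {
  if (nrow(de_table) == 0L) abort("empty DE-mRNA table")
  sig <- unique(de_table$gene_id[de_table$significant])
  out <- consensus |>
    filter(.data$gene_id %in% sig) |>
    distinct(.data$tsrna_name, .data$gene_id) |>
    as_tibble()
  if (nrow(out) == 0L) warn("no predicted target overlaps the significant DE mRNAs")
  attr(out, "validated_genes") <- sort(unique(out$gene_id))
  out
}

#' Accumulative hypergeometric pathway enrichment
#'
#' For each annotation term, tests whether the gene list contains more
#' term members than expected by chance under sampling without
#' replacement: with universe size N, term size K and list size n, the
#' P value of observing k members is the upper hypergeometric tail
#' `P(X >= k)`, and the enrichment factor is `k / (n * K / N)`. A term
#' passes when `p < p_thresh`, `k >= min_count` and the enrichment factor
#' exceeds `ef_thresh`. Raw P values are reported (with a
#' Benjamini-Hochberg column for information only) because the published
#' convention this mirrors applies raw-P gates.
#'
#' @param gene_list Character vector of genes to test.
#' @param annotation Tibble with `gene_id`, `term_id`, `term_name`.
#' @param universe Character vector of background genes; defaults to all
#'   genes in the annotation. Genes of `gene_list` outside the universe
#'   are dropped with a warning.
#' @param p_thresh,min_count,ef_thresh Pass gates (defaults 0.01, 3, 1.5).
#' @return A `tsrna_enrich` tibble sorted by p: `term_id`, `term_name`,
#'   `observed`, `list_size`, `term_size`, `universe_size`, `expected`,
#'   `enrichment_factor`, `p`, `p_adjust`, `pass`.
#' @export
enrich <- function(gene_list, annotation, universe = NULL,
                   p_thresh = 0.01, min_count = 3L, ef_thresh = 1.5) {
  universe <- unique(universe %||% annotation$gene_id)
  gene_list <- unique(gene_list)
  if (length(universe) < length(gene_list)) abort("universe smaller than the gene list")
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warn(sprintf("%d gene(s) of the list are outside the universe and were dropped", length(outside)))
    gene_list <- setdiff(gene_list, outside)
  }
  N <- length(universe)
  n <- length(gene_list)
  if (N < n) abort("universe smaller than the gene list")
  ann <- annotation |>
    filter(.data$gene_id %in% universe) |>
    distinct(.data$gene_id, .data$term_id, .data$term_name)
  out <- ann |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(
      observed = sum(.data$gene_id %in% gene_list),
      term_size = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      list_size = n, universe_size = N,
      expected = n * .data$term_size / N,
      enrichment_factor = .data$observed / .data$expected,
      p = stats::phyper(.data$observed - 1L, .data$term_size,
                        N - .data$term_size, n, lower.tail = FALSE),
      p_adjust = stats::p.adjust(.data$p, method = "BH"),
      pass = .data$p < p_thresh & .data$observed >= min_count &
        .data$enrichment_factor > ef_thresh
    ) |>
    arrange(.data$p, .data$term_id) |>
    select("term_id", "term_name", "observed", "list_size", "term_size",
           "universe_size", "expected", "enrichment_factor", "p",
           "p_adjust", "pass")
  class(out) <- c("tsrna_enrich", class(out))
  out
}

#' Build the tsRNA-mRNA-pathway network
#'
#' Assembles a bipartite-by-kind edge list: `targets` edges from tsRNAs to
#' their validated target mRNAs and `member_of` edges from mRNAs to the
#' pathway terms they belong to. Edges are deduplicated and self-edges
#' are impossible by construction (node kinds differ within an edge).
#'
#' @param validated Tibble of (`tsrna_name`, `gene_id`) pairs from
#'   [intersect_targets()].
#' @param term_members Tibble with `gene_id` and `term_id` (or
#'   `term_name`) giving the member genes of the enriched terms.
#' @return A `tsrna_network` tibble of edges (`source`, `target`, `kind`)
#'   with the per-node degree table in `attr(, "degrees")` (also via
#'   [network_degrees()]).
#' @export
build_network <- function(validated, term_members = NULL) {
  e1 <- if (nrow(validated)) {
    tibble(source = validated$tsrna_name, target = validated$gene_id,
           kind = "targets")
  } else {
    tibble(source = character(), target = character(), kind = character())
  }
  e2 <- NULL
  if (!is.null(term_members) && nrow(term_members)) {
    term_col <- if ("term_id" %in% names(term_members)) "term_id" else "term_name"
    keep <- term_members$gene_id %in% validated$gene_id
    e2 <- tibble(source = term_members$gene_id[keep],
                 target = term_members[[term_col]][keep], kind = "member_of")
  }
  edges <- bind_rows(e1, e2) |> distinct()
  node_tbl <- bind_rows(
    tibble(node = edges$source[edges$kind == "targets"], node_type = "tsrna"),
    tibble(node = edges$target[edges$kind == "targets"], node_type = "mrna"),
    tibble(node = edges$source[edges$kind == "member_of"], node_type = "mrna"),
    tibble(node = edges$target[edges$kind == "member_of"], node_type = "pathway")
  ) |> distinct()
  deg <- bind_rows(
    edges |> count(node = .data$source, name = "degree"),
    edges |> count(node = .data$target, name = "degree")
  ) |>
    group_by(.data$node) |>
    summarise(degree = sum(.data$degree)) |>
    left_join(node_tbl, by = "node") |>
    arrange(desc(.data$degree), .data$node)
  attr(edges, "degrees") <- deg
  class(edges) <- c("tsrna_network", class(edges))
  edges
}

#' @rdname build_network
#' @param network A `tsrna_network` from [build_network()].
#' @export
network_degrees <- function(network) attr(network, "degrees")
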