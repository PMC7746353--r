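#' Pipeline configuration
#'
#' Bundles the stage configurations and the output directory for
#' [run_stage()] / [run_pipeline()]. All stage outputs are plain text
#' (TSV/FASTQ/FASTA) under `outdir`; a JSON manifest records the config
#' hash and the MD5 of every artifact each stage writes.
#'
#' @param outdir Output directory (created if needed).
#' @param sim A [sim_config()].
#' @param prep A [read_prep_config()]; defaults to trimming the
#'   simulator's 3' adapter.
#' @param target A [target_config()].
#' @param model A [duplex_model()].
#' @param fc_thresh,alpha Differential-expression gates (defaults 1.5,
#'   0.05).
#' @param enrich_p,enrich_min_count,enrich_ef Enrichment gates (defaults
#'   0.01, 3, 1.5).
#' @param max_mismatch Alignment mismatches (default 0).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, sim = sim_config(), prep = NULL,
                            target = target_config(), model = duplex_model(),
                            fc_thresh = 1.5, alpha = 0.05,
                            enrich_p = 0.01, enrich_min_count = 3L,
                            enrich_ef = 1.5, max_mismatch = 0L) {
  if (is.null(prep)) prep <- read_prep_config(adapter3 = sim$adapter3)
  stopifnot(fc_thresh > 1, alpha > 0, alpha < 1, enrich_p > 0)
  structure(
    list(outdir = outdir, sim = sim, prep = prep, target = target,
         model = model, fc_thresh = fc_thresh, alpha = alpha,
         enrich_p = enrich_p, enrich_min_count = enrich_min_count,
         enrich_ef = enrich_ef, max_mismatch = max_mismatch),
    class = "pipeline_config"
  )
}

PIPELINE_STAGES <- c("simulate", "prep", "classify", "quantify", "diff",
                     "targets", "integrate", "enrich", "network")

# upstream artifact -> the stage that produces it
stage_requires <- list(
  simulate = character(),
  prep = c(reference.txt = "simulate", samples.tsv = "simulate"),
  classify = c(reference.txt = "simulate", samples.tsv = "simulate",
               prep_summary.tsv = "prep"),
  quantify = c(counts.tsv = "classify", fragments.tsv = "classify"),
  diff = c(tpm.tsv = "quantify"),
  targets = c(fragments.tsv = "classify", diff_results.tsv = "diff",
              utrs.fasta = "simulate"),
  integrate = c(consensus_genes.tsv = "targets", de_mrna.tsv = "simulate"),
  enrich = c(validated_targets.tsv = "integrate", annotation.tsv = "simulate"),
  network = c(validated_targets.tsv = "integrate", enrichment.tsv = "enrich",
              annotation.tsv = "simulate")
)

write_tsv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(x, tmp)
  file.rename(tmp, path)
  invisible(path)
}

check_upstream <- function(cfg, stage) {
  req <- stage_requires[[stage]]
  for (f in names(req)) {
    if (!file.exists(file.path(cfg$outdir, f))) {
      abort(sprintf(
        "stage '%s' needs %s, which is produced by stage '%s'; run that first",
        stage, f, req[[f]]
      ))
    }
  }
}

update_manifest <- function(cfg, stage, outputs) {
  mpath <- file.path(cfg$outdir, "manifest.json")
  man <- if (file.exists(mpath)) jsonlite::read_json(mpath) else list()
  cfg_tmp <- tempfile()
  writeLines(deparse(cfg[setdiff(names(cfg), "outdir")]), cfg_tmp)
  man$config_md5 <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)
  man$package_version <- as.character(utils::packageVersion("tsrnakit"))
  paths <- file.path(cfg$outdir, outputs)
  man[[stage]] <- as.list(stats::setNames(unname(tools::md5sum(paths)), outputs))
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, mpath)
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (write synthetic inputs), `prep` (trim + length
#' filter), `classify` (map, classify, name, count), `quantify` (TPM,
#' composition, Venn), `diff` (differential tsRNAs), `targets` (consensus
#' prediction for the significant tsRNAs), `integrate` (intersection with
#' DE mRNAs), `enrich` (pathway enrichment of validated targets),
#' `network` (edge-list export), or `all`. Outputs are written
#' atomically; each stage refuses to run if an upstream artifact is
#' missing and names the stage that produces it.
#'
#' @param stage One of the stage names or `"all"`.
#' @param cfg A [pipeline_config()].
#' @return Character vector of the files written, invisibly.
#' @export
run_stage <- function(stage, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (identical(stage, "all")) {
    out <- unlist(lapply(PIPELINE_STAGES, run_stage, cfg = cfg))
    return(invisible(out))
  }
  if (!stage %in% PIPELINE_STAGES) {
    abort(sprintf("unknown stage '%s' (stages: %s)", stage,
                  paste(c(PIPELINE_STAGES, "all"), collapse = ", ")))
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  check_upstream(cfg, stage)
  od <- function(...) file.path(cfg$outdir, ...)
  outputs <- switch(stage,
    simulate = {
      ref <- simulate_references(cfg$sim)
      write_trna_reference(ref, od("reference.txt"))
      sim <- simulate_reads(cfg$sim, ref)
      write_tsv_atomic(sim$samples, od("samples.tsv"))
      write_tsv_atomic(sim$truth, od("truth_fragments.tsv"))
      fq <- character()
      for (s in names(sim$reads)) {
        f <- sprintf("reads_%s.fastq", s)
        write_fastq(sim$reads[[s]], od(f))
        fq <- c(fq, f)
      }
      tsrnas <- sim$truth |>
        filter(.data$planted_de) |>
        distinct(name = .data$fragment, sequence = .data$sequence)
      tg <- simulate_targets(cfg$sim, tsrnas, cfg$target, cfg$model)
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(tg$utrs), od("utrs.fasta"))
      write_tsv_atomic(tg$de_table, od("de_mrna.tsv"))
      write_tsv_atomic(tg$annotation, od("annotation.tsv"))
      write_tsv_atomic(tg$truth$sites, od("truth_sites.tsv"))
      c("reference.txt", "samples.tsv", "truth_fragments.tsv", fq,
        "utrs.fasta", "de_mrna.tsv", "annotation.tsv", "truth_sites.tsv")
    },
    prep = {
      samples <- readr::read_tsv(od("samples.tsv"), show_col_types = FALSE)
      outs <- character()
      summaries <- list()
      for (s in samples$sample) {
        reads <- read_fastq(od(sprintf("reads_%s.fastq", s)))
        trimmed <- trim_and_filter(reads, cfg$prep)
        f <- sprintf("trimmed_%s.fastq", s)
        write_fastq(trimmed, od(f))
        outs <- c(outs, f)
        summaries[[s]] <- prep_summary(trimmed) |> mutate(sample = s)
      }
      write_tsv_atomic(bind_rows(summaries), od("prep_summary.tsv"))
      c(outs, "prep_summary.tsv")
    },
    classify = {
      ref <- parse_trna_reference(od("reference.txt"))
      samples <- readr::read_tsv(od("samples.tsv"), show_col_types = FALSE)
      per_sample <- purrr::map(samples$sample, function(s) {
        read_fastq(od(sprintf("trimmed_%s.fastq", s)))$seq
      })
      names(per_sample) <- samples$sample
      all_seqs <- unique(unlist(per_sample))
      aln <- map_reads(all_seqs, ref, cfg$max_mismatch) |>
        classify_fragments(ref)
      abundance <- table(factor(unlist(per_sample), levels = all_seqs))
      frags <- collapse_and_name(aln, cfg$sim$organism,
                                 stats::setNames(as.numeric(abundance), all_seqs))
      counts <- purrr::imap(per_sample, function(seqs, s) {
        tibble(
          name = frags$name,
          sample = s,
          group = samples$group[samples$sample == s],
          count = as.integer(table(factor(seqs, levels = frags$sequence)))
        )
      }) |> bind_rows()
      write_tsv_atomic(frags, od("fragments.tsv"))
      write_tsv_atomic(counts, od("counts.tsv"))
      c("fragments.tsv", "counts.tsv")
    },
    quantify = {
      counts <- readr::read_tsv(od("counts.tsv"), show_col_types = FALSE)
      frags <- readr::read_tsv(od("fragments.tsv"), show_col_types = FALSE)
      expr <- compute_tpm(counts)
      write_tsv_atomic(expr, od("tpm.tsv"))
      write_tsv_atomic(composition(expr, frags), od("composition.tsv"))
      write_tsv_atomic(venn_counts(expr), od("venn.tsv"))
      c("tpm.tsv", "composition.tsv", "venn.tsv")
    },
    diff = {
      expr <- readr::read_tsv(od("tpm.tsv"), show_col_types = FALSE)
      res <- diff_test(expr, ref = cfg$sim$groups[1], alt = cfg$sim$groups[2],
                       fc_thresh = cfg$fc_thresh, alpha = cfg$alpha)
      write_tsv_atomic(res, od("diff_results.tsv"))
      "diff_results.tsv"
    },
    targets = {
      frags <- readr::read_tsv(od("fragments.tsv"), show_col_types = FALSE)
      res <- readr::read_tsv(od("diff_results.tsv"), show_col_types = FALSE)
      cand <- frags |> filter(.data$name %in% res$name[res$significant])
      if (nrow(cand) == 0L) {
        warn("no significant tsRNA; predicting targets for all fragments")
        cand <- frags
      }
      utrs <- as.character(Biostrings::readDNAStringSet(od("utrs.fasta")))
      names(utrs) <- sub("\\s.*$", "", names(utrs))
      calls <- consensus_targets(cand |> select("name", "sequence"),
                                 utrs, cfg$target, cfg$model)
      write_tsv_atomic(calls, od("target_calls.tsv"))
      write_tsv_atomic(consensus_genes(calls), od("consensus_genes.tsv"))
      c("target_calls.tsv", "consensus_genes.tsv")
    },
    integrate = {
      cons <- readr::read_tsv(od("consensus_genes.tsv"), show_col_types = FALSE)
      de <- read_de_table(od("de_mrna.tsv"), cfg$fc_thresh, cfg$alpha)
      val <- intersect_targets(cons, de)
      write_tsv_atomic(val, od("validated_targets.tsv"))
      "validated_targets.tsv"
    },
    enrich = {
      val <- readr::read_tsv(od("validated_targets.tsv"), show_col_types = FALSE)
      ann <- readr::read_tsv(od("annotation.tsv"), show_col_types = FALSE)
      er <- enrich(unique(val$gene_id), ann, p_thresh = cfg$enrich_p,
                   min_count = cfg$enrich_min_count, ef_thresh = cfg$enrich_ef)
      write_tsv_atomic(er, od("enrichment.tsv"))
      "enrichment.tsv"
    },
    network = {
      val <- readr::read_tsv(od("validated_targets.tsv"), show_col_types = FALSE)
      er <- readr::read_tsv(od("enrichment.tsv"), show_col_types = FALSE)
      ann <- readr::read_tsv(od("annotation.tsv"), show_col_types = FALSE)
      members <- ann |> filter(.data$term_id %in% er$term_id[er$pass])
      net <- build_network(val, members)
      write_tsv_atomic(as_tibble(net), od("network_edges.tsv"))
      write_tsv_atomic(network_degrees(net), od("network_degrees.tsv"))
      c("network_edges.tsv", "network_degrees.tsv")
    }
  )
  update_manifest(cfg, stage, outputs)
  invisible(file.path(cfg$outdir, outputs))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(cfg) run_stage("all", cfg)
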