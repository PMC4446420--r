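# End-to-end orchestration: simulate a dataset to disk, analyze a SAM
# against a gene model, and compare editing between two analyses (or two
# stages of one). Outputs are plain TSVs plus a manifest with the resolved
# configuration and file checksums, so reruns are verifiably identical.

#' Simulate a dataset to disk
#'
#' Builds the synthetic genome and reads for one condition and writes
#' `genome.fa`, `genes.tsv`, `reads.fastq`, `truth.sam`, `truth.tsv`,
#' `config.yaml` and `manifest.yaml` (seed plus md5 of every output).
#' Rerunning with the same config and seed is byte-identical.
#'
#' @param config [sim_config()].
#' @param out_dir output directory.
#' @param condition `"control"` or `"knockdown"`.
#' @param seed RNG seed (default `config$seed`).
#' @param force overwrite a non-empty `out_dir`.
#' @return Invisibly, `list(paths = <named output paths>, truth = <truth
#'   tibble>)`.
#' @export
run_simulate <- function(config, out_dir, condition = "control",
                         seed = config$seed, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("output directory ", out_dir,
         " exists and is non-empty (use force = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- build_genome(config, seed = seed)
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                genes = file.path(out_dir, "genes.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  write_trna_genes(sim$genes, paths$genes)
  truth <- simulate_reads(sim$genome, sim$genes, config,
                          condition = condition, seed = seed,
                          out_dir = out_dir)
  paths <- c(paths, attr(truth, "paths"))
  cfg <- unclass(config)
  cfg$seed <- seed
  cfg$condition <- condition
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  manifest <- list(seed = as.integer(seed), condition = condition,
                   md5 = as.list(tools::md5sum(unlist(paths))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(paths = paths, truth = truth))
}

#' Analyze a SAM file against a tRNA gene model
#'
#' Chains the full analysis: read alignments, resolve each read to a unique
#' tRNA type (discarding cross-type multi-mappers), classify precursor vs
#' processed, build per-copy pileups in a window around the anticodon,
#' remove copies with anticodon depth below `min_depth`, aggregate to type
#' level, and emit composition, editing and stage-proportion tables.
#' Read accounting (total / assigned / AMBIGUOUS / UNASSIGNED) is reported
#' via `message()` and returned.
#'
#' @param gene_table gene table TSV path (or [trna_genes()] tibble).
#' @param genome FASTA path or `DNAStringSet`.
#' @param sam SAM file path.
#' @param out_dir optional directory for `assignment.tsv`,
#'   `stage_proportions.tsv`, `composition.tsv`, `editing.tsv`,
#'   `accounting.tsv`.
#' @param window half-window around the anticodon in nt (>= 3 so residues
#'   34-37 are covered).
#' @param leader,trailer flank window lengths in nt.
#' @param min_depth anticodon coverage threshold per gene copy.
#' @param condition condition label attached to all outputs.
#' @param include_intronic include intron-carrying gene copies.
#' @return List with `assigned`, `accounting`, `pileups` (type-level,
#'   coverage-filtered), `composition` (all window positions),
#'   `editing` (per type and stage), `stage_proportions`,
#'   `removed_copies`.
#' @export
run_analyze <- function(gene_table, genome, sam, out_dir = NULL,
                        window = 50L, leader = 50L, trailer = 50L,
                        min_depth = 10L, condition = NA_character_,
                        include_intronic = FALSE) {
  stopifnot(window >= 3L)
  genome <- load_genome(genome)
  genes <- if (inherits(gene_table, "trna_genes")) {
    gene_table
  } else {
    read_trna_genes(gene_table, genome)
  }
  aln <- read_alignments(sam, genes)
  if (!nrow(aln)) {
    warning("no mapped alignments in ", sam)
  }
  ar <- assign_reads(aln, genes, leader, trailer,
                     include_intronic = include_intronic)
  msg <- paste(sprintf("%s=%d", ar$accounting$category,
                       ar$accounting$n_reads), collapse = ", ")
  message("read accounting: ", msg)
  copy_pileups <- build_pileups(ar$assigned, genes, window = window,
                                condition = condition)
  kept <- filter_anticodon_coverage(copy_pileups, min_depth = min_depth)
  removed <- attr(kept, "removed_copies")
  if (length(removed)) {
    message("coverage filter removed ", length(removed), " gene copies: ",
            paste(removed, collapse = ", "))
  }
  type_pileups <- aggregate_pileups(kept)
  composition <- lapply(seq(-window, window), function(p) {
    composition_at(type_pileups, p)
  })
  composition <- dplyr::bind_rows(composition) %>%
    dplyr::filter(.data$depth > 0)
  editing <- editing_fraction(type_pileups)
  props <- stage_proportions(ar$assigned)
  out <- list(assigned = ar$assigned, accounting = ar$accounting,
              pileups = type_pileups, composition = composition,
              editing = editing, stage_proportions = props,
              removed_copies = removed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) {
      utils::write.table(d, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wr(dplyr::select(ar$assigned, -"seq", -"cigar"), "assignment.tsv")
    wr(props, "stage_proportions.tsv")
    wr(composition, "composition.tsv")
    wr(editing, "editing.tsv")
    wr(ar$accounting, "accounting.tsv")
  }
  invisible(out)
}

#' Compare editing between two analyses or between stages
#'
#' In `condition` mode, tests control vs knockdown per tRNA type on pooled
#' A/G counts at residue 34 (both stages combined); in `stage` mode, tests
#' precursor vs processed within a single analysis.
#'
#' @param analysis_a result of [run_analyze()] (baseline group: control, or
#'   the run whose precursor/processed contrast is wanted in `stage` mode).
#' @param analysis_b second [run_analyze()] result (`condition` mode only).
#' @param mode `"stage"` or `"condition"`.
#' @param out_file optional TSV path for the comparison table.
#' @return [compare_editing()] tibble.
#' @export
run_compare <- function(analysis_a, analysis_b = NULL,
                        mode = c("stage", "condition"), out_file = NULL) {
  mode <- match.arg(mode)
  if (mode == "stage") {
    ed <- analysis_a$editing
    a <- dplyr::filter(ed, .data$stage == "precursor")
    b <- dplyr::filter(ed, .data$stage == "processed")
    labels <- c("precursor", "processed")
  } else {
    if (is.null(analysis_b)) {
      stop("condition mode needs two analyses")
    }
    pool <- function(an) {
      aggregate_pileups(an$pileups, by_stage = FALSE) %>%
        editing_fraction()
    }
    a <- pool(analysis_a)
    b <- pool(analysis_b)
    shared <- intersect(a$type_key, b$type_key)
    if (!length(shared)) {
      stop("the two analyses share no tRNA types")
    }
    labels <- c("control", "knockdown")
  }
  cmp <- compare_editing(a, b, labels = labels)
  if (!is.null(out_file)) {
    utils::write.table(cmp, out_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cmp
}
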