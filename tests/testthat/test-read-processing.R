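# Type resolution, stage classification, single-counting and the anticodon
# coverage filter, on hand-built SAM fixtures and on simulated data.

# 30 nt of a gene's sense sequence starting at mature-local offset
local_seq <- function(ref, gene_id, from, len) {
  g <- ref$genes[ref$genes$gene_id == gene_id, ]
  s <- Biostrings::subseq(ref$genome[[g$chrom]], g$mature_start + 1L,
                          g$mature_end)
  if (g$strand == "-") s <- Biostrings::reverseComplement(s)
  substr(as.character(s), from + 1L, from + len)
}

test_that("reads are resolved to unique types; cross-type reads removed", {
  ref <- toy_reference()
  sam <- withr::local_tempfile(fileext = ".sam")
  v1 <- ref$genes[1, ]  # Val plus-strand copy
  v2 <- ref$genes[2, ]  # Val minus-strand copy
  a1 <- ref$genes[3, ]  # Ala copy
  seq30 <- local_seq(ref, "ValAAC-c01", 20L, 30L)
  rec <- tibble::tibble(
    read_id = c("within_type", "within_type", "cross_type", "cross_type",
                "nowhere"),
    flag = c(0L, 272L, 0L, 256L, 0L),
    chrom = c(v1$chrom, v2$chrom, v1$chrom, a1$chrom, v1$chrom),
    pos0 = c(v1$mature_start + 20L, v2$mature_end - 50L,
             v1$mature_start + 20L, a1$mature_start + 20L, 700L),
    cigar = "30M",
    seq = c(seq30, as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(seq30))), seq30, seq30, seq30))
  write_sam(rec, Biostrings::width(ref$genome) |>
              stats::setNames(names(ref$genome)), sam)
  aln <- read_alignments(sam, ref$genes)
  res <- resolve_types(aln, ref$genes)
  expect_equal(res$status[res$read_id == "within_type"], "assigned")
  expect_equal(res$type_key[res$read_id == "within_type"], "Val-AAC")
  expect_equal(res$status[res$read_id == "cross_type"], "AMBIGUOUS")
  expect_equal(res$status[res$read_id == "nowhere"], "UNASSIGNED")
  # partition: every read lands in exactly one category
  expect_equal(nrow(res), 3L)
  ar <- assign_reads(aln, ref$genes)
  expect_equal(sum(ar$accounting$n_reads[ar$accounting$category != "total"]),
               ar$accounting$n_reads[ar$accounting$category == "total"])
  # the ambiguous read contributes nowhere
  expect_false("cross_type" %in% ar$assigned$read_id)
})

test_that("within-type multi-mappers are counted exactly once", {
  ref <- toy_reference()
  sam <- withr::local_tempfile(fileext = ".sam")
  v1 <- ref$genes[1, ]
  v2 <- ref$genes[2, ]
  seq30 <- local_seq(ref, "ValAAC-c01", 20L, 30L)
  rc30 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq30)))
  rec <- tibble::tibble(
    read_id = "multi",
    flag = c(0L, 272L, 256L),
    chrom = v1$chrom,
    pos0 = c(v1$mature_start + 20L, v2$mature_end - 50L,
             v1$mature_start + 20L),
    cigar = "30M",
    seq = c(seq30, rc30, seq30))
  write_sam(rec, Biostrings::width(ref$genome) |>
              stats::setNames(names(ref$genome)), sam)
  ar <- assign_reads(read_alignments(sam, ref$genes), ref$genes)
  expect_equal(nrow(ar$assigned), 1L)
  counts <- count_reads(ar$assigned)
  expect_equal(counts$n_reads, 1L)
  # the primary record is the counted one
  expect_equal(ar$assigned$gene_id, "ValAAC-c01")
})

test_that("stage classification follows the mature-span containment rule", {
  gene <- trna_genes(tibble::tibble(
    gene_id = "g", type_key = "Val-AAC", chrom = "c", strand = "+",
    mature_start = 100L, mature_end = 176L, anticodon_offset = 33L,
    has_intron = FALSE))[1, ]
  expect_equal(classify_stage(95L, 130L, gene), "precursor")
  expect_equal(classify_stage(100L, 176L, gene), "processed")
  expect_equal(classify_stage(120L, 150L, gene), "processed")  # fragment
  expect_equal(classify_stage(150L, 200L, gene), "precursor")  # trailer
  expect_equal(classify_stage(60L, 95L, gene), "precursor")    # flank only
  expect_error(classify_stage(400L, 430L, gene), "overlap")
  # minus-strand gene: leader is genomically downstream
  mgene <- gene
  mgene$strand <- "-"
  expect_equal(classify_stage(170L, 200L, mgene), "precursor")
  expect_equal(classify_stage(100L, 176L, mgene), "processed")
})

test_that("stage labels agree with simulation truth read by read", {
  cfg <- sim_config(n_types = 3L, depth_per_copy = 80, seed = 31)
  ds <- sim_and_analyze(cfg)
  j <- dplyr::inner_join(ds$analysis$assigned, ds$truth, by = "read_id",
                         suffix = c(".obs", ".truth"))
  expect_equal(nrow(j), nrow(ds$truth))
  expect_equal(j$stage.obs, j$stage.truth)
  expect_equal(j$type_key.obs, j$type_key.truth)
  expect_equal(j$gene_id.obs, j$gene_id.truth)
})

test_that("soft-clipped bases are excluded from spans and pileups", {
  ref <- toy_reference()
  sam <- withr::local_tempfile(fileext = ".sam")
  v1 <- ref$genes[1, ]
  core <- local_seq(ref, "ValAAC-c01", 30L, 10L)
  rec <- tibble::tibble(read_id = "clipped", flag = 0L, chrom = v1$chrom,
                        pos0 = v1$mature_start + 30L, cigar = "4S10M3S",
                        seq = paste0("AAAA", core, "CCC"))
  write_sam(rec, Biostrings::width(ref$genome) |>
              stats::setNames(names(ref$genome)), sam)
  aln <- read_alignments(sam, ref$genes)
  expect_equal(aln$gend - aln$gstart, 10L)
  ar <- assign_reads(aln, ref$genes)
  expect_equal(ar$assigned$stage, "processed")
  pu <- build_pileups(ar$assigned, ref$genes, window = 50L)
  expect_equal(sum(pu$A + pu$C + pu$G + pu$T), 10L)
})

test_that("ambiguous-pair reads leak into no count anywhere", {
  cfg <- sim_config(n_types = 3L, ambiguous_pair = TRUE,
                    depth_per_copy = 60, seed = 41)
  ds <- sim_and_analyze(cfg, min_depth = 1L)
  two_rec <- ds$truth$read_id[ds$truth$n_records == 2L]
  expect_gt(length(two_rec), 0L)
  expect_false(any(two_rec %in% ds$analysis$assigned$read_id))
  one_rec <- ds$truth$read_id[ds$truth$n_records == 1L]
  expect_true(all(one_rec %in% ds$analysis$assigned$read_id))
  expect_equal(ds$analysis$accounting$n_reads[
    ds$analysis$accounting$category == "AMBIGUOUS"], length(two_rec))
})

test_that("coverage filter retains exactly the copies at or above the
           depth threshold", {
  cfg <- sim_config(n_types = 4L, depth_per_copy = 14, seed = 51)
  ds <- sim_and_analyze(cfg, min_depth = 1L)
  truth_depth <- ds$truth %>%
    dplyr::filter(.data$covers34) %>%
    dplyr::count(.data$gene_id, name = "depth")
  copy_pileups <- build_pileups(ds$analysis$assigned,
                                build_genome(cfg)$genes, window = 3L)
  kept <- filter_anticodon_coverage(copy_pileups, min_depth = 10L)
  expected_kept <- truth_depth$gene_id[truth_depth$depth >= 10L]
  expect_setequal(unique(kept$gene_id), expected_kept)
  # boundary: depth exactly min_depth is retained, one below is not
  kept9 <- filter_anticodon_coverage(copy_pileups, min_depth = 9L)
  drop9 <- setdiff(unique(copy_pileups$gene_id), unique(kept9$gene_id))
  expect_true(all(truth_depth$depth[match(drop9, truth_depth$gene_id)] < 9L |
                    !drop9 %in% truth_depth$gene_id))
  expect_error(filter_anticodon_coverage(copy_pileups, min_depth = 0L))
  # anticodon_depth agrees with the truth depth per copy
  ad <- anticodon_depth(ds$analysis$assigned, build_genome(cfg)$genes)
  j <- dplyr::left_join(ad, truth_depth, by = "gene_id")
  expect_equal(j$depth34, dplyr::coalesce(j$depth, 0L))
})

test_that("stage proportions are per-type fractions with missing, not zero,
           for empty types", {
  assigned <- tibble::tibble(
    read_id = sprintf("r%03d", 1:100),
    type_key = "Val-AAC", gene_id = "g",
    gstart = 0L, gend = 10L, cigar = "10M", seq = strrep("A", 10),
    is_reverse = FALSE,
    stage = rep(c("precursor", "processed"), c(70, 30)))
  sp <- stage_proportions(assigned)
  val <- sp[sp$type_key == "Val-AAC", ]
  expect_equal(val$frac_precursor, 0.70)
  expect_equal(val$frac_processed, 0.30)
  overall <- sp[sp$type_key == "(overall)", ]
  expect_equal(overall$n_precursor + overall$n_processed, 100L)
  # no rows fabricated for unobserved types
  empty <- stage_proportions(assigned[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("stage proportions equal truth fractions on noise-free data", {
  cfg <- sim_config(n_types = 2L, depth_per_copy = 80, error_rate = 0,
                    seed = 61)
  ds <- sim_and_analyze(cfg)
  sp <- stage_proportions(ds$analysis$assigned)
  tp <- ds$truth %>%
    dplyr::count(.data$type_key, .data$stage) %>%
    tidyr::pivot_wider(names_from = "stage", values_from = "n",
                       values_fill = 0L)
  for (tk in tp$type_key) {
    expect_equal(sp$n_precursor[sp$type_key == tk],
                 tp$precursor[tp$type_key == tk])
    expect_equal(sp$n_processed[sp$type_key == tk],
                 tp$processed[tp$type_key == tk])
  }
})
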