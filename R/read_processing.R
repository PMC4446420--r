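# SAM ingestion and per-read resolution: unique-type assignment across
# multi-copy gene families, precursor/processed stage classification, and
# the anticodon coverage filter. Spans are 0-based half-open with
# soft-clipped bases excluded.

#' Read SAM alignments into a tidy table
#'
#' Reads a headered SAM file (via Rsamtools), drops unmapped records, and
#' returns one row per alignment with the reference span computed from the
#' CIGAR (soft clips excluded from both span and bases).
#'
#' @param sam_path SAM file path.
#' @param genes optional [trna_genes()] table; if given, alignments to
#'   chromosomes absent from the gene table's genome raise an error only
#'   when the chromosome is also absent from the SAM header mapping, while
#'   alignments outside any gene are simply left unassigned later.
#' @return Tibble `read_id`, `flag`, `chrom`, `gstart`, `gend` (0-based
#'   half-open reference span), `cigar`, `seq` (as aligned, reference
#'   forward strand), `is_secondary`, `is_reverse`.
#' @export
read_alignments <- function(sam_path, genes = NULL) {
  if (!file.exists(sam_path)) {
    stop("cannot read SAM file: ", sam_path)
  }
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  mapped <- !bitwAnd(x$flag, 4L)
  aln <- tibble::tibble(
    read_id = x$qname[mapped],
    flag = x$flag[mapped],
    chrom = as.character(x$rname[mapped]),
    gstart = x$pos[mapped] - 1L,
    cigar = x$cigar[mapped],
    seq = as.character(x$seq[mapped]))
  aln$gend <- aln$gstart + cigar_ref_width(aln$cigar)
  aln$is_secondary <- bitwAnd(aln$flag, 256L) > 0L
  aln$is_reverse <- bitwAnd(aln$flag, 16L) > 0L
  if (!is.null(genes)) {
    unknown <- setdiff(unique(aln$chrom), unique(genes$chrom))
    if (length(unknown)) {
      stop("alignment(s) to chromosome(s) unknown to the gene model: ",
           paste(unknown, collapse = ", "))
    }
  }
  dplyr::select(aln, "read_id", "flag", "chrom", "gstart", "gend", "cigar",
                "seq", "is_secondary", "is_reverse")
}

# Reference-consumed width of CIGAR strings (M/D/N/=/X).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_ops <- function(cg) {
  len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
  op <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
  if (length(len) != length(op)) {
    stop("malformed CIGAR: ", cg)
  }
  list(len = len, op = op)
}

# Map aligned read bases to 0-based reference positions for one record.
# Returns list(ref_pos, base); insertions/soft clips consume query only,
# deletions/skips consume reference only.
aligned_bases <- function(cigar, seq, gstart) {
  if (grepl("^[0-9]+M$", cigar)) {
    n <- nchar(seq)
    return(list(ref_pos = gstart + 0:(n - 1L),
                base = strsplit(seq, "")[[1]]))
  }
  ops <- cigar_ops(cigar)
  qbases <- strsplit(seq, "")[[1]]
  rp <- integer(0)
  bb <- character(0)
  q <- 1L
  r <- gstart
  for (k in seq_along(ops$op)) {
    n <- ops$len[k]
    switch(ops$op[k],
      "M" = , "=" = , "X" = {
        rp <- c(rp, r + 0:(n - 1L))
        bb <- c(bb, qbases[q:(q + n - 1L)])
        q <- q + n
        r <- r + n
      },
      "I" = , "S" = {
        q <- q + n
      },
      "D" = , "N" = {
        r <- r + n
      },
      "H" = , "P" = NULL)
  }
  list(ref_pos = rp, base = bb)
}

#' Resolve each read to a unique tRNA type
#'
#' Collects, over all alignments of a read, the set of tRNA types whose
#' mature span extended by leader/trailer windows the alignment spans
#' overlap. Reads touching exactly one type are assigned to it; reads
#' touching two or more types are `AMBIGUOUS` (removed from all counts);
#' reads touching none are `UNASSIGNED`.
#'
#' @param aln alignment tibble from [read_alignments()].
#' @param genes [trna_genes()] table.
#' @param leader,trailer flank window lengths in nt.
#' @return Tibble `read_id`, `status` (`assigned`/`AMBIGUOUS`/`UNASSIGNED`),
#'   `type_key` (`NA` unless assigned).
#' @export
resolve_types <- function(aln, genes, leader = 50L, trailer = 50L) {
  hits <- gene_overlaps(aln, genes, leader, trailer)
  per_read <- hits %>%
    dplyr::distinct(.data$read_id, .data$type_key) %>%
    dplyr::count(.data$read_id, name = "n_types")
  all_reads <- unique(aln$read_id)
  status <- tibble::tibble(read_id = all_reads) %>%
    dplyr::left_join(per_read, by = "read_id") %>%
    dplyr::mutate(n_types = dplyr::coalesce(.data$n_types, 0L),
                  status = dplyr::case_when(
                    .data$n_types == 0L ~ "UNASSIGNED",
                    .data$n_types == 1L ~ "assigned",
                    TRUE ~ "AMBIGUOUS"))
  one_type <- hits %>%
    dplyr::distinct(.data$read_id, .data$type_key) %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::filter(dplyr::n() == 1L) %>%
    dplyr::ungroup()
  status %>%
    dplyr::left_join(one_type, by = "read_id") %>%
    dplyr::mutate(type_key = as.character(ifelse(.data$status == "assigned",
                                                 .data$type_key,
                                                 NA_character_))) %>%
    dplyr::select("read_id", "status", "type_key")
}

# Overlaps between alignment spans and gene intervals extended by flanks.
# Returns one row per (alignment row, gene) overlap with overlap width.
gene_overlaps <- function(aln, genes, leader, trailer) {
  if (!nrow(aln) || !nrow(genes)) {
    return(tibble::tibble(aln_row = integer(), read_id = character(),
                          gene_id = character(), type_key = character(),
                          overlap = integer()))
  }
  fl <- flank_windows(genes, leader, trailer)
  ext_start <- pmin(genes$mature_start, fl$leader_start, fl$trailer_start)
  ext_end <- pmax(genes$mature_end, fl$leader_end, fl$trailer_end)
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = ext_start + 1L, end = ext_end))
  gr_aln <- GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(start = aln$gstart + 1L, end = aln$gend))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_aln, gr_genes))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  width <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_aln)[qh], IRanges::ranges(gr_genes)[sh]))
  tibble::tibble(aln_row = qh,
                 read_id = aln$read_id[qh],
                 gene_id = genes$gene_id[sh],
                 type_key = genes$type_key[sh],
                 overlap = width)
}

#' Classify a read span as precursor or processed
#'
#' A read is `processed` iff its aligned span lies entirely within the
#' mature gene span; any aligned nucleotide outside it (leader/trailer
#' sequence) makes the read `precursor`. A read overlapping only a flank is
#' precursor: it consists of leader/trailer sequence by definition.
#'
#' @param gstart,gend 0-based half-open aligned span (soft clips excluded).
#' @param gene one-row [trna_genes()] table.
#' @param leader,trailer flank window lengths used to sanity-check overlap.
#' @return `"precursor"` or `"processed"`; a span disjoint from the gene's
#'   mature-plus-flank interval is a caller bug and raises an error.
#' @export
classify_stage <- function(gstart, gend, gene, leader = 50L, trailer = 50L) {
  ext_start <- gene$mature_start - ifelse(gene$strand == "+", leader, trailer)
  ext_end <- gene$mature_end + ifelse(gene$strand == "+", trailer, leader)
  if (gend <= ext_start || gstart >= ext_end) {
    stop("span [", gstart, ",", gend, ") does not overlap gene ",
         gene$gene_id)
  }
  if (gstart >= gene$mature_start && gend <= gene$mature_end) {
    "processed"
  } else {
    "precursor"
  }
}

#' Assign reads to unique types, stages and counted gene copies
#'
#' Applies [resolve_types()], then for each assigned read selects a single
#' counted alignment (the primary record among those overlapping the
#' assigned type's genes; within-type multi-mappers therefore contribute
#' exactly once), attaches the gene copy with the largest overlap, and
#' classifies the maturation stage from the counted span.
#'
#' @param aln alignment tibble from [read_alignments()].
#' @param genes [trna_genes()] table.
#' @param leader,trailer flank window lengths in nt.
#' @param include_intronic keep intron-carrying gene copies (default drops
#'   them from assignment: their genomic anticodon coordinates only apply to
#'   unspliced precursors).
#' @return List with `assigned` (tibble `read_id`, `type_key`, `gene_id`,
#'   `gstart`, `gend`, `cigar`, `seq`, `is_reverse`, `stage`) and
#'   `accounting` (tibble of read counts per terminal category:
#'   total/assigned/AMBIGUOUS/UNASSIGNED).
#' @export
assign_reads <- function(aln, genes, leader = 50L, trailer = 50L,
                         include_intronic = FALSE) {
  if (!include_intronic) {
    genes <- genes[!genes$has_intron, ]
  }
  res <- resolve_types(aln, genes, leader, trailer)
  hits <- gene_overlaps(aln, genes, leader, trailer)
  assigned_ids <- res$read_id[res$status == "assigned"]
  counted <- hits %>%
    dplyr::inner_join(dplyr::filter(res, .data$status == "assigned"),
                      by = c("read_id", "type_key")) %>%
    dplyr::mutate(is_secondary = aln$is_secondary[.data$aln_row]) %>%
    dplyr::arrange(.data$read_id, .data$is_secondary,
                   dplyr::desc(.data$overlap), .data$aln_row) %>%
    dplyr::distinct(.data$read_id, .keep_all = TRUE)
  assigned <- counted %>%
    dplyr::transmute(.data$read_id, .data$type_key, .data$gene_id,
                     gstart = aln$gstart[.data$aln_row],
                     gend = aln$gend[.data$aln_row],
                     cigar = aln$cigar[.data$aln_row],
                     seq = aln$seq[.data$aln_row],
                     is_reverse = aln$is_reverse[.data$aln_row])
  if (nrow(assigned)) {
    gidx <- match(assigned$gene_id, genes$gene_id)
    assigned$stage <- vapply(seq_len(nrow(assigned)), function(i) {
      classify_stage(assigned$gstart[i], assigned$gend[i],
                     genes[gidx[i], ], leader, trailer)
    }, character(1))
  } else {
    assigned$stage <- character(0)
  }
  accounting <- tibble::tibble(
    category = c("total", "assigned", "AMBIGUOUS", "UNASSIGNED"),
    n_reads = c(length(unique(aln$read_id)),
                sum(res$status == "assigned"),
                sum(res$status == "AMBIGUOUS"),
                sum(res$status == "UNASSIGNED")))
  list(assigned = assigned, accounting = accounting)
}

#' Per-(type, stage) read counts
#'
#' Each assigned read contributes exactly once (single counted alignment).
#'
#' @param assigned assigned-read tibble from [assign_reads()].
#' @return Tibble `type_key`, `stage`, `n_reads`.
#' @export
count_reads <- function(assigned) {
  assigned %>%
    dplyr::count(.data$type_key, .data$stage, name = "n_reads") %>%
    dplyr::arrange(.data$type_key, .data$stage)
}

#' Precursor/processed read proportions
#'
#' @param assigned assigned-read tibble from [assign_reads()].
#' @return Tibble `type_key`, `n_precursor`, `n_processed`,
#'   `frac_precursor`, `frac_processed`, with a read-weighted `(overall)`
#'   row; types with zero reads are absent (missing), never reported as 0.
#' @export
stage_proportions <- function(assigned) {
  per_type <- assigned %>%
    dplyr::group_by(.data$type_key) %>%
    dplyr::summarise(n_precursor = sum(.data$stage == "precursor"),
                     n_processed = sum(.data$stage == "processed"),
                     .groups = "drop")
  overall <- tibble::tibble(type_key = "(overall)",
                            n_precursor = sum(per_type$n_precursor),
                            n_processed = sum(per_type$n_processed))
  out <- dplyr::bind_rows(per_type, overall) %>%
    dplyr::mutate(total = .data$n_precursor + .data$n_processed) %>%
    dplyr::filter(.data$total > 0L) %>%
    dplyr::mutate(frac_precursor = .data$n_precursor / .data$total,
                  frac_processed = .data$n_processed / .data$total) %>%
    dplyr::select(-"total")
  out
}

#' Depth at the anticodon position per gene copy
#'
#' Counts, per gene copy, the assigned reads whose counted alignment covers
#' the genomic position of residue 34.
#'
#' @param assigned assigned-read tibble from [assign_reads()].
#' @param genes [trna_genes()] table.
#' @return Tibble `gene_id`, `type_key`, `depth34` (all gene copies listed,
#'   zero where uncovered).
#' @export
anticodon_depth <- function(assigned, genes) {
  ac <- anticodon_positions(genes)
  p34 <- stats::setNames(ac$pos34, ac$gene_id)
  covered <- assigned %>%
    dplyr::mutate(pos34 = p34[.data$gene_id]) %>%
    dplyr::filter(.data$gstart <= .data$pos34, .data$pos34 < .data$gend) %>%
    dplyr::count(.data$gene_id, name = "depth34")
  genes %>%
    tibble::as_tibble() %>%
    dplyr::select("gene_id", "type_key") %>%
    dplyr::left_join(covered, by = "gene_id") %>%
    dplyr::mutate(depth34 = dplyr::coalesce(.data$depth34, 0L))
}
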