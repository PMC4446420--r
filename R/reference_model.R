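# tRNA gene model: loading, validation, type grouping, anticodon coordinates
# and leader/trailer windows. All coordinates are 0-based half-open
# internally (BED/SAM arithmetic); FASTA extraction converts at the boundary.

#' Validate and construct a tRNA gene table
#'
#' A tRNA gene table has one row per genomic gene copy with the columns
#' `gene_id`, `type_key` (\code{"AminoAcid-Anticodon"}, e.g. `"Val-AAC"`),
#' `chrom`, `strand` (`+`/`-`), `mature_start`, `mature_end` (0-based
#' half-open span of the mature sequence), `anticodon_offset` (0-based index
#' of residue 34 within the mature sense-strand sequence) and `has_intron`.
#'
#' @param df data frame with the columns above.
#' @return A `tbl_df` of class `trna_genes`.
#' @export
trna_genes <- function(df) {
  req <- c("gene_id", "type_key", "chrom", "strand", "mature_start",
           "mature_end", "anticodon_offset", "has_intron")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("gene table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  df$mature_start <- as.integer(df$mature_start)
  df$mature_end <- as.integer(df$mature_end)
  df$anticodon_offset <- as.integer(df$anticodon_offset)
  df$has_intron <- as.logical(df$has_intron)
  bad <- which(
    is.na(df$gene_id) | duplicated(df$gene_id) |
      !df$strand %in% c("+", "-") |
      is.na(df$mature_start) | is.na(df$mature_end) |
      df$mature_start >= df$mature_end | df$mature_start < 0 |
      is.na(df$anticodon_offset) | df$anticodon_offset < 0 |
      df$anticodon_offset > (df$mature_end - df$mature_start) - 3L |
      !grepl("^[A-Za-z]+[A-Za-z0-9]*-[ACGT]{3}$", df$type_key)
  )
  if (length(bad)) {
    stop("invalid tRNA gene rows (invariant violation) at row(s): ",
         paste(bad, collapse = ", "))
  }
  class(df) <- c("trna_genes", class(df))
  df
}

#' Read a tRNA gene table (BED-like TSV) against a genome
#'
#' The table is tab-separated with columns exactly
#' `chrom, start, end, gene_id, score, strand, type_key, anticodon_offset,
#' has_intron`; lines starting with `#` are comments and an optional header
#' row repeating the column names is tolerated. `start`/`end` are 0-based
#' half-open mature-span coordinates. Every `chrom` must exist in the genome
#' and the span must lie within the chromosome; violations are hard errors
#' naming the offender. Rows failing a gene invariant are reported with their
#' (1-based) file line numbers.
#'
#' @param path gene table TSV.
#' @param genome FASTA path or a named [Biostrings::DNAStringSet].
#' @param check_anticodon verify that the genomic sense-strand triplet at the
#'   anticodon coordinates equals the anticodon encoded in `type_key`
#'   (intronless genes only); mismatches are an error.
#' @return [trna_genes()] table; intron-carrying rows are retained but
#'   flagged via `has_intron`.
#' @export
read_trna_genes <- function(path, genome, check_anticodon = TRUE) {
  genome <- load_genome(genome)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  cols <- c("chrom", "start", "end", "gene_id", "score", "strand",
            "type_key", "anticodon_offset", "has_intron")
  if (length(lines) && identical(strsplit(lines[[1]], "\t")[[1]], cols)) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (!length(lines)) {
    return(trna_genes(tibble::tibble(
      gene_id = character(), type_key = character(), chrom = character(),
      strand = character(), mature_start = integer(), mature_end = integer(),
      anticodon_offset = integer(), has_intron = logical()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed gene table rows (expected 9 tab-separated fields) at line(s): ",
         paste(line_no[nf != 9L], collapse = ", "))
  }
  m <- do.call(rbind, fields)
  df <- tibble::tibble(
    gene_id = m[, 4], type_key = m[, 7], chrom = m[, 1], strand = m[, 6],
    mature_start = suppressWarnings(as.integer(m[, 2])),
    mature_end = suppressWarnings(as.integer(m[, 3])),
    anticodon_offset = suppressWarnings(as.integer(m[, 8])),
    has_intron = m[, 9] %in% c("1", "TRUE", "true", "T")
  )
  bad_chrom <- setdiff(unique(df$chrom), names(genome))
  if (length(bad_chrom)) {
    stop("chromosome(s) absent from genome FASTA: ",
         paste(bad_chrom, collapse = ", "))
  }
  clen <- Biostrings::width(genome)[match(df$chrom, names(genome))]
  oob <- which(is.na(df$mature_start) | is.na(df$mature_end) |
                 df$mature_start < 0 | df$mature_end > clen)
  if (length(oob)) {
    stop("gene span outside chromosome bounds at line(s): ",
         paste(line_no[oob], collapse = ", "))
  }
  genes <- tryCatch(trna_genes(df), error = function(e) {
    stop("gene table invariant violations (file line numbers): ",
         conditionMessage(e), call. = FALSE)
  })
  if (check_anticodon) {
    check_anticodon_sequence(genes, genome)
  }
  genes
}

load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    return(genome)
  }
  gs <- Biostrings::readDNAStringSet(genome)
  # FASTA descriptions may carry text after the first token
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

#' Check annotated anticodons against the genome sequence
#'
#' For every intronless gene, the sense-strand triplet at
#' [anticodon_positions()] must equal the anticodon part of `type_key`.
#'
#' @param genes [trna_genes()] table.
#' @param genome FASTA path or `DNAStringSet`.
#' @return Invisibly `TRUE`; mismatches raise an error naming the genes.
#' @export
check_anticodon_sequence <- function(genes, genome) {
  genome <- load_genome(genome)
  idx <- which(!genes$has_intron)
  if (!length(idx)) {
    return(invisible(TRUE))
  }
  triplet <- vapply(idx, function(i) {
    g <- genes[i, ]
    seq <- gene_sense_sequence(g, genome)
    substr(seq, g$anticodon_offset + 1L, g$anticodon_offset + 3L)
  }, character(1))
  expected <- sub("^.*-", "", genes$type_key[idx])
  bad <- triplet != expected
  if (any(bad)) {
    stop("anticodon sequence mismatch for gene(s): ",
         paste(sprintf("%s (found %s, annotated %s)", genes$gene_id[idx][bad],
                       triplet[bad], expected[bad]), collapse = "; "))
  }
  invisible(TRUE)
}

# Sense-strand mature sequence of one gene row.
gene_sense_sequence <- function(gene, genome) {
  s <- Biostrings::subseq(genome[[gene$chrom]],
                          start = gene$mature_start + 1L,
                          end = gene$mature_end)
  if (gene$strand == "-") {
    s <- Biostrings::reverseComplement(s)
  }
  as.character(s)
}

#' Group tRNA gene copies into types
#'
#' Partitions genes by `type_key` (amino acid + anticodon), the unit at which
#' multi-copy reads can still be assigned unequivocally.
#'
#' @param genes [trna_genes()] table.
#' @return Tibble with `type_key`, `gene_ids` (list column) and `n_copies`,
#'   ordered by `type_key`.
#' @export
trna_type_groups <- function(genes) {
  if (!nrow(genes)) {
    return(tibble::tibble(type_key = character(), gene_ids = list(),
                          n_copies = integer()))
  }
  genes %>%
    dplyr::group_by(.data$type_key) %>%
    dplyr::summarise(gene_ids = list(sort(.data$gene_id)),
                     n_copies = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$type_key)
}

#' Genomic coordinates of anticodon residues 34-36
#'
#' @param genes [trna_genes()] table.
#' @return Tibble `gene_id`, `pos34`, `pos35`, `pos36`: 0-based genomic
#'   coordinates in residue order 34 to 36 (decreasing for minus-strand
#'   genes).
#' @export
anticodon_positions <- function(genes) {
  plus <- genes$strand == "+"
  p34 <- ifelse(plus,
                genes$mature_start + genes$anticodon_offset,
                genes$mature_end - 1L - genes$anticodon_offset)
  step <- ifelse(plus, 1L, -1L)
  tibble::tibble(gene_id = genes$gene_id,
                 pos34 = as.integer(p34),
                 pos35 = as.integer(p34 + step),
                 pos36 = as.integer(p34 + 2L * step))
}

#' Leader and trailer genomic windows
#'
#' The leader window is the `leader` nt immediately 5' of the mature span in
#' tRNA sense (genomically downstream for minus-strand genes); the trailer
#' window likewise 3'. Intervals are 0-based half-open and clipped at
#' chromosome bounds when `chrom_lengths` is supplied.
#'
#' @param genes [trna_genes()] table.
#' @param leader,trailer window lengths in nt (defaults 50, matching the
#'   +/-50 nt base-calling window around the anticodon).
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return Tibble `gene_id`, `leader_start`, `leader_end`, `trailer_start`,
#'   `trailer_end`.
#' @export
flank_windows <- function(genes, leader = 50L, trailer = 50L,
                          chrom_lengths = NULL) {
  stopifnot(leader >= 0, trailer >= 0)
  plus <- genes$strand == "+"
  ls <- ifelse(plus, genes$mature_start - leader, genes$mature_end)
  le <- ifelse(plus, genes$mature_start, genes$mature_end + leader)
  ts <- ifelse(plus, genes$mature_end, genes$mature_start - trailer)
  te <- ifelse(plus, genes$mature_end + trailer, genes$mature_start)
  out <- tibble::tibble(gene_id = genes$gene_id,
                        leader_start = as.integer(pmax(ls, 0L)),
                        leader_end = as.integer(pmax(le, 0L)),
                        trailer_start = as.integer(pmax(ts, 0L)),
                        trailer_end = as.integer(pmax(te, 0L)))
  if (!is.null(chrom_lengths)) {
    cl <- chrom_lengths[genes$chrom]
    out$leader_start <- as.integer(pmin(out$leader_start, cl))
    out$leader_end <- as.integer(pmin(out$leader_end, cl))
    out$trailer_start <- as.integer(pmin(out$trailer_start, cl))
    out$trailer_end <- as.integer(pmin(out$trailer_end, cl))
  }
  out
}

#' Derive the anticodon offset from a mature sequence
#'
#' Locates the annotated anticodon triplet within a mature sense-strand
#' sequence by substring search. The search errs on ambiguity rather than
#' guessing: zero or multiple occurrences raise an error (anticodon offsets
#' vary with D-loop length, so silent inference would be fragile).
#'
#' @param mature_seq mature sense-strand sequence (character).
#' @param anticodon 3-nt anticodon, e.g. `"AAC"`.
#' @return 0-based offset of residue 34 within `mature_seq`.
#' @export
infer_anticodon_offset <- function(mature_seq, anticodon) {
  stopifnot(nchar(anticodon) == 3L)
  hits <- gregexpr(anticodon, mature_seq, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (length(hits) == 0L) {
    stop("anticodon '", anticodon, "' not found in mature sequence")
  }
  if (length(hits) > 1L) {
    stop("anticodon '", anticodon, "' occurs ", length(hits),
         " times in mature sequence; offset is ambiguous")
  }
  as.integer(hits - 1L)
}

#' Write a tRNA gene table in the package's BED-like dialect
#'
#' @param genes [trna_genes()] table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trna_genes <- function(genes, path) {
  header <- paste(c("chrom", "start", "end", "gene_id", "score", "strand",
                    "type_key", "anticodon_offset", "has_intron"),
                  collapse = "\t")
  rows <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t%d\t%d",
                  genes$chrom, genes$mature_start, genes$mature_end,
                  genes$gene_id, genes$strand, genes$type_key,
                  genes$anticodon_offset, as.integer(genes$has_intron))
  writeLines(c(header, rows), path)
  invisible(path)
}
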