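# Per-position base-count pileups in a window around the anticodon.
# Positions are indexed relative to residue 34 in tRNA sense orientation
# (0 = residue 34, +1 = residue 35, +3 = residue 37); minus-strand genes
# contribute complemented, sense-oriented bases.

#' Build per-gene-copy pileups around the anticodon
#'
#' For every assigned read, aligned bases falling within `window` nt of
#' residue 34 (in tRNA sense coordinates) increment the base counts of the
#' read's counted gene copy and stage. Bases of reads on minus-strand genes
#' are complemented; positions a read does not cover are untouched.
#'
#' @param assigned assigned-read tibble from [assign_reads()].
#' @param genes [trna_genes()] table.
#' @param window half-window in nt around residue 34 (default 50).
#' @param condition optional condition label attached to every row.
#' @return Long tibble (class `pileup_tbl`) with `gene_id`, `type_key`,
#'   `stage`, `condition`, `pos` (relative position, `-window..window`) and
#'   counts `A`, `C`, `G`, `T`; only positions with depth > 0 appear. The
#'   window is kept in attribute `window`.
#' @export
build_pileups <- function(assigned, genes, window = 50L,
                          condition = NA_character_) {
  stopifnot(window >= 0L)
  ac <- anticodon_positions(genes)
  p34 <- stats::setNames(ac$pos34, ac$gene_id)
  strand <- stats::setNames(genes$strand, genes$gene_id)
  width <- 2L * window + 1L
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(assigned))) {
    ab <- aligned_bases(assigned$cigar[i], assigned$seq[i],
                        assigned$gstart[i])
    g <- assigned$gene_id[i]
    if (strand[g] == "+") {
      rel <- ab$ref_pos - p34[g]
      base <- ab$base
    } else {
      rel <- p34[g] - ab$ref_pos
      base <- comp_base(ab$base)
    }
    keep <- which(abs(rel) <= window & base %in% DNA_BASES)
    if (!length(keep)) {
      next
    }
    key <- paste(g, assigned$stage[i], sep = "\r")
    m <- acc[[key]]
    if (is.null(m)) {
      m <- matrix(0L, nrow = width, ncol = 4L,
                  dimnames = list(NULL, DNA_BASES))
    }
    idx <- cbind(rel[keep] + window + 1L,
                 match(base[keep], DNA_BASES))
    m[idx] <- m[idx] + 1L
    acc[[key]] <- m
  }
  keys <- ls(acc)
  rows <- lapply(keys, function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    m <- acc[[key]]
    covered <- which(rowSums(m) > 0L)
    tibble::tibble(gene_id = parts[1],
                   type_key = unname(
                     stats::setNames(genes$type_key, genes$gene_id)[parts[1]]),
                   stage = parts[2],
                   condition = condition,
                   pos = covered - window - 1L,
                   A = m[covered, "A"], C = m[covered, "C"],
                   G = m[covered, "G"], T = m[covered, "T"])
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(gene_id = character(), type_key = character(),
                          stage = character(), condition = character(),
                          pos = integer(), A = integer(), C = integer(),
                          G = integer(), T = integer())
  }
  out <- dplyr::arrange(out, .data$gene_id, .data$stage, .data$pos)
  attr(out, "window") <- as.integer(window)
  class(out) <- c("pileup_tbl", class(out))
  out
}

#' Remove gene copies with insufficient anticodon coverage
#'
#' A copy is retained iff its total depth at residue 34 (relative position
#' 0, summed over stages within the dataset) is at least `min_depth`.
#' Removal is per gene copy, before type-level aggregation.
#'
#' @param pileups per-copy pileup tibble from [build_pileups()].
#' @param min_depth minimum read depth at the anticodon position
#'   (default 10; copies with depth below it are removed).
#' @return Filtered pileup tibble; removed copies are recorded in attribute
#'   `removed_copies`.
#' @export
filter_anticodon_coverage <- function(pileups, min_depth = 10L) {
  stopifnot(min_depth >= 1L)
  depth0 <- pileups %>%
    dplyr::filter(.data$pos == 0L) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(depth = sum(.data$A + .data$C + .data$G + .data$T),
                     .groups = "drop")
  keep <- depth0$gene_id[depth0$depth >= min_depth]
  removed <- setdiff(unique(pileups$gene_id), keep)
  out <- pileups[pileups$gene_id %in% keep, ]
  attr(out, "window") <- attr(pileups, "window")
  attr(out, "removed_copies") <- removed
  class(out) <- class(pileups)
  out
}

#' Aggregate per-copy pileups to tRNA-type level
#'
#' Element-wise sum of base counts within (`type_key`, `stage`,
#' `condition`, `pos`); copies and replicates can be pooled in either order
#' (bind rows of several runs first to aggregate over replicates). The sum
#' is associative and order-independent.
#'
#' @param pileups pileup tibble (or several, row-bound) from
#'   [build_pileups()].
#' @param by_stage set `FALSE` to additionally pool precursor and processed
#'   reads.
#' @return Type-level pileup tibble with `key` = `type_key`.
#' @export
aggregate_pileups <- function(pileups, by_stage = TRUE) {
  grp <- c("type_key", if (by_stage) "stage", "condition", "pos")
  out <- pileups %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(DNA_BASES), sum),
                     .groups = "drop") %>%
    dplyr::arrange(.data$type_key, .data$pos)
  if (!by_stage) {
    out$stage <- "(pooled)"
  }
  attr(out, "window") <- attr(pileups, "window")
  class(out) <- c("pileup_tbl", class(tibble::tibble()))
  out
}

#' Base composition at one relative position
#'
#' @param pileups pileup tibble (copy- or type-level).
#' @param position relative position (0 = residue 34, +1 = residue 35,
#'   +3 = residue 37).
#' @return Tibble with the grouping columns, `position`, `depth` and
#'   `frac_A`..`frac_T` (fractions sum to 1). Groups without coverage at
#'   `position` are reported with `depth = 0` and `NA` fractions, never as
#'   zeros.
#' @export
composition_at <- function(pileups, position = 0L) {
  grp <- intersect(c("type_key", "gene_id", "stage", "condition"),
                   names(pileups))
  groups <- dplyr::distinct(tibble::as_tibble(pileups)[grp])
  here <- pileups %>%
    dplyr::filter(.data$pos == position) %>%
    tibble::as_tibble()
  out <- groups %>%
    dplyr::left_join(here, by = grp) %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(DNA_BASES),
                                ~ dplyr::coalesce(.x, 0L)),
                  position = position,
                  depth = .data$A + .data$C + .data$G + .data$T,
                  frac_A = ifelse(.data$depth > 0, .data$A / .data$depth, NA),
                  frac_C = ifelse(.data$depth > 0, .data$C / .data$depth, NA),
                  frac_G = ifelse(.data$depth > 0, .data$G / .data$depth, NA),
                  frac_T = ifelse(.data$depth > 0, .data$T / .data$depth, NA))
  dplyr::select(out, dplyr::all_of(grp), "position", "depth",
                dplyr::all_of(DNA_BASES), "frac_A", "frac_C", "frac_G",
                "frac_T")
}

#' Inosine (A/G mismatch) editing estimate at residue 34
#'
#' The editing fraction is `n_G / (n_A + n_G)` at relative position 0; C and
#' T calls (error/noise) are reported but excluded from the fraction, which
#' is the A/G mismatch proportion the Fisher tests operate on.
#'
#' @param pileups pileup tibble (typically type-level, coverage-filtered).
#' @return Tibble with the grouping columns and `n_A`, `n_C`, `n_G`, `n_T`,
#'   `depth`, `editing_fraction` (`NA` when `n_A + n_G = 0`).
#' @export
editing_fraction <- function(pileups) {
  composition_at(pileups, 0L) %>%
    dplyr::mutate(n_A = .data$A, n_C = .data$C, n_G = .data$G, n_T = .data$T,
                  editing_fraction = ifelse(
                    .data$n_A + .data$n_G > 0,
                    .data$n_G / (.data$n_A + .data$n_G), NA_real_)) %>%
    dplyr::select(-dplyr::all_of(DNA_BASES), -"position", -"frac_A",
                  -"frac_C", -"frac_G", -"frac_T")
}

#' Base composition at residue 37
#'
#' Composition at relative position +3, the readout of the stepwise
#' position-37 modification on Ala-AGC (inosine 37 sequenced as G,
#' 1-methylinosine 37 as T).
#'
#' @param pileups pileup tibble; callers normally filter to the
#'   position-37-modifiable type (Ala-AGC) first.
#' @return As [composition_at()] evaluated at +3.
#' @export
position37_composition <- function(pileups) {
  composition_at(pileups, 3L)
}

#' Background A-to-G mismatch profile
#'
#' For every window position within the mature sequence whose reference
#' (sense) base is A, reports the A-to-G mismatch proportion `G / (A + G)`,
#' flagging residue 34. Comparing position 34 against this background
#' separates editing signal from sequencing error.
#'
#' @param pileups type-level pileup tibble from [aggregate_pileups()].
#' @param genes [trna_genes()] table (copies of a type share the mature
#'   sequence; the first copy provides the reference window).
#' @param genome FASTA path or `DNAStringSet`.
#' @return Tibble `type_key`, `stage`, `condition`, `pos`, `ref_base`,
#'   `depth`, `n_A`, `n_G`, `prop_AG`, `is_pos34`, restricted to
#'   reference-A positions
#'   inside the mature span. Summary statistics per group (max and mean
#'   background proportion excluding residue 34) are in attribute
#'   `background_summary`.
#' @export
background_profile <- function(pileups, genes, genome) {
  genome <- load_genome(genome)
  types <- unique(pileups$type_key)
  refs <- lapply(stats::setNames(types, types), function(tk) {
    g <- genes[genes$type_key == tk, ][1, ]
    seq <- strsplit(gene_sense_sequence(g, genome), "")[[1]]
    # relative coords of mature positions: -offset .. len-offset-1
    tibble::tibble(pos = seq_along(seq) - 1L - g$anticodon_offset,
                   ref_base = seq)
  })
  out <- lapply(types, function(tk) {
    ref <- refs[[tk]]
    pileups %>%
      dplyr::filter(.data$type_key == tk) %>%
      dplyr::inner_join(ref, by = "pos") %>%
      dplyr::filter(.data$ref_base == "A") %>%
      dplyr::mutate(depth = .data$A + .data$C + .data$G + .data$T,
                    n_A = .data$A, n_G = .data$G,
                    prop_AG = ifelse(.data$A + .data$G > 0,
                                     .data$G / (.data$A + .data$G), NA_real_),
                    is_pos34 = .data$pos == 0L) %>%
      dplyr::select(dplyr::any_of(c("type_key", "stage", "condition")),
                    "pos", "ref_base", "depth", "n_A", "n_G", "prop_AG",
                    "is_pos34")
  })
  out <- dplyr::bind_rows(out)
  summ <- out %>%
    dplyr::filter(!.data$is_pos34, !is.na(.data$prop_AG)) %>%
    dplyr::group_by(dplyr::across(dplyr::any_of(c("type_key", "stage",
                                                  "condition")))) %>%
    dplyr::summarise(max_background = max(.data$prop_AG),
                     mean_background = mean(.data$prop_AG),
                     .groups = "drop")
  attr(out, "background_summary") <- summ
  out
}
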