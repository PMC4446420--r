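# In-silico counterparts of the two biochemical inosine assays: the Sanger
# readout of a deaminated pre-tRNA (inosine reads as G) and Endonuclease V
# cleavage fragment prediction (EndoV cuts the second phosphodiester bond
# 3' of an inosine).

#' Pre-tRNA construct
#'
#' A pre-tRNA as used for in-vitro deamination assays: 5'-leader, mature
#' sequence and 3'-trailer, with the set of mature residues (1-based) that
#' are deaminated to inosine. Residue 34 means mature index 34. Every
#' inosine position must index an A in the (pre-deamination) mature
#' sequence. `U` is accepted and normalised to `T` (DNA alphabet of the
#' sequencing readout).
#'
#' @param leader,mature,trailer nucleotide strings (trailer/leader may be
#'   empty).
#' @param inosine integer vector of 1-based mature residue indices carrying
#'   inosine.
#' @return List of class `pre_trna`.
#' @export
pre_trna <- function(leader, mature, trailer = "", inosine = integer(0)) {
  norm <- function(x) chartr("uU", "tT", toupper(x))
  leader <- norm(leader)
  mature <- norm(mature)
  trailer <- norm(trailer)
  if (!grepl("^[ACGT]*$", paste0(leader, mature, trailer))) {
    stop("sequences must contain only A, C, G, T/U")
  }
  inosine <- as.integer(inosine)
  if (any(inosine < 1L | inosine > nchar(mature))) {
    stop("inosine positions must index the mature sequence (1-based)")
  }
  bad <- if (length(inosine)) {
    inosine[substring(mature, inosine, inosine) != "A"]
  } else {
    integer(0)
  }
  if (length(bad)) {
    stop("inosine position(s) not at an A in the mature sequence: ",
         paste(bad, collapse = ", "))
  }
  structure(list(leader = leader, mature = mature, trailer = trailer,
                 inosine = sort(unique(inosine))),
            class = "pre_trna")
}

#' @export
print.pre_trna <- function(x, ...) {
  cat(sprintf("pre-tRNA construct: %d nt leader + %d nt mature + %d nt trailer (%d nt total)\n",
              nchar(x$leader), nchar(x$mature), nchar(x$trailer),
              nchar(x$leader) + nchar(x$mature) + nchar(x$trailer)))
  if (length(x$inosine)) {
    cat("inosine at mature residue(s):", paste(x$inosine, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Predicted Sanger sequencing readout of a pre-tRNA
#'
#' Without deamination the readout is the construct sequence verbatim
#' (expected A at residue 34). After deamination, every inosine position
#' reads as G and nothing else changes: full conversion shows a clear G
#' with no trace of A at the edited position.
#'
#' @param construct [pre_trna()] construct.
#' @param deaminated has the construct been deaminated (A at the inosine
#'   positions converted to inosine)?
#' @return Full-length readout string (leader + mature + trailer).
#' @export
sanger_readout <- function(construct, deaminated = FALSE) {
  stopifnot(inherits(construct, "pre_trna"))
  mature <- construct$mature
  if (deaminated && length(construct$inosine)) {
    ch <- strsplit(mature, "")[[1]]
    ch[construct$inosine] <- "G"
    mature <- paste(ch, collapse = "")
  }
  paste0(construct$leader, mature, construct$trailer)
}

#' Predicted Endonuclease V cleavage fragments
#'
#' EndoV cleaves the second phosphodiester bond 3' of an inosine, so the 5'
#' product ends one nucleotide after the inosine: for a single inosine at
#' mature residue `p`, the 5' fragment is `len(leader) + p + 1` nt and the
#' 3' fragment is the remainder. Zero inosines give a single full-length
#' fragment.
#'
#' @param construct [pre_trna()] construct.
#' @param nt_after_inosine nucleotides retained 3' of the inosine on the 5'
#'   product (default 1, the second-phosphodiester-bond rule).
#' @return List of class `cleavage_result` with `fragment_lengths` (ordered
#'   5' to 3', summing to the construct length) and `cut_sites`.
#' @export
endov_cleave <- function(construct, nt_after_inosine = 1L) {
  stopifnot(inherits(construct, "pre_trna"), nt_after_inosine >= 0L)
  total <- nchar(construct$leader) + nchar(construct$mature) +
    nchar(construct$trailer)
  cuts <- nchar(construct$leader) + construct$inosine + nt_after_inosine
  cuts <- sort(unique(cuts[cuts > 0L & cuts < total]))
  bounds <- c(0L, cuts, total)
  structure(list(fragment_lengths = as.integer(diff(bounds)),
                 cut_sites = as.integer(cuts),
                 total_length = as.integer(total)),
            class = "cleavage_result")
}

#' @export
print.cleavage_result <- function(x, ...) {
  cat(sprintf("EndoV digest: %d fragment(s) from a %d nt construct\n",
              length(x$fragment_lengths), x$total_length))
  cat("fragment lengths (5'->3'):",
      paste(x$fragment_lengths, collapse = ", "), "nt\n")
  invisible(x)
}

#' Canonical pre-tRNA-Val(AAC)-like construct for the EndoV worked example
#'
#' A synthetic stand-in with the canonical length arithmetic of the
#' in-vitro substrate: a 6-nt leader, a 76-nt mature sequence with an A at
#' residue 34 (inosine after deamination), and a 13-nt trailer; 95 nt in
#' total, cleaved by EndoV into 41 nt (5') + 54 nt (3'). The sequence
#' itself is synthetic; only the length arithmetic matches the biochemical
#' construct.
#'
#' @param seed RNG seed for the synthetic sequence.
#' @return [pre_trna()] construct with inosine at residue 34.
#' @export
example_val_construct <- function(seed = 1L) {
  with_seed(seed, {
    mature <- strsplit(random_dna(76L), "")[[1]]
    mature[34:36] <- c("A", "A", "C")
    pre_trna(leader = random_dna(6L),
             mature = paste(mature, collapse = ""),
             trailer = random_dna(13L),
             inosine = 34L)
  })
}
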