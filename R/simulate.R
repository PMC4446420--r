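# Synthetic small RNA-seq over multi-copy tRNA gene families, with per-read
# modification truth. The generator emulates the features the analysis has
# to cope with: identical gene copies within a type (within-type
# multi-mapping), an optional cross-type ambiguous pair, reads with and
# without leader/trailer sequence, stage-dependent Bernoulli editing at
# residue 34 (read as G), the stepwise position-37 modification of Ala-AGC
# (G then T readout), uniform per-base sequencing error, fragment-length
# variation, and a knockdown condition with multiplicatively reduced
# editing.

# The eight human tRNA types whose genomic anticodon starts with A.
ANN_TYPES <- c("Ala-AGC", "Arg-ACG", "Ile-AAT", "Leu-AAG",
               "Pro-AGG", "Ser-AGA", "Thr-AGT", "Val-AAC")

#' Simulation configuration
#'
#' Defaults encode the study conditions the package is tested under:
#' editing probability 0.2 at residue 34 in precursor reads rising to 0.8 in
#' processed reads, per-base substitution error 0.005, a knockdown that
#' halves editing on every substrate, an even precursor/processed read split,
#' and a fragment model in which 85% of reads cover the anticodon.
#'
#' @param n_types number of ANN tRNA types to simulate (1-8).
#' @param copies_per_type identical genomic copies per type (copy 2 of each
#'   type is placed on the minus strand).
#' @param ambiguous_pair add two genes of different `type_key` sharing an
#'   identical mature sequence, so their mature-contained reads multi-map
#'   across types.
#' @param pi_precursor,pi_processed editing probability at residue 34 per
#'   stage; scalar or named per `type_key`.
#' @param knockdown_factor multiplicative factor on editing probabilities in
#'   the knockdown condition, in (0, 1].
#' @param error_rate uniform per-base substitution probability, in [0, 0.1].
#' @param depth_per_copy expected reads per gene copy (Poisson).
#' @param stage_fraction_precursor probability a read is a precursor read.
#' @param p_cover_anticodon probability a read span covers the anticodon.
#' @param p37_G_precursor,p37_G_processed,p37_T_processed position-37 readout
#'   model for Ala-AGC: precursor reads carry G37 with `p37_G_precursor`
#'   (never T); processed reads carry G or T with the two processed
#'   probabilities (inosine 37 reads as G, 1-methylinosine 37 as T).
#' @param mature_len mature tRNA length in nt (canonical 76).
#' @param seed default RNG seed used by [build_genome()]/[simulate_reads()]
#'   when none is passed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_types = 8L,
                       copies_per_type = 3L,
                       ambiguous_pair = FALSE,
                       pi_precursor = 0.2,
                       pi_processed = 0.8,
                       knockdown_factor = 0.5,
                       error_rate = 0.005,
                       depth_per_copy = 200,
                       stage_fraction_precursor = 0.5,
                       p_cover_anticodon = 0.85,
                       p37_G_precursor = 0.3,
                       p37_G_processed = 0.3,
                       p37_T_processed = 0.4,
                       mature_len = 76L,
                       seed = 1L) {
  cfg <- list(n_types = as.integer(n_types),
              copies_per_type = as.integer(copies_per_type),
              ambiguous_pair = isTRUE(ambiguous_pair),
              pi_precursor = pi_precursor,
              pi_processed = pi_processed,
              knockdown_factor = knockdown_factor,
              error_rate = error_rate,
              depth_per_copy = depth_per_copy,
              stage_fraction_precursor = stage_fraction_precursor,
              p_cover_anticodon = p_cover_anticodon,
              p37_G_precursor = p37_G_precursor,
              p37_G_processed = p37_G_processed,
              p37_T_processed = p37_T_processed,
              mature_len = as.integer(mature_len),
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_types) || cfg$n_types < 1L ||
      cfg$n_types > length(ANN_TYPES)) {
    stop("n_types must be an integer in 1..", length(ANN_TYPES))
  }
  if (!is_count(cfg$copies_per_type) || cfg$copies_per_type < 1L) {
    stop("copies_per_type must be a positive integer")
  }
  for (nm in c("pi_precursor", "pi_processed", "stage_fraction_precursor",
               "p_cover_anticodon", "p37_G_precursor", "p37_G_processed",
               "p37_T_processed")) {
    if (!is_prob(cfg[[nm]])) stop(nm, " must be probabilities in [0, 1]")
  }
  if (cfg$p37_G_processed + cfg$p37_T_processed > 1) {
    stop("p37_G_processed + p37_T_processed must not exceed 1")
  }
  if (!is_prob(cfg$knockdown_factor) || any(cfg$knockdown_factor <= 0)) {
    stop("knockdown_factor must lie in (0, 1]")
  }
  if (!is_prob(cfg$error_rate) || cfg$error_rate > 0.1) {
    stop("error_rate must lie in [0, 0.1]")
  }
  if (!is.numeric(cfg$depth_per_copy) || cfg$depth_per_copy < 0) {
    stop("depth_per_copy must be non-negative")
  }
  if (cfg$mature_len < 45L) {
    stop("mature_len too short to hold anticodon at offset 33")
  }
  invisible(cfg)
}

# Per-type editing probability for one stage.
pi_for <- function(p, type_key) {
  if (length(p) == 1L && is.null(names(p))) {
    return(unname(p))
  }
  if (!type_key %in% names(p)) {
    stop("no editing probability given for type ", type_key)
  }
  unname(p[[type_key]])
}

# Random DNA of length n as a single string.
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Build a synthetic genome of multi-copy tRNA genes
#'
#' One chromosome per tRNA type; all copies of a type share an identical
#' mature sequence (so mature-contained reads multi-map within the type)
#' embedded in distinct random flanking sequence. The anticodon sits at
#' offset 33 (residues 34-36 of a 76-nt gene) and residue 37 is fixed to A.
#' Copy 2 of each type is minus-strand. With `ambiguous_pair = TRUE`, two
#' extra single-copy genes (`Xxa-AAC`, `Xxb-AAC`) share one mature sequence
#' across different type keys.
#'
#' @param config [sim_config()].
#' @param seed RNG seed (default `config$seed`). Identical config + seed
#'   gives byte-identical output.
#' @return List with `genome` (named [Biostrings::DNAStringSet]) and `genes`
#'   ([trna_genes()] table).
#' @export
build_genome <- function(config, seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, {
    gap <- 300L
    margin <- 100L
    M <- config$mature_len
    types <- ANN_TYPES[seq_len(config$n_types)]
    chroms <- character(0)
    seqs <- character(0)
    rows <- list()
    make_mature <- function(anticodon) {
      s <- strsplit(random_dna(M), "")[[1]]
      s[34:36] <- strsplit(anticodon, "")[[1]]
      s[37] <- "A"  # canonical purine 37; reference base for the 37 readout
      paste(s, collapse = "")
    }
    place_type <- function(type_key, n_copies, mature, copy_prefix) {
      chrom <- paste0("chrT_", sub("-", "_", type_key))
      clen <- margin + n_copies * gap + margin
      cs <- strsplit(random_dna(clen), "")[[1]]
      for (j in seq_len(n_copies)) {
        start <- margin + (j - 1L) * gap
        strand <- if (j == 2L) "-" else "+"
        ins <- if (strand == "+") mature else revcomp_chr(mature)
        cs[(start + 1L):(start + M)] <- strsplit(ins, "")[[1]]
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          gene_id = sprintf("%s-c%02d", copy_prefix, j),
          type_key = type_key, chrom = chrom, strand = strand,
          mature_start = start, mature_end = start + M,
          anticodon_offset = 33L, has_intron = FALSE)
      }
      chroms <<- c(chroms, chrom)
      seqs <<- c(seqs, paste(cs, collapse = ""))
    }
    for (tk in types) {
      anticodon <- sub("^.*-", "", tk)
      place_type(tk, config$copies_per_type, make_mature(anticodon),
                 sub("-", "", tk))
    }
    if (config$ambiguous_pair) {
      shared <- make_mature("AAC")
      place_type("Xxa-AAC", 1L, shared, "XxaAAC")
      place_type("Xxb-AAC", 1L, shared, "XxbAAC")
    }
    genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
    list(genome = genome, genes = trna_genes(dplyr::bind_rows(rows)))
  })
}

# Sample one read span in mature-local sense coordinates (0-based half-open;
# negative start = leader overlap, end > M = trailer overlap). Local index of
# residue 34 is `p` (= anticodon_offset). Returns c(ls, le).
sample_span <- function(stage, cover34, p, M) {
  if (stage == "precursor") {
    f <- sample_from(5:15)
    if (stats::runif(1) < 0.5) {  # leader-anchored
      ls <- -f
      le <- if (cover34) sample_from((p + 3L):M) else sample_from(10:p)
    } else {                      # trailer-anchored
      le <- M + f
      ls <- if (cover34) sample_from(0:p) else sample_from((p + 3L):(M - 10L))
    }
  } else {
    if (cover34) {
      ls <- sample_from(0:p)
      le <- sample_from((p + 3L):M)
    } else if (stats::runif(1) < 0.5) {  # 5' fragment
      ls <- sample_from(0:10)
      le <- sample_from((ls + 10L):p)
    } else {                             # 3' fragment
      ls <- sample_from((p + 3L):(M - 10L))
      le <- sample_from((ls + 10L):M)
    }
  }
  c(ls, le)
}

# Substitute each base independently with prob eps, uniform over the other 3.
inject_error <- function(bases, eps) {
  if (eps <= 0) {
    return(bases)
  }
  hit <- which(stats::runif(length(bases)) < eps)
  if (length(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
  }
  bases
}

#' Simulate small RNA-seq reads with modification truth
#'
#' For each gene copy, draws Poisson(`depth_per_copy`) reads; each read gets
#' a maturation stage, a span (precursor spans overlap >= 1 nt of
#' leader/trailer; processed spans lie inside the mature interval; spans
#' cover the anticodon with probability `p_cover_anticodon`), an edited base
#' at residue 34 (G with the stage/type/condition-effective probability,
#' else A), the Ala-AGC position-37 readout, and uniform substitution noise
#' over all bases. Truth (pre-error emitted bases) is recorded per read.
#'
#' @param genome named `DNAStringSet` from [build_genome()].
#' @param genes [trna_genes()] table from [build_genome()].
#' @param config [sim_config()].
#' @param condition `"control"` or `"knockdown"`; knockdown multiplies
#'   editing probabilities by `knockdown_factor`.
#' @param seed RNG seed (default `config$seed`).
#' @param out_dir if non-`NULL`, write `reads.fastq`, `truth.sam` (one
#'   alignment per true origin, plus a secondary record on the partner gene
#'   for ambiguous-pair reads contained in the shared mature sequence) and
#'   `truth.tsv` there.
#' @return Tibble of per-read truth (`read_id`, `gene_id`, `type_key`,
#'   `stage`, `condition`, `chrom`, `gstart`, `gend`, `covers34`,
#'   `edited_34`, `base34_emitted`, `base35_emitted`, `base37_emitted`,
#'   `n_records`), with file paths in attribute `paths` when written.
#' @export
simulate_reads <- function(genome, genes, config,
                           condition = c("control", "knockdown"),
                           seed = config$seed, out_dir = NULL) {
  condition <- match.arg(condition)
  validate_sim_config(config)
  M <- config$mature_len
  kappa <- if (condition == "knockdown") config$knockdown_factor else 1
  # partner lookup for the ambiguous pair (identical mature sequences)
  partner <- ambiguous_partners(genes, genome)

  with_seed(seed, {
    fastq_parts <- vector("list", nrow(genes))
    sam_parts <- vector("list", nrow(genes))
    truth_parts <- vector("list", nrow(genes))
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      p <- g$anticodon_offset
      ext <- sense_window_sequence(g, genome, M)
      n_reads <- stats::rpois(1L, config$depth_per_copy)
      if (n_reads == 0L) {
        next
      }
      pi_pre <- pi_for(config$pi_precursor, g$type_key) * kappa
      pi_pro <- pi_for(config$pi_processed, g$type_key) * kappa
      stage <- ifelse(stats::runif(n_reads) < config$stage_fraction_precursor,
                      "precursor", "processed")
      cover34 <- stats::runif(n_reads) < config$p_cover_anticodon
      ls <- integer(n_reads)
      le <- integer(n_reads)
      edited <- rep(NA, n_reads)
      b34 <- rep(NA_character_, n_reads)
      b35 <- rep(NA_character_, n_reads)
      b37 <- rep(NA_character_, n_reads)
      sense_seq <- character(n_reads)
      for (r in seq_len(n_reads)) {
        span <- sample_span(stage[r], cover34[r], p, M)
        ls[r] <- span[1]
        le[r] <- span[2]
        bases <- ext[(span[1] + 50L + 1L):(span[2] + 50L)]
        covers34 <- span[1] <= p && p < span[2]
        covers35 <- span[1] <= p + 1L && p + 1L < span[2]
        covers37 <- span[1] <= p + 3L && p + 3L < span[2]
        if (covers34) {
          pi_eff <- if (stage[r] == "precursor") pi_pre else pi_pro
          edited[r] <- stats::runif(1) < pi_eff
          b34[r] <- if (edited[r]) "G" else "A"
          bases[p - span[1] + 1L] <- b34[r]
        }
        if (covers35) {
          b35[r] <- bases[p + 1L - span[1] + 1L]
        }
        if (covers37) {
          b <- ext[p + 3L + 50L + 1L]
          if (g$type_key == "Ala-AGC") {
            u <- stats::runif(1)
            if (stage[r] == "precursor") {
              if (u < config$p37_G_precursor) b <- "G"
            } else {
              if (u < config$p37_G_processed) {
                b <- "G"
              } else if (u < config$p37_G_processed + config$p37_T_processed) {
                b <- "T"
              }
            }
          }
          b37[r] <- b
          bases[p + 3L - span[1] + 1L] <- b
        }
        bases <- inject_error(bases, config$error_rate)
        sense_seq[r] <- paste(bases, collapse = "")
      }
      read_id <- sprintf("%s_%s_r%05d", condition, g$gene_id,
                         seq_len(n_reads))
      if (g$strand == "+") {
        gstart <- g$mature_start + ls
        gend <- g$mature_start + le
        sam_seq <- sense_seq
        flag <- 0L
      } else {
        gstart <- g$mature_end - le
        gend <- g$mature_end - ls
        sam_seq <- revcomp_fast(sense_seq)
        flag <- 16L
      }
      # ambiguous-pair partner records for mature-contained spans
      has_partner <- !is.na(partner[g$gene_id]) & ls >= 0L & le <= M
      n_rec <- ifelse(has_partner, 2L, 1L)
      own_sam <- sam_record(read_id, flag, g$chrom, gstart, le - ls,
                            sam_seq, n_rec)
      partner_sam <- character(0)
      if (any(has_partner)) {
        pg <- genes[genes$gene_id == partner[g$gene_id], ]
        i <- which(has_partner)
        if (pg$strand == "+") {
          pstart <- pg$mature_start + ls[i]
          pflag <- 256L
          pseq <- sense_seq[i]
        } else {
          pstart <- pg$mature_end - le[i]
          pflag <- 272L
          pseq <- revcomp_fast(sense_seq[i])
        }
        partner_sam <- sam_record(read_id[i], pflag, pg$chrom, pstart,
                                  le[i] - ls[i], pseq, 2L)
      }
      # interleave so a read's records are adjacent (any order is valid)
      sam_lines <- character(length(own_sam) + length(partner_sam))
      sam_lines[cumsum(n_rec) - n_rec + 1L] <- own_sam
      if (any(has_partner)) {
        sam_lines[cumsum(n_rec)[has_partner]] <- partner_sam
      }
      sam_parts[[gi]] <- sam_lines
      fastq_parts[[gi]] <- paste0("@", read_id, "\n", sense_seq, "\n+\n",
                                  strrep("I", nchar(sense_seq)))
      truth_parts[[gi]] <- tibble::tibble(
        read_id = read_id, gene_id = g$gene_id, type_key = g$type_key,
        stage = stage, condition = condition, chrom = g$chrom,
        gstart = gstart, gend = gend, covers34 = ls <= p & p < le,
        edited_34 = edited, base34_emitted = b34, base35_emitted = b35,
        base37_emitted = b37, n_records = n_rec)
    }
    fastq <- unlist(fastq_parts)
    sam <- unlist(sam_parts)
    truth <- dplyr::bind_rows(truth_parts)
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(fastq = file.path(out_dir, "reads.fastq"),
                    sam = file.path(out_dir, "truth.sam"),
                    truth = file.path(out_dir, "truth.tsv"))
      writeLines(fastq, paths$fastq)
      header <- c("@HD\tVN:1.6\tSO:unsorted",
                  sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                          Biostrings::width(genome)))
      writeLines(c(header, sam), paths$sam)
      utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      attr(truth, "paths") <- paths
    }
    attr(truth, "sam_records") <- sam
    attr(truth, "sam_header_chroms") <- stats::setNames(
      Biostrings::width(genome), names(genome))
    truth
  })
}

# One SAM alignment line (pos is 0-based here; SAM POS is 1-based).
sam_record <- function(read_id, flag, chrom, pos0, len, seq, nh) {
  sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
          read_id, flag, chrom, pos0 + 1L, len, seq, strrep("I", nchar(seq)),
          nh)
}

# Named vector gene_id -> partner gene_id for genes sharing an identical
# mature sequence under different type keys; NA where no partner.
ambiguous_partners <- function(genes, genome) {
  out <- stats::setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
  if (nrow(genes) < 2L) {
    return(out)
  }
  seqs <- vapply(seq_len(nrow(genes)), function(i) {
    gene_sense_sequence(genes[i, ], genome)
  }, character(1))
  for (i in seq_len(nrow(genes))) {
    same <- which(seqs == seqs[i] & genes$type_key != genes$type_key[i])
    if (length(same) == 1L) {
      out[i] <- genes$gene_id[same]
    }
  }
  out
}

# Sense-oriented sequence of [mature_start - 50, mature_end + 50) for one
# gene (requires 50 nt of genomic context, which build_genome guarantees).
sense_window_sequence <- function(gene, genome, M) {
  s <- Biostrings::subseq(genome[[gene$chrom]],
                          start = gene$mature_start - 50L + 1L,
                          end = gene$mature_end + 50L)
  if (gene$strand == "-") {
    s <- Biostrings::reverseComplement(s)
  }
  strsplit(as.character(s), "")[[1]]
}

#' Summarise simulation truth into per-residue base counts
#'
#' Exact counts of emitted (pre-error) bases at residues 34, 35 and 37 by
#' (type, stage, condition), the gold standard the pipeline is compared to.
#'
#' @param truth truth tibble from [simulate_reads()], or a path to a
#'   `truth.tsv`; malformed file rows raise an error with their row number.
#' @return Tibble `type_key`, `stage`, `condition`, `residue` (34/35/37),
#'   `A`, `C`, `G`, `T` counts over reads covering that residue.
#' @export
truth_summary <- function(truth) {
  if (is.character(truth)) {
    truth <- read_truth(truth)
  }
  if (!nrow(truth)) {
    return(tibble::tibble(type_key = character(), stage = character(),
                          condition = character(), residue = integer(),
                          A = integer(), C = integer(), G = integer(),
                          T = integer()))
  }
  one <- function(col, residue) {
    truth %>%
      dplyr::filter(!is.na(.data[[col]])) %>%
      dplyr::count(.data$type_key, .data$stage, .data$condition,
                   base = .data[[col]]) %>%
      dplyr::mutate(residue = residue)
  }
  long <- dplyr::bind_rows(one("base34_emitted", 34L),
                           one("base35_emitted", 35L),
                           one("base37_emitted", 37L))
  long %>%
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L) %>%
    (function(d) {
      for (b in DNA_BASES) if (!b %in% names(d)) d[[b]] <- 0L
      d
    }) %>%
    dplyr::select("type_key", "stage", "condition", "residue",
                  dplyr::all_of(DNA_BASES)) %>%
    dplyr::arrange(.data$type_key, .data$stage, .data$condition,
                   .data$residue)
}

#' Read a truth table written by [simulate_reads()]
#'
#' @param path `truth.tsv` path.
#' @return Truth tibble; malformed rows raise an error naming the row.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  req <- c("read_id", "gene_id", "type_key", "stage", "condition", "chrom",
           "gstart", "gend", "covers34", "edited_34", "base34_emitted",
           "base35_emitted", "base37_emitted", "n_records")
  if (!all(req %in% names(df))) {
    stop("truth table missing columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  bad <- which(!df$stage %in% c("precursor", "processed") |
                 !df$condition %in% c("control", "knockdown") |
                 is.na(df$gstart) | is.na(df$gend) | df$gstart >= df$gend)
  if (length(bad)) {
    stop("malformed truth rows at row(s): ", paste(bad, collapse = ", "))
  }
  tibble::as_tibble(df)
}
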