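# Shared fixtures and independent oracles. Everything is built in code at
# test time; no data files.

suppressPackageStartupMessages({
  library(dplyr)
})

# Hand-built three-gene reference: two Val-AAC copies (one plus, one minus
# strand) on chrV and one Ala-AGC copy on chrA. Mature length 76, anticodon
# offset 33.
toy_reference <- function(seed = 42) {
  withr::with_seed(seed, {
    mk_mature <- function(anticodon) {
      repeat {
        s <- sample(c("A", "C", "G", "T"), 76, replace = TRUE)
        s[34:36] <- strsplit(anticodon, "")[[1]]
        s[37] <- "A"
        seq <- paste(s, collapse = "")
        # keep the anticodon unique within the mature sequence so offset
        # inference has a single answer
        if (length(gregexpr(anticodon, seq, fixed = TRUE)[[1]]) == 1L) {
          return(seq)
        }
      }
    }
    val <- mk_mature("AAC")
    ala <- mk_mature("AGC")
    rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
    chrV <- paste0(rnd(100), val, rnd(124),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(val))), rnd(100))
    chrA <- paste0(rnd(100), ala, rnd(100))
    genome <- Biostrings::DNAStringSet(c(chrV = chrV, chrA = chrA))
    genes <- trna_genes(tibble::tibble(
      gene_id = c("ValAAC-c01", "ValAAC-c02", "AlaAGC-c01"),
      type_key = c("Val-AAC", "Val-AAC", "Ala-AGC"),
      chrom = c("chrV", "chrV", "chrA"),
      strand = c("+", "-", "+"),
      mature_start = c(100L, 300L, 100L),
      mature_end = c(176L, 376L, 176L),
      anticodon_offset = 33L,
      has_intron = FALSE))
    list(genome = genome, genes = genes, val = val, ala = ala)
  })
}

# Write a SAM file from a record tibble (read_id, flag, chrom, pos0, cigar,
# seq); pos0 is 0-based.
write_sam <- function(records, chrom_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      chrom_lengths))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
                  records$read_id, records$flag, records$chrom,
                  records$pos0 + 1L, records$cigar, records$seq,
                  strrep("I", nchar(records$seq)))
  writeLines(c(header, body), path)
  path
}

# Independent two-sided Fisher oracle: explicit hypergeometric enumeration
# via log-binomial coefficients.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    return(1)
  }
  xs <- max(0, r1 - (n - c1)):min(r1, c1)
  logp <- lchoose(c1, xs) + lchoose(n - c1, r1 - xs) - lchoose(n, r1)
  p <- exp(logp)
  p_obs <- exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1))
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Direct step-up Benjamini-Hochberg oracle: q_(i) = min_{j>=i} (m/j) p_(j),
# capped at 1, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- (m / seq_len(m)) * p[o]
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Simulate one condition to a temp dir and analyze it; returns truth,
# analysis result and the dataset directory.
sim_and_analyze <- function(cfg, condition = "control", seed = cfg$seed,
                            min_depth = 10L) {
  td <- tempfile("ds")  # session-scoped scratch; removed with the session
  res <- run_simulate(cfg, td, condition = condition, seed = seed)
  an <- suppressMessages(run_analyze(
    file.path(td, "genes.tsv"), file.path(td, "genome.fa"),
    file.path(td, "truth.sam"), min_depth = min_depth,
    condition = condition))
  list(truth = res$truth, analysis = an, dir = td)
}

# Cache for datasets shared across test files (built once per run).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# The stage-contrast study conditions: editing 0.2 (precursor) vs 0.8
# (processed), error 0.005, >= 2000 anticodon-covering reads per type and
# stage (3 copies x 1700 expected reads x 0.5 stage split x 0.85 cover
# = 2168 expected informative reads per type and stage).
fig1c_dataset <- function() {
  cached("fig1c", sim_and_analyze(sim_config(depth_per_copy = 1700,
                                             seed = 101)))
}
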