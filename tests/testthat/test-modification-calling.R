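# Pileups, base composition, editing fractions, position-37 readout and the
# background mismatch profile.

test_that("pileups count sense-oriented bases, complementing minus-strand
           genes", {
  ref <- toy_reference()
  # one processed read per Val copy, bases taken from the reference
  mk_read <- function(gene_row, id) {
    g <- ref$genes[gene_row, ]
    s <- Biostrings::subseq(ref$genome[[g$chrom]], g$mature_start + 1L,
                            g$mature_end)
    tibble::tibble(read_id = id, type_key = g$type_key, gene_id = g$gene_id,
                   gstart = g$mature_start, gend = g$mature_end,
                   cigar = "76M", seq = as.character(s),
                   is_reverse = g$strand == "-", stage = "processed")
  }
  assigned <- dplyr::bind_rows(mk_read(1, "p"), mk_read(2, "m"))
  pu <- build_pileups(assigned, ref$genes, window = 3L)
  at0 <- pu[pu$pos == 0L, ]
  # both copies share the sense mature sequence, so both report sense A at
  # residue 34: the minus-strand read's genomic T is complemented
  expect_equal(at0$A, c(1L, 1L))
  expect_equal(at0$G + at0$C + at0$T, c(0L, 0L))
  at1 <- pu[pu$pos == 1L, ]
  expect_equal(at1$A, c(1L, 1L))  # Val-AAC: residue 35 is A
  # window restricted to +/- 3 nt
  expect_true(all(abs(pu$pos) <= 3L))
})

test_that("aggregation sums counts and is order-independent", {
  cfg <- sim_config(n_types = 2L, depth_per_copy = 50, seed = 71)
  ds <- sim_and_analyze(cfg, min_depth = 1L)
  genes <- build_genome(cfg)$genes
  copies <- build_pileups(ds$analysis$assigned, genes, window = 10L)
  agg <- aggregate_pileups(copies)
  # total counts conserved
  expect_equal(sum(agg$A + agg$C + agg$G + agg$T),
               sum(copies$A + copies$C + copies$G + copies$T))
  # aggregating an aggregate is the identity
  agg2 <- aggregate_pileups(agg)
  expect_equal(dplyr::arrange(tibble::as_tibble(agg2), type_key, stage, pos)$G,
               dplyr::arrange(tibble::as_tibble(agg), type_key, stage, pos)$G)
  # splitting the copies and aggregating in either order gives the same sums
  half <- unique(copies$gene_id)[1]
  a <- aggregate_pileups(dplyr::bind_rows(
    copies[copies$gene_id == half, ], copies[copies$gene_id != half, ]))
  expect_equal(dplyr::arrange(tibble::as_tibble(a), type_key, stage, pos)$A,
               dplyr::arrange(tibble::as_tibble(agg), type_key, stage, pos)$A)
})

test_that("composition rows are fractions of depth, missing when depth 0", {
  pu <- tibble::tibble(gene_id = "g", type_key = "Val-AAC",
                       stage = "processed", condition = NA_character_,
                       pos = 0L, A = 30L, C = 0L, G = 70L, T = 0L)
  comp <- composition_at(pu, 0L)
  expect_equal(comp$frac_A, 0.30)
  expect_equal(comp$frac_G, 0.70)
  expect_equal(comp$depth, 100L)
  expect_equal(comp$frac_A + comp$frac_C + comp$frac_G + comp$frac_T, 1)
  # position nobody covers: depth 0 and NA fractions, not zeros
  comp9 <- composition_at(pu, 9L)
  expect_equal(comp9$depth, 0L)
  expect_true(is.na(comp9$frac_A))
  single <- composition_at(dplyr::mutate(pu, A = 1L, G = 0L), 0L)
  expect_equal(single$frac_A, 1)
})

test_that("editing fraction is G/(A+G) with C/T reported but excluded", {
  pu <- tibble::tibble(type_key = "Val-AAC", stage = "processed",
                       condition = NA_character_, pos = 0L,
                       A = 30L, C = 2L, G = 70L, T = 1L)
  ef <- editing_fraction(pu)
  expect_equal(ef$editing_fraction, 0.70)
  expect_equal(ef$n_C, 2L)
  ef1 <- editing_fraction(dplyr::mutate(pu, A = 0L, G = 50L))
  expect_equal(ef1$editing_fraction, 1.0)
  ef_na <- editing_fraction(dplyr::mutate(pu, A = 0L, G = 0L))
  expect_true(is.na(ef_na$editing_fraction))
})

test_that("pipeline reproduces truth counts exactly without sequencing
           error", {
  cfg <- sim_config(n_types = 4L, depth_per_copy = 120, error_rate = 0,
                    seed = 81)
  ds <- sim_and_analyze(cfg)
  ts <- truth_summary(ds$truth)
  pc <- ds$analysis$pileups %>%
    dplyr::filter(.data$pos %in% c(0L, 1L, 3L)) %>%
    dplyr::mutate(residue = c(`0` = 34L, `1` = 35L,
                              `3` = 37L)[as.character(.data$pos)]) %>%
    dplyr::select("type_key", "stage", "residue", "A", "C", "G", "T") %>%
    dplyr::arrange(.data$type_key, .data$stage, .data$residue)
  tt <- ts %>%
    dplyr::select("type_key", "stage", "residue", "A", "C", "G", "T") %>%
    dplyr::arrange(.data$type_key, .data$stage, .data$residue)
  expect_equal(as.data.frame(pc), as.data.frame(tt), ignore_attr = TRUE)
})

test_that("editing fractions recover the simulated editing probability", {
  # error-adjusted expectation: an emitted G survives with 1-eps and an A
  # turns into G with eps/3, so
  # E[G/(A+G)] ~ (pi(1-eps) + (1-pi)eps/3) / ((1-2eps/3) adjusted margins)
  eps <- 0.005
  adj <- function(pi) {
    pg <- pi * (1 - eps) + (1 - pi) * eps / 3
    pa <- (1 - pi) * (1 - eps) + pi * eps / 3
    pg / (pg + pa)
  }
  cfg <- function(seed) sim_config(n_types = 2L, copies_per_type = 2L,
                                   depth_per_copy = 2400, error_rate = eps,
                                   seed = seed)
  devs <- replicate(4, NULL, simplify = FALSE)
  for (i in seq_along(devs)) {
    ds <- sim_and_analyze(cfg(900 + i))
    ef <- editing_fraction(ds$analysis$pileups)
    pi_eff <- adj(ifelse(ef$stage == "precursor", 0.2, 0.8))
    devs[[i]] <- ef$editing_fraction - pi_eff
  }
  expect_lt(mean(abs(unlist(devs))), 0.02)
})

test_that("editing fraction increases with the simulated editing
           probability", {
  mk <- function(pi) {
    cfg <- sim_config(n_types = 1L, copies_per_type = 2L,
                      depth_per_copy = 300, pi_precursor = pi,
                      pi_processed = pi, error_rate = 0, seed = 55)
    ds <- sim_and_analyze(cfg)
    ef <- editing_fraction(aggregate_pileups(ds$analysis$pileups,
                                             by_stage = FALSE))
    ef$editing_fraction
  }
  expect_lt(mk(0.2), mk(0.5))
  expect_lt(mk(0.5), mk(0.8))
})

test_that("position-37 readout separates precursor G from processed G+T on
           Ala-AGC", {
  pu <- tibble::tibble(type_key = "Ala-AGC", stage = "processed",
                       condition = NA_character_, pos = 3L,
                       A = 50L, C = 0L, G = 30L, T = 20L)
  p37 <- position37_composition(pu)
  expect_equal(c(p37$frac_A, p37$frac_G, p37$frac_T), c(0.5, 0.3, 0.2))
  cfg <- sim_config(n_types = 1L, depth_per_copy = 700, error_rate = 0,
                    seed = 91)  # type 1 is Ala-AGC
  ds <- sim_and_analyze(cfg)
  p37 <- position37_composition(ds$analysis$pileups) %>%
    dplyr::filter(.data$type_key == "Ala-AGC")
  pre <- p37[p37$stage == "precursor", ]
  pro <- p37[p37$stage == "processed", ]
  # precursor: G37 present, T37 absent (modification not yet methylated)
  expect_equal(pre$frac_T, 0)
  expect_gt(pre$frac_G, 0.2)
  # processed: T37 recovers its simulated probability within 3 binomial SE
  se <- sqrt(0.4 * 0.6 / pro$depth)
  expect_lt(abs(pro$frac_T - 0.4), 3 * se)
  se_g <- sqrt(0.3 * 0.7 / pro$depth)
  expect_lt(abs(pro$frac_G - 0.3), 3 * se_g)
})

test_that("background A-to-G profile isolates residue 34 from error", {
  cfg <- sim_config(n_types = 2L, depth_per_copy = 400, error_rate = 0,
                    seed = 93)
  ds <- sim_and_analyze(cfg)
  genes <- build_genome(cfg)$genes
  genome <- build_genome(cfg)$genome
  bp <- background_profile(ds$analysis$pileups, genes, genome)
  # only reference-A positions are profiled
  expect_true(all(bp$ref_base == "A"))
  # without sequencing error the background is exactly zero off residue 34
  # (residue 37 of Ala-AGC carries its own modification and is excluded)
  bg <- bp[!bp$is_pos34 & !(bp$type_key == "Ala-AGC" & bp$pos == 3L), ]
  expect_true(all(bg$prop_AG[!is.na(bg$prop_AG)] == 0))
  at34 <- bp[bp$is_pos34, ]
  expect_true(all(at34$prop_AG > 0))
  summ <- attr(bp, "background_summary")
  expect_true(all(c("max_background", "mean_background") %in% names(summ)))
})
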