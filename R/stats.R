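# Fisher exact tests on A/G contingency tables, Benjamini-Hochberg
# adjustment across the tested tRNA-type family, and star annotation.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Rows are groups (precursor/processed or control/knockdown), columns are
#' bases (A, G). The two-sided p-value sums hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (ties included within relative tolerance
#' 1e-7, the common convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled row-wise.
#' @return Two-sided p-value; `1` for tables with a zero margin, `NA` for
#'   the all-zero table.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) {
    stopifnot(length(tab) == 4L)
    tab <- matrix(tab, nrow = 2L, byrow = TRUE)
  }
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != floor(tab)) || any(is.na(tab))) {
    stop("contingency table must contain non-negative integer counts")
  }
  if (sum(tab) == 0) {
    return(NA_real_)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with the `m` non-missing p-values sorted
#' ascending, `q_(i) = min(1, min_{j >= i} p_(j) * m / j)`, returned in the
#' input order. Missing values propagate as missing and do not count
#' towards `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Significance stars from adjusted p-values
#'
#' Thresholds 0.05 / 0.01 / 0.001 (`*`, `**`, `***`), `ns` otherwise.
#'
#' @param q numeric vector of adjusted p-values.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(q) {
  dplyr::case_when(is.na(q) ~ NA_character_,
                   q <= 0.001 ~ "***",
                   q <= 0.01 ~ "**",
                   q <= 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Compare editing fractions between two groups of estimates
#'
#' One two-sided Fisher exact test per tRNA type on the 2x2 table of A/G
#' counts at residue 34 (rows: group A, group B), BH adjustment across the
#' family of types tested together (one figure-equivalent comparison), and
#' direction of the change in group B relative to group A. A type absent
#' from one group yields a missing comparison that does not enter the BH
#' family.
#'
#' @param group_a,group_b tibbles with `type_key`, `n_A`, `n_G` (e.g. from
#'   [editing_fraction()]); group A is the baseline (precursor, or
#'   control).
#' @param labels length-2 labels for the two groups, used in column names.
#' @param family optional character vector restricting and ordering the
#'   tested family of type keys (default: union of both groups).
#' @return Tibble with per-type counts and fractions for both groups,
#'   `p_value`, `q_value`, `direction` (`increased`/`reduced`/`unchanged`
#'   in group B vs group A) and `stars`.
#' @export
compare_editing <- function(group_a, group_b, labels = c("A", "B"),
                            family = NULL) {
  pick <- function(d, suffix) {
    d <- tibble::as_tibble(d)[, c("type_key", "n_A", "n_G")]
    names(d) <- c("type_key", paste0(c("n_A_", "n_G_"), suffix))
    d
  }
  if (is.null(family)) {
    family <- sort(union(group_a$type_key, group_b$type_key))
  }
  out <- tibble::tibble(type_key = family) %>%
    dplyr::left_join(pick(group_a, labels[1]), by = "type_key") %>%
    dplyr::left_join(pick(group_b, labels[2]), by = "type_key")
  na1 <- out[[paste0("n_A_", labels[1])]]
  ng1 <- out[[paste0("n_G_", labels[1])]]
  na2 <- out[[paste0("n_A_", labels[2])]]
  ng2 <- out[[paste0("n_G_", labels[2])]]
  complete <- !(is.na(na1) | is.na(ng1) | is.na(na2) | is.na(ng2))
  out$p_value <- NA_real_
  out$p_value[complete] <- vapply(which(complete), function(i) {
    fisher_exact_2x2(matrix(c(na1[i], ng1[i], na2[i], ng2[i]),
                            nrow = 2L, byrow = TRUE))
  }, numeric(1))
  out$q_value <- bh_adjust(out$p_value)
  f1 <- ng1 / (na1 + ng1)
  f2 <- ng2 / (na2 + ng2)
  out[[paste0("fraction_", labels[1])]] <- f1
  out[[paste0("fraction_", labels[2])]] <- f2
  out$direction <- dplyr::case_when(
    !complete | is.na(f1) | is.na(f2) ~ NA_character_,
    f2 > f1 ~ "increased",
    f2 < f1 ~ "reduced",
    TRUE ~ "unchanged")
  out$stars <- significance_stars(out$q_value)
  out
}

#' Wilson score interval for an editing fraction
#'
#' Convenience interval for `n_G` successes out of `n_A + n_G` A/G calls;
#' not part of the testing procedure.
#'
#' @param n_G,n_A counts of G and A calls at residue 34.
#' @param conf confidence level.
#' @return Tibble `estimate`, `lower`, `upper`.
#' @export
wilson_interval <- function(n_G, n_A, conf = 0.95) {
  n <- n_G + n_A
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- n_G / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  tibble::tibble(estimate = p,
                 lower = pmax(0, centre - half),
                 upper = pmin(1, centre + half))
}
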