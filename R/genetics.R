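# Instrument handling: SNP panel definitions, allele-frequency and
# Hardy-Weinberg diagnostics, and weighted genetic risk scores (GRS).

#' The four-SNP vitamin-D instrument panel
#'
#' Two synthesis SNPs (DHCR7/NADSYN1-rs12785878, CYP2R1-rs10741657), one
#' transport SNP (GC-rs2282679) and one catabolism SNP (CYP24A1-rs6013897).
#' The transport and catabolism SNPs together form the "metabolism" panel;
#' all four form the "combined" panel.
#'
#' `grs_weight` is the external per-allele weight (nmol/L scale) from a prior
#' study; such weights are a required configuration input in real analyses,
#' and the equal-weight default of 1.0 is provided for testing and
#' simulation work only. `coded_allele` records which direction the 0/1/2
#' coding counts: `"vitd_increasing"` means each counted allele raises
#' 25(OH)D.
#'
#' @param weights per-SNP external GRS weights (positive, nmol/L scale).
#' @return a `data.frame` with columns `rsid`, `gene`, `functional_class`,
#'   `coded_allele`, `grs_weight`.
#' @export
default_snp_panel <- function(weights = c(1, 1, 1, 1)) {
  if (length(weights) != 4L || any(!is.finite(weights) | weights <= 0))
    stop_("weights must be four finite positive numbers")
  data.frame(
    rsid = c("rs12785878", "rs10741657", "rs2282679", "rs6013897"),
    gene = c("DHCR7/NADSYN1", "CYP2R1", "GC", "CYP24A1"),
    functional_class = c("synthesis", "synthesis", "transport", "catabolism"),
    coded_allele = "vitd_increasing",
    grs_weight = weights,
    stringsAsFactors = FALSE)
}

#' Select the SNPs of a named GRS panel
#'
#' @param panel a SNP panel data.frame.
#' @param grs one of `"synthesis"` (the two synthesis SNPs),
#'   `"metabolism"` (transport + catabolism) or `"combined"` (all).
#' @return the subset of panel rows.
#' @export
panel_subset <- function(panel, grs = c("combined", "synthesis", "metabolism")) {
  grs <- match.arg(grs)
  keep <- switch(grs,
    combined   = rep(TRUE, nrow(panel)),
    synthesis  = panel$functional_class == "synthesis",
    metabolism = panel$functional_class %in% c("transport", "catabolism"))
  panel[keep, , drop = FALSE]
}

#' Effect-allele frequency from genotype counts
#'
#' @param counts integer vector `c(n0, n1, n2)` of individuals carrying 0, 1
#'   or 2 effect alleles.
#' @return the allele frequency `(2*n2 + n1) / (2 * sum(counts))`.
#' @export
allele_frequency <- function(counts) {
  if (length(counts) != 3L || any(!is.finite(counts) | counts < 0))
    stop_("counts must be three non-negative numbers (n0, n1, n2)")
  if (sum(counts) == 0) stop_("all genotype counts are zero")
  (2 * counts[3] + counts[2]) / (2 * sum(counts))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts against
#' Hardy-Weinberg expectations at the estimated allele frequency. Deviation
#' suggests genotyping error or population structure; instrument SNPs are
#' expected to pass (p > 0.05).
#'
#' @param counts integer vector `c(n0, n1, n2)`.
#' @return a list with `chi2`, `p`, `allele_freq`, `defined` (FALSE for a
#'   monomorphic marker, where the test is undefined and `chi2`/`p` are NA).
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(!is.finite(counts) | counts < 0))
    stop_("counts must be three non-negative numbers (n0, n1, n2)")
  n <- sum(counts)
  if (n < 1) stop_("total genotype count must be >= 1")
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p <= 0 || p >= 1)
    return(list(chi2 = NA_real_, p = NA_real_, allele_freq = p, defined = FALSE))
  expected <- n * genotype_probabilities(p)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       allele_freq = p, defined = TRUE)
}

#' Weighted genetic risk score
#'
#' Additive scoring: the per-person score is `sum_j w_j * g_j` over the panel
#' SNPs, where `g_j` is the 0/1/2 count of the analysis allele. With
#' `orientation = "decreasing"` (the default used throughout the MR layer)
#' alleles are counted in the 25(OH)D-*decreasing* direction — genotypes
#' coded on a vitamin-D-increasing allele are recoded `g -> 2 - g` — so that
#' "per 1 unit higher GRS" aligns with lower vitamin D and causal odds
#' ratios are naturally expressed per 25 nmol/L *decrease* in 25(OH)D.
#'
#' A missing genotype gives a missing score for that person; there is no
#' silent zero-fill.
#'
#' @param genotypes a cohort data.frame with `snp_<rsid>` columns, or a
#'   matrix whose columns are named by rsid.
#' @param panel SNP panel rows to score (see [panel_subset()]).
#' @param orientation count alleles in the 25(OH)D-`"decreasing"` (default)
#'   or `"increasing"` direction.
#' @return numeric vector of per-person scores.
#' @export
compute_grs <- function(genotypes, panel,
                        orientation = c("decreasing", "increasing")) {
  orientation <- match.arg(orientation)
  score <- 0
  for (i in seq_len(nrow(panel))) {
    rsid <- panel$rsid[i]
    col <- if (paste0("snp_", rsid) %in% colnames(genotypes))
      paste0("snp_", rsid) else rsid
    if (!col %in% colnames(genotypes))
      stop_("genotype column for SNP ", rsid, " not found")
    gv <- genotypes[[col]] %||% genotypes[, col]
    if (any(!is.na(gv) & !gv %in% 0:2))
      stop_("genotype values for ", rsid, " must be 0, 1 or 2")
    coded_increasing <- panel$coded_allele[i] == "vitd_increasing"
    flip <- (orientation == "decreasing") == coded_increasing
    if (flip) gv <- 2 - gv
    score <- score + panel$grs_weight[i] * gv
  }
  score
}

#' Flip the allele coding of one SNP
#'
#' Recodes genotypes `g -> 2 - g` for the given SNP and flips the panel's
#' `coded_allele` direction accordingly. Because every scoring and estimation
#' routine resolves orientation explicitly, all instrumental-variable
#' estimates are invariant under this flip.
#'
#' @param cohort a cohort data.frame with a `snp_<rsid>` column.
#' @param panel the SNP panel.
#' @param rsid SNP to flip.
#' @return a list with elements `cohort` and `panel`, recoded.
#' @export
flip_snp_coding <- function(cohort, panel, rsid) {
  col <- paste0("snp_", rsid)
  if (!col %in% names(cohort)) stop_("no genotype column ", col)
  i <- match(rsid, panel$rsid)
  if (is.na(i)) stop_("SNP ", rsid, " not in panel")
  cohort[[col]] <- 2L - cohort[[col]]
  panel$coded_allele[i] <- if (panel$coded_allele[i] == "vitd_increasing")
    "vitd_decreasing" else "vitd_increasing"
  list(cohort = cohort, panel = panel)
}

#' Read / write a SNP panel as TSV
#'
#' Columns: `rsid`, `gene`, `class` (synthesis/transport/catabolism),
#' `coded_allele` (vitd_increasing/vitd_decreasing), `weight`.
#'
#' @param path file path.
#' @param panel a SNP panel data.frame.
#' @return `read_snp_panel()` returns the panel data.frame.
#' @export
read_snp_panel <- function(path) {
  x <- utils::read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("rsid", "gene", "class", "coded_allele", "weight")
  if (!all(need %in% names(x)))
    stop_("SNP panel file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(x$rsid)) stop_("duplicate rsid in SNP panel")
  if (any(!is.finite(x$weight) | x$weight <= 0))
    stop_("GRS weights must be finite and positive")
  data.frame(rsid = x$rsid, gene = x$gene, functional_class = x$class,
             coded_allele = x$coded_allele, grs_weight = x$weight,
             stringsAsFactors = FALSE)
}

#' @rdname read_snp_panel
#' @export
write_snp_panel <- function(panel, path) {
  out <- data.frame(rsid = panel$rsid, gene = panel$gene,
                    class = panel$functional_class,
                    coded_allele = panel$coded_allele,
                    weight = panel$grs_weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
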