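# cohort allele-frequency and association statistics

#' Construct a cohort allele-count table
#'
#' Per-group variant and total allele counts (2 alleles per diploid
#' subject); optional carrier/subject counts.
#'
#' @param group character group labels.
#' @param variant_alleles,total_alleles nonnegative counts with
#'   `variant_alleles <= total_alleles`.
#' @param carriers,subjects optional per-group carrier and subject
#'   counts.
#' @return tibble of class `cohort_table`.
#' @export
cohort_table <- function(group, variant_alleles, total_alleles,
                         carriers = NA_integer_, subjects = NA_integer_) {
  if (any(variant_alleles < 0) || any(total_alleles <= 0) ||
      any(variant_alleles > total_alleles))
    stop_param("need 0 <= variant_alleles <= total_alleles, total > 0")
  out <- tibble::tibble(group = as.character(group),
                        variant_alleles = as.integer(variant_alleles),
                        total_alleles = as.integer(total_alleles),
                        carriers = as.integer(carriers),
                        subjects = as.integer(subjects))
  class(out) <- c("cohort_table", class(tibble::tibble()))
  out
}

#' Variant allele frequency as a percentage
#'
#' `100 * variant_alleles / total_alleles`, unrounded (the published
#' display rounds to about 3 significant figures, e.g. 15/1,696
#' alleles prints as 0.884%; rounding is left to formatting).
#'
#' @param variant_alleles,total_alleles counts; alternatively pass a
#'   one-row [cohort_table()] as `variant_alleles`.
#' @return percentage (unrounded).
#' @export
allele_frequency <- function(variant_alleles, total_alleles = NULL) {
  if (inherits(variant_alleles, "cohort_table")) {
    tab <- variant_alleles
    if (nrow(tab) != 1L) stop_param("pass a one-row cohort table")
    total_alleles <- tab$total_alleles
    variant_alleles <- tab$variant_alleles
  }
  if (is.null(total_alleles) || total_alleles <= 0)
    stop_param("total_alleles must be positive")
  if (variant_alleles < 0 || variant_alleles > total_alleles)
    stop_param("variant_alleles out of range")
  100 * variant_alleles / total_alleles
}

#' Case fraction as a percentage
#'
#' `100 * cases_with_variant / total_cases`, unrounded; the counting
#' unit (alleles vs index cases) is whatever the caller supplies,
#' e.g. 15 variant alleles over 848 cases prints as 1.769%.
#'
#' @param cases_with_variant,total_cases counts.
#' @return percentage (unrounded).
#' @export
case_frequency <- function(cases_with_variant, total_cases) {
  if (total_cases <= 0) stop_param("total_cases must be positive")
  if (cases_with_variant < 0) stop_param("negative count")
  100 * cases_with_variant / total_cases
}

#' Case-control allele association (Fisher's exact test)
#'
#' Builds the 2x2 allele table
#' (case variant, case non-variant; control variant, control
#' non-variant), computes the two-sided Fisher exact p-value
#' (probability mass of all tables with fixed margins whose
#' probability does not exceed the observed table's), and the
#' sample odds ratio as the cross-product. With a zero cell the
#' Haldane-Anscombe 0.5 correction is applied to the odds ratio only,
#' and flagged.
#'
#' @param case_table,control_table one-row [cohort_table()]s (or any
#'   lists with `variant_alleles` and `total_alleles`).
#' @return list of class `association_result`: `odds_ratio`,
#'   `p_two_sided`, `test`, `table` (2x2 matrix),
#'   `haldane_corrected`.
#' @export
association_test <- function(case_table, control_table) {
  a <- case_table$variant_alleles
  b <- case_table$total_alleles - a
  c_ <- control_table$variant_alleles
  d <- control_table$total_alleles - c_
  if (length(a) != 1L || length(c_) != 1L)
    stop_param("pass one-row tables")
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("variant", "non_variant")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_param("degenerate table: zero margin")
  p <- stats::fisher.test(tab)$p.value
  zero_cell <- any(tab == 0)
  or <- if (zero_cell)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  else (a * d) / (b * c_)
  structure(list(odds_ratio = or, p_two_sided = min(p, 1),
                 test = "fisher.exact", table = tab,
                 haldane_corrected = zero_cell),
            class = "association_result")
}

#' Construct a plasma-glycine panel
#'
#' @param subject subject identifiers.
#' @param group `"carrier"` or `"control"` per subject.
#' @param age_class `"preadolescent"`, `"adolescent"` or `"adult"`.
#' @param concentration plasma glycine concentrations (positive; uM
#'   or kit units).
#' @return tibble of class `glycine_panel`.
#' @export
glycine_panel <- function(subject, group, age_class, concentration) {
  if (!all(group %in% c("carrier", "control")))
    stop_param("group must be carrier or control")
  if (!all(age_class %in% c("preadolescent", "adolescent", "adult")))
    stop_param("unknown age class")
  if (any(concentration <= 0))
    stop_param("concentrations must be positive")
  out <- tibble::tibble(subject = as.character(subject),
                        group = group, age_class = age_class,
                        concentration = as.numeric(concentration))
  class(out) <- c("glycine_panel", class(tibble::tibble()))
  out
}

#' Compare plasma glycine between carriers and controls
#'
#' Unpaired two-sided Student's t test on carrier vs control
#' concentrations, optionally restricted to one age stratum (the
#' published comparison is within adolescents).
#'
#' @param panel a [glycine_panel()].
#' @param stratum optional age class to restrict to.
#' @param var_equal pooled-variance t test (default TRUE).
#' @return list: `statistic` (t), `df`, `p_value`, group means, `fit`.
#' @export
glycine_group_compare <- function(panel, stratum = NULL,
                                  var_equal = TRUE) {
  stopifnot(inherits(panel, "glycine_panel") || is.data.frame(panel))
  d <- panel
  if (!is.null(stratum)) d <- d[d$age_class == stratum, ]
  x <- d$concentration[d$group == "carrier"]
  y <- d$concentration[d$group == "control"]
  if (length(x) < 2L || length(y) < 2L)
    stop_param("need >= 2 observations per group in the stratum")
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_carrier = mean(x),
       mean_control = mean(y), fit = ht)
}
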