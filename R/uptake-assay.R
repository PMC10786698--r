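# glycine-uptake rates, percent-of-WT and membrane normalization

#' Construct an uptake plate
#'
#' Per-well radiolabeled-glycine uptake measurements.
#'
#' @param well well identifiers.
#' @param genotype genotype label per well (e.g. `"WT"`, a variant
#'   name, `"vector"`).
#' @param nmol glycine quantity taken up (nmol, >= 0).
#' @param time_min incubation time (min, > 0).
#' @param protein_mg protein mass (mg, > 0).
#' @param replicate replicate id.
#' @return tibble of class `uptake_plate`.
#' @export
uptake_plate <- function(well, genotype, nmol, time_min, protein_mg,
                         replicate = seq_along(well)) {
  if (any(nmol < 0)) stop_param("uptake quantity must be >= 0")
  if (any(time_min <= 0)) stop_param("incubation time must be positive")
  if (any(protein_mg <= 0)) stop_param("protein mass must be positive")
  out <- tibble::tibble(well = as.character(well),
                        genotype = as.character(genotype),
                        nmol = as.numeric(nmol),
                        time_min = as.numeric(time_min),
                        protein_mg = as.numeric(protein_mg),
                        replicate = replicate)
  class(out) <- c("uptake_plate", class(tibble::tibble()))
  out
}

#' Per-well uptake rate
#'
#' `nmol / (time_min * protein_mg)` — nanomoles per minute per
#' milligram of protein, the assay's standard rate unit.
#'
#' @param plate an [uptake_plate()] (or any data frame with columns
#'   `nmol`, `time_min`, `protein_mg`).
#' @return the plate with a `rate_nmol_min_mg` column appended.
#' @export
uptake_rate <- function(plate) {
  stopifnot(is.data.frame(plate),
            all(c("nmol", "time_min", "protein_mg") %in% names(plate)))
  if (any(plate$time_min <= 0) || any(plate$protein_mg <= 0))
    stop_param("nonpositive time or protein")
  plate$rate_nmol_min_mg <- plate$nmol / (plate$time_min * plate$protein_mg)
  plate
}

#' Convert scintillation counts to nmol
#'
#' Optional helper for plates recorded as disintegrations per minute:
#' `nmol = dpm / (2.22e6 * specific_activity_ci_mmol)` scaled by the
#' counting efficiency (2.22e6 dpm per uCi; 1 Ci/mmol = 1 uCi/nmol).
#'
#' @param dpm disintegrations per minute.
#' @param specific_activity_ci_mmol specific activity (Ci/mmol);
#'   tritiated glycine assays commonly use 60.
#' @param efficiency counting efficiency in (0, 1]; default 1 assumes
#'   dpm already efficiency-corrected.
#' @return nmol.
#' @export
dpm_to_nmol <- function(dpm, specific_activity_ci_mmol = 60,
                        efficiency = 1) {
  check_scalar(specific_activity_ci_mmol, "specific_activity",
               lower = 0, closed_lower = FALSE)
  check_scalar(efficiency, "efficiency", lower = 0, upper = 1,
               closed_lower = FALSE)
  (dpm / efficiency) / (2.22e6 * specific_activity_ci_mmol)
}

#' Uptake as percent of wild type
#'
#' Per-genotype mean rate expressed as a percentage of the mean WT
#' rate; the WT group itself maps to 100%.
#'
#' @param plate an [uptake_plate()]; rates are computed if absent.
#' @param wt_label genotype label of the wild-type group; default
#'   `"WT"`.
#' @return tibble (genotype, n, mean_rate, percent_of_wt).
#' @export
percent_of_wt <- function(plate, wt_label = "WT") {
  if (!"rate_nmol_min_mg" %in% names(plate)) plate <- uptake_rate(plate)
  if (!wt_label %in% plate$genotype)
    stop_param("no wells labeled ", wt_label)
  means <- tapply(plate$rate_nmol_min_mg, plate$genotype, mean)
  wt <- means[[wt_label]]
  if (wt <= 0) stop_param("mean WT rate must be positive")
  tibble::tibble(genotype = names(means),
                 n = as.integer(table(plate$genotype)[names(means)]),
                 mean_rate = as.numeric(means),
                 percent_of_wt = 100 * as.numeric(means) / wt)
}

#' Membrane-level-normalized uptake
#'
#' Divides each genotype's percent-of-WT uptake by its relative
#' cytomembrane protein level (WT = 1). A variant at 40% uptake with
#' 0.4 relative membrane level normalizes to 100% — parity with WT at
#' the per-transporter level.
#'
#' @param pct table from [percent_of_wt()].
#' @param membrane named numeric vector of relative membrane levels
#'   (> 0), one per genotype in `pct`.
#' @return `pct` with a `membrane_level` and
#'   `membrane_normalized_pct` column.
#' @export
membrane_normalized_uptake <- function(pct, membrane) {
  missing <- setdiff(pct$genotype, names(membrane))
  if (length(missing))
    stop_param("missing membrane level for: ",
               paste(missing, collapse = ", "))
  lev <- membrane[pct$genotype]
  if (any(lev <= 0)) stop_param("membrane levels must be positive")
  pct$membrane_level <- as.numeric(lev)
  pct$membrane_normalized_pct <- pct$percent_of_wt / pct$membrane_level
  pct
}

#' One-way ANOVA with per-variant contrasts against WT
#'
#' One-way ANOVA across genotypes on per-well rates, followed by
#' per-variant vs WT pairwise t tests on the ANOVA's pooled residual
#' variance (Dunnett-style comparison to control), with a declared
#' multiplicity adjustment recorded in the output.
#'
#' @param plate an [uptake_plate()]; rates computed if absent.
#' @param wt_label wild-type genotype label.
#' @param p_adjust_method method for [stats::p.adjust()]; default
#'   `"holm"`.
#' @return list: `anova` (F, dfs, p), `contrasts` tibble (genotype,
#'   estimate, t, df, p, p_adjusted), `p_adjust_method`, `fit`.
#' @export
compare_to_wt <- function(plate, wt_label = "WT",
                          p_adjust_method = "holm") {
  if (!"rate_nmol_min_mg" %in% names(plate)) plate <- uptake_rate(plate)
  if (!wt_label %in% plate$genotype) stop_param("no WT group")
  counts <- table(plate$genotype)
  if (length(counts) < 2L || any(counts < 2L))
    stop_param("need >= 2 genotypes with >= 2 replicates each")
  g <- factor(plate$genotype)
  fit <- stats::aov(plate$rate_nmol_min_mg ~ g)
  tab <- summary(fit)[[1]]
  mse <- tab$`Mean Sq`[2]; df_res <- tab$Df[2]
  means <- tapply(plate$rate_nmol_min_mg, g, mean)
  ns <- table(g)
  others <- setdiff(names(means), wt_label)
  est <- means[others] - means[[wt_label]]
  se <- sqrt(mse * (1 / as.numeric(ns[others]) + 1 / ns[[wt_label]]))
  tstat <- as.numeric(est) / se
  p <- 2 * stats::pt(-abs(tstat), df_res)
  contrasts <- tibble::tibble(
    genotype = others, estimate = as.numeric(est), t = tstat,
    df = df_res, p = p,
    p_adjusted = stats::p.adjust(p, method = p_adjust_method))
  list(anova = list(F = tab$`F value`[1], df = tab$Df,
                    p_value = tab$`Pr(>F)`[1]),
       contrasts = contrasts, p_adjust_method = p_adjust_method,
       fit = fit)
}
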