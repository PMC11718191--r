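## Reduction of raw assay readouts: ultrafiltration / equilibrium-dialysis
## free fractions, radioligand saturation binding capacity, Pfaffl relative
## qPCR quantification, and unit conversions.

#' Free fraction from ultrafiltration counts
#'
#' Percentage free glucocorticoid as the cpm ratio of filtrate to
#' retentate, `100 * filtrate / retentate`. The retentate aliquot is
#' removed before the column is loaded, so it approximates total (free
#' plus bound) tracer and the ratio approximates free/total. When a
#' background is supplied it is subtracted from both counts first.
#' Values above 100 are clipped to 100 with a warning.
#'
#' @param cpm_filtrate Filtrate counts (cpm, `>= 0`).
#' @param cpm_retentate Retentate counts (cpm); must be positive after
#'   background subtraction.
#' @param background_cpm Optional background counts subtracted from both.
#' @return Free fraction (%), in `[0, 100]`.
#' @export
#' @examples
#' ultrafiltration_free_fraction(500, 10000)                  # 5 %
#' ultrafiltration_free_fraction(500, 10000, background_cpm = 100)  # 4.04 %
ultrafiltration_free_fraction <- function(cpm_filtrate, cpm_retentate,
                                          background_cpm = 0) {
  check_scalar(cpm_filtrate, "cpm_filtrate", min = 0)
  check_scalar(cpm_retentate, "cpm_retentate", min = 0)
  check_scalar(background_cpm, "background_cpm", min = 0)
  filt <- max(cpm_filtrate - background_cpm, 0)
  ret <- cpm_retentate - background_cpm
  if (ret <= 0)
    stop("retentate counts must be positive after background subtraction",
         call. = FALSE)
  ff <- 100 * filt / ret
  if (ff > 100) {
    warning("free fraction > 100%; clipped", call. = FALSE)
    ff <- 100
  }
  ff
}

#' Free fraction from equilibrium dialysis
#'
#' `100 * dialysate / serum` concentration ratio.
#'
#' @param conc_dialysate_nM Dialysate steroid concentration (nmol/L).
#' @param conc_serum_nM Serum steroid concentration (nmol/L, `> 0`).
#' @return Free fraction (%).
#' @export
#' @examples
#' dialysis_free_fraction(1, 20)  # 5 %
dialysis_free_fraction <- function(conc_dialysate_nM, conc_serum_nM) {
  check_scalar(conc_dialysate_nM, "conc_dialysate_nM", min = 0)
  check_scalar(conc_serum_nM, "conc_serum_nM", min = 0, strict_min = TRUE)
  100 * conc_dialysate_nM / conc_serum_nM
}

#' CBG binding capacity from a radioligand saturation assay
#'
#' Specific binding is total minus nonspecific counts; dividing by the
#' tracer specific activity gives bound steroid (fmol), which over the
#' assay volume is an in-assay bound concentration (fmol/uL = nmol/L).
#' Multiplying by the serum dilution factor (default 1:500) expresses the
#' capacity in nmol/L of undiluted serum. By default the capacity is
#' reported as assayed (tracer occupancy is not corrected for); supplying
#' `occupancy_kd_nM` divides by the fractional occupancy
#' `L / (Kd + L)` at the tracer concentration `tracer_nM` (2 nmol/L by
#' default) for sensitivity analyses.
#'
#' @param cpm_total Total binding counts (cpm).
#' @param cpm_nsb Nonspecific binding counts (cpm); must not exceed
#'   `cpm_total`.
#' @param specific_activity_cpm_per_fmol Tracer specific activity
#'   (cpm/fmol, `> 0`).
#' @param assay_volume_ul Assay volume (uL, `> 0`).
#' @param dilution_factor Serum fold-dilution; default 500.
#' @param occupancy_kd_nM Optional Kd (nmol/L) for occupancy correction.
#' @param tracer_nM Tracer concentration used for the correction; default 2.
#' @return Binding capacity (nmol/L undiluted serum).
#' @export
#' @examples
#' cbg_binding_capacity(8000, 500, 50, 100)                       # 750
#' cbg_binding_capacity(8000, 500, 50, 100, occupancy_kd_nM = 2)  # 1500
cbg_binding_capacity <- function(cpm_total, cpm_nsb,
                                 specific_activity_cpm_per_fmol,
                                 assay_volume_ul,
                                 dilution_factor = 500,
                                 occupancy_kd_nM = NULL,
                                 tracer_nM = 2) {
  check_scalar(cpm_total, "cpm_total", min = 0)
  check_scalar(cpm_nsb, "cpm_nsb", min = 0)
  check_scalar(specific_activity_cpm_per_fmol,
               "specific_activity_cpm_per_fmol", min = 0, strict_min = TRUE)
  check_scalar(assay_volume_ul, "assay_volume_ul", min = 0,
               strict_min = TRUE)
  check_scalar(dilution_factor, "dilution_factor", min = 1)
  if (cpm_total < cpm_nsb)
    stop("total counts below nonspecific counts: negative specific binding",
         call. = FALSE)
  specific <- cpm_total - cpm_nsb
  bound_fmol <- specific / specific_activity_cpm_per_fmol
  bound_nM <- bound_fmol / assay_volume_ul   # fmol/uL == nmol/L
  capacity <- bound_nM * dilution_factor
  if (!is.null(occupancy_kd_nM)) {
    check_scalar(occupancy_kd_nM, "occupancy_kd_nM", min = 0,
                 strict_min = TRUE)
    check_scalar(tracer_nM, "tracer_nM", min = 0, strict_min = TRUE)
    capacity <- capacity / (tracer_nM / (occupancy_kd_nM + tracer_nM))
  }
  capacity
}

#' qPCR sample (one gene, one condition, triplicate wells)
#'
#' @param gene Gene label.
#' @param role `"target"` or `"reference"` (housekeeping).
#' @param efficiency Amplification efficiency as fold per cycle (2.0 =
#'   100%); admissible range `(1, 2.2]`, covering calibrated efficiencies
#'   of 90-110%.
#' @param ct_triplicate Exactly three crossing-point values.
#' @return An object of class `qpcr_sample`.
#' @export
qpcr_sample <- function(gene, role = c("target", "reference"),
                        efficiency, ct_triplicate) {
  stopifnot(is.character(gene), length(gene) == 1L)
  role <- match.arg(role)
  check_scalar(efficiency, "efficiency", min = 1, max = 2.2,
               strict_min = TRUE)
  if (!is.numeric(ct_triplicate) || length(ct_triplicate) != 3L ||
      any(!is.finite(ct_triplicate)))
    stop("ct_triplicate must be exactly 3 finite crossing points",
         call. = FALSE)
  structure(list(gene = gene, role = role, efficiency = efficiency,
                 ct_triplicate = ct_triplicate),
            class = "qpcr_sample")
}

#' Triplicate quality control
#'
#' A qPCR triplicate passes when the n-1 sample standard deviation of its
#' crossing points is below 0.5 cycles.
#'
#' @param ct_triplicate Three crossing-point values.
#' @param sd_max Maximum admissible SD (cycles); default 0.5.
#' @return `TRUE` (pass) or `FALSE`, with attribute `"reason"` on failure.
#' @export
#' @examples
#' qc_triplicate(c(20.0, 20.4, 20.8))  # TRUE  (SD 0.4)
#' qc_triplicate(c(20.0, 20.6, 21.2))  # FALSE (SD 0.6)
qc_triplicate <- function(ct_triplicate, sd_max = 0.5) {
  if (!is.numeric(ct_triplicate) || length(ct_triplicate) != 3L)
    return(structure(FALSE, reason = "triplicate incomplete"))
  if (any(!is.finite(ct_triplicate)))
    return(structure(FALSE, reason = "missing or non-finite well"))
  s <- stats::sd(ct_triplicate)
  if (s < sd_max) TRUE
  else structure(FALSE, reason = sprintf("triplicate SD %.3g >= %.3g", s,
                                         sd_max))
}

#' Efficiency-corrected relative expression (Pfaffl method)
#'
#' Fold change of a target gene between a control and a treated sample,
#' normalised to one or more housekeeping genes:
#' `E_t^dCt_t / geomean_r(E_r^dCt_r)` with
#' `dCt = Ct(control) - Ct(treated)` and per-sample Ct the mean of its
#' triplicate. Multiple references are aggregated by the geometric mean,
#' the standard choice for multiplicative Ct-derived quantities. Every
#' triplicate must pass [qc_triplicate()].
#'
#' @param target_control,target_treated [qpcr_sample()] objects for the
#'   target gene under control and treated conditions.
#' @param references List of `list(control = , treated = )` pairs of
#'   [qpcr_sample()] objects for the housekeeping genes (at least one).
#' @return Fold change (dimensionless).
#' @export
#' @examples
#' tc <- qpcr_sample("Gilz", "target", 1.9, c(25, 25, 25))
#' tt <- qpcr_sample("Gilz", "target", 1.9, c(23, 23, 23))
#' r1 <- list(control = qpcr_sample("Hprt", "reference", 2, c(20.5, 20.5, 20.5)),
#'            treated = qpcr_sample("Hprt", "reference", 2, c(20, 20, 20)))
#' r2 <- list(control = qpcr_sample("18S", "reference", 2, c(10, 10, 10)),
#'            treated = qpcr_sample("18S", "reference", 2, c(10.5, 10.5, 10.5)))
#' pfaffl_ratio(tc, tt, list(r1, r2))  # 1.9^2 / 1 = 3.61
pfaffl_ratio <- function(target_control, target_treated, references) {
  stopifnot(inherits(target_control, "qpcr_sample"),
            inherits(target_treated, "qpcr_sample"))
  if (!is.list(references) || length(references) == 0L)
    stop("at least one housekeeping reference pair is required",
         call. = FALSE)
  all_samples <- c(list(target_control, target_treated),
                   unlist(references, recursive = FALSE))
  for (s in all_samples) {
    qc <- qc_triplicate(s$ct_triplicate)
    if (!isTRUE(qc))
      stop(sprintf("QC failure for gene '%s': %s", s$gene,
                   attr(qc, "reason")), call. = FALSE)
  }
  ct <- function(s) mean(s$ct_triplicate)
  dct_t <- ct(target_control) - ct(target_treated)
  num <- target_control$efficiency^dct_t
  ref_terms <- vapply(references, function(pair) {
    stopifnot(inherits(pair$control, "qpcr_sample"),
              inherits(pair$treated, "qpcr_sample"))
    pair$control$efficiency^(ct(pair$control) - ct(pair$treated))
  }, 0)
  num / exp(mean(log(ref_terms)))
}

#' Scalar unit conversions used in reporting
#'
#' Supported kinds: `"aat_mgdl_to_uM"` (alpha-1-antitrypsin, molecular
#' weight 52 kDa: mg/dL -> umol/L), `"insulin_pmolL_to_mUL"` (divide by
#' 6.945), and `"steroid_ngml_to_nM"` (requires `steroid`, one of
#' `"cortisol"` MW 362.46 or `"corticosterone"` MW 346.46 g/mol).
#'
#' @param value Numeric value(s) to convert.
#' @param kind Conversion kind (see above).
#' @param steroid Steroid name for `"steroid_ngml_to_nM"`.
#' @return Converted value(s).
#' @export
#' @examples
#' convert_units(565, "aat_mgdl_to_uM")       # 108.65 uM
#' convert_units(6.945, "insulin_pmolL_to_mUL")  # 1 mU/L
convert_units <- function(value,
                          kind = c("aat_mgdl_to_uM", "insulin_pmolL_to_mUL",
                                   "steroid_ngml_to_nM"),
                          steroid = c("cortisol", "corticosterone")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(value))
  switch(kind,
    # mg/dL -> g/L (x 0.01) -> mol/L (/ 52000 g/mol) -> umol/L (x 1e6)
    aat_mgdl_to_uM = value * 0.01 / 52000 * 1e6,
    insulin_pmolL_to_mUL = value / 6.945,
    steroid_ngml_to_nM = {
      steroid <- match.arg(steroid)
      mw <- c(cortisol = 362.46, corticosterone = 346.46)[[steroid]]
      value / mw * 1000
    })
}
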