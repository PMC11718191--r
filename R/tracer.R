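## Steady-state D4-cortisol tracer dilution: steadiness checks, clearance,
## whole-body rates of appearance, and arterio-venous net balances.

#' Tracer infusion protocol
#'
#' Design constants of a primed, constant-rate deuterated-cortisol
#' infusion. Defaults reproduce the study protocol: 0.92 umol priming
#' dose, 17.2 nmol/min infusion, sampling every 30 min from 60 to
#' 270 min, steadiness judged on the closed 180-270 min window with a
#' 5% CV threshold on the D4:cortisol and D4:D3 ratios.
#'
#' @param prime_umol Priming dose (umol).
#' @param infusion_nmol_min Constant infusion rate F (nmol/min, `> 0`).
#' @param duration_min Total infusion duration (min).
#' @param sampling_times_min Sampling schedule (min).
#' @param steady_window_min Closed interval `[lo, hi]` (min) within the
#'   infusion over which steadiness and rates are evaluated.
#' @param cv_threshold_pct CV threshold (%) for the steadiness criterion.
#' @return An object of class `tracer_protocol`.
#' @export
tracer_protocol <- function(prime_umol = 0.92,
                            infusion_nmol_min = 17.2,
                            duration_min = 295,
                            sampling_times_min = seq(60, 270, by = 30),
                            steady_window_min = c(180, 270),
                            cv_threshold_pct = 5) {
  check_scalar(prime_umol, "prime_umol", min = 0)
  check_scalar(infusion_nmol_min, "infusion_nmol_min", min = 0,
               strict_min = TRUE)
  check_scalar(duration_min, "duration_min", min = 0, strict_min = TRUE)
  stopifnot(is.numeric(sampling_times_min), length(sampling_times_min) >= 1L,
            length(steady_window_min) == 2L,
            steady_window_min[1] < steady_window_min[2],
            steady_window_min[1] >= 0,
            steady_window_min[2] <= duration_min)
  check_scalar(cv_threshold_pct, "cv_threshold_pct", min = 0)
  structure(list(prime_umol = prime_umol,
                 infusion_nmol_min = infusion_nmol_min,
                 duration_min = duration_min,
                 sampling_times_min = sampling_times_min,
                 steady_window_min = steady_window_min,
                 cv_threshold_pct = cv_threshold_pct),
            class = "tracer_protocol")
}

# Rows of an arterial series inside the steady window, ordered by time.
window_rows <- function(df, window) {
  df <- df[df$time_min >= window[1] & df$time_min <= window[2], , drop = FALSE]
  df[order(df$time_min), , drop = FALSE]
}

#' Steady-state check on an arterial tracer series
#'
#' Computes the per-timepoint D4:cortisol and D4:D3 ratios over the
#' protocol's steady window and their percent coefficients of variation
#' (n-1 sample SD over mean). The subject is steady when both CVs are at
#' or below the protocol threshold.
#'
#' @param arterial Data frame with columns `time_min`, `cortisol_nM`,
#'   `d4_nM`, `d3_nM` (one arterial sample per row).
#' @param protocol A [tracer_protocol()].
#' @return List with `is_steady`, `cv_d4_cortisol_pct`, `cv_d4_d3_pct`.
#' @export
#' @examples
#' arterial <- data.frame(time_min = c(180, 210, 240, 270),
#'                        cortisol_nM = c(260, 255, 250, 252),
#'                        d4_nM = c(15.5, 15.6, 15.4, 15.5),
#'                        d3_nM = c(4.6, 4.7, 4.6, 4.6))
#' steady_state_check(arterial, tracer_protocol())
steady_state_check <- function(arterial, protocol = tracer_protocol()) {
  stopifnot(inherits(protocol, "tracer_protocol"),
            all(c("time_min", "cortisol_nM", "d4_nM", "d3_nM") %in%
                  names(arterial)))
  w <- window_rows(arterial, protocol$steady_window_min)
  if (nrow(w) < 3L)
    stop("need at least 3 arterial samples inside the steady window",
         call. = FALSE)
  if (any(w$cortisol_nM <= 0) || any(w$d3_nM <= 0))
    stop("zero or negative denominator in a tracer ratio", call. = FALSE)
  cv1 <- cv_pct(w$d4_nM / w$cortisol_nM)
  cv2 <- cv_pct(w$d4_nM / w$d3_nM)
  list(is_steady = cv1 <= protocol$cv_threshold_pct &&
         cv2 <= protocol$cv_threshold_pct,
       cv_d4_cortisol_pct = cv1,
       cv_d4_d3_pct = cv2)
}

#' Tracer clearance
#'
#' Steady-state clearance as the ratio of infusion rate to the mean
#' steady-state arterial tracer concentration: `CL = F / C_D4`, in L/min
#' (nmol/min over nmol/L).
#'
#' @param infusion_nmol_min Infusion rate F (nmol/min).
#' @param d4_nM Mean steady-state arterial D4-cortisol (nmol/L, `> 0`).
#' @return Clearance (L/min).
#' @export
#' @examples
#' clearance(17.2, 17.2)  # 1 L/min
clearance <- function(infusion_nmol_min, d4_nM) {
  check_scalar(infusion_nmol_min, "infusion_nmol_min", min = 0)
  check_scalar(d4_nM, "d4_nM", min = 0, strict_min = TRUE)
  infusion_nmol_min / d4_nM
}

#' Whole-body rate of appearance by isotope dilution
#'
#' `Ra = CL * C_analyte`. Applied to endogenous cortisol it measures the
#' rate at which cortisol dilutes the tracer (net production from all
#' sources); applied to D3-cortisol it isolates regeneration of cortisol
#' by 11beta-HSD1. Substituting `CL = F / C_D4` gives the equivalent form
#' `Ra = F * C_analyte / C_D4`, which assumes tracer and tracee share
#' clearance (the standard steady-state dilution assumption).
#'
#' @param clearance_L_min Clearance (L/min, `>= 0`).
#' @param analyte_nM Mean steady-state arterial concentration of the
#'   analyte (nmol/L, `>= 0`).
#' @return Rate of appearance (nmol/min).
#' @export
#' @examples
#' rate_of_appearance(1, 250)  # 250 nmol/min
rate_of_appearance <- function(clearance_L_min, analyte_nM) {
  check_scalar(clearance_L_min, "clearance_L_min", min = 0)
  check_scalar(analyte_nM, "analyte_nM", min = 0)
  clearance_L_min * analyte_nM
}

#' Arterio-venous net balance across a tissue bed
#'
#' Concentration difference venous minus arterial per analyte, at one
#' matched timepoint: positive values indicate net release into the vein.
#' When both samples carry a free fraction, the free-cortisol balance
#' `(ff_v/100) * C_v - (ff_a/100) * C_a` is computed as well; when either
#' is missing, `nb_free_nM` is `NA` (absent), never silently zero. The
#' operation is antisymmetric: swapping the two sites negates every
#' balance.
#'
#' @param arterial,venous One-row data frames (or lists) with
#'   `subject_id`, `time_min`, `cortisol_nM`, `d4_nM`, `d3_nM` and
#'   optionally `free_fraction_pct`; `venous` must carry a `tissue` label.
#' @return One-row data frame: `subject_id`, `tissue`, `time_min`,
#'   `nb_cortisol_nM`, `nb_d4_nM`, `nb_d3_nM`, `nb_free_nM`,
#'   `ff_arterial_pct`, `ff_venous_pct`.
#' @export
#' @examples
#' a <- list(subject_id = "s1", time_min = 180, cortisol_nM = 100,
#'           d4_nM = 15, d3_nM = 5, free_fraction_pct = 5)
#' v <- list(subject_id = "s1", time_min = 180, cortisol_nM = 105,
#'           d4_nM = 15.2, d3_nM = 5.1, free_fraction_pct = 6,
#'           tissue = "muscle")
#' net_balance(a, v)$nb_free_nM  # 6.30 - 5.00 = 1.30
net_balance <- function(arterial, venous) {
  if (!identical(as.character(arterial$subject_id),
                 as.character(venous$subject_id)))
    stop("arterial and venous samples are from different subjects",
         call. = FALSE)
  if (!isTRUE(all.equal(arterial$time_min, venous$time_min)))
    stop("arterial and venous samples are from different times",
         call. = FALSE)
  tissue <- venous$tissue
  if (is.null(tissue) || is.na(tissue) || !nzchar(tissue))
    stop("venous sample must carry a tissue label", call. = FALSE)

  ffa <- arterial$free_fraction_pct %||% NA_real_
  ffv <- venous$free_fraction_pct %||% NA_real_
  nb_free <- if (is.finite(ffa) && is.finite(ffv)) {
    (ffv / 100) * venous$cortisol_nM - (ffa / 100) * arterial$cortisol_nM
  } else NA_real_

  data.frame(subject_id = as.character(arterial$subject_id),
             tissue = as.character(tissue),
             time_min = arterial$time_min,
             nb_cortisol_nM = venous$cortisol_nM - arterial$cortisol_nM,
             nb_d4_nM = venous$d4_nM - arterial$d4_nM,
             nb_d3_nM = venous$d3_nM - arterial$d3_nM,
             nb_free_nM = nb_free,
             ff_arterial_pct = ffa,
             ff_venous_pct = ffv,
             stringsAsFactors = FALSE)
}

# Long-format plasma table -> one wide row per (subject, site, tissue, time).
widen_samples <- function(samples) {
  req <- c("subject_id", "group", "site", "time_min", "analyte", "conc_nM")
  if (!all(req %in% names(samples)))
    stop("plasma table must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (!"tissue" %in% names(samples)) samples$tissue <- ""
  samples$tissue[is.na(samples$tissue)] <- ""
  if (any(!samples$analyte %in%
          c("cortisol", "d4", "d3", "free_fraction_pct")))
    stop("unknown analyte in plasma table", call. = FALSE)
  if (any(samples$conc_nM < 0, na.rm = TRUE))
    stop("negative concentration in plasma table", call. = FALSE)

  key <- interaction(samples$subject_id, samples$group, samples$site,
                     samples$tissue, samples$time_min, drop = TRUE)
  pick <- function(d, a) {
    v <- d$conc_nM[d$analyte == a]
    if (length(v) == 0L) NA_real_ else v[1]
  }
  out <- do.call(rbind, lapply(split(samples, key), function(d) {
    data.frame(subject_id = d$subject_id[1], group = d$group[1],
               site = d$site[1], tissue = d$tissue[1],
               time_min = d$time_min[1],
               cortisol_nM = pick(d, "cortisol"),
               d4_nM = pick(d, "d4"), d3_nM = pick(d, "d3"),
               free_fraction_pct = pick(d, "free_fraction_pct"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Analyse a steady-state tracer study
#'
#' Per subject: checks steadiness of the arterial series over the
#' protocol window, then estimates clearance (`F / mean D4`), Ra of
#' cortisol and Ra of D3-cortisol from window means, and computes
#' per-timepoint arterio-venous net balances averaged over the window.
#' Subjects failing the steadiness criterion are retained in the output,
#' flagged, and excluded from rate estimates and group summaries.
#'
#' @param samples Long-format plasma table: columns `subject_id`, `group`,
#'   `site` (`"arterial"`/`"venous"`), `tissue` (for venous rows),
#'   `time_min`, `analyte` (`cortisol`, `d4`, `d3`, `free_fraction_pct`),
#'   `conc_nM`.
#' @param protocol A [tracer_protocol()].
#' @return An object of class `gc_tracer_study`: list with
#'   `results` (per-subject data frame: steadiness flags and CVs,
#'   `clearance_L_min`, `ra_cortisol_nmol_min`, `ra_d3_nmol_min`),
#'   `balances` (per-subject, per-tissue window means of the net
#'   balances), `summary` (group means and SDs of the rate estimates
#'   among steady subjects), `status` (`"ok"` or `"warning"`), and the
#'   protocol.
#' @export
analyze_study <- function(samples, protocol = tracer_protocol()) {
  stopifnot(inherits(protocol, "tracer_protocol"))
  if (is.null(samples) || nrow(samples) == 0L)
    stop("empty plasma sample table", call. = FALSE)
  wide <- widen_samples(samples)
  F_rate <- protocol$infusion_nmol_min

  results <- list(); balances <- list()
  for (sid in unique(wide$subject_id)) {
    sub <- wide[wide$subject_id == sid, , drop = FALSE]
    art <- sub[sub$site == "arterial", , drop = FALSE]
    if (nrow(art) == 0L)
      stop(sprintf("subject %s has no arterial series", sid), call. = FALSE)
    ss <- steady_state_check(art, protocol)
    aw <- window_rows(art, protocol$steady_window_min)

    if (ss$is_steady) {
      cl <- clearance(F_rate, mean(aw$d4_nM))
      ra_c <- rate_of_appearance(cl, mean(aw$cortisol_nM))
      ra_d3 <- rate_of_appearance(cl, mean(aw$d3_nM))
    } else {
      cl <- ra_c <- ra_d3 <- NA_real_
    }
    results[[sid]] <- data.frame(
      subject_id = sid, group = sub$group[1],
      is_steady = ss$is_steady,
      cv_d4_cortisol_pct = ss$cv_d4_cortisol_pct,
      cv_d4_d3_pct = ss$cv_d4_d3_pct,
      clearance_L_min = cl,
      ra_cortisol_nmol_min = ra_c,
      ra_d3_nmol_min = ra_d3,
      stringsAsFactors = FALSE)

    for (tis in setdiff(unique(sub$tissue[sub$site == "venous"]), "")) {
      ven <- sub[sub$site == "venous" & sub$tissue == tis, , drop = FALSE]
      vw <- window_rows(ven, protocol$steady_window_min)
      times <- intersect(aw$time_min, vw$time_min)
      if (length(times) == 0L) next
      nb <- do.call(rbind, lapply(times, function(tm)
        net_balance(aw[aw$time_min == tm, ], vw[vw$time_min == tm, ])))
      balances[[paste(sid, tis)]] <- data.frame(
        subject_id = sid, group = sub$group[1], tissue = tis,
        is_steady = ss$is_steady,
        nb_cortisol_nM = mean(nb$nb_cortisol_nM),
        nb_d4_nM = mean(nb$nb_d4_nM),
        nb_d3_nM = mean(nb$nb_d3_nM),
        nb_free_nM = mean(nb$nb_free_nM),
        ff_arterial_pct = mean(nb$ff_arterial_pct),
        ff_venous_pct = mean(nb$ff_venous_pct),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, results); rownames(results) <- NULL
  balances <- if (length(balances)) {
    b <- do.call(rbind, balances); rownames(b) <- NULL; b
  } else NULL

  steady <- results[results$is_steady, , drop = FALSE]
  summ <- if (nrow(steady) > 0L) {
    do.call(rbind, lapply(split(steady, steady$group), function(d)
      data.frame(group = d$group[1], n_steady = nrow(d),
                 n_total = sum(results$group == d$group[1]),
                 clearance_L_min = mean(d$clearance_L_min),
                 clearance_sd = stats::sd(d$clearance_L_min),
                 ra_cortisol_nmol_min = mean(d$ra_cortisol_nmol_min),
                 ra_cortisol_sd = stats::sd(d$ra_cortisol_nmol_min),
                 ra_d3_nmol_min = mean(d$ra_d3_nmol_min),
                 ra_d3_sd = stats::sd(d$ra_d3_nmol_min),
                 stringsAsFactors = FALSE)))
  } else NULL
  if (!is.null(summ)) rownames(summ) <- NULL

  status <- if (is.null(summ)) "warning" else "ok"
  if (status == "warning")
    warning("no subject passed the steadiness criterion; ",
            "summary omitted", call. = FALSE)
  structure(list(results = results, balances = balances, summary = summ,
                 status = status, protocol = protocol),
            class = "gc_tracer_study")
}

#' @export
print.gc_tracer_study <- function(x, ...) {
  cat(sprintf(
    "Steady-state tracer study: %d subjects (%d steady), status '%s'\n",
    nrow(x$results), sum(x$results$is_steady), x$status))
  if (!is.null(x$summary)) {
    cat("Group means (steady subjects):\n")
    print(x$summary[, c("group", "n_steady", "clearance_L_min",
                        "ra_cortisol_nmol_min", "ra_d3_nmol_min")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.gc_tracer_study <- function(object, ...) object$summary

#' Write tracer-study outputs to CSV
#'
#' Writes `tracer_results.csv`, `tissue_balance.csv` (when balances
#' exist) and `group_summary.csv` (when a summary exists) into `dir`.
#'
#' @param study A `gc_tracer_study` from [analyze_study()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_tracer_csv <- function(study, dir) {
  stopifnot(inherits(study, "gc_tracer_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "tracer_results.csv")
  utils::write.csv(study$results, p, row.names = FALSE); paths <- c(paths, p)
  if (!is.null(study$balances)) {
    p <- file.path(dir, "tissue_balance.csv")
    utils::write.csv(study$balances, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(study$summary)) {
    p <- file.path(dir, "group_summary.csv")
    utils::write.csv(study$summary, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
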