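## Seeded synthetic-data generators. Every generator emits the data its
## consuming module expects plus a `truth` record of the hidden parameters
## (pre-noise values, per-subject rates, effect multipliers), so pipeline
## estimates can be tested against known ground truth. Regeneration from
## the same (seed, parameters) is bit-identical.

# Multiplicative lognormal measurement noise with unit mean and the
# requested coefficient of variation.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Default serum-panel generator parameters
#'
#' Generator conditions for the in-vitro treatment panels: reference
#' human constants (CBG 336.8 nmol/L, Kd 10 nmol/L, albumin ratio 1.74,
#' total cortisol 200 nmol/L), mouse constants (CBG 500 nmol/L, Kd
#' 25 nmol/L, total corticosterone 150 nmol/L), between-replicate CBG
#' variability 5%, measurement CV 3%, reporter Hill curve
#' (basal 1, emax 4, ec50 10 nmol/L, hill 1), and the protease defaults
#' of [protease_constants()].
#'
#' @return Named list of parameters.
#' @export
serum_panel_params <- function() {
  list(human = list(total = 200, cbg_bmax = 336.8, cbg_kd = 10,
                    albumin_ratio = 1.74),
       mouse = list(total = 150, cbg_bmax = 500, cbg_kd = 25,
                    albumin_ratio = 1.74),
       bmax_cv = 0.05, noise_cv = 0.03,
       reporter = list(basal = 1, emax = 4, ec50 = 10, hill = 1),
       affinity_ratio = 10,
       arms = list(vehicle = c(ne_units = 0, aat_uM = 0),
                   NE = c(ne_units = 4, aat_uM = 0),
                   NE_AAT = c(ne_units = 4, aat_uM = 100)))
}

#' Simulate the in-vitro serum treatment panel
#'
#' Generates mouse and human serum compositions under the three treatment
#' arms (vehicle, NE 4 U, NE 4 U + AAT 100 uM), passes each replicate
#' through [treat_serum()], and reports noisy measurements of CBG binding
#' capacity, free fraction and reporter signal. Between-replicate
#' biological variability enters through the CBG capacity; measurement
#' noise is multiplicative lognormal.
#'
#' @param seed Integer seed (mandatory).
#' @param n_replicates Biological replicates per arm; default 4.
#' @param params Parameter list as from [serum_panel_params()].
#' @return List with `panel` (data frame: `sample_id`, `species`, `arm`,
#'   `ne_units`, `aat_uM`, `replicate`, `binding_capacity_nM`,
#'   `free_fraction_pct`, `reporter_signal`) and `truth` (seed, params,
#'   and the pre-noise values per sample).
#' @export
gen_serum_panel <- function(seed, n_replicates = 4,
                            params = serum_panel_params()) {
  check_scalar(seed, "seed")
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  constants <- protease_constants()

  rows <- list(); truth_rows <- list()
  for (species in c("mouse", "human")) {
    sp <- params[[species]]
    for (arm in names(params$arms)) {
      dose <- params$arms[[arm]]
      for (rep_i in seq_len(n_replicates)) {
        bmax_i <- sp$cbg_bmax * lognormal_noise(1, params$bmax_cv)
        serum <- serum_composition(
          sp$total,
          saturable = list(saturable_site("CBG_intact", bmax_i, sp$cbg_kd)),
          nonsaturable = list(nonsaturable_term("albumin",
                                                sp$albumin_ratio)),
          dilution = 50, species_label = species)
        treated <- treat_serum(
          serum,
          protease_treatment(ne_units = dose[["ne_units"]],
                             aat_conc = dose[["aat_uM"]]),
          constants, affinity_ratio = params$affinity_ratio)
        cap <- binding_capacity_of(treated$serum)
        ff <- treated$partition$free_fraction_pct
        rep_sig <- reporter_response(treated$partition$free,
                                     params$reporter$basal,
                                     params$reporter$emax,
                                     params$reporter$ec50,
                                     params$reporter$hill)
        noise <- lognormal_noise(3, params$noise_cv)
        sid <- sprintf("%s_%s_r%d", species, arm, rep_i)
        rows[[sid]] <- data.frame(
          sample_id = sid, species = species, arm = arm,
          ne_units = dose[["ne_units"]], aat_uM = dose[["aat_uM"]],
          replicate = rep_i,
          binding_capacity_nM = cap * noise[1],
          free_fraction_pct = ff * noise[2],
          reporter_signal = rep_sig * noise[3],
          stringsAsFactors = FALSE)
        truth_rows[[sid]] <- data.frame(
          sample_id = sid, species = species, arm = arm,
          cbg_bmax_nM = bmax_i,
          fraction_cleaved = treated$fraction_cleaved,
          residual_activity = treated$residual_activity,
          binding_capacity_nM = cap,
          free_nM = treated$partition$free,
          free_fraction_pct = ff,
          reporter_signal = rep_sig,
          stringsAsFactors = FALSE)
      }
    }
  }
  panel <- do.call(rbind, rows); rownames(panel) <- NULL
  truth_panel <- do.call(rbind, truth_rows); rownames(truth_panel) <- NULL
  list(panel = panel,
       truth = list(seed = seed, n_replicates = n_replicates,
                    params = params, pre_noise = truth_panel))
}

#' Default tracer-study generator parameters
#'
#' Study conditions of the simulated two-group arterio-venous tracer
#' infusion: whole-body clearance lognormal around 1.1 L/min with 12%
#' between-subject CV; one-compartment distribution volume 35 L (so the
#' tracer plateau is reached well before the 180-min window opens);
#' endogenous cortisol decaying from 400 nmol/L toward a 250 nmol/L
#' plateau with a 45-min time constant; D3:D4 ratio 0.30 in controls with
#' a 0.75 multiplier in the AAT-deficient group (reduced 11beta-HSD1
#' regeneration); free fraction 5% in controls with a 1.3 multiplier in
#' the AAT-deficient group and a 1.05 venous:arterial multiplier; skeletal
#' muscle release terms (venous minus arterial) of +5/+12 nmol/L cortisol,
#' +0.2/+0.6 nmol/L D4 and +0.05/+0.15 nmol/L D3 in control/AAT-deficient
#' subjects; measurement CV 3% per concentration, three quarters of its
#' variance shared among analytes measured in the same draw (isotopologue
#' channels come from one injection, so their errors are strongly
#' correlated and tracer ratios are more precise than either
#' concentration alone). Group magnitudes encode the study's effect
#' directions; they are generator parameters, not reported values.
#'
#' @return Named list of parameters.
#' @export
tracer_study_params <- function() {
  list(cl_mean_L_min = 1.1, cl_cv = 0.12, vd_L = 35,
       cortisol_ss_nM = 250, cortisol_0_nM = 400, cortisol_tau_min = 45,
       d3_ratio = 0.30, ff_pct = 5, ff_venous_mult = 1.05,
       groups = list(
         control = list(d3_mult = 1.0, ff_mult = 1.0,
                        release_cortisol_nM = 5, release_d4_nM = 0.2,
                        release_d3_nM = 0.05),
         AAT_def = list(d3_mult = 0.75, ff_mult = 1.3,
                        release_cortisol_nM = 12, release_d4_nM = 0.6,
                        release_d3_nM = 0.15)),
       noise_cv = 0.03, noise_shared_frac = 0.75)
}

#' Simulate a two-group steady-state tracer study
#'
#' Per subject, arterial D4-cortisol follows the one-compartment approach
#' to plateau `F/CL` (priming bolus `prime/Vd` decaying with rate
#' `CL/Vd`), calibrated so that concentrations sit exactly on their
#' steady-state values from the opening of the steady window onwards;
#' endogenous cortisol declines toward its plateau over the earlier part
#' of the infusion; D3-cortisol is a group-dependent fixed fraction of
#' D4; venous (forearm skeletal muscle) channels are offset by
#' group-dependent release terms; and every measurement carries
#' multiplicative lognormal noise. With `noise_cv = 0` the steady-window
#' analysis recovers the generator truth exactly.
#'
#' @param seed Integer seed (mandatory).
#' @param n_per_group Subjects per group; default 16.
#' @param protocol A [tracer_protocol()].
#' @param params Parameter list as from [tracer_study_params()].
#' @return List with `samples` (long-format plasma table consumed by
#'   [analyze_study()]) and `truth` (seed, params, and a per-subject data
#'   frame of true clearance, Ra cortisol, Ra D3, free fractions and
#'   release terms).
#' @export
gen_tracer_study <- function(seed, n_per_group = 16,
                             protocol = tracer_protocol(),
                             params = tracer_study_params()) {
  check_scalar(seed, "seed")
  stopifnot(n_per_group >= 2, inherits(protocol, "tracer_protocol"))
  set.seed(seed)

  F_rate <- protocol$infusion_nmol_min
  prime_nmol <- protocol$prime_umol * 1000
  times <- protocol$sampling_times_min
  w0 <- protocol$steady_window_min[1]

  samples <- list(); truth_rows <- list()
  for (g in names(params$groups)) {
    gp <- params$groups[[g]]
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", g, i)
      cl <- params$cl_mean_L_min * lognormal_noise(1, params$cl_cv)
      k <- cl / params$vd_L
      plateau <- F_rate / cl
      c0_bolus <- prime_nmol / params$vd_L

      # steady values; transient applies strictly before the window opens
      d4_a <- ifelse(times >= w0, plateau,
                     plateau + (c0_bolus - plateau) * exp(-k * times))
      cort_a <- ifelse(times >= w0, params$cortisol_ss_nM,
                       params$cortisol_ss_nM +
                         (params$cortisol_0_nM - params$cortisol_ss_nM) *
                         exp(-times / params$cortisol_tau_min))
      d3_a <- params$d3_ratio * gp$d3_mult * d4_a
      ff_a <- params$ff_pct * gp$ff_mult
      cort_v <- cort_a + gp$release_cortisol_nM
      d4_v <- d4_a + gp$release_d4_nM
      d3_v <- d3_a + gp$release_d3_nM
      ff_v <- ff_a * params$ff_venous_mult

      # total measurement CV split into a component shared by the steroid
      # channels of one draw and an analyte-specific remainder
      shared_frac <- params$noise_shared_frac %||% 0
      cv_shared <- params$noise_cv * sqrt(shared_frac)
      cv_spec <- params$noise_cv * sqrt(1 - shared_frac)
      emit <- function(site, tissue, analyte, value, shared) {
        spec <- if (identical(analyte, "free_fraction_pct")) {
          lognormal_noise(length(times), params$noise_cv)
        } else {
          shared * lognormal_noise(length(times), cv_spec)
        }
        data.frame(subject_id = sid, group = g, site = site,
                   tissue = tissue, time_min = times, analyte = analyte,
                   conc_nM = value * spec,
                   stringsAsFactors = FALSE)
      }
      sh_a <- lognormal_noise(length(times), cv_shared)
      sh_v <- lognormal_noise(length(times), cv_shared)
      samples[[length(samples) + 1L]] <- rbind(
        emit("arterial", "", "cortisol", cort_a, sh_a),
        emit("arterial", "", "d4", d4_a, sh_a),
        emit("arterial", "", "d3", d3_a, sh_a),
        emit("arterial", "", "free_fraction_pct", rep(ff_a, length(times)),
             sh_a),
        emit("venous", "muscle", "cortisol", cort_v, sh_v),
        emit("venous", "muscle", "d4", d4_v, sh_v),
        emit("venous", "muscle", "d3", d3_v, sh_v),
        emit("venous", "muscle", "free_fraction_pct",
             rep(ff_v, length(times)), sh_v))

      truth_rows[[sid]] <- data.frame(
        subject_id = sid, group = g,
        clearance_L_min = cl,
        d4_plateau_nM = plateau,
        ra_cortisol_nmol_min = cl * params$cortisol_ss_nM,
        ra_d3_nmol_min = cl * params$d3_ratio * gp$d3_mult * plateau,
        ff_arterial_pct = ff_a, ff_venous_pct = ff_v,
        release_cortisol_nM = gp$release_cortisol_nM,
        release_d4_nM = gp$release_d4_nM,
        release_d3_nM = gp$release_d3_nM,
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, samples); rownames(samples) <- NULL
  truth <- do.call(rbind, truth_rows); rownames(truth) <- NULL
  list(samples = samples,
       truth = list(seed = seed, n_per_group = n_per_group,
                    params = params, subjects = truth))
}

#' Default mouse-cohort generator parameters
#'
#' Conditions of the synthetic high-fat-diet mouse cohort. Baseline body
#' weight 25 g (males) / 20 g (females) gaining 1.0 / 0.8 g per week on
#' diet; gonadal white adipose (gWAT) corticosterone 30 ng/g and
#' subcutaneous (sWAT) 20 ng/g; fasting glucose 8 mmol/L and insulin
#' 60 pmol/L rising to 180 pmol/L at 15 min post-glucose; GTT peak
#' 22 mmol/L at 15 min; ITT decay 2.5 %/min. Genotype effect multipliers
#' (defaults: elastase-knockout males gain weight at 0.6 times the
#' wild-type rate and carry 0.7 times the gWAT corticosterone; females
#' and adrenalectomised (ADX) animals show no genotype effect) encode the
#' study's effect directions, not its magnitudes. Noise: 3% CV on plasma
#' measures and weights, 8% on tissue corticosterone.
#'
#' @return Named list of parameters.
#' @export
mouse_cohort_params <- function() {
  list(weeks = 0:10,
       baseline_weight_g = c(M = 25, F = 20),
       weekly_gain_g = c(M = 1.0, F = 0.8),
       gwat_cort_ng_g = 30, swat_cort_ng_g = 20,
       fasting_glucose_mM = 8, fasting_insulin_pmolL = 60,
       insulin_15min_pmolL = 180,
       gtt_times_min = c(0, 15, 30, 60, 90, 120),
       gtt_peak_mM = 22, gtt_decay_per_min = 0.02,
       itt_times_min = c(0, 15, 30, 60),
       kitt_pct_min = 2.5,
       serum_ne_au = c(WT = 0.30, Elane_KO = 0.02),
       serum_aat_g_L = 1.2,
       effects = list(ko_male_weight_gain = 0.6,
                      ko_male_gwat_cort = 0.7,
                      female_mult = 1.0, adx_mult = 1.0),
       noise_cv_plasma = 0.03, noise_cv_tissue = 0.08)
}

# Effect multiplier for one (genotype, sex, surgery) arm and one readout.
arm_multiplier <- function(genotype, sex, surgery, effects, which) {
  if (genotype != "Elane_KO") return(1)
  if (sex == "F") return(effects$female_mult)
  if (surgery == "ADX") return(effects$adx_mult)
  effects[[which]]
}

#' Simulate a mouse cohort (genotype x sex x surgery arms)
#'
#' Generates per-animal weight trajectories, glucose- and
#' insulin-tolerance curves, fasting/post-challenge insulin, depot
#' corticosterone and serum NE/AAT for the requested arms, with group
#' means scaled by the effect multipliers in [mouse_cohort_params()]
#' plus multiplicative lognormal noise.
#'
#' @param seed Integer seed (mandatory).
#' @param arms Data frame with columns `genotype` (`"WT"`/`"Elane_KO"`),
#'   `sex` (`"M"`/`"F"`), `surgery` (`"intact"`/`"sham"`/`"ADX"`).
#'   Default: WT and knockout, both sexes, intact.
#' @param n_per_arm Animals per arm; default 7.
#' @param params Parameter list as from [mouse_cohort_params()].
#' @return List with `weights`, `gtt`, `itt` (long-format data frames),
#'   `insulin`, `tissue`, `serum` (per-animal data frames) and `truth`.
#' @export
gen_mouse_cohort <- function(seed,
                             arms = expand.grid(
                               genotype = c("WT", "Elane_KO"),
                               sex = c("M", "F"),
                               surgery = "intact",
                               stringsAsFactors = FALSE),
                             n_per_arm = 7,
                             params = mouse_cohort_params()) {
  check_scalar(seed, "seed")
  stopifnot(is.data.frame(arms),
            all(c("genotype", "sex", "surgery") %in% names(arms)),
            all(arms$genotype %in% c("WT", "Elane_KO")),
            all(arms$sex %in% c("M", "F")),
            all(arms$surgery %in% c("intact", "sham", "ADX")),
            n_per_arm >= 1)
  set.seed(seed)
  eff <- params$effects

  weights <- list(); gtt <- list(); itt <- list()
  insulin <- list(); tissue <- list(); serum <- list(); truth_rows <- list()
  for (a in seq_len(nrow(arms))) {
    gt <- arms$genotype[a]; sx <- arms$sex[a]; sg <- arms$surgery[a]
    w_mult <- arm_multiplier(gt, sx, sg, eff, "ko_male_weight_gain")
    c_mult <- arm_multiplier(gt, sx, sg, eff, "ko_male_gwat_cort")
    gain <- params$weekly_gain_g[[sx]] * w_mult
    for (i in seq_len(n_per_arm)) {
      aid <- sprintf("%s_%s_%s_%02d", gt, sx, sg, i)
      base_w <- params$baseline_weight_g[[sx]]
      wk <- params$weeks
      weights[[aid]] <- data.frame(
        animal_id = aid, genotype = gt, sex = sx, surgery = sg,
        week = wk,
        weight_g = (base_w + gain * wk) *
          lognormal_noise(length(wk), params$noise_cv_plasma),
        stringsAsFactors = FALSE)

      tg <- params$gtt_times_min
      g_curve <- params$fasting_glucose_mM +
        (params$gtt_peak_mM - params$fasting_glucose_mM) *
        (tg / 15) * exp(1 - tg / 15) *
        exp(-params$gtt_decay_per_min * pmax(tg - 15, 0))
      gtt[[aid]] <- data.frame(
        animal_id = aid, genotype = gt, sex = sx, surgery = sg,
        test = "GTT", time_min = tg,
        glucose_mM = g_curve *
          lognormal_noise(length(tg), params$noise_cv_plasma),
        stringsAsFactors = FALSE)

      ti <- params$itt_times_min
      i_curve <- params$fasting_glucose_mM *
        exp(-params$kitt_pct_min / 100 * ti)
      itt[[aid]] <- data.frame(
        animal_id = aid, genotype = gt, sex = sx, surgery = sg,
        test = "ITT", time_min = ti,
        glucose_mM = i_curve *
          lognormal_noise(length(ti), params$noise_cv_plasma),
        stringsAsFactors = FALSE)

      ins_noise <- lognormal_noise(3, params$noise_cv_plasma)
      insulin[[aid]] <- data.frame(
        animal_id = aid, genotype = gt, sex = sx, surgery = sg,
        fasting_glucose_mM = params$fasting_glucose_mM * ins_noise[1],
        fasting_insulin_pmolL = params$fasting_insulin_pmolL * ins_noise[2],
        insulin_15min_pmolL = params$insulin_15min_pmolL * ins_noise[3],
        stringsAsFactors = FALSE)

      tis_noise <- lognormal_noise(2, params$noise_cv_tissue)
      tissue[[aid]] <- data.frame(
        animal_id = rep(aid, 2), genotype = gt, sex = sx, surgery = sg,
        depot = c("gWAT", "sWAT"),
        corticosterone_ng_g = c(params$gwat_cort_ng_g * c_mult *
                                  tis_noise[1],
                                params$swat_cort_ng_g * tis_noise[2]),
        stringsAsFactors = FALSE)

      ser_noise <- lognormal_noise(2, params$noise_cv_plasma)
      serum[[aid]] <- data.frame(
        animal_id = aid, genotype = gt, sex = sx, surgery = sg,
        ne_activity_au = params$serum_ne_au[[gt]] * ser_noise[1],
        aat_g_L = params$serum_aat_g_L * ser_noise[2],
        stringsAsFactors = FALSE)
    }
    truth_rows[[a]] <- data.frame(
      genotype = gt, sex = sx, surgery = sg,
      weight_gain_mult = w_mult, gwat_cort_mult = c_mult,
      weekly_gain_g = gain,
      gwat_cort_ng_g = params$gwat_cort_ng_g * c_mult,
      stringsAsFactors = FALSE)
  }
  bind <- function(x) { d <- do.call(rbind, x); rownames(d) <- NULL; d }
  list(weights = bind(weights), gtt = bind(gtt), itt = bind(itt),
       insulin = bind(insulin), tissue = bind(tissue), serum = bind(serum),
       truth = list(seed = seed, n_per_arm = n_per_arm, params = params,
                    arms = bind(truth_rows)))
}

#' Simulate ultrafiltration counts from a known partition
#'
#' Produces filtrate/retentate counts proportional to the free and total
#' steroid of a solved partition (the retentate aliquot approximates
#' total tracer), so that [ultrafiltration_free_fraction()] applied to
#' the noiseless counts recovers `free_fraction_pct` exactly.
#'
#' @param partition A `gc_partition` from [solve_free()].
#' @param cpm_per_nM Counts per nmol/L scaling; default 100.
#' @return List with `cpm_filtrate` and `cpm_retentate`.
#' @export
simulate_ultrafiltration_counts <- function(partition, cpm_per_nM = 100) {
  stopifnot(inherits(partition, "gc_partition"))
  check_scalar(cpm_per_nM, "cpm_per_nM", min = 0, strict_min = TRUE)
  list(cpm_filtrate = partition$free * cpm_per_nM,
       cpm_retentate = partition$total_steroid * cpm_per_nM)
}
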