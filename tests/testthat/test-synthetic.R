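# Synthetic-data generators: determinism, validity, and ground-truth
# recovery by the consuming analyses.

test_that("generators regenerate bit-identically from the same seed", {
  expect_identical(gen_serum_panel(17), gen_serum_panel(17))
  expect_identical(gen_tracer_study(17, n_per_group = 3),
                   gen_tracer_study(17, n_per_group = 3))
  expect_identical(gen_mouse_cohort(17, n_per_arm = 2),
                   gen_mouse_cohort(17, n_per_arm = 2))
  # a different seed changes the data
  expect_false(identical(gen_serum_panel(17)$panel,
                         gen_serum_panel(18)$panel))
})

test_that("serum panel reproduces the treatment-arm effect structure", {
  sim <- gen_serum_panel(seed = 1)
  panel <- sim$panel
  expect_equal(nrow(panel), 2 * 3 * 4)   # species x arm x replicate

  for (sp in c("mouse", "human")) {
    d <- panel[panel$species == sp, ]
    veh <- d[d$arm == "vehicle", ]
    ne <- d[d$arm == "NE", ]
    ne_aat <- d[d$arm == "NE_AAT", ]
    # NE raises free glucocorticoid in every replicate set and lowers
    # capacity; AAT pre-incubation restores vehicle behaviour
    expect_gt(min(ne$free_fraction_pct), max(veh$free_fraction_pct))
    expect_lt(max(ne$binding_capacity_nM), min(veh$binding_capacity_nM))
    expect_gt(min(ne$reporter_signal), max(veh$reporter_signal))
    expect_lt(abs(mean(ne_aat$free_fraction_pct) /
                    mean(veh$free_fraction_pct) - 1), 0.1)
  }

  # vehicle-arm mean tracks the pre-noise truth within ~2 CV / sqrt(n)
  truth <- sim$truth$pre_noise
  for (sp in c("mouse", "human")) {
    obs <- panel[panel$arm == "vehicle" & panel$species == sp,
                 "free_fraction_pct"]
    expected <- mean(truth[truth$arm == "vehicle" & truth$species == sp,
                           "free_fraction_pct"])
    expect_lt(abs(mean(obs) / expected - 1), 2 * 0.03 / sqrt(length(obs)) +
                0.02)
  }
})

test_that("tracer generator honours the protocol and plateau identity", {
  prot <- tracer_protocol()
  params <- tracer_study_params()
  params$noise_cv <- 0
  sim <- gen_tracer_study(seed = 4, n_per_group = 2, params = params)
  s <- sim$samples

  expect_setequal(unique(s$time_min), seq(60, 270, by = 30))
  expect_setequal(unique(s$analyte),
                  c("cortisol", "d4", "d3", "free_fraction_pct"))
  expect_true(all(s$conc_nM >= 0))

  # noiseless steady-window mean D4 equals F / CL exactly
  truth <- sim$truth$subjects
  for (i in seq_len(nrow(truth))) {
    d4 <- s[s$subject_id == truth$subject_id[i] & s$site == "arterial" &
              s$analyte == "d4" & s$time_min >= 180, "conc_nM"]
    expect_equal(mean(d4),
                 prot$infusion_nmol_min / truth$clearance_L_min[i],
                 tolerance = 1e-12)
  }

  # endogenous cortisol declines over the infusion
  cort <- s[s$subject_id == truth$subject_id[1] & s$site == "arterial" &
              s$analyte == "cortisol", ]
  cort <- cort[order(cort$time_min), ]
  expect_true(!is.unsorted(rev(cort$conc_nM)))
})

test_that("simulated cohorts pass steadiness and recover clearance", {
  sim <- gen_tracer_study(seed = 1)
  study <- analyze_study(sim$samples)

  # >= 95% of subjects satisfy the 5% CV criterion
  expect_gte(mean(study$results$is_steady), 0.95)

  # group-mean clearance within 2% of generator truth
  m <- merge(study$results, sim$truth$subjects, by = c("subject_id",
                                                       "group"))
  for (g in unique(m$group)) {
    d <- m[m$group == g & m$is_steady, ]
    expect_lt(abs(mean(d$clearance_L_min.x) /
                    mean(d$clearance_L_min.y) - 1), 0.02)
  }

  # AAT-deficient group direction: lower Ra D3, higher free fraction,
  # greater free-cortisol release across muscle
  s <- study$summary
  expect_lt(s$ra_d3_nmol_min[s$group == "AAT_def"],
            s$ra_d3_nmol_min[s$group == "control"])
  b <- study$balances
  expect_gt(mean(b$nb_free_nM[b$group == "AAT_def"]),
            mean(b$nb_free_nM[b$group == "control"]))
  expect_gt(mean(b$ff_arterial_pct[b$group == "AAT_def"]),
            mean(b$ff_arterial_pct[b$group == "control"]))
})

test_that("effect multipliers are recovered across seeds", {
  # pre-registered bands: clearance within 2%, multiplicative group
  # effects within 3 relative standard errors
  cl_err <- numeric(0)
  for (seed in 1:20) {
    sim <- gen_tracer_study(seed, n_per_group = 8)
    study <- suppressWarnings(analyze_study(sim$samples))
    m <- merge(study$results, sim$truth$subjects,
               by = c("subject_id", "group"))
    m <- m[m$is_steady, ]
    cl_err <- c(cl_err, abs(mean(m$clearance_L_min.x) /
                              mean(m$clearance_L_min.y) - 1))
  }
  expect_lt(mean(cl_err), 0.02)
  expect_lt(max(cl_err), 0.05)

  # mouse weight-gain multiplier
  ratios <- vapply(1:10, function(seed) {
    sim <- gen_mouse_cohort(seed)
    w <- sim$weights
    gain <- function(gt) {
      d <- w[w$genotype == gt & w$sex == "M", ]
      fit <- stats::coef(stats::lm(weight_g ~ week, data = d))[["week"]]
      fit
    }
    gain("Elane_KO") / gain("WT")
  }, 0)
  expect_lt(abs(mean(ratios) - 0.6), 0.05)
})

test_that("mouse cohort encodes genotype effects in males only", {
  sim <- gen_mouse_cohort(seed = 2)
  tis <- sim$tissue
  gw <- tis[tis$depot == "gWAT", ]
  mean_by <- function(gt, sx) mean(gw$corticosterone_ng_g[
    gw$genotype == gt & gw$sex == sx])
  expect_lt(mean_by("Elane_KO", "M") / mean_by("WT", "M"), 0.85)
  expect_lt(abs(mean_by("Elane_KO", "F") / mean_by("WT", "F") - 1), 0.15)

  # generated curves pass the phenotyping module validation
  g1 <- sim$gtt[sim$gtt$animal_id == sim$gtt$animal_id[1], ]
  expect_s3_class(glucose_curve(g1$animal_id[1], "GTT", g1$time_min,
                                g1$glucose_mM), "glucose_curve")
  expect_error(gen_mouse_cohort(1, arms = data.frame(
    genotype = "WT", sex = "M", surgery = "hemi")), "surgery")
})
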