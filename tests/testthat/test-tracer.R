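# Steady-state tracer dilution: steadiness, clearance, Ra, net balance.

make_arterial <- function(times = c(180, 210, 240, 270),
                          cortisol = 250, d4 = 15.6, d3 = 4.7) {
  data.frame(time_min = times,
             cortisol_nM = rep_len(cortisol, length(times)),
             d4_nM = rep_len(d4, length(times)),
             d3_nM = rep_len(d3, length(times)))
}

test_that("steadiness criterion uses the sample CV of window ratios", {
  prot <- tracer_protocol()

  # constant ratios are perfectly steady
  ss <- steady_state_check(make_arterial(), prot)
  expect_true(ss$is_steady)
  expect_equal(ss$cv_d4_cortisol_pct, 0)

  # frozen example: ratios 10, 10.5, 9.5, 10, 10 -> CV = 100*sqrt(0.125)/10
  art <- data.frame(time_min = c(180, 200, 220, 240, 260),
                    cortisol_nM = rep(10, 5),
                    d4_nM = c(100, 105, 95, 100, 100),
                    d3_nM = rep(10, 5))
  ss2 <- steady_state_check(art, prot)
  expect_equal(ss2$cv_d4_cortisol_pct, 100 * sqrt(0.125) / 10,
               tolerance = 1e-12)
  expect_equal(ss2$cv_d4_cortisol_pct, 3.5355339, tolerance = 1e-7)

  # one criterion failing is enough to reject steadiness
  art$d3_nM <- c(10, 12, 8.5, 10, 10)   # D4:D3 CV > 5%
  ss3 <- steady_state_check(art, prot)
  expect_lte(ss3$cv_d4_cortisol_pct, 5)
  expect_gt(ss3$cv_d4_d3_pct, 5)
  expect_false(ss3$is_steady)

  # errors: too few samples, zero denominators
  expect_error(steady_state_check(make_arterial(times = c(180, 270)), prot),
               "at least 3")
  expect_error(steady_state_check(make_arterial(cortisol = 0), prot),
               "denominator")
})

test_that("clearance and Ra follow the dilution identities", {
  expect_equal(clearance(17.2, 17.2), 1)
  expect_equal(clearance(17.2, 8.6), 2)
  expect_equal(clearance(17.2, 34.4), 0.5)
  expect_error(clearance(17.2, 0), "d4")

  expect_equal(rate_of_appearance(1, 250), 250)
  expect_equal(rate_of_appearance(0.8, 5), 4)
  expect_equal(rate_of_appearance(1, 0), 0)

  # Ra_cortisol * C_D4 = F * C_cortisol to machine precision
  set.seed(11)
  for (i in 1:50) {
    F_rate <- runif(1, 5, 30); c_d4 <- runif(1, 5, 40)
    c_cort <- runif(1, 100, 500)
    cl <- clearance(F_rate, c_d4)
    expect_equal(rate_of_appearance(cl, c_cort) * c_d4, F_rate * c_cort,
                 tolerance = 1e-12)
  }
})

test_that("net balance is venous minus arterial and antisymmetric", {
  a <- list(subject_id = "s1", time_min = 180, cortisol_nM = 100,
            d4_nM = 15, d3_nM = 5, free_fraction_pct = 5, tissue = "muscle")
  v <- list(subject_id = "s1", time_min = 180, cortisol_nM = 105,
            d4_nM = 15.4, d3_nM = 5.2, free_fraction_pct = 6,
            tissue = "muscle")

  nb <- net_balance(a, v)
  expect_equal(nb$nb_cortisol_nM, 5)
  expect_equal(nb$nb_d4_nM, 0.4)
  # frozen free-cortisol balance: 6% of 105 minus 5% of 100
  expect_equal(nb$nb_free_nM, 1.3)

  # identical sites balance to zero
  nb0 <- net_balance(a, a)
  expect_true(all(c(nb0$nb_cortisol_nM, nb0$nb_d4_nM, nb0$nb_d3_nM,
                    nb0$nb_free_nM) == 0))

  # swapping the sites negates every balance
  swapped <- net_balance(v, a)
  for (col in c("nb_cortisol_nM", "nb_d4_nM", "nb_d3_nM", "nb_free_nM"))
    expect_equal(swapped[[col]], -nb[[col]], tolerance = 1e-12)

  # missing free fraction yields NA, never silent zero
  a2 <- a; a2$free_fraction_pct <- NULL
  expect_true(is.na(net_balance(a2, v)$nb_free_nM))

  # mismatches are rejected
  expect_error(net_balance(modifyList(a, list(subject_id = "s2")), v),
               "different subjects")
  expect_error(net_balance(modifyList(a, list(time_min = 210)), v),
               "different times")
  v2 <- v; v2$tissue <- NULL
  expect_error(net_balance(a, v2), "tissue")
})

test_that("a noiseless cohort is recovered exactly", {
  params <- tracer_study_params()
  params$noise_cv <- 0
  sim <- gen_tracer_study(seed = 3, n_per_group = 4, params = params)
  study <- analyze_study(sim$samples)

  expect_true(all(study$results$is_steady))
  m <- merge(study$results, sim$truth$subjects, by = c("subject_id",
                                                       "group"))
  expect_equal(m$clearance_L_min.x, m$clearance_L_min.y,
               tolerance = 1e-12)
  expect_equal(m$ra_cortisol_nmol_min.x, m$ra_cortisol_nmol_min.y,
               tolerance = 1e-12)
  expect_equal(m$ra_d3_nmol_min.x, m$ra_d3_nmol_min.y, tolerance = 1e-12)

  b <- merge(study$balances, sim$truth$subjects, by = c("subject_id",
                                                        "group"))
  expect_equal(b$nb_cortisol_nM, b$release_cortisol_nM, tolerance = 1e-9)
  expect_equal(b$nb_d4_nM, b$release_d4_nM, tolerance = 1e-9)
})

test_that("noisy group-mean estimates stay within sampling error of truth", {
  sim <- gen_tracer_study(seed = 1)
  study <- analyze_study(sim$samples)
  m <- merge(study$results, sim$truth$subjects, by = c("subject_id",
                                                       "group"))
  for (g in unique(m$group)) {
    d <- m[m$group == g & m$is_steady, ]
    # 3 sigma / sqrt(n) band on the group mean, sigma = measurement CV
    band <- 3 * 0.03 / sqrt(nrow(d))
    expect_lt(abs(mean(d$clearance_L_min.x) / mean(d$clearance_L_min.y) - 1),
              band + 0.005)
  }
})

test_that("full study analysis flags, summarises and exports", {
  sim <- gen_tracer_study(seed = 2, n_per_group = 4)
  study <- analyze_study(sim$samples)
  expect_s3_class(study, "gc_tracer_study")
  expect_equal(nrow(study$results), 8)
  expect_setequal(study$summary$group, c("control", "AAT_def"))

  # effect directions propagate: lower Ra D3, positive muscle release
  s <- study$summary
  expect_lt(s$ra_d3_nmol_min[s$group == "AAT_def"],
            s$ra_d3_nmol_min[s$group == "control"])
  expect_true(all(aggregate(nb_cortisol_nM ~ group, study$balances,
                            mean)$nb_cortisol_nM > 0))

  # CSV export round-trip
  dir <- withr::local_tempdir()
  paths <- write_tracer_csv(study, dir)
  expect_true(all(file.exists(file.path(dir, c("tracer_results.csv",
                                               "tissue_balance.csv",
                                               "group_summary.csv")))))
  back <- read.csv(file.path(dir, "tracer_results.csv"))
  expect_equal(back$clearance_L_min, study$results$clearance_L_min)

  # an impossible threshold flags everyone and warns
  strict <- tracer_protocol(cv_threshold_pct = 0)
  expect_warning(out <- analyze_study(sim$samples, strict), "steadiness")
  expect_equal(out$status, "warning")
  expect_true(all(!out$results$is_steady))
  expect_error(analyze_study(sim$samples[0, ]), "empty")
})
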