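# Mass-action partitioning of steroid among CBG, albumin and the free pool.

test_that("trivial compositions solve in closed form", {
  # no binding species: everything is free
  p <- solve_free(serum_composition(100))
  expect_equal(p$free, 100)
  expect_equal(p$free_fraction_pct, 100)

  # zero steroid: all pools empty
  p0 <- solve_free(reference_serum(total_steroid = 0))
  expect_equal(p0$free, 0)
  expect_true(all(p0$bound_by_site == 0))
})

test_that("reference human set reproduces the physiological partition", {
  p <- solve_free(reference_serum())
  # frozen from the independent grid/uniroot oracle
  expect_equal(p$free, 10.381738, tolerance = 1e-6)
  expect_equal(p$free_fraction_pct, 5.1908692, tolerance = 1e-6)
  expect_equal(unname(p$fraction_by_site_pct[["CBG_intact"]]), 85.777018,
               tolerance = 1e-6)
  # the partition lies inside the stated physiological bounds
  expect_gte(p$fraction_by_site_pct[["CBG_intact"]], 85)
  expect_gte(p$free_fraction_pct, 5)
  expect_lte(p$free_fraction_pct, 10)
})

test_that("solver agrees with the exhaustive grid oracle", {
  for (case in list(list(total = 200, bmax = ref_bmax, kd = ref_kd,
                         nr = ref_albumin),
                    list(total = 200, bmax = ref_bmax, kd = 100,
                         nr = ref_albumin),
                    list(total = 50, bmax = c(400, 100), kd = c(5, 60),
                         nr = c(1.74, 0.4)))) {
    sat <- mapply(function(b, k, i) saturable_site(paste0("s", i), b, k),
                  case$bmax, case$kd, seq_along(case$bmax),
                  SIMPLIFY = FALSE)
    non <- mapply(function(n, i) nonsaturable_term(paste0("n", i), n),
                  case$nr, seq_along(case$nr), SIMPLIFY = FALSE)
    serum <- serum_composition(case$total, sat, non)
    grid_step <- case$total / (1e6 - 1)
    expect_lt(abs(solve_free(serum)$free -
                    oracle_grid_free(case$total, case$bmax, case$kd,
                                     case$nr)),
              grid_step)
  }
})

test_that("mass is conserved across random compositions", {
  set.seed(42)
  for (i in 1:1000) {
    serum <- random_composition()
    p <- solve_free(serum)
    total_back <- p$free + sum(p$bound_by_site)
    expect_lt(abs(total_back - serum$total_steroid),
              1e-9 * max(serum$total_steroid, 1))
    expect_true(p$free >= 0 && all(p$bound_by_site >= 0))
    expect_lt(abs(p$free_fraction_pct + sum(p$fraction_by_site_pct) - 100),
              1e-6)
  }
})

test_that("free concentration is monotone in every parameter", {
  base <- function(total = 200, kd = 10, bmax = 336.8, nr = 1.74) {
    solve_free(serum_composition(
      total, list(saturable_site("CBG_intact", bmax, kd)),
      list(nonsaturable_term("albumin", nr))))$free
  }
  totals <- seq(20, 500, length.out = 12)
  expect_true(all(diff(vapply(totals, function(t) base(total = t), 0)) > 0))
  kds <- c(1, 5, 10, 50, 200)
  expect_true(!is.unsorted(vapply(kds, function(k) base(kd = k), 0)))
  bmaxs <- c(0, 100, 336.8, 800)
  expect_true(!is.unsorted(rev(vapply(bmaxs, function(b) base(bmax = b),
                                      0))))
  nrs <- c(0, 0.5, 1.74, 5)
  expect_true(!is.unsorted(rev(vapply(nrs, function(n) base(nr = n), 0))))
})

test_that("limiting cases behave physically", {
  # no binders in the limit: free -> total
  expect_equal(solve_free(serum_composition(
    150, list(saturable_site("s", 0, 10)),
    list(nonsaturable_term("n", 0))))$free, 150)
  # infinitely tight site with excess capacity: free -> 0
  expect_lt(solve_free(serum_composition(
    150, list(saturable_site("s", 1000, 1e-9))))$free, 1e-6)
})

test_that("cleavage redistributes capacity, conserves it, and raises free", {
  serum <- reference_serum()

  # identity cases
  same <- apply_cleavage(serum, 0)
  expect_equal(solve_free(same)$free, solve_free(serum)$free)
  ratio1 <- apply_cleavage(serum, 0.7, affinity_ratio = 1)
  expect_equal(solve_free(ratio1)$free, solve_free(serum)$free,
               tolerance = 1e-12)

  # full cleavage at 10x affinity loss (frozen from the oracle)
  full <- apply_cleavage(serum, 1, affinity_ratio = 10)
  p <- solve_free(full)
  expect_equal(p$free, 38.697382, tolerance = 1e-6)
  expect_equal(p$free / solve_free(serum)$free, 3.7274472,
               tolerance = 1e-5)

  # capacity conservation and monotonicity of the freed pool
  caps <- function(s) sum(vapply(s$saturable, `[[`, 0, "bmax"))
  fracs <- seq(0, 1, by = 0.2)
  frees <- vapply(fracs, function(f) {
    cl <- apply_cleavage(serum, f, 10)
    expect_equal(caps(cl), caps(serum))
    solve_free(cl)$free
  }, 0)
  expect_true(!is.unsorted(frees))
  ratios <- c(1, 2, 5, 10, 50)
  frees_r <- vapply(ratios, function(r)
    solve_free(apply_cleavage(serum, 0.8, r))$free, 0)
  expect_true(!is.unsorted(frees_r))

  # errors
  expect_error(apply_cleavage(serum_composition(100), 0.5), "CBG_intact")
  expect_error(apply_cleavage(serum, 1.5), "outside")
})

test_that("reporter response follows the Hill curve", {
  expect_equal(reporter_response(0, 1, 4, 10), 1)
  expect_equal(reporter_response(10, 1, 4, 10), 3)       # ec50: half-max
  expect_equal(reporter_response(1e9, 1, 4, 10), 5, tolerance = 1e-6)
  f <- seq(0, 100, by = 5)
  expect_true(!is.unsorted(reporter_response(f, 1, 4, 10, hill = 2)))
  expect_error(reporter_response(-1, 1, 4, 10), "free")
  expect_error(reporter_response(10, 1, 4, ec50 = 0), "ec50")
})

test_that("serum compositions round-trip through JSON", {
  serum <- apply_cleavage(reference_serum(), 0.4)
  js <- serum_to_json(serum)
  back <- serum_from_json(js)
  expect_equal(back, serum)

  path <- withr::local_tempfile(fileext = ".json")
  serum_to_json(serum, path)
  expect_equal(serum_from_json(path), serum)
})

test_that("partitions export to CSV with the documented columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_partition_csv(solve_free(reference_serum()), path)
  d <- read.csv(path)
  expect_identical(names(d), c("pool", "conc_nM", "fraction_pct"))
  expect_equal(sum(d$conc_nM), 200, tolerance = 1e-8)
  expect_equal(sum(d$fraction_pct), 100, tolerance = 1e-8)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(serum_composition(-5), "total_steroid")
  expect_error(serum_composition(NaN), "total_steroid")
  expect_error(saturable_site("s", 10, 0), "kd")
  expect_error(nonsaturable_term("n", -1), "n_ratio")
  expect_error(serum_composition(
    100, list(saturable_site("CBG_intact", 1, 1),
              saturable_site("CBG_intact", 2, 1))), "at most one")
})

test_that("dilution scales pools but not affinities", {
  stock <- reference_serum()
  dil <- dilute_serum(stock, 50)
  expect_equal(dil$total_steroid, 4)
  expect_equal(dil$saturable[[1]]$bmax, ref_bmax / 50)
  expect_equal(dil$saturable[[1]]$kd, ref_kd)
  expect_equal(dil$dilution, 50)
})
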