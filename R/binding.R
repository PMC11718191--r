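## Mass-action partitioning of a glucocorticoid among saturable binding
## proteins (intact and protease-cleaved CBG), a nonsaturable albumin-like
## pool, and the free fraction.

#' Saturable binding site
#'
#' A single class of saturable, independent binding sites characterised by
#' its capacity and dissociation constant, e.g. corticosteroid-binding
#' globulin (CBG).
#'
#' @param name Site label. The labels `"CBG_intact"` and `"CBG_cleaved"`
#'   have special meaning to [apply_cleavage()].
#' @param bmax Binding-site concentration (nmol/L), `>= 0`.
#' @param kd Dissociation constant (nmol/L), `> 0`.
#' @return An object of class `saturable_site`.
#' @seealso [serum_composition()], [solve_free()]
#' @export
#' @examples
#' saturable_site("CBG_intact", bmax = 336.8, kd = 10)
saturable_site <- function(name, bmax, kd) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_scalar(bmax, "bmax", min = 0)
  check_scalar(kd, "kd", min = 0, strict_min = TRUE)
  structure(list(name = name, bmax = bmax, kd = kd),
            class = "saturable_site")
}

#' Nonsaturable binding term
#'
#' A linear (nonsaturable) partition: bound = `n_ratio` * free. Used for
#' the low-affinity, high-capacity albumin pool, which is far from
#' saturation at physiological steroid levels.
#'
#' @param name Term label, e.g. `"albumin"`.
#' @param n_ratio Bound-to-free concentration ratio (dimensionless), `>= 0`.
#' @return An object of class `nonsaturable_term`.
#' @export
#' @examples
#' nonsaturable_term("albumin", n_ratio = 1.74)
nonsaturable_term <- function(name, n_ratio) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_scalar(n_ratio, "n_ratio", min = 0)
  structure(list(name = name, n_ratio = n_ratio),
            class = "nonsaturable_term")
}

#' Serum composition
#'
#' A steroid pool together with its binding species at a stated dilution.
#' All concentrations are post-dilution (in-assay) values; use
#' [dilute_serum()] to derive a diluted composition from a stock.
#'
#' @param total_steroid Total steroid concentration (nmol/L), `>= 0`.
#' @param saturable List of [saturable_site()] objects. At most one site
#'   may be named `"CBG_intact"` and one `"CBG_cleaved"`.
#' @param nonsaturable List of [nonsaturable_term()] objects.
#' @param dilution Fold-dilution already applied (`>= 1`); a record, not a
#'   scaling instruction.
#' @param species_label `"human"` or `"mouse"`.
#' @return An object of class `serum_composition`.
#' @export
#' @examples
#' reference_serum()
serum_composition <- function(total_steroid,
                              saturable = list(),
                              nonsaturable = list(),
                              dilution = 1,
                              species_label = c("human", "mouse")) {
  check_scalar(total_steroid, "total_steroid", min = 0)
  check_scalar(dilution, "dilution", min = 1)
  species_label <- match.arg(species_label)
  stopifnot(is.list(saturable), is.list(nonsaturable))
  for (s in saturable) {
    if (!inherits(s, "saturable_site"))
      stop("'saturable' must contain saturable_site objects", call. = FALSE)
  }
  for (n in nonsaturable) {
    if (!inherits(n, "nonsaturable_term"))
      stop("'nonsaturable' must contain nonsaturable_term objects",
           call. = FALSE)
  }
  nm <- vapply(saturable, `[[`, "", "name")
  for (special in c("CBG_intact", "CBG_cleaved")) {
    if (sum(nm == special) > 1L)
      stop(sprintf("at most one site may be named '%s'", special),
           call. = FALSE)
  }
  structure(list(total_steroid = total_steroid,
                 saturable = saturable,
                 nonsaturable = nonsaturable,
                 dilution = dilution,
                 species_label = species_label),
            class = "serum_composition")
}

#' @export
print.serum_composition <- function(x, ...) {
  cat(sprintf("Serum composition (%s, %g-fold diluted)\n",
              x$species_label, x$dilution))
  cat(sprintf("  total steroid: %.4g nmol/L\n", x$total_steroid))
  for (s in x$saturable)
    cat(sprintf("  site %-12s Bmax %.4g nmol/L, Kd %.4g nmol/L\n",
                s$name, s$bmax, s$kd))
  for (n in x$nonsaturable)
    cat(sprintf("  term %-12s bound:free ratio %.4g\n", n$name, n$n_ratio))
  invisible(x)
}

#' Dilute a stock serum composition
#'
#' Divides the total steroid and every saturable capacity by `factor`
#' (dissociation constants and nonsaturable ratios are concentration
#' ratios and do not scale), and multiplies the recorded dilution.
#'
#' @param serum A [serum_composition()].
#' @param factor Fold-dilution to apply (`>= 1`).
#' @return A new `serum_composition`.
#' @export
dilute_serum <- function(serum, factor) {
  stopifnot(inherits(serum, "serum_composition"))
  check_scalar(factor, "factor", min = 1)
  sat <- lapply(serum$saturable, function(s)
    saturable_site(s$name, s$bmax / factor, s$kd))
  serum_composition(serum$total_steroid / factor, sat, serum$nonsaturable,
                    dilution = serum$dilution * factor,
                    species_label = serum$species_label)
}

#' Pinned reference human serum composition
#'
#' The reference parameter set used throughout: CBG Bmax 336.8 nmol/L
#' (control-group mean binding capacity), CBG Kd 10 nmol/L, albumin
#' bound:free ratio 1.74, total cortisol 200 nmol/L. Under these constants
#' the solved partition lies inside the physiological bounds for human
#' plasma (CBG-bound > 85%, free 5-10%).
#'
#' @param total_steroid Total cortisol (nmol/L); default 200.
#' @param cbg_bmax CBG capacity (nmol/L); default 336.8.
#' @param cbg_kd CBG dissociation constant (nmol/L); default 10.
#' @param albumin_ratio Albumin bound:free ratio; default 1.74.
#' @return A `serum_composition`.
#' @export
#' @examples
#' solve_free(reference_serum())
reference_serum <- function(total_steroid = 200, cbg_bmax = 336.8,
                            cbg_kd = 10, albumin_ratio = 1.74) {
  serum_composition(
    total_steroid,
    saturable = list(saturable_site("CBG_intact", cbg_bmax, cbg_kd)),
    nonsaturable = list(nonsaturable_term("albumin", albumin_ratio)),
    dilution = 1, species_label = "human")
}

# Scalar mass balance: positive free concentration F satisfies
#   F * (1 + sum n_ratio) + sum Bmax_i * F / (Kd_i + F) = total.
# Strictly increasing in F, so a sign change on [0, total] brackets the
# unique root.
balance_fn <- function(F, serum) {
  nr <- vapply(serum$nonsaturable, `[[`, 0, "n_ratio")
  bound_sat <- 0
  for (s in serum$saturable) bound_sat <- bound_sat + s$bmax * F / (s$kd + F)
  F * (1 + sum(nr)) + bound_sat - serum$total_steroid
}

#' Solve the free-steroid equilibrium
#'
#' Finds the unique free concentration `F >= 0` satisfying the mass-action
#' balance `F(1 + sum n_i) + sum Bmax_i F/(Kd_i + F) = total`, by bracketed
#' bisection on `[0, total]` to 1e-12 absolute tolerance (200-iteration
#' cap). The balance is strictly increasing in `F`, so the bracket is
#' guaranteed and the root unique.
#'
#' @param serum A [serum_composition()].
#' @return An object of class `gc_partition`: a list with `free` (nmol/L),
#'   `bound_by_site` (named numeric, nmol/L; nonsaturable terms reported as
#'   `n_ratio * free`), `free_fraction_pct`, `fraction_by_site_pct`, and
#'   `total_steroid`. Free plus total bound equals the total steroid to
#'   within 1e-9 relative tolerance.
#' @export
#' @examples
#' p <- solve_free(reference_serum())
#' p$free_fraction_pct                      # ~5.19 %
#' p$fraction_by_site_pct[["CBG_intact"]]   # ~85.8 %
solve_free <- function(serum) {
  stopifnot(inherits(serum, "serum_composition"))
  total <- serum$total_steroid
  if (!is.finite(total)) stop("non-finite total steroid", call. = FALSE)

  if (total == 0) {
    free <- 0
  } else {
    lo <- 0; hi <- total
    f_lo <- balance_fn(lo, serum)      # = -total < 0
    f_hi <- balance_fn(hi, serum)      # >= 0 since F(1+.) >= total at F=total
    if (!is.finite(f_lo) || !is.finite(f_hi))
      stop("non-finite balance; check composition parameters", call. = FALSE)
    converged <- FALSE
    for (it in seq_len(200L)) {
      mid <- 0.5 * (lo + hi)
      f_mid <- balance_fn(mid, serum)
      if (f_mid >= 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-12) { converged <- TRUE; break }
    }
    if (!converged && hi - lo >= 1e-12)
      stop("bisection failed to converge within 200 iterations",
           call. = FALSE)
    free <- 0.5 * (lo + hi)
  }

  bound <- numeric(0)
  for (s in serum$saturable)
    bound[s$name] <- s$bmax * free / (s$kd + free)
  for (n in serum$nonsaturable)
    bound[n$name] <- n$n_ratio * free

  # Renormalise the residual bisection error onto the free pool so mass
  # conservation holds to ~machine precision.
  if (total > 0) free <- total - sum(bound)
  free <- max(free, 0)

  frac <- if (total > 0) 100 * bound / total else bound * 0
  structure(list(free = free,
                 bound_by_site = bound,
                 free_fraction_pct = if (total > 0) 100 * free / total else 100,
                 fraction_by_site_pct = frac,
                 total_steroid = total),
            class = "gc_partition")
}

#' @export
print.gc_partition <- function(x, ...) {
  cat(sprintf("Glucocorticoid partition of %.4g nmol/L total\n",
              x$total_steroid))
  cat(sprintf("  free : %.4g nmol/L (%.3g%%)\n", x$free,
              x$free_fraction_pct))
  for (nm in names(x$bound_by_site))
    cat(sprintf("  %-12s %.4g nmol/L (%.3g%%)\n", nm,
                x$bound_by_site[[nm]], x$fraction_by_site_pct[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.gc_partition <- function(x, ...) {
  data.frame(pool = c("free", names(x$bound_by_site)),
             conc_nM = c(x$free, unname(x$bound_by_site)),
             fraction_pct = c(x$free_fraction_pct,
                              unname(x$fraction_by_site_pct)),
             stringsAsFactors = FALSE)
}

#' Write a partition to CSV
#'
#' Columns `pool,conc_nM,fraction_pct`, UTF-8, "." decimal.
#'
#' @param partition A `gc_partition` from [solve_free()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  stopifnot(inherits(partition, "gc_partition"))
  utils::write.csv(as.data.frame(partition), path, row.names = FALSE)
  invisible(path)
}

#' Redistribute CBG capacity after proteolytic cleavage
#'
#' Moves a fraction of the intact-CBG capacity to a cleaved-CBG site whose
#' dissociation constant is `affinity_ratio` times the intact Kd (cleavage
#' of the reactive centre loop lowers affinity, i.e. raises Kd). Total
#' binding capacity is conserved.
#'
#' @param serum A [serum_composition()] containing a site named
#'   `"CBG_intact"`.
#' @param fraction_cleaved Fraction of intact capacity cleaved, in `[0, 1]`.
#' @param affinity_ratio Kd multiplier for the cleaved site (`>= 1`);
#'   default 10.
#' @return A new `serum_composition` with the capacity split between
#'   `"CBG_intact"` and `"CBG_cleaved"`.
#' @export
#' @examples
#' cleaved <- apply_cleavage(reference_serum(), 1.0, affinity_ratio = 10)
#' solve_free(cleaved)$free_fraction_pct    # ~19.3 %
apply_cleavage <- function(serum, fraction_cleaved, affinity_ratio = 10) {
  stopifnot(inherits(serum, "serum_composition"))
  check_scalar(fraction_cleaved, "fraction_cleaved", min = 0, max = 1)
  check_scalar(affinity_ratio, "affinity_ratio", min = 1)

  nm <- vapply(serum$saturable, `[[`, "", "name")
  i_int <- which(nm == "CBG_intact")
  if (length(i_int) != 1L)
    stop("serum has no site named 'CBG_intact'", call. = FALSE)
  intact <- serum$saturable[[i_int]]

  moved <- intact$bmax * fraction_cleaved
  sat <- serum$saturable
  sat[[i_int]] <- saturable_site("CBG_intact", intact$bmax - moved,
                                 intact$kd)
  i_clv <- which(nm == "CBG_cleaved")
  if (length(i_clv) == 1L) {
    prev <- sat[[i_clv]]
    sat[[i_clv]] <- saturable_site("CBG_cleaved", prev$bmax + moved,
                                   prev$kd)
  } else if (moved > 0) {
    sat[[length(sat) + 1L]] <- saturable_site(
      "CBG_cleaved", moved, intact$kd * affinity_ratio)
  }
  serum_composition(serum$total_steroid, sat, serum$nonsaturable,
                    dilution = serum$dilution,
                    species_label = serum$species_label)
}

#' Sigmoid-Emax reporter response to free glucocorticoid
#'
#' Maps a free glucocorticoid concentration to a transcriptional reporter
#' signal (e.g. a glucocorticoid-responsive luciferase/beta-galactosidase
#' ratio) through a Hill curve: `basal + emax * free^h / (ec50^h + free^h)`.
#' Monotone non-decreasing in `free`.
#'
#' @param free Free glucocorticoid (nmol/L), `>= 0`. Vectorised.
#' @param basal Signal at zero free steroid (arbitrary units).
#' @param emax Maximal signal increment above basal.
#' @param ec50 Free concentration giving the half-maximal increment
#'   (nmol/L, `> 0`).
#' @param hill Hill coefficient (`>= 0`); default 1.
#' @return Reporter signal, same length as `free`.
#' @export
#' @examples
#' reporter_response(10, basal = 1, emax = 4, ec50 = 10)  # 3 = basal + emax/2
reporter_response <- function(free, basal, emax, ec50, hill = 1) {
  if (any(!is.finite(free)) || any(free < 0))
    stop("'free' must be finite and >= 0", call. = FALSE)
  check_scalar(ec50, "ec50", min = 0, strict_min = TRUE)
  check_scalar(hill, "hill", min = 0)
  fh <- free^hill
  basal + emax * fh / (ec50^hill + fh)
}

#' Serialise a serum composition to JSON
#'
#' Keys: `total_nM`, `sites` (array of `{name, bmax_nM, kd_nM}`),
#' `nonsaturable` (array of `{name, n_ratio}`), `dilution`,
#' `species_label`. [serum_from_json()] inverts it exactly.
#'
#' @param serum A [serum_composition()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
serum_to_json <- function(serum, path = NULL) {
  stopifnot(inherits(serum, "serum_composition"))
  obj <- list(
    total_nM = serum$total_steroid,
    sites = lapply(serum$saturable, function(s)
      list(name = s$name, bmax_nM = s$bmax, kd_nM = s$kd)),
    nonsaturable = lapply(serum$nonsaturable, function(n)
      list(name = n$name, n_ratio = n$n_ratio)),
    dilution = serum$dilution,
    species_label = serum$species_label)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname serum_to_json
#' @param json JSON string or path to a JSON file.
#' @export
serum_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  serum_composition(
    obj$total_nM,
    saturable = lapply(obj$sites, function(s)
      saturable_site(s$name, s$bmax_nM, s$kd_nM)),
    nonsaturable = lapply(obj$nonsaturable, function(n)
      nonsaturable_term(n$name, n$n_ratio)),
    dilution = obj$dilution %||% 1,
    species_label = obj$species_label %||% "human")
}
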