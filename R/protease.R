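## Neutrophil elastase (NE) activity, its stoichiometric inhibition by
## alpha-1-antitrypsin (AAT), and the resulting time/dose-dependent
## cleavage of CBG.

#' Protease model constants
#'
#' The three constants that connect NE dose units to the binding model.
#' The commercial enzyme is dosed in activity units ("U"); a single
#' conversion maps U to an in-assay micromolar concentration so that the
#' serpin stoichiometry can be applied. Defaults: 1 uM per U (so 100 uM
#' AAT is a large stoichiometric excess over a 4 U dose), a 1:1 serpin
#' inhibition stoichiometry, and a cleavage rate constant `ln(10)/40` per
#' U per minute (a 4 U, 10-minute exposure cleaves 90% of intact CBG).
#'
#' @param units_to_umolar Conversion from NE activity units to umol/L
#'   in-assay (`> 0`).
#' @param si Serpin inhibition stoichiometry, mol AAT per mol NE (`> 0`).
#' @param k_cleave Pseudo-first-order cleavage rate constant, per U per
#'   minute (`> 0`).
#' @return An object of class `protease_constants`.
#' @export
protease_constants <- function(units_to_umolar = 1, si = 1,
                               k_cleave = log(10) / 40) {
  check_scalar(units_to_umolar, "units_to_umolar", min = 0, strict_min = TRUE)
  check_scalar(si, "si", min = 0, strict_min = TRUE)
  check_scalar(k_cleave, "k_cleave", min = 0, strict_min = TRUE)
  structure(list(units_to_umolar = units_to_umolar, si = si,
                 k_cleave = k_cleave),
            class = "protease_constants")
}

#' Protease treatment arm
#'
#' One in-vitro treatment condition: an NE dose, an optional AAT
#' pre-incubation, and the incubation times. The headline conditions are
#' vehicle (0 U), NE 4 U, and NE 4 U + AAT 100 uM, each 10 min at 37 C
#' with AAT pre-incubated with the enzyme before serum exposure.
#'
#' @param ne_units NE dose (activity units, `>= 0`).
#' @param aat_conc AAT concentration (umol/L, `>= 0`).
#' @param preincubation_min AAT-NE pre-incubation time (min); recorded.
#' @param incubation_min Serum incubation time (min, `>= 0`).
#' @param temperature_c Temperature (degrees C); recorded only.
#' @return An object of class `protease_treatment`.
#' @export
#' @examples
#' protease_treatment(ne_units = 4, aat_conc = 100)
protease_treatment <- function(ne_units = 0, aat_conc = 0,
                               preincubation_min = 10, incubation_min = 10,
                               temperature_c = 37) {
  check_scalar(ne_units, "ne_units", min = 0)
  check_scalar(aat_conc, "aat_conc", min = 0)
  check_scalar(preincubation_min, "preincubation_min", min = 0)
  check_scalar(incubation_min, "incubation_min", min = 0)
  check_scalar(temperature_c, "temperature_c")
  structure(list(ne_units = ne_units, aat_conc = aat_conc,
                 preincubation_min = preincubation_min,
                 incubation_min = incubation_min,
                 temperature_c = temperature_c),
            class = "protease_treatment")
}

#' Residual NE activity after serpin inhibition
#'
#' Stoichiometric (suicide-substrate) inhibition: AAT irreversibly
#' consumes NE mole for mole (times the stoichiometry `si`), so with
#' enzyme concentration `E = ne_units * units_to_umolar` the surviving
#' active fraction is `max(0, (E - si * aat) / E)`. Zero NE returns 0 by
#' convention (no activity to retain).
#'
#' @param ne_units NE dose (U, `>= 0`).
#' @param aat_conc AAT concentration (umol/L, `>= 0`).
#' @param constants A [protease_constants()].
#' @return Fraction of NE activity remaining, in `[0, 1]`.
#' @export
#' @examples
#' residual_activity(4, 0)     # 1: uninhibited
#' residual_activity(4, 100)   # 0: stoichiometric excess
#' residual_activity(4, 2)     # 0.5 at the default 1 uM/U conversion
residual_activity <- function(ne_units, aat_conc,
                              constants = protease_constants()) {
  check_scalar(ne_units, "ne_units", min = 0)
  check_scalar(aat_conc, "aat_conc", min = 0)
  stopifnot(inherits(constants, "protease_constants"))
  if (ne_units == 0) return(0)
  e_um <- ne_units * constants$units_to_umolar
  max(0, (e_um - constants$si * aat_conc) / e_um)
}

#' Fraction of CBG cleaved by active NE
#'
#' Pseudo-first-order cleavage of the CBG reactive centre loop:
#' `1 - exp(-k_cleave * active_dose * minutes)`. Zero at zero dose or
#' zero time; saturates at 1.
#'
#' @param ne_units_active Active NE dose (U, `>= 0`), i.e. the nominal
#'   dose times [residual_activity()].
#' @param minutes Incubation time (min, `>= 0`).
#' @param k_cleave Rate constant per U per minute; default `ln(10)/40`.
#' @return Cleaved fraction in `[0, 1]`.
#' @export
#' @examples
#' cleave_fraction(4, 10)  # 0.90 at the default rate constant
cleave_fraction <- function(ne_units_active, minutes,
                            k_cleave = log(10) / 40) {
  check_scalar(ne_units_active, "ne_units_active", min = 0)
  check_scalar(minutes, "minutes", min = 0)
  check_scalar(k_cleave, "k_cleave", min = 0, strict_min = TRUE)
  1 - exp(-k_cleave * ne_units_active * minutes)
}

#' Apply a protease treatment to serum and re-solve the equilibrium
#'
#' Composes the axis: AAT pre-incubation first commits inhibition
#' (sequential, not competitive), the surviving NE then cleaves CBG for
#' the incubation time, and the steroid equilibrium is re-solved on the
#' post-cleavage composition. Vehicle (0 U) is the identity: the returned
#' partition equals `solve_free(serum)` field for field.
#'
#' @param serum A [serum_composition()] with a `"CBG_intact"` site.
#' @param treatment A [protease_treatment()].
#' @param constants A [protease_constants()].
#' @param affinity_ratio Kd multiplier for cleaved CBG; default 10.
#' @return A list with `serum` (post-treatment composition), `partition`
#'   (its [solve_free()] result), `residual_activity` and
#'   `fraction_cleaved`.
#' @export
#' @examples
#' out <- treat_serum(reference_serum(), protease_treatment(ne_units = 4))
#' out$partition$free_fraction_pct   # risen from ~5.2 %
treat_serum <- function(serum, treatment,
                        constants = protease_constants(),
                        affinity_ratio = 10) {
  stopifnot(inherits(serum, "serum_composition"),
            inherits(treatment, "protease_treatment"))
  act <- residual_activity(treatment$ne_units, treatment$aat_conc, constants)
  frac <- cleave_fraction(treatment$ne_units * act,
                          treatment$incubation_min,
                          constants$k_cleave)
  post <- if (frac > 0) {
    apply_cleavage(serum, frac, affinity_ratio)
  } else {
    serum
  }
  list(serum = post,
       partition = solve_free(post),
       residual_activity = act,
       fraction_cleaved = frac)
}

#' High-affinity steroid-binding capacity of a composition
#'
#' The capacity a ligand-saturation assay reports: the summed Bmax of
#' sites whose Kd does not exceed a high-affinity cutoff. Cleaved CBG
#' (Kd raised ~10-fold) falls above the default cutoff and therefore no
#' longer counts as binding capacity, so capacity is non-increasing under
#' cleavage.
#'
#' @param serum A [serum_composition()].
#' @param kd_cutoff Absolute Kd cutoff (nmol/L). Default: the intact-CBG
#'   Kd times `affinity_cutoff_ratio`, or `Inf` when no intact site exists.
#' @param affinity_cutoff_ratio Multiplier defining the default cutoff;
#'   default 2.
#' @return Binding capacity (nmol/L).
#' @export
#' @examples
#' binding_capacity_of(reference_serum())                       # 336.8
#' binding_capacity_of(apply_cleavage(reference_serum(), 0.5))  # 168.4
binding_capacity_of <- function(serum, kd_cutoff = NULL,
                                affinity_cutoff_ratio = 2) {
  stopifnot(inherits(serum, "serum_composition"))
  if (is.null(kd_cutoff)) {
    nm <- vapply(serum$saturable, `[[`, "", "name")
    i <- which(nm == "CBG_intact")
    kd_cutoff <- if (length(i) == 1L)
      serum$saturable[[i]]$kd * affinity_cutoff_ratio else Inf
  }
  sum(vapply(serum$saturable, function(s)
    if (s$kd <= kd_cutoff) s$bmax else 0, 0))
}
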