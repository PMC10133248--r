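#' Configuration for the synthetic explant cohort generator
#'
#' Defines the joint distribution of planted ground-truth states, the assay
#' condition grids, per-assay effect sizes and noise, and the survival
#' outcome model. Defaults encode the cohort structure reported for the
#' validation setting: 29 patients with 22/5/2 patients carrying 1/2/3
#' explants, 44% HR-defective prevalence, near mutual exclusivity of the
#' two double-strand-break defects, single-strand-break defect probabilities
#' elevated under HR deficiency, and mitochondrial dysfunction more frequent
#' in HR-competent tumours (0.78 vs 0.57).
#'
#' @param n_patients Number of patients (>= 2).
#' @param explants_per_patient Named probability vector over `"1"`, `"2"`,
#'   `"3"` explants per patient; must sum to 1.
#' @param hrd_prevalence Probability an explant lineage is HR-defective.
#' @param nhej_defect_given_hr Named probabilities
#'   `c(hr_defective = , hr_competent = )` for an NHEJ defect conditional on
#'   HR state; the defaults (0.1 / 0.7) encode the near mutual exclusivity
#'   of the two DSB defects.
#' @param ssb_defect_probs List with elements `BER`, `NER`, `MMR`, each a
#'   named vector `c(hr_competent = , hr_defective = )`; defaults elevate
#'   SSB defects under HR deficiency.
#' @param platinum_resistant_prevalence Probability an explant is platinum
#'   resistant (GR50 >= 48 uM).
#' @param mito_dysfunction_probs Named probabilities
#'   `c(hr_competent = , hr_defective = )` of mitochondrial membrane
#'   dysfunction.
#' @param ros_mito_inverse_strength Association parameter `s` in `[0, 1)`:
#'   P(ROS homoeostatic | mito dysfunctional) = 0.5 + s/2 and
#'   P(ROS homoeostatic | mito homoeostatic) = 0.5 - s/2, encoding the
#'   inverse coupling of the two metabolic states.
#' @param outcome_model `"separable"` (15-month progression label is a
#'   deterministic function of the patient-aggregated true signature),
#'   `"noisy"` (exponential survival whose log-rate is a linear score of the
#'   true signature), or `"null"` (outcomes independent of the signature).
#' @param discordance_prob Per-pathway probability that an explant's true
#'   state differs from its patient's base state (inter-explant
#'   heterogeneity).
#' @param effect_sizes Named list of per-assay signal magnitudes; see
#'   Details. Missing entries keep defaults.
#' @param noise_model Named list of per-assay dispersion parameters; missing
#'   entries keep defaults.
#' @param sizes Named list of per-assay sampling sizes (nuclei, reporter
#'   events, comets per condition, replicates).
#' @param seed Integer RNG seed; a fixed seed reproduces the cohort
#'   bit-identically.
#'
#' @details Effect-size defaults: gamma-H2AX control mean 4 foci with
#' threefold induction; Rad51 control mean 3 foci with fold 3.2 (competent)
#' vs 1.15 (defective); host-cell reactivation uncut-control GFP rate 0.4
#' with conformation repair fractions (0.55, 0.40, 0.30) when competent and
#' 0.03 when defective; comet medians (vehicle 8%, blockade +4, assault+
#' blockade 45% tail DNA) with repair fraction 0.85 vs 0.15; GR50 sampled
#' log-uniformly on [4, 32] uM (sensitive) or [90, 1400] uM (resistant,
#' with 15% censored above the dose range); DCFDA retention plateau 1.3 vs
#' 4.5; JC-10 ratio response 0.45 vs 0.03.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [validation_cohort_config()]
#' @export
cohort_config <- function(n_patients = 29,
                          explants_per_patient = c(`1` = 22, `2` = 5, `3` = 2) / 29,
                          hrd_prevalence = 0.44,
                          nhej_defect_given_hr = c(hr_defective = 0.1, hr_competent = 0.7),
                          ssb_defect_probs = list(
                            BER = c(hr_competent = 0.30, hr_defective = 0.65),
                            NER = c(hr_competent = 0.30, hr_defective = 0.65),
                            MMR = c(hr_competent = 0.20, hr_defective = 0.50)
                          ),
                          platinum_resistant_prevalence = 0.65,
                          mito_dysfunction_probs = c(hr_competent = 0.78, hr_defective = 0.57),
                          ros_mito_inverse_strength = 0.47,
                          outcome_model = c("separable", "noisy", "null"),
                          discordance_prob = 0.05,
                          effect_sizes = list(),
                          noise_model = list(),
                          sizes = list(),
                          seed = NULL) {
  outcome_model <- match.arg(outcome_model)

  if (!is.numeric(n_patients) || n_patients < 2) {
    stop_ddr("n_patients must be >= 2", class = "ddr_config_error")
  }
  assert_prob(hrd_prevalence, "hrd_prevalence")
  assert_prob(platinum_resistant_prevalence, "platinum_resistant_prevalence")
  assert_prob(nhej_defect_given_hr, "nhej_defect_given_hr")
  assert_prob(mito_dysfunction_probs, "mito_dysfunction_probs")
  assert_prob(ros_mito_inverse_strength, "ros_mito_inverse_strength")
  assert_prob(discordance_prob, "discordance_prob")
  for (p in names(ssb_defect_probs)) assert_prob(ssb_defect_probs[[p]], paste0("ssb_defect_probs$", p))
  assert_prob(explants_per_patient, "explants_per_patient")
  if (abs(sum(explants_per_patient) - 1) > 1e-8) {
    stop_ddr("explants_per_patient masses must sum to 1", class = "ddr_config_error")
  }

  es <- utils::modifyList(list(
    gh2ax_control_mean  = 4,
    gh2ax_assault_fold  = 3,
    rad51_control_mean  = 3,
    rad51_fold_competent = 3.2,
    rad51_fold_defective = 1.15,
    reporter_control_rate = 0.40,
    reporter_fractions_competent = c(blunt = 0.55, overhang_5to3 = 0.40, overhang_3to5 = 0.30),
    reporter_fractions_defective = c(blunt = 0.03, overhang_5to3 = 0.03, overhang_3to5 = 0.03),
    comet_vehicle_median = 8,
    comet_blockade_shift = 4,
    comet_assault_median = 45,
    comet_repair_competent = 0.85,
    comet_repair_defective = 0.15,
    survivorship_competent = c(blockade = 0.95, assault = 0.85, both = 0.80),
    survivorship_defective = c(blockade = 0.90, assault = 0.60, both = 0.35),
    gr50_sensitive_range = c(4, 32),
    gr50_resistant_range = c(90, 1400),
    gr50_censored_prob = 0.15,
    ros_plateau_homoeostatic = 1.3,
    ros_plateau_dysfunctional = 4.5,
    mito_response_homoeostatic = 0.45,
    mito_response_dysfunctional = 0.03
  ), effect_sizes)

  nm <- utils::modifyList(list(
    foci_dispersion = 8,          # negative binomial size
    comet_logit_sd = 0.8,         # logit-normal tail %DNA
    comet_variance_inflation_hr_defective = 1.6,
    viability_sigma = 0.05,       # lognormal sdlog around the GR curve
    fluor_cv = 0.08               # gamma CV for plate fluorescence
  ), noise_model)

  sz <- utils::modifyList(list(
    nuclei_per_condition = 150,
    events_per_condition = 5000,  # reporter cells per conformation x timepoint
    comets_per_condition = 7000,
    replicates = 3,
    seeded_cells = 400000,        # comet assay input cells per condition
    cells_per_well = 2000         # cytotoxicity plate seeding
  ), sizes)

  structure(
    list(n_patients = as.integer(n_patients),
         explants_per_patient = explants_per_patient,
         hrd_prevalence = hrd_prevalence,
         nhej_defect_given_hr = nhej_defect_given_hr,
         ssb_defect_probs = ssb_defect_probs,
         platinum_resistant_prevalence = platinum_resistant_prevalence,
         mito_dysfunction_probs = mito_dysfunction_probs,
         ros_mito_inverse_strength = ros_mito_inverse_strength,
         outcome_model = outcome_model,
         discordance_prob = discordance_prob,
         effect_sizes = es, noise_model = nm, sizes = sz,
         seed = seed),
    class = "cohort_config"
  )
}

#' Cohort configuration matching the reported validation-cohort fractions
#'
#' Returns a [cohort_config()] whose planting probabilities equal the
#' printed cohort fractions of the validation setting: HR-defective
#' prevalence 0.44 (7/16 patients), platinum-resistant prevalence 0.75
#' (12/16 patients), and mitochondrial dysfunction probability 0.78 given
#' HR competence vs 0.57 given HR deficiency.
#'
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
validation_cohort_config <- function(...) {
  defaults <- list(
    n_patients = 29,
    hrd_prevalence = 0.44,
    platinum_resistant_prevalence = 0.75,
    mito_dysfunction_probs = c(hr_competent = 0.78, hr_defective = 0.57)
  )
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d patients, HRD prevalence %.2f, platinum-resistant %.2f, outcome model '%s'\n",
              x$n_patients, x$hrd_prevalence, x$platinum_resistant_prevalence, x$outcome_model))
  invisible(x)
}

#' The 12-point carboplatin concentration grid (uM)
#' @export
carboplatin_grid <- function() c(0, 1, 4, 8, 16, 32, 64, 128, 256, 512, 1024, 2048)

#' The 8-point TBHP concentration grid for the DCFDA ROS assay (uM)
#' @export
tbhp_grid <- function() c(0, 4, 8, 16, 32, 64, 128, 256)

#' The 5-point hydrogen peroxide grid for the JC-10 assay (mM)
#' @export
h2o2_grid <- function() c(0, 0.2, 0.4, 0.8, 1.6)
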