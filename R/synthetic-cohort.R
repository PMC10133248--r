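#' Generate a synthetic explant cohort with planted ground truth
#'
#' Draws a full cohort — patients, explants, raw per-cell/per-well readouts
#' for all eight assays, and survival outcomes — from the generative model
#' described in [cohort_config()]. Every downstream scorer in the package
#' can be exercised against the planted states.
#'
#' Measurement families: foci counts are negative binomial; comet tail %DNA
#' is logit-normal (median-preserving) clipped to \[0, 100\]; reporter GFP
#' events are Bernoulli per cell; viability counts are lognormal around the
#' explant's true GR curve; plate fluorescence is gamma-distributed.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ddr_cohort`: a list with elements
#'   `truth` (`$explants`, `$patients` data frames of planted states),
#'   `clinical` (patient table with PFS/OS days, event flags and PS/IDS
#'   route), `assays` (named list of long-format measurement tables:
#'   `foci`, `reporter`, `comet`, `viability`, `dcfda`, `jc10`,
#'   `variants`), and the `config` used.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_ddr("config must be a cohort_config object", class = "ddr_config_error")
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  es <- config$effect_sizes; nm <- config$noise_model; sz <- config$sizes
  n_pat <- config$n_patients

  ## ---- patient-level base states --------------------------------------
  patient_id <- sprintf("P%03d", seq_len(n_pat))
  n_expl_per_pat <- sample(as.integer(names(config$explants_per_patient)),
                           n_pat, replace = TRUE,
                           prob = config$explants_per_patient)
  hr_def <- stats::runif(n_pat) < config$hrd_prevalence
  nhej_def <- stats::runif(n_pat) < ifelse(hr_def,
                                           config$nhej_defect_given_hr[["hr_defective"]],
                                           config$nhej_defect_given_hr[["hr_competent"]])
  ssb_def <- sapply(c("BER", "NER", "MMR"), function(p) {
    pr <- config$ssb_defect_probs[[p]]
    stats::runif(n_pat) < ifelse(hr_def, pr[["hr_defective"]], pr[["hr_competent"]])
  })
  plat_res <- stats::runif(n_pat) < config$platinum_resistant_prevalence
  mito_dys <- stats::runif(n_pat) < ifelse(hr_def,
                                           config$mito_dysfunction_probs[["hr_defective"]],
                                           config$mito_dysfunction_probs[["hr_competent"]])
  s <- config$ros_mito_inverse_strength
  ros_hom <- stats::runif(n_pat) < ifelse(mito_dys, 0.5 + s / 2, 0.5 - s / 2)

  base <- data.frame(
    patient_id = patient_id,
    hr = ifelse(hr_def, "defective", "competent"),
    nhej = ifelse(nhej_def, "defective", "competent"),
    ber = ifelse(ssb_def[, "BER"], "defective", "competent"),
    ner = ifelse(ssb_def[, "NER"], "defective", "competent"),
    mmr = ifelse(ssb_def[, "MMR"], "defective", "competent"),
    platinum = ifelse(plat_res, "resistant", "sensitive"),
    mito = ifelse(mito_dys, "dysfunctional", "homoeostatic"),
    ros = ifelse(ros_hom, "homoeostatic", "dysfunctional"),
    stringsAsFactors = FALSE
  )

  ## ---- explant-level states (patient base with rare discordance) ------
  ex_pat <- rep(seq_len(n_pat), n_expl_per_pat)
  n_ex <- length(ex_pat)
  explant_id <- sprintf("%s-E%d", patient_id[ex_pat],
                        unlist(lapply(n_expl_per_pat, seq_len)))
  flip <- function(states) {
    f <- stats::runif(n_ex) < config$discordance_prob
    lv <- sort(unique(states))
    ifelse(f & length(lv) == 2, ifelse(states == lv[1], lv[2], lv[1]), states)
  }
  ex <- data.frame(explant_id = explant_id, patient_id = patient_id[ex_pat],
                   stringsAsFactors = FALSE)
  for (col in c("hr", "nhej", "ber", "ner", "mmr", "platinum", "mito", "ros")) {
    st <- base[[col]][ex_pat]
    # ensure both labels are available to flip into even if the cohort draw
    # happened to be homogeneous
    lv2 <- switch(col,
                  platinum = c("resistant", "sensitive"),
                  mito = c("dysfunctional", "homoeostatic"),
                  ros = c("dysfunctional", "homoeostatic"),
                  c("competent", "defective"))
    f <- stats::runif(n_ex) < config$discordance_prob
    ex[[col]] <- ifelse(f, ifelse(st == lv2[1], lv2[2], lv2[1]), st)
  }

  ## ---- planted GR curves ----------------------------------------------
  resist <- ex$platinum == "resistant"
  censored <- resist & stats::runif(n_ex) < es$gr50_censored_prob
  gr50 <- ifelse(resist,
                 exp(stats::runif(n_ex, log(es$gr50_resistant_range[1]),
                                  log(es$gr50_resistant_range[2]))),
                 exp(stats::runif(n_ex, log(es$gr50_sensitive_range[1]),
                                  log(es$gr50_sensitive_range[2]))))
  gr50[censored] <- Inf
  gr_inf <- ifelse(resist, stats::runif(n_ex, -0.2, 0.3), stats::runif(n_ex, -0.6, 0.1))
  gr_inf[censored] <- stats::runif(sum(censored), 0.55, 0.85)
  hill <- stats::runif(n_ex, 1.2, 2.5)
  gec50 <- ifelse(is.finite(gr50),
                  gr50 / (0.5 / (0.5 - pmin(gr_inf, 0.499)))^(1 / hill),
                  exp(stats::runif(n_ex, log(20), log(200))))

  ex$gr50_true <- gr50
  ex$gr_inf_true <- gr_inf
  ex$hill_true <- hill
  ex$gec50_true <- gec50

  ## ---- patient-aggregated truth (defective/resistant-dominant) --------
  agg_dom <- function(states, bad) {
    vapply(split(states, ex$patient_id), function(s) {
      if (any(s == bad)) bad else s[1]
    }, character(1))
  }
  pat_truth <- data.frame(patient_id = sort(unique(ex$patient_id)), stringsAsFactors = FALSE)
  for (col in c("hr", "nhej", "ber", "ner", "mmr")) {
    pat_truth[[col]] <- agg_dom(ex[[col]], "defective")[pat_truth$patient_id]
  }
  pat_truth$platinum <- agg_dom(ex$platinum, "resistant")[pat_truth$patient_id]
  pat_truth$mito <- agg_dom(ex$mito, "dysfunctional")[pat_truth$patient_id]
  pat_truth$ros <- agg_dom(ex$ros, "dysfunctional")[pat_truth$patient_id]
  pat_truth <- pat_truth[match(patient_id, pat_truth$patient_id), ]
  rownames(pat_truth) <- NULL

  ## ---- survival outcomes ----------------------------------------------
  horizon15 <- 15 * DAYS_PER_MONTH
  # separable regime: the label depends on the two widest-margin signature
  # components (GR50 platinum class and Rad51 HR state), so separability
  # survives the measurement layer; the noisy model also loads on the
  # lower-margin mitochondrial state
  risk15 <- pat_truth$platinum == "resistant" & pat_truth$hr == "defective"
  if (config$outcome_model == "separable") {
    pfs_days <- ifelse(risk15, stats::runif(n_pat, 80, horizon15 - 20),
                       stats::runif(n_pat, horizon15 + 50, 1200))
    pfs_event <- risk15
  } else if (config$outcome_model == "noisy") {
    lp <- 1.2 * (pat_truth$platinum == "resistant") +
      1.0 * (pat_truth$mito == "dysfunctional") +
      0.5 * (pat_truth$hr == "defective") - 1.5
    pfs_days <- stats::rexp(n_pat, rate = exp(lp) / 600)
    pfs_event <- pfs_days < 1500
    pfs_days <- pmin(pfs_days, 1500)
  } else { # null
    pfs_days <- stats::rexp(n_pat, rate = 1 / 500)
    pfs_event <- pfs_days < 1500
    pfs_days <- pmin(pfs_days, 1500)
  }
  pfs_days <- pmax(pfs_days, 1)
  os_days <- pfs_days + stats::runif(n_pat, 60, 400)
  os_event <- pfs_event & stats::runif(n_pat) < 0.7

  clinical <- data.frame(
    patient_id = patient_id,
    histotype = ifelse(stats::runif(n_pat) < 0.62, "HGSOC", "other"),
    route = ifelse(stats::runif(n_pat) < 0.44, "PS", "IDS"),
    n_explants = n_expl_per_pat,
    pfs_days = round(pfs_days, 1),
    os_days = round(os_days, 1),
    pfs_event = pfs_event,
    os_event = os_event,
    stringsAsFactors = FALSE
  )

  ## ---- assay tables -----------------------------------------------------
  assays <- list(
    foci = sim_foci(ex, es, nm, sz),
    reporter = sim_reporter(ex, es, sz),
    comet = sim_comet(ex, es, nm, sz),
    viability = sim_viability(ex, nm, sz),
    dcfda = sim_dcfda(ex, es, nm, sz),
    jc10 = sim_jc10(ex, es, nm, sz),
    variants = sim_variants(ex)
  )

  structure(list(truth = list(explants = ex, patients = cbind(pat_truth,
                                clinical[, c("pfs_days", "os_days", "pfs_event",
                                             "os_event", "route")])),
                 clinical = clinical, assays = assays, config = config),
            class = "ddr_cohort")
}

# ---- per-assay simulators (internal, vectorised across explants) --------

sim_foci <- function(ex, es, nm, sz) {
  n_ex <- nrow(ex); n <- sz$nuclei_per_condition
  rad51_fold <- ifelse(ex$hr == "competent", es$rad51_fold_competent, es$rad51_fold_defective)
  grid <- expand.grid(i = seq_len(n_ex), condition = c("control", "irradiated"),
                      stringsAsFactors = FALSE)
  mu_gh2ax <- ifelse(grid$condition == "control", es$gh2ax_control_mean,
                     es$gh2ax_control_mean * es$gh2ax_assault_fold)
  mu_rad51 <- ifelse(grid$condition == "control", es$rad51_control_mean,
                     es$rad51_control_mean * rad51_fold[grid$i])
  idx <- rep(seq_len(nrow(grid)), each = n)
  data.frame(
    explant_id = ex$explant_id[grid$i][idx],
    nucleus_id = sequence(rep(n, nrow(grid))),
    condition = grid$condition[idx],
    gH2AX_foci = stats::rnbinom(length(idx), size = nm$foci_dispersion, mu = mu_gh2ax[idx]),
    rad51_foci = stats::rnbinom(length(idx), size = nm$foci_dispersion, mu = mu_rad51[idx]),
    stringsAsFactors = FALSE
  )
}

sim_reporter <- function(ex, es, sz) {
  n_ex <- nrow(ex); n <- sz$events_per_condition
  confs <- c("uncut_control", "blunt", "overhang_5to3", "overhang_3to5")
  grid <- expand.grid(i = seq_len(n_ex), conformation = confs,
                      timepoint_h = c(24, 48, 72), stringsAsFactors = FALSE)
  frac <- matrix(1, nrow = n_ex, ncol = 4, dimnames = list(NULL, confs))
  comp <- ex$nhej == "competent"
  for (cf in confs[-1]) {
    frac[, cf] <- ifelse(comp, es$reporter_fractions_competent[[cf]],
                         es$reporter_fractions_defective[[cf]])
  }
  rate <- es$reporter_control_rate *
    frac[cbind(grid$i, match(grid$conformation, confs))]
  idx <- rep(seq_len(nrow(grid)), each = n)
  data.frame(
    explant_id = ex$explant_id[grid$i][idx],
    conformation = grid$conformation[idx],
    timepoint_h = grid$timepoint_h[idx],
    cell_id = sequence(rep(n, nrow(grid))),
    gfp_positive = stats::runif(length(idx)) < rate[idx],
    stringsAsFactors = FALSE
  )
}

sim_comet <- function(ex, es, nm, sz) {
  n_ex <- nrow(ex)
  conds <- c("1_vehicle", "2_blockade", "3_assault", "4_assault_plus_blockade")
  m1 <- es$comet_vehicle_median
  m4 <- es$comet_assault_median
  out <- vector("list", 2)
  comp <- ex$hr == "competent"
  surv <- t(vapply(seq_len(n_ex), function(i) {
    s <- if (comp[i]) es$survivorship_competent else es$survivorship_defective
    c(1, s[["blockade"]], s[["assault"]], s[["both"]])
  }, numeric(4)))
  for (pi in 1:2) {
    pathway <- c("BER", "NER")[pi]
    R <- ifelse(switch(pathway, BER = ex$ber, NER = ex$ner) == "competent",
                es$comet_repair_competent, es$comet_repair_defective)
    med <- cbind(m1, m1 + es$comet_blockade_shift, m4 - R * (m4 - m1), m4)
    grid <- expand.grid(i = seq_len(n_ex), cond = 1:4)
    counts <- stats::rpois(nrow(grid),
                           sz$comets_per_condition * surv[cbind(grid$i, grid$cond)])
    counts <- pmax(counts, 2L)
    idx <- rep(seq_len(nrow(grid)), counts)
    sd_logit <- nm$comet_logit_sd *
      ifelse(grid$cond == 3 & !comp[grid$i], nm$comet_variance_inflation_hr_defective, 1)
    mlog <- stats::qlogis(med[cbind(grid$i, grid$cond)] / 100)
    tail_pct <- 100 * stats::plogis(stats::rnorm(length(idx), mlog[idx], sd_logit[idx]))
    out[[pi]] <- data.frame(
      explant_id = ex$explant_id[grid$i][idx],
      pathway = pathway,
      condition = conds[grid$cond][idx],
      comet_id = sequence(counts),
      tail_pct_dna = tail_pct,
      stringsAsFactors = FALSE
    )
  }
  rbind(out[[1]], out[[2]])
}

sim_viability <- function(ex, nm, sz) {
  n_ex <- nrow(ex)
  doses <- carboplatin_grid()
  growth <- stats::runif(n_ex, 1.5, 2.5)       # control doublings over the assay
  x0 <- sz$cells_per_well
  grid <- expand.grid(i = seq_len(n_ex), dose = doses,
                      replicate = seq_len(sz$replicates))
  gr_true <- gr_sigmoid(grid$dose, ex$gr_inf_true[grid$i],
                        ex$gec50_true[grid$i], ex$hill_true[grid$i])
  gr_true[grid$dose == 0] <- 1
  xc <- x0 * 2^(log2(gr_true + 1) * growth[grid$i])
  data.frame(
    explant_id = ex$explant_id[grid$i],
    dose_uM = grid$dose,
    replicate = grid$replicate,
    count = xc * stats::rlnorm(nrow(grid), 0, nm$viability_sigma),
    x0 = x0,
    stringsAsFactors = FALSE
  )
}

sim_dcfda <- function(ex, es, nm, sz) {
  n_ex <- nrow(ex)
  doses <- tbhp_grid()
  plateau <- ifelse(ex$ros == "homoeostatic",
                    es$ros_plateau_homoeostatic, es$ros_plateau_dysfunctional)
  grid <- expand.grid(i = seq_len(n_ex), dose = doses,
                      replicate = seq_len(sz$replicates))
  rho <- 1 + (plateau[grid$i] - 1) * grid$dose / (grid$dose + 16)
  mu <- 1000 * rho
  cv <- nm$fluor_cv
  data.frame(
    explant_id = ex$explant_id[grid$i],
    dose_uM = grid$dose,
    replicate = grid$replicate,
    fluorescence_au = stats::rgamma(nrow(grid), shape = 1 / cv^2, scale = mu * cv^2),
    stringsAsFactors = FALSE
  )
}

sim_jc10 <- function(ex, es, nm, sz) {
  n_ex <- nrow(ex)
  doses <- h2o2_grid()
  delta <- ifelse(ex$mito == "homoeostatic",
                  es$mito_response_homoeostatic, es$mito_response_dysfunctional)
  grid <- expand.grid(i = seq_len(n_ex), dose = doses,
                      replicate = seq_len(sz$replicates))
  r <- 1 - delta[grid$i] * (grid$dose / max(doses))^0.8
  cv <- nm$fluor_cv
  mono <- stats::rgamma(nrow(grid), shape = 1 / cv^2, scale = 1000 * cv^2)
  aggr <- stats::rgamma(nrow(grid), shape = 1 / cv^2, scale = 2000 * r * cv^2)
  rbind(
    data.frame(explant_id = ex$explant_id[grid$i], dose_mM = grid$dose,
               replicate = grid$replicate, channel = "em525",
               fluorescence_au = mono, stringsAsFactors = FALSE),
    data.frame(explant_id = ex$explant_id[grid$i], dose_mM = grid$dose,
               replicate = grid$replicate, channel = "em590",
               fluorescence_au = aggr, stringsAsFactors = FALSE)
  )
}

sim_variants <- function(ex) {
  panel <- mmr_panel()
  background_genes <- c("TP53", "KRAS", "BRAF", "PTEN", "PIK3CA", "NF1", "RB1")
  rows <- lapply(seq_len(nrow(ex)), function(i) {
    nb <- 1 + stats::rpois(1, 1.5)
    bg <- data.frame(
      explant_id = ex$explant_id[i],
      gene = sample(background_genes, nb, replace = TRUE),
      impact_snpeff = sample(c("MODERATE", "LOW", "MODIFIER", "HIGH"), nb,
                             replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
      impact_vep = NA_character_,
      consequence = "missense_variant",
      stringsAsFactors = FALSE
    )
    bg$impact_vep <- bg$impact_snpeff   # background: concordant annotators
    if (ex$mmr[i] == "defective") {
      nh <- 1 + stats::rpois(1, 0.5)
      hit <- data.frame(
        explant_id = ex$explant_id[i],
        gene = sample(panel, nh, replace = TRUE),
        impact_snpeff = "HIGH", impact_vep = "HIGH",
        consequence = sample(c("stop_gained", "frameshift_variant"), nh, replace = TRUE),
        stringsAsFactors = FALSE
      )
      rbind(bg, hit)
    } else {
      np <- stats::rpois(1, 1)
      if (np > 0) {
        benign <- data.frame(
          explant_id = ex$explant_id[i],
          gene = sample(panel, np, replace = TRUE),
          impact_snpeff = sample(c("MODERATE", "LOW"), np, replace = TRUE),
          impact_vep = sample(c("MODERATE", "LOW", "MODIFIER"), np, replace = TRUE),
          consequence = "missense_variant",
          stringsAsFactors = FALSE
        )
        # occasional single-annotator HIGH: separates intersect from union mode
        if (stats::runif(1) < 0.15) {
          benign$impact_snpeff[1] <- "HIGH"
        }
        rbind(bg, benign)
      } else bg
    }
  })
  do.call(rbind, rows)
}

#' @export
print.ddr_cohort <- function(x, ...) {
  cat(sprintf("<ddr_cohort> %d patients / %d explants (outcome model '%s')\n",
              nrow(x$clinical), nrow(x$truth$explants), x$config$outcome_model))
  cat("  assays:", paste(names(x$assays), collapse = ", "), "\n")
  invisible(x)
}

#' Write cohort tables to CSV files
#'
#' Writes one CSV per assay plus the clinical and ground-truth tables.
#'
#' @param cohort A `ddr_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (a in names(cohort$assays)) {
    p <- file.path(dir, paste0("assay_", a, ".csv"))
    utils::write.csv(cohort$assays[[a]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort$clinical, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "ground_truth_explants.csv")
  utils::write.csv(cohort$truth$explants, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
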