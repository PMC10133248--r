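# Deterministic fixture builders: constant-valued tables whose summary
# statistics are exact, so expected values can be computed by hand.

make_foci <- function(g_ctrl, g_irr, r_ctrl, r_irr, n = 60, explant = "E1") {
  data.frame(
    explant_id = explant,
    nucleus_id = rep(seq_len(n), 2),
    condition = rep(c("control", "irradiated"), each = n),
    gH2AX_foci = rep(c(g_ctrl, g_irr), each = n),
    rad51_foci = rep(c(r_ctrl, r_irr), each = n),
    stringsAsFactors = FALSE
  )
}

# reporter table with exact GFP+ rates per conformation (same at all
# timepoints unless `best_tp_rates` overrides timepoint 48)
make_events <- function(rates, control_rate = 0.4, n = 1000, explant = "E1") {
  confs <- c(names(rates), "uncut_control")
  rates <- c(rates, uncut_control = control_rate)
  rows <- lapply(confs, function(cf) {
    do.call(rbind, lapply(c(24, 48, 72), function(tp) {
      k <- round(rates[[cf]] * n)
      data.frame(explant_id = explant, conformation = cf, timepoint_h = tp,
                 cell_id = seq_len(n),
                 gfp_positive = c(rep(TRUE, k), rep(FALSE, n - k)),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

make_comet <- function(m1, m2, m3, m4, n = 600, pathway = "BER", explant = "E1") {
  conds <- c("1_vehicle", "2_blockade", "3_assault", "4_assault_plus_blockade")
  vals <- c(m1, m2, m3, m4)
  do.call(rbind, lapply(1:4, function(i) {
    data.frame(explant_id = explant, pathway = pathway, condition = conds[i],
               comet_id = seq_len(n), tail_pct_dna = vals[i],
               stringsAsFactors = FALSE)
  }))
}

make_call <- function(pathway, state, score = NULL) {
  score <- score %||% switch(pathway,
    HR = if (state == "competent") 3 else 1,
    NHEJ = if (state == "competent") 7 else 1,
    MMR = if (state == "competent") 0 else 2,
    if (state == "competent") 0.9 else 0.1)
  ddr_call(pathway, score = score, state = state, qc_pass = TRUE)
}

make_sig <- function(states = c(HR = "competent", NHEJ = "competent",
                                BER = "competent", NER = "competent",
                                MMR = "competent"),
                     platinum = "sensitive", explant = "E1", patient = "P1") {
  calls <- lapply(names(states), function(p) make_call(p, states[[p]]))
  sig <- assemble_explant(calls, explant_id = explant, patient_id = patient)
  sig$platinum_class <- platinum
  sig
}

# desk-scale sampling sizes for generator-backed tests; effect sizes and
# prevalences stay at package defaults
small_sizes <- function() {
  list(nuclei_per_condition = 120, events_per_condition = 1200,
       comets_per_condition = 2000)
}

tiny_sizes <- function() {
  list(nuclei_per_condition = 4, events_per_condition = 20,
       comets_per_condition = 20)
}

# brute-force AUC oracle: average over all positive-negative pairs
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# exhaustive concordant/discordant pair counting for Kendall tau-b
tau_b_bruteforce <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; Tx <- 0; Ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    else if (dx == 0) Tx <- Tx + 1
    else if (dy == 0) Ty <- Ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + Tx) * (C + D + Ty))
}
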