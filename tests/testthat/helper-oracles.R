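# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# P(score_RA > score_OA) + 0.5 P(tie) by an explicit double loop.
oracle_pairwise_auc <- function(scores, labels) {
  ra <- scores[labels == "RA"]
  oa <- scores[labels == "OA"]
  s <- 0
  for (r in ra) for (o in oa) s <- s + (r > o) + 0.5 * (r == o)
  s / (length(ra) * length(oa))
}

# Best Youden J by exhaustively scanning every candidate cut on the
# oriented scores (rule: oriented score >= cut predicts RA).
oracle_youden <- function(scores, labels, orientation) {
  s <- orientation * scores
  ra <- labels == "RA"
  best <- list(J = -Inf, cut = NA)
  for (c in sort(unique(s), decreasing = TRUE)) {
    sens <- mean(s[ra] >= c)
    spec <- mean(s[!ra] < c)
    j <- sens + spec - 1
    if (j > best$J) best <- list(J = j, cut = c, sens = sens, spec = spec)
  }
  best
}

# Random small score/label instance with heavy ties (ordinal-like).
random_auc_instance <- function(n_max = 30) {
  n_ra <- sample(2:n_max, 1)
  n_oa <- sample(2:n_max, 1)
  k <- sample(2:6, 1)
  list(scores = c(sample(0:(k - 1), n_ra, replace = TRUE),
                  sample(0:(k - 1), n_oa, replace = TRUE)),
       labels = rep(c("RA", "OA"), c(n_ra, n_oa)))
}

# Minimal valid cohort data.frame with constant scores, for I/O tests.
blank_cohort_df <- function(n = 4) {
  reg <- feature_registry()
  df <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    disease = rep(c("OA", "RA"), length.out = n),
    stringsAsFactors = FALSE
  )
  for (f in names(reg)) df[[f]] <- 0L
  df$density <- NA_real_
  df
}
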