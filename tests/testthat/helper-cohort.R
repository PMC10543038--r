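# Small synthetic cohorts reused across tests.

tiny_cohort <- function(seed = 11, n_cases = 60, n_controls = 40, ...) {
  simulate_cohort(simulation_config(
    seed = seed, n_cases = n_cases, n_controls = n_controls,
    n_common_variants = 120, n_rare_per_gene = 5,
    n_event_slots_per_gene = 4, simulate_depths = FALSE, ...))
}

planted_cohort <- function(seed = 13, ...) {
  simulate_cohort(simulation_config(
    seed = seed, n_cases = 150, n_controls = 100,
    n_common_variants = 150, n_rare_per_gene = 6,
    planted_monogenic = tibble::tibble(
      gene = c("SI", "ALDOB"), n_case_carriers = c(4L, 1L),
      n_control_carriers = c(0L, 0L)),
    planted_digenic = tibble::tibble(
      gene_a = "LCT", gene_b = "SI", n_case_carriers = 1L),
    ...))
}

# A minimal sample tibble builder
make_samples <- function(n_case, n_control, ...) {
  n <- n_case + n_control
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    status = rep(c("case", "control"), c(n_case, n_control)),
    subtype = rep(c("IBS-D", "none"), c(n_case, n_control)),
    sex = rep_len(c("female", "male"), n),
    age = rep(30L, n), site = rep("UW", n),
    ethnicity = rep("White", n),
    pain = rep(2L, n), diarrhea = rep(1L, n),
    constipation = rep(0L, n), bloating = rep(3L, n),
    ...)
}

# Independent HWE oracle: conditional distribution of the heterozygote
# count by direct log-gamma evaluation of the multinomial probabilities,
# normalised over all parity-matched heterozygote counts.
hwe_oracle_distribution <- function(n, n_rare) {
  if (n_rare == 0) return(stats::setNames(1, "0"))
  hets <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  hom_r <- (n_rare - hets) / 2
  hom_c <- n - hets - hom_r
  lp <- lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(hets + 1) -
    lgamma(hom_c + 1) + hets * log(2)
  w <- exp(lp - max(lp))
  stats::setNames(w / sum(w), hets)
}

hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  probs <- hwe_oracle_distribution(n, n_rare)
  p_obs <- probs[[as.character(n_het)]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}
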