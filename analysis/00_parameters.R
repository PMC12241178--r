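# Shared study parameters for the analysis scripts. Desk-scale configuration:
# 30 subjects, 50 regions (1,225 edges), the 15-clip catalogue at half
# duration (+10 trailing TRs per segment). All scripts regenerate the same
# dataset deterministically from MASTER_SEED, so they can be run
# independently and in any order.

library(moviefc)

MASTER_SEED <- 20260925
N_SUBJECTS <- 30
N_REGIONS <- 50
SEX_RATIO <- 68 / 169          # the study cohort's female fraction
SPARSITIES <- c(0.2, 0.25, 0.3)
PRIMARY_SPARSITY <- 0.25
ALPHA <- 0.05
RESULTS_DIR <- file.path("results", "analysis")

study_dataset <- function() {
  cohort <- make_cohort(N_SUBJECTS, SEX_RATIO, seed = MASTER_SEED)
  truth <- make_ground_truth(N_REGIONS, seed = MASTER_SEED,
                             clip_edges = 400, clip_strength = 0.25,
                             fingerprint_edges = 100, fingerprint_sd = 0.15,
                             sex_edges = 50, sex_delta = 0.15,
                             age_edges = 50, age_slope = 0.08)
  make_dataset(cohort, clip_catalogue(), truth,
               duration_scale = 0.5, extra_tr = 10)
}

dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
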