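# Shared settings for the analysis drivers. Each script regenerates the
# cohorts deterministically from these seeds, so the scripts can be run
# independently and in any order.

library(rvatlas)

RESULTS <- file.path("results")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

N_SUBJECTS <- 300L   # per cohort; discovery and validation are disjoint
N_VERTICES <- 1000L  # scaled-down RV wall surface
N_PERM <- 9999L
N_BOOT <- 1000L
SEED_DISCOVERY <- 101L
SEED_VALIDATION <- 202L
SEED_PERM <- 303L
SEED_BOOT <- 404L
SEED_REPEAT <- 505L

make_mesh <- function() generate_mesh(N_VERTICES, axis_length = 85, radius = 30)

make_discovery_cohort <- function(mesh = make_mesh()) {
  generate_cohort(
    generator_config(n_subjects = N_SUBJECTS, n_vertices = N_VERTICES,
                     effect_size = 0.3, seed = SEED_DISCOVERY,
                     with_motion = FALSE),
    mesh = mesh)
}

make_validation_cohort <- function() {
  generate_cohort(
    generator_config(n_subjects = N_SUBJECTS, n_vertices = 60,
                     seed = SEED_VALIDATION, with_motion = FALSE))
}
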