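# Shared scenario for the numbered analysis scripts.
#
# A desk-scale cohort mirroring the study's structure: every video has a
# present and an absent version, half the videos use the slow-start head
# profile that triggers reverse saccades, and the observer policy uses the
# study's latency / reverse-saccade parameters.

library(dynagaze)

SCENARIO_SEED <- 20230824L

scenario_cohort <- function() {
  simulate_cohort(
    n_subjects = 8,
    n_videos = 20,
    n_sessions = 1,
    manipulation_scheme = "none",
    policy = observer_policy(),
    p_slow_videos = 0.5,
    seed = SCENARIO_SEED
  )
}

results_path <- function(...) {
  dir.create(file.path("results"), showWarnings = FALSE)
  file.path("results", ...)
}
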