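#' Small deterministic test cohort
#'
#' Four-subject mini-cohort used by the test suite: short paradigm, reduced
#' sensor and region counts, exactly known planted parameters (modulation
#' depths follow a noise-free age trend; two bad channels and two
#' high-variance trials are planted per subject).
#'
#' @param seed Integer seed (default 42).
#' @param nTrialsPerFinger Trials per finger (default 8).
#' @param nSensors Sensors (default 24, i.e. 72 channels).
#' @param nRegions Parcellation regions (default 16).
#' @param connectivity Simulate the coupled region network (default TRUE).
#' @return List as from [makeCohort()] plus `recordings` (materialized) and
#'   `plantedBad` (per-subject planted bad channel/trial indices).
#' @export
fixtureCohort <- function(seed = 42, nTrialsPerFinger = 8, nSensors = 24,
                          nRegions = 16, connectivity = TRUE) {
  trends <- cohortTrends(
    depth = c(intercept = 0.10, slope = 0.025, sd = 0),
    tilt = c(intercept = -0.90, slope = 0.05, sd = 0))
  cohort <- makeCohort(
    nSubjects = 4, ageRange = c(4, 30), trendSpec = trends,
    paradigm = makeParadigm(nTrialsPerFinger = nTrialsPerFinger),
    fs = 300, nSensors = nSensors, seed = seed,
    connectivity = connectivity, nRegions = nRegions,
    plantArtifacts = TRUE)
  recordings <- lapply(1:4, cohort$simulate)
  plantedBad <- lapply(recordings, function(r) {
    list(flat = r@provenance$simulate$flatChannels,
         noisy = r@provenance$simulate$noisyChannels,
         trials = r@provenance$simulate$badTrials)
  })
  c(cohort, list(recordings = recordings, plantedBad = plantedBad))
}
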