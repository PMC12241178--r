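# Simulate the synthetic movie-watching cohort and export it as plain-text
# files: one time-series TSV per subject x clip, plus participants, network
# partition, clip catalogue and a ground-truth sidecar.
#
# Run from the repository root:  Rscript analysis/01_simulate.R

source(file.path("analysis", "00_parameters.R"))

ds <- study_dataset()
out <- file.path(RESULTS_DIR, "data")
files <- write_dataset(ds, out)

cat(sprintf("Simulated %d subjects x %d clips (%d series) at R = %d regions\n",
            nrow(ds$cohort), nrow(ds$catalogue), length(ds$timeseries),
            ds$truth$n_regions))
cat(sprintf("Sexes: %d F / %d M; age groups: %s\n",
            sum(ds$cohort$sex == "F"), sum(ds$cohort$sex == "M"),
            paste(table(ds$cohort$age_group), collapse = "/")))
cat(sprintf("Planted: %d clip-informative, %d fingerprint, %d sex-effect, %d age-effect edges\n",
            length(ds$truth$clip_edges), length(ds$truth$fingerprint_edges),
            length(ds$truth$sex_effect_edges), length(ds$truth$age_effect_edges)))
cat(sprintf("Wrote %d files under %s\n", length(files), out))
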