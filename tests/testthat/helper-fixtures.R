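# Shared fixtures: a small single-trial design and a deterministic toy table.

single_trial_design <- function(doses = c(0, 60, 120, 180, 230, 280),
                                replicates = 3) {
  study_design(trials = "AD15", n_levels = list(AD15 = doses),
               replicates = replicates)
}

# Hand-built 4-feature x 7-sample table with known structure:
# F1/F2 co-eluting and proportional, F3 at a distant rt, F4 a blank artefact.
toy_table <- function() {
  features <- data.frame(
    feature_id = c("F1", "F2", "F3", "F4"),
    mz = c(300.1, 322.1, 451.2, 150.05),
    rt = c(5.20, 5.21, 12.0, 8.0)
  )
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "qa1", "qa2", "blk"),
    role = c(rep("experimental", 4), "qa", "qa", "blank")
  )
  intens <- rbind(
    c(10, 20, 30, 40, 25, 25, 0),
    c(1, 2, 3, 4, 2.5, 2.5, 0),
    c(5, 4, 3, 2, 3.5, 3.5, 0),
    c(1, 1, 1, 1, 1, 1, 500)
  )
  feature_table(features, samples, intens)
}
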