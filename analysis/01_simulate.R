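#!/usr/bin/env Rscript
# Simulate the study's data structures: a full hierarchical interval
# dataset under the default (paced-clicks-like) design, plus reference
# series from each timing process. Writes CSVs under results/data/.

suppressPackageStartupMessages(library(isochron))
seed <- 20260920
out_dir <- file.path("results", "data")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

design <- study_design()  # 25 subjects x 2 cases x 16 sets x 50 intervals
study <- gen_study(design, seed = seed)
write_intervals(study, file.path(out_dir, "study_intervals.csv"))
message(sprintf("study: %d sets, %d intervals -> study_intervals.csv",
                length(study$sets), nrow(study$observations)))

# single-process reference series for the classification analyses
eb <- gen_event_based(500, timekeeper_sd = 20, motor_delay_sd = 10,
                      n = 500, seed = seed + 1)
em <- gen_emergent(500, ar_coefficient = 0.4, innovation_sd = 10,
                   n = 500, seed = seed + 2)
sw <- gen_switching(list(
  list(process = "event_based", mean_interval = 500,
       timekeeper_sd = 20, motor_delay_sd = 10, n = 200),
  list(process = "emergent", mean_interval = 500,
       ar_coefficient = 0.4, innovation_sd = 10, n = 200)
), seed = seed + 3)
write_intervals(list(eb, em, sw), file.path(out_dir, "process_series.csv"))
message(sprintf(
  "process series: event-based lag1 %.3f, emergent lag1 %.3f -> process_series.csv",
  lag_one_autocorr(eb), lag_one_autocorr(em)))

# one synthetic accelerometer recording (60 s of movement + 5 s pads)
src <- gen_event_based(550, 20, 10, n = 110, seed = seed + 4)
trace <- gen_accel_trace(src, sample_rate = 200, noise_sd = 0.05,
                         seed = seed + 5, pad_s = 5)
write_trace(trace, file.path(out_dir, "trace_example.csv"))
write_intervals(interval_series(durations(src), subject = "S01",
                                case = "N/KTT", condition = "Fr",
                                set_index = 1L, regime = "event_based"),
                file.path(out_dir, "trace_example_truth.csv"))
message(sprintf("trace: %d samples at 200 Hz -> trace_example.csv",
                length(trace$time_s)))
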