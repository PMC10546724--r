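# Shared setup for the analysis drivers: default study configuration and
# a cached pipeline run. Bulky intermediates live under scratch/ (not
# part of the deliverable); small result tables go to results/.
suppressPackageStartupMessages(library(snregnet))

config <- synth_config()
pipeline <- function() {
  run_pipeline(config, out_dir = file.path("scratch", "pipeline"),
               affinity_runs = 25L)
}
write_result <- function(d, name) {
  dir.create("results", showWarnings = FALSE)
  utils::write.table(d, file.path("results", name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("results/", name, ": ", nrow(d), " rows")
}
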