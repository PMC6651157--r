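#!/usr/bin/env Rscript
# Stage 2 — quality control and semi-monthly integration.
#
# Clusters stations by haversine distance, screens each cluster's hourly
# series (deviation against the station-median reference, then the
# quadratic-gradient screen), and integrates the cleaned hours into
# semi-monthly cluster panels (all-value and fourth-quartile-averaged).

library(aqmca)

records <- read_hourly("scratch/run/hourly.csv")
stations <- utils::read.csv("scratch/run/stations.csv",
                            stringsAsFactors = FALSE)

clusters <- cluster_stations(stations, cutoff_km = 10)
print(clusters)

qc <- apply_qc(records, clusters, qc_config())
for (g in names(qc$report))
  cat(sprintf("%-5s removed %5.2f%% (%d deviation, %d gradient flags)\n",
              g, 100 * qc$report[[g]]$removed_fraction,
              qc$report[[g]]$n_flagged_deviation,
              qc$report[[g]]$n_flagged_gradient))
write_result_json(qc$report, "results/02_qc_report.json")

for (g in c("PM25", "SO2", "NO2")) {
  panel <- integrate_semimonthly(qc$records, clusters, pollutant = g,
                                 min_completeness = 0.5)
  panel <- exclude_gappy(panel, max_missing_fraction = 0.2)
  write_panel(panel, sprintf("results/02_panel_%s.csv", g))
  cat(g, ": ", length(panel$cluster_ids), " clusters kept, ",
      sum(is.na(panel$values_all)), " missing cells\n", sep = "")
}
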