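#!/usr/bin/env Rscript
# Strings-and-binders polymer demonstration: a matched comparison of the
# TAD-only and metaTAD presets in the calibrated domain-forming regime.
# Writes the ensemble contact matrices and the compaction report.

suppressMessages(library(metatadr))
out <- "results/polymer"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sbs_experiment_defaults()
ex <- suppressWarnings(do.call(sbs_metatad_experiment,
                               c(cfg, list(seed = 7))))

write.table(round(ex$tad$contact_prob, 4),
            file.path(out, "contacts_tad_only.tsv"), sep = "\t",
            row.names = FALSE, col.names = FALSE)
write.table(round(ex$metatad$contact_prob, 4),
            file.path(out, "contacts_metatad.tsv"), sep = "\t",
            row.names = FALSE, col.names = FALSE)

report <- data.frame(
  quantity = c("volume_tad_only", "volume_metatad",
               "percent_volume_reduction",
               "red_green_contact_tad", "red_green_contact_metatad",
               "intra_red_contact_metatad", "blue_engaged_percent"),
  value = c(ex$volume_tad, ex$volume_meta,
            ex$percent_volume_reduction,
            ex$red_green_contact["tad"], ex$red_green_contact["metatad"],
            ex$metatad$cross_contact[1, 1], ex$blue_engaged_percent))
write.table(report, file.path(out, "report.tsv"), sep = "\t",
            row.names = FALSE)

message(sprintf(
  "occupied volume: %.0f (TAD-only) -> %.0f (metaTAD): %.1f%% reduction",
  ex$volume_tad, ex$volume_meta, ex$percent_volume_reduction))
message(sprintf(
  "red-green cross contact stays at %.1e (vs intra-red %.3f); blue sites engaged %.1f%% of the time",
  ex$red_green_contact["metatad"], ex$metatad$cross_contact[1, 1],
  ex$blue_engaged_percent))
if (ex$flagged) message("NOTE: a trajectory failed the plateau check")
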