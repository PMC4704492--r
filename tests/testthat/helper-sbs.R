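# The matched TAD-only/metaTAD polymer experiment is the most expensive
# fixture in the suite; the blue-engagement measurement is defined on the
# same equilibrated metaTAD trajectory as the volume comparison, so both
# acceptance checks share one cached run.
sbs_acceptance_cache <- new.env(parent = emptyenv())

get_sbs_acceptance_experiment <- function() {
  if (is.null(sbs_acceptance_cache$ex)) {
    cfg <- sbs_experiment_defaults()
    cfg$n_replicates <- 4  # reduced scale: keeps the whole suite rerunnable
    sbs_acceptance_cache$ex <- suppressWarnings(
      do.call(sbs_metatad_experiment, c(cfg, list(seed = 15))))
  }
  sbs_acceptance_cache$ex
}
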