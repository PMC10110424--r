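# shared fixture builders; everything is generated in code at test time

default_phases <- function() phase_durations(t_g1 = 10, t_s = 6, t_g2m = 4)

make_population <- function(n = 10000, phases = default_phases(),
                            quiescent = 0, seed = 42, ...) {
  simulate_population(sim_config(phases, n_cells = n,
                                 quiescent_fraction = quiescent,
                                 seed = seed, ...))
}

# hand-checkable counts: expected phase split of 20000 P cells under
# (10, 6, 4) h phases, labelling counts in the exact t_i / t_s ratio
analytic_flow <- function() {
  flow_counts(n_total_singlets = 20000, n_sox2 = 20000, n_pcells = 20000,
              n_g1 = 10000, n_s_flow = 6000, n_g2m = 4000,
              n_tuj1_ki67 = 1000)
}
analytic_labeling <- function() {
  labeling_counts(l_cells = 150, s_cells = 600, t_i = 1.5)
}
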