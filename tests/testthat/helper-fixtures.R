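# Shared fixtures: FLC-like baseline kinetics and small generators.

# baseline with transit times L/v = 2 min, 1/k_s = 3 min, L/k_d = 6 min
base_intron <- function(f_lariat = 0.17) {
  intron_params(init_rate = 1, pol_speed = 1500, proc_rate = 1 / 3,
                lariat_speed = 500, intron_length = 3000,
                f_lariat = f_lariat)
}

# hand-evaluable baseline: L/v = 3, 1/k_s = 1, L/k_d = 6 (arbitrary units)
toy_intron <- function(f_lariat = 0) {
  intron_params(init_rate = 1, pol_speed = 1000, proc_rate = 1,
                lariat_speed = 500, intron_length = 3000,
                f_lariat = f_lariat)
}

fc_2w <- function() {
  fold_change_params(alpha_total = 0.67, alpha_cb = 1.3, beta = 0.8,
                     gamma = 6.8)
}

# smFISH-style decay course (foci per area, per-timepoint mean +/- s.e.),
# untreated timepoint already excluded
smfish_course <- function(seed, m0 = 1.4, halflife = 4.1, n_cells = 100) {
  s <- sim_smfish_decay(m0, halflife,
                        sim_config(seed = seed, n_cells = n_cells))
  exclude_untreated(s$course)
}

# FLC-like gene: 5.7 kb span, first major PAS at 5200
flc_windows <- function() {
  gene_windows(start = 0, end = 5700, pas = 5200,
               splice_sites_5 = c(500, 4100),
               splice_sites_3 = c(3500, 4300))
}
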