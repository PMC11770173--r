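metric_id	instrument_class	best_threshold	worst_threshold	direction
median_ms1_mass_accuracy	orbitrap	1	5	lower_is_better
median_ms1_mass_accuracy	tof	5	20	lower_is_better
q_ms2	default	0.85	0.5	higher_is_better
ms2_utilization	default	1.5	0.7	higher_is_better
spectra_complexity	default	2.5	1	higher_is_better
dup_rate	default	1.3	4	lower_is_better
missed_cleavage_rate	default	10	40	lower_is_better
median_peak_width	default	0.4	1.2	lower_is_better
median_fwhm	default	0.2	0.6	lower_is_better
lc_delay_time	default	2	12	lower_is_better
lc_tail_time	default	2	12	lower_is_better
active_gradient_fraction	default	0.85	0.5	higher_is_better
window_load_imbalance	default	2	10	lower_is_better
median_cycle_time	default	1.5	4	lower_is_better
fraction_scans_at_max_fill	default	0.2	0.9	lower_is_better
tic_cv	default	20	100	lower_is_better
tic_jump_count	default	0.5	10	lower_is_better
n_precursors	default	60000	10000	higher_is_better
n_peptides	default	45000	8000	higher_is_better
n_protein_groups	default	3000	1000	higher_is_better
intensity_dynamic_range	default	4	2	higher_is_better
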