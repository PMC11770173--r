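metric_id	category	factor	unit	direction	description
n_precursors	identification	identified_precursors	count	higher_is_better	Number of identified peptide precursors
n_peptides	identification	identified_precursors	count	higher_is_better	Number of identified stripped peptide sequences
n_protein_groups	identification	identified_precursors	count	higher_is_better	Number of identified protein groups
intensity_dynamic_range	identification	identified_precursors	log10	higher_is_better	log10 ratio of the 99th to 1st percentile of protein intensity
mean_protein_sequence_coverage	identification	identified_precursors	%	higher_is_better	Mean protein sequence coverage (requires a sequence database)
q_ms2	identification	q_ms2	fraction	higher_is_better	Fraction of acquired MS2 scans yielding at least one identification
ms2_utilization	identification	identified_precursors	ratio	higher_is_better	Unique precursors per identified MS2 scan (complexity / duplicate rate)
missed_cleavage_rate	sample	q_ms2	%	lower_is_better	Percent of precursors with one or more missed cleavages
median_peak_width	chromatography	dup_rate	min	lower_is_better	Median chromatographic peak width
median_fwhm	chromatography	dup_rate	min	lower_is_better	Median chromatographic full width at half maximum
lc_delay_time	chromatography	q_ms2	min	lower_is_better	Invalid acquiring time before identifiable analytes elute
lc_tail_time	chromatography	q_ms2	min	lower_is_better	Run time after the last identifiable analytes elute
active_gradient_fraction	chromatography	q_ms2	fraction	higher_is_better	Fraction of the gradient producing identifications
n_windows_per_cycle	dia_windows	acquired_ms2	count	higher_is_better	DIA isolation windows per acquisition cycle
mean_window_width	dia_windows	spectra_complexity	Th	lower_is_better	Mean isolation-window width
window_load_imbalance	dia_windows	spectra_complexity	ratio	lower_is_better	Max/median precursors per isolation window
spectra_complexity	dia_windows	spectra_complexity	ratio	higher_is_better	Redundant precursor identifications per identified MS2 scan
dup_rate	dia_windows	dup_rate	ratio	lower_is_better	Redundant precursor identifications per unique precursor
n_ms1_scans	ms_signal	acquired_ms2	count	higher_is_better	Number of MS1 scans
n_ms2_scans	ms_signal	acquired_ms2	count	higher_is_better	Number of MS2 scans
n_acquired_ms2	ms_signal	acquired_ms2	count	higher_is_better	Number of acquired MS2 scans
median_cycle_time	ms_signal	acquired_ms2	s	lower_is_better	Median duty-cycle time
median_injection_time_ms1	ms_signal	q_ms2	ms	lower_is_better	Median MS1 ion injection time
median_injection_time_ms2	ms_signal	q_ms2	ms	lower_is_better	Median MS2 ion injection time
fraction_scans_at_max_fill	ms_signal	q_ms2	fraction	lower_is_better	Fraction of scans filled to the maximum injection time
median_peak_count_ms1	ms_signal	q_ms2	count	higher_is_better	Median centroid peak count per MS1 scan
median_peak_count_ms2	ms_signal	q_ms2	count	higher_is_better	Median centroid peak count per MS2 scan
median_base_peak_intensity_ms1	ms_signal	q_ms2	log10	higher_is_better	Median log10 base-peak intensity of MS1 scans
median_base_peak_intensity_ms2	ms_signal	q_ms2	log10	higher_is_better	Median log10 base-peak intensity of MS2 scans
median_ms1_mass_accuracy	ms_signal	q_ms2	ppm	lower_is_better	Median absolute MS1 mass deviation in ppm
median_log10_precursor_intensity	ms_signal	q_ms2	log10	higher_is_better	Median log10 precursor intensity
tic_cv	ion_source	q_ms2	%	lower_is_better	Coefficient of variation of the MS1 total ion current
tic_jump_count	ion_source	q_ms2	count	lower_is_better	Adjacent-MS1 TIC jumps beyond 10-fold (spray instability)
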