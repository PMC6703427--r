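# SYNTHETIC example counting setups for the CARD-FISH enumeration arithmetic.
# The study protocol's raw counts and filter geometry are unpublished, so these
# rows are plausible stand-ins for testing and documentation only; they carry
# no measured data. Areas in um^2, volumes in ml.
label	mean_count_per_grid	n_grids	grid_area_um2	effective_filter_area_um2	sample_volume_ml	dilution_factor
sparse_single_cells	5	20	1.56e4	2.27e8	1.3e-3	1
dense_single_cells	48	20	1.56e4	2.27e8	1.3e-3	10
aggregate_rich	12	20	1.56e4	2.27e8	1.3e-3	5
blank	0	20	1.56e4	2.27e8	1.3e-3	1
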