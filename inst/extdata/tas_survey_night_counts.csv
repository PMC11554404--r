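quantity,count
full_moon_nights,89847
new_moon_nights,90759
moon_subset_nights,180060
capture_nights_in_subset,7433
operating_days_total,234200
retained_sites,651
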