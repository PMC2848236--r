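# Observed relative isotopologue intensities of a four-carbon example
# molecule, contaminated by 13C natural abundance (NA = 0.01109).
# Correct with: cli_main(c("correct", path, "--cmax", "4"))
metabolite	isotopologue	intensity
four_carbon_example	0	0.956
four_carbon_example	1	1.01
four_carbon_example	2	3.33e-2
four_carbon_example	3	3.70e-4
four_carbon_example	4	1.38e-6
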