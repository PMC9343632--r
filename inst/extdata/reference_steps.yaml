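# Synthetic reference histogram of downward-arrow step counts (step count ->
# number of people). Stands in for the unpublished historical distribution
# used by the step-count feedback; same values as
# default_reference_distribution().
"0": 4
"1": 10
"2": 18
"3": 24
"4": 20
"5": 14
"6": 8
"7": 5
"8": 3
"9": 2
"10": 2
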