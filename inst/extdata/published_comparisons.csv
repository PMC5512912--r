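comparison,pupil_mm,metric,reference,proposed,mode
builtin_vs_ga,5,SA,0.01,0.032994,aberration
builtin_vs_ga,5,TCO,-0.0162,-0.011763,aberration
builtin_vs_ga,5,RMS,0.032718,0.020633,aberration
builtin_vs_ga,6,SA,0.01,0.014618,aberration
builtin_vs_ga,6,TCO,-0.01781,-0.010201,aberration
builtin_vs_ga,6,RMS,0.038357,0.031816,aberration
myopic_vs_ga,5,SA,-0.073302,0.032994,aberration
myopic_vs_ga,5,TCO,-0.052464,-0.011763,aberration
myopic_vs_ga,6,SA,-0.126666,0.014618,aberration
myopic_vs_ga,6,TCO,-0.075548,-0.010201,aberration
builtin_vs_ga,5,MTF10,0.768,0.901,resolution
builtin_vs_ga,5,MTF20,0.356,0.657,resolution
builtin_vs_ga,5,MTF30,0.145,0.389,resolution
builtin_vs_ga,6,MTF10,0.695,0.783,resolution
builtin_vs_ga,6,MTF20,0.253,0.391,resolution
builtin_vs_ga,6,MTF30,0.115,0.177,resolution
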