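feature,neuron,mean,sd
voltage_response,D1_051811,0.996,0.021
baseline_pre,D1_051811,0.018,0.001
baseline_post,D1_051811,0.016,0.001
falling_curve,D1_051811,0.233,0.039
spike_width,D1_051811,0.253,0.028
spike_height,D1_051811,0.203,0.008
latency,D1_051811,0.207,0.017
spike_count,D1_051811,1.077,0.011
ahp_depth,D1_051811,0.187,0.015
ahp_curve,D1_051811,2.434,0.147
charging_curve,D1_051811,0.147,0.024
histogram,D1_051811,0.591,0.011
total,D1_051811,0.851,0.036
voltage_response,D1_042811,0.057,0.032
baseline_pre,D1_042811,0.072,0.003
baseline_post,D1_042811,0.057,0.002
falling_curve,D1_042811,0.058,0.026
spike_width,D1_042811,0.171,0.022
spike_height,D1_042811,0.096,0.007
latency,D1_042811,0.311,0.027
spike_count,D1_042811,1.066,0.001
ahp_depth,D1_042811,0.019,0.013
ahp_curve,D1_042811,2.618,0.062
charging_curve,D1_042811,0.174,0.025
histogram,D1_042811,0.075,0.007
total,D1_042811,0.826,0.016
voltage_response,D1_010612,0.228,0.121
baseline_pre,D1_010612,0.044,0.007
baseline_post,D1_010612,0.039,0.008
falling_curve,D1_010612,0.273,0.084
spike_width,D1_010612,0.055,0.040
spike_height,D1_010612,0.123,0.005
latency,D1_010612,0.332,0.086
spike_count,D1_010612,1.021,0.067
ahp_depth,D1_010612,0.342,0.003
ahp_curve,D1_010612,3.750,0.023
charging_curve,D1_010612,0.056,0.022
histogram,D1_010612,0.357,0.019
total,D1_010612,1.142,0.003
voltage_response,D2_081011,0.243,0.121
baseline_pre,D2_081011,0.110,0.026
baseline_post,D2_081011,0.004,0.003
falling_curve,D2_081011,0.393,0.053
spike_width,D2_081011,0.141,0.030
spike_height,D2_081011,0.187,0.004
latency,D2_081011,0.339,0.070
spike_count,D2_081011,0.958,0.044
ahp_depth,D2_081011,0.184,0.014
ahp_curve,D2_081011,3.336,0.032
charging_curve,D2_081011,0.094,0.026
histogram,D2_081011,0.392,0.036
total,D2_081011,1.027,0.0093
voltage_response,D2_051311,0.414,0.038
baseline_pre,D2_051311,0.015,0.001
baseline_post,D2_051311,0.013,0.001
falling_curve,D2_051311,0.294,0.111
spike_width,D2_051311,0.040,0.022
spike_height,D2_051311,0.191,0.010
latency,D2_051311,0.153,0.017
spike_count,D2_051311,0.946,0.000
ahp_depth,D2_051311,0.256,0.003
ahp_curve,D2_051311,3.437,0.025
charging_curve,D2_051311,0.058,0.023
histogram,D2_051311,0.601,0.010
total,D2_051311,1.060,0.006
voltage_response,D2_010612,0.944,0.025
baseline_pre,D2_010612,0.073,0.001
baseline_post,D2_010612,0.061,0.001
falling_curve,D2_010612,0.076,0.018
spike_width,D2_010612,0.241,0.016
spike_height,D2_010612,0.191,0.004
latency,D2_010612,0.313,0.016
spike_count,D2_010612,0.908,0.004
ahp_depth,D2_010612,0.170,0.013
ahp_curve,D2_010612,2.744,0.019
charging_curve,D2_010612,0.170,0.030
histogram,D2_010612,0.441,0.009
total,D2_010612,0.899,0.004
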