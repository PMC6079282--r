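feature,neuron,mean,sd
voltage_response,proto154F,0.367,0.022
baseline_post,proto154F,0.086,0.034
rectification,proto154F,0.261,0.107
falling_curve,proto154F,0.222,0.090
spike_time,proto154F,0.058,0.007
spike_width,proto154F,0.450,0.042
spike_height,proto154F,0.075,0.042
spike_count,proto154F,0.144,0.023
ahp_depth,proto154F,0.070,0.033
ahp_curve,proto154F,0.693,0.032
histogram,proto154F,0.299,0.039
total,proto154F,0.316,0.007
voltage_response,proto144F,0.154,0.085
baseline_post,proto144F,0.093,0.050
rectification,proto144F,0.324,0.130
falling_curve,proto144F,0.132,0.074
spike_time,proto144F,0.065,0.038
spike_width,proto144F,0.548,0.028
spike_height,proto144F,0.089,0.042
spike_count,proto144F,0.148,0.047
ahp_depth,proto144F,0.112,0.052
ahp_curve,proto144F,0.516,0.022
histogram,proto144F,0.239,0.092
total,proto144F,0.281,0.015
voltage_response,proto122F,0.289,0.057
baseline_post,proto122F,0.084,0.047
rectification,proto122F,1.318,0.015
falling_curve,proto122F,0.298,0.075
spike_time,proto122F,0.075,0.011
spike_width,proto122F,0.325,0.027
spike_height,proto122F,0.332,0.025
spike_count,proto122F,0.121,0.062
ahp_depth,proto122F,0.104,0.047
ahp_curve,proto122F,0.534,0.042
histogram,proto122F,0.329,0.049
total,proto122F,0.484,0.005
voltage_response,proto079F,0.272,0.081
baseline_post,proto079F,0.125,0.098
rectification,proto079F,0.705,0.267
falling_curve,proto079F,0.321,0.173
spike_time,proto079F,0.118,0.015
spike_width,proto079F,0.277,0.077
spike_height,proto079F,0.258,0.089
spike_count,proto079F,0.378,0.121
ahp_depth,proto079F,0.115,0.084
ahp_curve,proto079F,0.904,0.046
histogram,proto079F,0.478,0.110
total,proto079F,0.448,0.026
voltage_response,arky140F,0.240,0.093
baseline_post,arky140F,0.050,0.036
rectification,arky140F,0.540,0.037
falling_curve,arky140F,0.227,0.037
spike_time,arky140F,0.052,0.011
spike_width,arky140F,0.455,0.036
spike_height,arky140F,0.077,0.036
spike_count,arky140F,0.103,0.039
ahp_depth,arky140F,0.074,0.035
ahp_curve,arky140F,0.616,0.033
histogram,arky140F,0.146,0.052
total,arky140F,0.310,0.006
voltage_response,arky138F,0.565,0.076
baseline_post,arky138F,0.066,0.049
rectification,arky138F,0.853,0.146
falling_curve,arky138F,0.256,0.113
spike_time,arky138F,0.164,0.015
spike_width,arky138F,0.464,0.089
spike_height,arky138F,0.156,0.065
spike_count,arky138F,0.306,0.087
ahp_depth,arky138F,0.104,0.077
ahp_curve,arky138F,0.714,0.032
histogram,arky138F,0.332,0.096
total,arky138F,0.445,0.016
voltage_response,arky120F,0.273,0.116
baseline_post,arky120F,0.079,0.055
rectification,arky120F,0.511,0.241
falling_curve,arky120F,0.155,0.087
spike_time,arky120F,0.087,0.019
spike_width,arky120F,0.278,0.069
spike_height,arky120F,0.287,0.029
spike_count,arky120F,0.326,0.088
ahp_depth,arky120F,0.094,0.083
ahp_curve,arky120F,0.712,0.033
histogram,arky120F,0.271,0.074
total,arky120F,0.348,0.026
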