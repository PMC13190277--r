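# Published group-level summaries from a photothrombotic-stroke AIS study:
# back-transformed estimated marginal means per group and the reported
# unpaired mean differences (difference oriented comparison - reference,
# i.e. stroke - sham, or GFP+ - GFP-). Used as inputs to arithmetic
# consistency checks; all values as printed.
outcome,units,reference_label,comparison_label,emm_reference,emm_comparison,printed_diff
ais_length,um,sham,stroke,20.99,21.38,0.39
ap_threshold,mV,sham,stroke,-43.88,-44.58,-0.70
ap_amplitude,mV,sham,stroke,90.67,90.21,-0.46
max_firing_freq,Hz,sham,stroke,33.10,26.78,-6.32
evoked_firing_freq,Hz,sham,stroke,10.11,8.18,-1.93
membrane_capacitance,pF,sham,stroke,109.6,151.7,42.1
gfp_ap_amplitude,mV,gfp_negative,gfp_positive,88.7,93.7,5.0
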