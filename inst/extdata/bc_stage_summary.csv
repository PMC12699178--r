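stage,n_tips,n_cells,volume,roundness,elongation,ellipticity,longest_axis,intermediate_axis,minor_axis
initial_bud,2,272,79.97,3.27,1.93,0.56,5.76,3.69,2.42
ampulla,3,1517,100.70,3.02,2.28,0.62,7.50,4.08,2.63
asymmetric_ampulla,3,508,91.05,3.55,2.50,0.63,7.22,3.45,2.49
t_bud,3,1733,100.55,2.26,2.24,0.60,8.59,4.63,3.25
trunk,2,407,180.78,2.54,1.83,0.53,10.29,6.63,4.66
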