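tip,n_cells,volume,roundness,elongation,ellipticity,longest_axis,intermediate_axis,minor_axis
1,501,222.24,2.97,1.80,0.50,9.94,6.44,4.69
2,257,233.62,2.88,1.90,0.53,10.58,6.44,4.71
3,200,107.09,3.56,2.31,0.65,6.95,3.90,2.22
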