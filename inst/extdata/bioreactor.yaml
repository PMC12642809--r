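# Example device geometry config: 10.55 x 1.5 x 0.1 mm perfusion channel
# embedded in a 4-mm PDMS slab with 2-mm lateral margins.
length_mm: 10.55
width_mm: 1.5
height_mm: 0.1
slab_thickness_mm: 4
lateral_margin_mm: 2
flow_rate_ul_min: 10
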