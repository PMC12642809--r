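# Example chemical-PDMS parameter config (canonical units: mm^2/h, mm/h).
# Identical to the bundled progesterone parameter set.
name: progesterone
log_kpw: 3.30
log_kpd: -7.20
log_dp: -1.90
log_ds: 0.336
log_h: 1.56
h_is_lower_bound: true
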