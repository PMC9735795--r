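# Chelator proton- and Zn(II)-binding constants used for metal-buffer
# speciation. Values are conditional literature-compilation constants
# (NIST/Martell-style critical selections, ~25 C, I ~ 0.1 M) and are shipped
# as configuration, not as authoritative truth: review them against the
# medium of your experiment before use. logK entries are stepwise proton
# association constants, highest first; logB_ZnL is the log10 formation
# constant of the 1:1 Zn complex; logB_ZnHL (optional) is the log10 overall
# formation constant of the protonated ternary complex from Zn + H + L.
- name: EDTA
  logK: [10.19, 6.13, 2.69, 2.00]
  logB_ZnL: 16.50
  logB_ZnHL: 19.50
  reference: "critical stability constant compilation (25 C, I = 0.1 M)"
- name: EGTA
  logK: [9.40, 8.79, 2.70, 2.08]
  logB_ZnL: 12.60
  reference: "critical stability constant compilation (25 C, I = 0.1 M)"
- name: HEDTA
  logK: [9.81, 5.37, 2.60]
  logB_ZnL: 14.60
  reference: "critical stability constant compilation (25 C, I = 0.1 M)"
- name: TPEN
  logK: [7.19, 4.85, 3.32, 2.85]
  logB_ZnL: 15.58
  reference: "critical stability constant compilation (25 C, I = 0.1 M)"
- name: EDDS
  logK: [9.80, 6.80, 3.90, 2.90]
  logB_ZnL: 13.50
  reference: "critical stability constant compilation (25 C, I = 0.1 M)"
- name: NDAP
  logK: [9.50, 2.50]
  logB_ZnL: 8.80
  reference: "approximate values (sparse literature coverage); verify before quantitative use"
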