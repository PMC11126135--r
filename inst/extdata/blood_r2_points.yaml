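# Blood transverse relaxation rates R2 = 1000/T2 (s^-1) versus field
# strength (T), for quadratic interpolation across B0. T2 in ms.
# Oxygenation: venous Y ~ 72%, arterial Y ~ 98%; HCT = 0.44.
venous:
  - {field_strength: 1.5, t2: 148, source: "Silvennoinen et al."}
  - {field_strength: 3.0, t2: 48, source: "Zhao et al."}
  - {field_strength: 4.7, t2: 28, source: "Silvennoinen et al."}
arterial:
  - {field_strength: 1.5, t2: 207, source: "Silvennoinen et al."}
  - {field_strength: 3.0, t2: 111, source: "Zhao et al."}
  - {field_strength: 4.7, t2: 66, source: "Silvennoinen et al."}
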