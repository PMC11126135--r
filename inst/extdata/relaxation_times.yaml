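# Literature relaxation-time sets for the three-compartment voxel model.
# Times in ms, field strengths in tesla, oxygen saturation in percent.
# The "muscle" slot holds the tissue compartment: skeletal muscle in the
# calf sets, liver parenchyma in the liver sets.
calf_0.55T:
  field_strength: 0.55
  t1: {venous: 1122, arterial: 1122, muscle: 701}
  t2: {venous: 148, arterial: 207, muscle: 44}
  oxygen_saturation: {venous: 72, arterial: 98}
  hematocrit: 0.44
  source:
    - "blood T1 1122 ms at 0.55 T: Campbell-Washburn et al.; venous T1 set equal to arterial (blood T1 nearly independent of oxygenation at low field, Barth et al.)"
    - "muscle T1 701 ms: 0.55 T myocardial value, Campbell-Washburn et al., as calf-muscle proxy"
    - "blood T2 148 ms (venous, Y=72%) / 207 ms (arterial, Y=98%): 1.5 T values of Silvennoinen et al., used at 0.55 T because arterial blood T2 is reported field-independent between 0.55 T (263 +/- 27 ms, Campbell-Washburn et al.) and 1.5 T"
    - "muscle T2 44 ms: 1.5 T value of Stanisz et al."
calf_7T:
  field_strength: 7
  t1: {venous: 2090, arterial: 2990, muscle: 1864}
  t2: {venous: 20, arterial: 55, muscle: 22}
  oxygen_saturation: {venous: 66, arterial: 98}
  hematocrit: 0.44
  source:
    - "blood T1 2090/2990 ms at 7 T: Rane et al."
    - "muscle T1 1864 ms and T2 22 ms at 7 T: Marschar et al."
    - "blood T2 20/55 ms at 7 T: second-order polynomial interpolation of blood relaxation rates (Silvennoinen et al. 1.5/4.7 T, Zhao et al. 3 T, Lin et al. 11.7 T) at HCT = 0.44"
calf_7T_t1a2290:
  field_strength: 7
  t1: {venous: 2090, arterial: 2290, muscle: 1864}
  t2: {venous: 20, arterial: 55, muscle: 22}
  oxygen_saturation: {venous: 66, arterial: 97}
  hematocrit: 0.44
  source:
    - "alternate arterial T1 2290 ms (Y = 95.6-99%) as tabulated for Rane et al.; otherwise identical to calf_7T"
liver_1.5T:
  field_strength: 1.5
  t1: {venous: 1434, arterial: 1435, muscle: 586}
  t2: {venous: 148, arterial: 207, muscle: 46}
  oxygen_saturation: {venous: 72, arterial: 97}
  source:
    - "liver parenchyma T1 586 ms / T2 46 ms at 1.5 T: De Bazelaire et al."
    - "blood T1 1434/1435 ms at 1.5 T: Barth et al.; blood T2 148/207 ms: Silvennoinen et al."
liver_3T:
  field_strength: 3
  t1: {venous: 1584, arterial: 1664, muscle: 809}
  t2: {venous: 48, arterial: 111, muscle: 34}
  oxygen_saturation: {venous: 69, arterial: 92}
  source:
    - "liver parenchyma T1 809 ms / T2 34 ms at 3 T: De Bazelaire et al."
    - "blood T1 1584/1664 ms and T2 48/111 ms at 3 T: Lu et al. / Zhao et al."
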