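criteria:
  fe_n_dist:
    reference: 2.5
    tolerance: 0.5
    abs_value: no
  o_ser_dist:
    reference: 2.8
    tolerance: 0.5
    abs_value: no
  o_his_dist:
    reference: 2.7
    tolerance: 0.5
    abs_value: no
  his_o_ser_angle:
    reference: 115.0
    tolerance: 15.0
    abs_value: no
  c_n_o_o_dihedral:
    reference: 85.0
    tolerance: 25.0
    abs_value: yes
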