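roles:
  FE:
    chain: A
    resno: 400.0
    resname: HEM
    atom: FE
  SER_O:
    chain: A
    resno: 219.0
    resname: SER
    atom: OG
  HIS_DONOR:
    chain: A
    resno: 320.0
    resname: HIS
    atom: NE2
  LIG_N:
    chain: A
    resno: 900.0
    resname: LIG
    atom: N1
  LIG_O:
    chain: A
    resno: 900.0
    resname: LIG
    atom: O1
  LIG_C:
    chain: A
    resno: 900.0
    resname: LIG
    atom: C1
  LIG_SUBSTITUENT_HEAVY:
    chain: A
    resno: 900.0
    resname: LIG
    atom: C2
  LIG_H_AT_STEREOCENTER:
    chain: A
    resno: 900.0
    resname: LIG
    atom: H2
  PARTNER_O:
    chain: A
    resno: 219.0
    resname: SER
    atom: OG
stereo:
  center:
    chain: A
    resno: 900.0
    resname: LIG
    atom: C2
  priority:
  - chain: A
    resno: 900.0
    resname: LIG
    atom: C1
  - chain: A
    resno: 900.0
    resname: LIG
    atom: CR
  - chain: A
    resno: 900.0
    resname: LIG
    atom: CM
  - chain: A
    resno: 900.0
    resname: LIG
    atom: H2
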