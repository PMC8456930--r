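REMARK 250 OXDOCK POSE_ID synthetic_active_site
REMARK 250 OXDOCK BINDING_ENERGY -7.5000
REMARK 250 OXDOCK EZ E
REMARK 250 OXDOCK RS S
ATOM      1  OG  SER A 219       2.800   0.000   0.000  1.00  0.00           O  
ATOM      2  CB  SER A 219       3.289  -0.672  -1.164  1.00  0.00           C  
ATOM      3  NE2 HIS A 320      -1.141   0.000   2.447  1.00  0.00           N  
ATOM      4  CE1 HIS A 320      -1.463  -1.089   3.138  1.00  0.00           C  
HETATM    5 FE   HEM A 400      -1.886   2.802   0.547  1.00  0.00          FE  
HETATM    6  O1  LIG A 900       0.000   0.000   0.000  1.00  0.00           O  
HETATM    7  N1  LIG A 900      -0.456   1.146  -0.662  1.00  0.00           N  
HETATM    8  C1  LIG A 900      -0.514   0.977  -1.929  1.00  0.00           C  
HETATM    9  C2  LIG A 900      -0.974   2.063  -2.856  1.00  0.00           C  
HETATM   10  CM  LIG A 900      -0.053   3.277  -2.716  1.00  0.00           C  
HETATM   11  CR  LIG A 900      -0.932   1.562  -4.280  1.00  0.00           C  
HETATM   12  H2  LIG A 900      -1.994   2.351  -2.602  1.00  0.00           H  
END
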