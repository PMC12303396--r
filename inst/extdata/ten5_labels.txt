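# scalpmorph modified 10-5 label registry (289 labels), version 1
# columns: label  midline_level_fraction  column_index(0..16)
Fp1 0.10 0
Fp1a 0.10 1
Fp1b 0.10 2
Fp1c 0.10 3
Fp1d 0.10 4
Fp1e 0.10 5
Fp1f 0.10 6
Fp1g 0.10 7
Fpz 0.10 8
Fp2g 0.10 9
Fp2f 0.10 10
Fp2e 0.10 11
Fp2d 0.10 12
Fp2c 0.10 13
Fp2b 0.10 14
Fp2a 0.10 15
Fp2 0.10 16
AFp7 0.15 0
AFp7h 0.15 1
AFp5 0.15 2
AFp5h 0.15 3
AFp3 0.15 4
AFp3h 0.15 5
AFp1 0.15 6
AFp1h 0.15 7
AFpz 0.15 8
AFp2h 0.15 9
AFp2 0.15 10
AFp4h 0.15 11
AFp4 0.15 12
AFp6h 0.15 13
AFp6 0.15 14
AFp8h 0.15 15
AFp8 0.15 16
AF7 0.20 0
AF7h 0.20 1
AF5 0.20 2
AF5h 0.20 3
AF3 0.20 4
AF3h 0.20 5
AF1 0.20 6
AF1h 0.20 7
AFz 0.20 8
AF2h 0.20 9
AF2 0.20 10
AF4h 0.20 11
AF4 0.20 12
AF6h 0.20 13
AF6 0.20 14
AF8h 0.20 15
AF8 0.20 16
AFF7 0.25 0
AFF7h 0.25 1
AFF5 0.25 2
AFF5h 0.25 3
AFF3 0.25 4
AFF3h 0.25 5
AFF1 0.25 6
AFF1h 0.25 7
AFFz 0.25 8
AFF2h 0.25 9
AFF2 0.25 10
AFF4h 0.25 11
AFF4 0.25 12
AFF6h 0.25 13
AFF6 0.25 14
AFF8h 0.25 15
AFF8 0.25 16
F7 0.30 0
F7h 0.30 1
F5 0.30 2
F5h 0.30 3
F3 0.30 4
F3h 0.30 5
F1 0.30 6
F1h 0.30 7
Fz 0.30 8
F2h 0.30 9
F2 0.30 10
F4h 0.30 11
F4 0.30 12
F6h 0.30 13
F6 0.30 14
F8h 0.30 15
F8 0.30 16
FFC7 0.35 0
FFC7h 0.35 1
FFC5 0.35 2
FFC5h 0.35 3
FFC3 0.35 4
FFC3h 0.35 5
FFC1 0.35 6
FFC1h 0.35 7
FFCz 0.35 8
FFC2h 0.35 9
FFC2 0.35 10
FFC4h 0.35 11
FFC4 0.35 12
FFC6h 0.35 13
FFC6 0.35 14
FFC8h 0.35 15
FFC8 0.35 16
FT7 0.40 0
FC7h 0.40 1
FC5 0.40 2
FC5h 0.40 3
FC3 0.40 4
FC3h 0.40 5
FC1 0.40 6
FC1h 0.40 7
FCz 0.40 8
FC2h 0.40 9
FC2 0.40 10
FC4h 0.40 11
FC4 0.40 12
FC6h 0.40 13
FC6 0.40 14
FC8h 0.40 15
FT8 0.40 16
FTT7 0.45 0
FCC7h 0.45 1
FCC5 0.45 2
FCC5h 0.45 3
FCC3 0.45 4
FCC3h 0.45 5
FCC1 0.45 6
FCC1h 0.45 7
FCCz 0.45 8
FCC2h 0.45 9
FCC2 0.45 10
FCC4h 0.45 11
FCC4 0.45 12
FCC6h 0.45 13
FCC6 0.45 14
FCC8h 0.45 15
FTT8 0.45 16
T7 0.50 0
C7h 0.50 1
C5 0.50 2
C5h 0.50 3
C3 0.50 4
C3h 0.50 5
C1 0.50 6
C1h 0.50 7
Cz 0.50 8
C2h 0.50 9
C2 0.50 10
C4h 0.50 11
C4 0.50 12
C6h 0.50 13
C6 0.50 14
C8h 0.50 15
T8 0.50 16
TTP7 0.55 0
CCP7h 0.55 1
CCP5 0.55 2
CCP5h 0.55 3
CCP3 0.55 4
CCP3h 0.55 5
CCP1 0.55 6
CCP1h 0.55 7
CCPz 0.55 8
CCP2h 0.55 9
CCP2 0.55 10
CCP4h 0.55 11
CCP4 0.55 12
CCP6h 0.55 13
CCP6 0.55 14
CCP8h 0.55 15
TTP8 0.55 16
TP7 0.60 0
CP7h 0.60 1
CP5 0.60 2
CP5h 0.60 3
CP3 0.60 4
CP3h 0.60 5
CP1 0.60 6
CP1h 0.60 7
CPz 0.60 8
CP2h 0.60 9
CP2 0.60 10
CP4h 0.60 11
CP4 0.60 12
CP6h 0.60 13
CP6 0.60 14
CP8h 0.60 15
TP8 0.60 16
CPP7 0.65 0
CPP7h 0.65 1
CPP5 0.65 2
CPP5h 0.65 3
CPP3 0.65 4
CPP3h 0.65 5
CPP1 0.65 6
CPP1h 0.65 7
CPPz 0.65 8
CPP2h 0.65 9
CPP2 0.65 10
CPP4h 0.65 11
CPP4 0.65 12
CPP6h 0.65 13
CPP6 0.65 14
CPP8h 0.65 15
CPP8 0.65 16
P7 0.70 0
P7h 0.70 1
P5 0.70 2
P5h 0.70 3
P3 0.70 4
P3h 0.70 5
P1 0.70 6
P1h 0.70 7
Pz 0.70 8
P2h 0.70 9
P2 0.70 10
P4h 0.70 11
P4 0.70 12
P6h 0.70 13
P6 0.70 14
P8h 0.70 15
P8 0.70 16
PPO7 0.75 0
PPO7h 0.75 1
PPO5 0.75 2
PPO5h 0.75 3
PPO3 0.75 4
PPO3h 0.75 5
PPO1 0.75 6
PPO1h 0.75 7
PPOz 0.75 8
PPO2h 0.75 9
PPO2 0.75 10
PPO4h 0.75 11
PPO4 0.75 12
PPO6h 0.75 13
PPO6 0.75 14
PPO8h 0.75 15
PPO8 0.75 16
PO7 0.80 0
PO7h 0.80 1
PO5 0.80 2
PO5h 0.80 3
PO3 0.80 4
PO3h 0.80 5
PO1 0.80 6
PO1h 0.80 7
POz 0.80 8
PO2h 0.80 9
PO2 0.80 10
PO4h 0.80 11
PO4 0.80 12
PO6h 0.80 13
PO6 0.80 14
PO8h 0.80 15
PO8 0.80 16
POO7 0.85 0
POO7h 0.85 1
POO5 0.85 2
POO5h 0.85 3
POO3 0.85 4
POO3h 0.85 5
POO1 0.85 6
POO1h 0.85 7
POOz 0.85 8
POO2h 0.85 9
POO2 0.85 10
POO4h 0.85 11
POO4 0.85 12
POO6h 0.85 13
POO6 0.85 14
POO8h 0.85 15
POO8 0.85 16
O1 0.90 0
O1a 0.90 1
O1b 0.90 2
O1c 0.90 3
O1d 0.90 4
O1e 0.90 5
O1f 0.90 6
O1g 0.90 7
Oz 0.90 8
O2g 0.90 9
O2f 0.90 10
O2e 0.90 11
O2d 0.90 12
O2c 0.90 13
O2b 0.90 14
O2a 0.90 15
O2 0.90 16
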