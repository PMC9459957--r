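# phenoscan edge measurements v1; units cm
# reference measurement set: 12 edges of the 5.5 cm calibration cube
edge_id,axis,ref_cm,measured_cm
U1,X,5.5,5.4383
U2,X,5.5,5.5573
D1,X,5.5,5.3808
D2,X,5.5,5.3692
U3,Y,5.5,5.5431
U4,Y,5.5,5.6141
D3,Y,5.5,5.3308
D4,Y,5.5,5.3552
L1,Z,5.5,5.4363
L2,Z,5.5,5.4902
L3,Z,5.5,5.3051
L4,Z,5.5,5.6002
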