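channel	x	y	z
Fpz	0	0.951057	0.309017
Fp1	-0.309017	0.904508	0.293893
Fp2	0.309017	0.904508	0.293893
AFz	0	0.809017	0.587785
AF3	-0.587785	0.654508	0.475528
AF4	0.587785	0.654508	0.475528
AF7	-0.951057	0.25	0.181636
AF8	0.951057	0.25	0.181636
Fz	0	0.587785	0.809017
F1	-0.309017	0.559017	0.769421
F2	0.309017	0.559017	0.769421
F3	-0.587785	0.475528	0.654508
F4	0.587785	0.475528	0.654508
F5	-0.809017	0.345492	0.475528
F6	0.809017	0.345492	0.475528
F7	-0.951057	0.181636	0.25
F8	0.951057	0.181636	0.25
FCz	0	0.309017	0.951057
FC1	-0.309017	0.293893	0.904508
FC2	0.309017	0.293893	0.904508
FC3	-0.587785	0.25	0.769421
FC4	0.587785	0.25	0.769421
FC5	-0.809017	0.181636	0.559017
FC6	0.809017	0.181636	0.559017
Cz	0	0	1
C1	-0.309017	0	0.951057
C2	0.309017	0	0.951057
C3	-0.587785	0	0.809017
C4	0.587785	0	0.809017
C5	-0.809017	0	0.587785
C6	0.809017	0	0.587785
CPz	0	-0.309017	0.951057
CP1	-0.309017	-0.293893	0.904508
CP2	0.309017	-0.293893	0.904508
CP3	-0.587785	-0.25	0.769421
CP4	0.587785	-0.25	0.769421
CP5	-0.809017	-0.181636	0.559017
CP6	0.809017	-0.181636	0.559017
Pz	0	-0.587785	0.809017
P1	-0.309017	-0.559017	0.769421
P2	0.309017	-0.559017	0.769421
P3	-0.587785	-0.475528	0.654508
P4	0.587785	-0.475528	0.654508
P5	-0.809017	-0.345492	0.475528
P6	0.809017	-0.345492	0.475528
P7	-0.951057	-0.181636	0.25
P8	0.951057	-0.181636	0.25
POz	0	-0.809017	0.587785
PO1	-0.309017	-0.769421	0.559017
PO2	0.309017	-0.769421	0.559017
PO3	-0.587785	-0.654508	0.475528
PO4	0.587785	-0.654508	0.475528
PO5	-0.809017	-0.475528	0.345492
PO6	0.809017	-0.475528	0.345492
Oz	0	-0.951057	0.309017
O1	-0.309017	-0.904508	0.293893
O2	0.309017	-0.904508	0.293893
CB1	-0.309017	-0.939347	0.148778
CB2	0.309017	-0.939347	0.148778
PO7	-0.951057	-0.25	0.181636
PO8	0.951057	-0.25	0.181636
T7	-0.951057	0	0.309017
T8	0.951057	0	0.309017
FT7	-0.951057	0.095492	0.293893
FT8	0.951057	0.095492	0.293893
TP7	-0.951057	-0.095492	0.293893
TP8	0.951057	-0.095492	0.293893
T3	-0.951057	0	0.309017
T4	0.951057	0	0.309017
T5	-0.951057	-0.181636	0.25
T6	0.951057	-0.181636	0.25
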