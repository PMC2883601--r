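name	mass	charge	has_lj	has_coulomb
POL-W	24	0	TRUE	FALSE
POL-WP	24	0.46	FALSE	TRUE
POL-WM	24	-0.46	FALSE	TRUE
Qda	72	0	TRUE	TRUE
Qd	72	1	TRUE	TRUE
Qa	72	-1	TRUE	TRUE
Q0	72	0	TRUE	TRUE
P5	72	0	TRUE	FALSE
P4	72	0	TRUE	FALSE
P3	72	0	TRUE	FALSE
P2	72	0	TRUE	FALSE
P1	72	0	TRUE	FALSE
Nda	72	0	TRUE	FALSE
Nd	72	0	TRUE	FALSE
Na	72	0	TRUE	FALSE
N0	72	0	TRUE	FALSE
C5	72	0	TRUE	FALSE
C4	72	0	TRUE	FALSE
C3	72	0	TRUE	FALSE
C2	72	0	TRUE	FALSE
C1	72	0	TRUE	FALSE
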