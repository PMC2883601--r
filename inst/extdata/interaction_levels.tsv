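type_a	type_b	level_polarizable	level_standard
POL	POL	III	III
POL	Qda	O	O
Qda	Qda	O	O
POL	Qd	I	O
Qda	Qd	I	O
Qd	Qd	IV	I
POL	Qa	I	O
Qda	Qa	I	O
Qd	Qa	III	O
Qa	Qa	IV	I
POL	Q0	II	O
Qda	Q0	IV	II
Qd	Q0	VII	II
Qa	Q0	VII	II
Q0	Q0	IV	IV
POL	P5	O	O
Qda	P5	O	O
Qd	P5	O	O
Qa	P5	O	O
Q0	P5	O	I
P5	P5	O	O
POL	P4	I	I
Qda	P4	O	O
Qd	P4	O	O
Qa	P4	O	O
Q0	P4	O	O
P5	P4	O	O
P4	P4	I	I
POL	P3	I	I
Qda	P3	O	O
Qd	P3	O	O
Qa	P3	O	O
Q0	P3	O	I
P5	P3	O	O
P4	P3	I	I
P3	P3	I	I
POL	P2	II	II
Qda	P2	O	I
Qd	P2	O	I
Qa	P2	O	I
Q0	P2	I	II
P5	P2	O	O
P4	P2	II	II
P3	P2	II	II
P2	P2	II	II
POL	P1	II	II
Qda	P1	O	I
Qd	P1	O	I
Qa	P1	O	I
Q0	P1	II	III
P5	P1	O	O
P4	P1	II	II
P3	P1	II	II
P2	P1	II	II
P1	P1	II	II
POL	Nda	III	III
Qda	Nda	O	I
Qd	Nda	O	I
Qa	Nda	O	I
Q0	Nda	II	III
P5	Nda	O	O
P4	Nda	III	III
P3	Nda	II	II
P2	Nda	II	II
P1	Nda	II	II
Nda	Nda	II	II
POL	Nd	III	III
Qda	Nd	O	I
Qd	Nd	II	III
Qa	Nd	O	I
Q0	Nd	II	III
P5	Nd	O	O
P4	Nd	III	III
P3	Nd	II	II
P2	Nd	II	II
P1	Nd	II	II
Nda	Nd	II	II
Nd	Nd	III	III
POL	Na	III	III
Qda	Na	O	I
Qd	Na	O	I
Qa	Na	II	III
Q0	Na	II	III
P5	Na	O	O
P4	Na	III	III
P3	Na	II	II
P2	Na	II	II
P1	Na	II	II
Nda	Na	II	II
Nd	Na	II	II
Na	Na	III	III
POL	N0	IV	IV
Qda	N0	III	IV
Qd	N0	III	IV
Qa	N0	III	IV
Q0	N0	III	IV
P5	N0	III	III
P4	N0	IV	IV
P3	N0	IV	IV
P2	N0	III	III
P1	N0	III	III
Nda	N0	IV	IV
Nd	N0	IV	IV
Na	N0	IV	IV
N0	N0	IV	IV
POL	C5	V	V
Qda	C5	IV	V
Qd	C5	IV	V
Qa	C5	IV	V
Q0	C5	IV	V
P5	C5	IV	IV
P4	C5	V	V
P3	C5	IV	IV
P2	C5	IV	IV
P1	C5	IV	IV
Nda	C5	IV	IV
Nd	C5	IV	IV
Na	C5	IV	IV
N0	C5	IV	IV
C5	C5	IV	IV
POL	C4	VI	VI
Qda	C4	V	VI
Qd	C4	V	VI
Qa	C4	V	VI
Q0	C4	V	VI
P5	C4	V	V
P4	C4	VI	VI
P3	C4	V	V
P2	C4	IV	IV
P1	C4	IV	IV
Nda	C4	V	V
Nd	C4	V	V
Na	C4	V	V
N0	C4	IV	IV
C5	C4	IV	IV
C4	C4	IV	IV
POL	C3	VI	VI
Qda	C3	VI	VII
Qd	C3	VI	VII
Qa	C3	VI	VII
Q0	C3	VI	VII
P5	C3	VI	VI
P4	C3	VI	VI
P3	C3	V	V
P2	C3	V	V
P1	C3	IV	IV
Nda	C3	VI	VI
Nd	C3	VI	VI
Na	C3	VI	VI
N0	C3	V	V
C5	C3	V	V
C4	C3	IV	IV
C3	C3	IV	IV
POL	C2	VII	VII
Qda	C2	VII	IX
Qd	C2	VII	IX
Qa	C2	VII	IX
Q0	C2	VII	IX
P5	C2	VII	VII
P4	C2	VII	VII
P3	C2	VI	VI
P2	C2	VI	VI
P1	C2	V	V
Nda	C2	VI	VI
Nd	C2	VI	VI
Na	C2	VI	VI
N0	C2	VI	VI
C5	C2	V	V
C4	C2	V	V
C3	C2	IV	IV
C2	C2	IV	IV
POL	C1	VIII	VIII
Qda	C1	VII	IX
Qd	C1	VII	IX
Qa	C1	VII	IX
Q0	C1	VII	IX
P5	C1	VIII	VIII
P4	C1	VIII	VIII
P3	C1	VII	VII
P2	C1	VII	VII
P1	C1	VI	VI
Nda	C1	VI	VI
Nd	C1	VI	VI
Na	C1	VI	VI
N0	C1	VI	VI
C5	C1	V	V
C4	C1	V	V
C3	C1	IV	IV
C2	C1	IV	IV
C1	C1	IV	IV
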