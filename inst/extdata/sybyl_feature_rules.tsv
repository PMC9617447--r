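sybyl_type	donor_candidate	acceptor	cation	anion	metal
C.1	FALSE	FALSE	FALSE	FALSE	FALSE
C.2	FALSE	FALSE	FALSE	FALSE	FALSE
C.3	FALSE	FALSE	FALSE	FALSE	FALSE
C.ar	FALSE	FALSE	FALSE	FALSE	FALSE
C.cat	FALSE	FALSE	FALSE	FALSE	FALSE
N.1	FALSE	TRUE	FALSE	FALSE	FALSE
N.2	TRUE	TRUE	FALSE	FALSE	FALSE
N.3	TRUE	FALSE	FALSE	FALSE	FALSE
N.4	TRUE	FALSE	TRUE	FALSE	FALSE
N.am	TRUE	FALSE	FALSE	FALSE	FALSE
N.ar	TRUE	TRUE	FALSE	FALSE	FALSE
N.pl3	TRUE	FALSE	FALSE	FALSE	FALSE
O.2	FALSE	TRUE	FALSE	FALSE	FALSE
O.3	TRUE	TRUE	FALSE	FALSE	FALSE
O.co2	FALSE	TRUE	FALSE	TRUE	FALSE
O.spc	TRUE	TRUE	FALSE	FALSE	FALSE
O.t3p	TRUE	TRUE	FALSE	FALSE	FALSE
S.2	FALSE	TRUE	FALSE	FALSE	FALSE
S.3	FALSE	FALSE	FALSE	FALSE	FALSE
S.o	FALSE	FALSE	FALSE	FALSE	FALSE
S.o2	FALSE	FALSE	FALSE	FALSE	FALSE
P.3	FALSE	FALSE	FALSE	FALSE	FALSE
F	FALSE	FALSE	FALSE	FALSE	FALSE
Cl	FALSE	FALSE	FALSE	FALSE	FALSE
Br	FALSE	FALSE	FALSE	FALSE	FALSE
I	FALSE	FALSE	FALSE	FALSE	FALSE
H	FALSE	FALSE	FALSE	FALSE	FALSE
H.spc	FALSE	FALSE	FALSE	FALSE	FALSE
H.t3p	FALSE	FALSE	FALSE	FALSE	FALSE
Li	FALSE	FALSE	TRUE	FALSE	TRUE
Na	FALSE	FALSE	TRUE	FALSE	TRUE
K	FALSE	FALSE	TRUE	FALSE	TRUE
Ca	FALSE	FALSE	TRUE	FALSE	TRUE
Mg	FALSE	FALSE	TRUE	FALSE	TRUE
Mn	FALSE	FALSE	TRUE	FALSE	TRUE
Fe	FALSE	FALSE	TRUE	FALSE	TRUE
Cu	FALSE	FALSE	TRUE	FALSE	TRUE
Zn	FALSE	FALSE	TRUE	FALSE	TRUE
Du	FALSE	FALSE	FALSE	FALSE	FALSE
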