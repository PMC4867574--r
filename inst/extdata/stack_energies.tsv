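stack	energy
AA/UU	-0.93
AU/UA	-1.1
AC/UG	-2.24
AG/UC	-2.08
AG/UU	-1.3
AU/UG	-1.3
UA/AU	-1.33
UU/AA	-0.93
UC/AG	-2.35
UG/AC	-2.11
UG/AU	-1.3
UU/AG	-1.3
CA/GU	-2.11
CU/GA	-2.08
CC/GG	-3.26
CG/GC	-2.36
CG/GU	-1.3
CU/GG	-1.3
GA/CU	-2.35
GU/CA	-2.24
GC/CG	-3.42
GG/CC	-3.26
GG/CU	-1.3
GU/CG	-1.3
GA/UU	-1.3
GU/UA	-1.3
GC/UG	-1.3
GG/UC	-1.3
GG/UU	-0.6
GU/UG	-0.6
UA/GU	-1.3
UU/GA	-1.3
UC/GG	-1.3
UG/GC	-1.3
UG/GU	-0.6
UU/GG	-0.6
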