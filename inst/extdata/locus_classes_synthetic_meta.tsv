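sample_id	sex	ploidy	colony	clonal_line
F01	female	2	A_c1	A
F02	female	2	A_c2	A
F03	female	2	A_c3	A
F04	female	2	A_c4	A
F05	female	2	A_c1	A
F06	female	2	A_c2	A
F07	female	2	A_c3	A
F08	female	2	A_c4	A
F09	female	2	A_c1	A
F10	female	2	A_c2	A
F11	female	2	A_c3	A
F12	female	2	A_c4	A
F13	female	2	A_c1	A
F14	female	2	A_c2	A
F15	female	2	A_c3	A
F16	female	2	A_c4	A
F17	female	2	A_c1	A
F18	female	2	A_c2	A
F19	female	2	A_c3	A
M01	male	2	A_c1	A
M02	male	2	A_c1	A
M03	male	2	A_c1	A
M04	male	2	A_c1	A
M05	male	2	A_c2	A
M06	male	2	A_c2	A
M07	male	2	A_c2	A
M08	male	2	A_c2	A
M09	male	2	A_c3	A
M10	male	2	A_c3	A
M11	male	2	A_c3	A
M12	male	2	A_c3	A
M13	male	2	A_c4	A
M14	male	2	A_c4	A
M15	male	2	A_c4	A
M16	male	2	A_c4	A
H01	male	1	A_c1	A
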