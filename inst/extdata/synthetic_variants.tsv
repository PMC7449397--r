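name	composition	substitutions	activity_pct	expression_tested
111	modern,modern,modern		100	TRUE
555	ancestral,ancestral,ancestral		85	TRUE
551	ancestral,ancestral,modern		90	TRUE
511	ancestral,modern,modern		90	TRUE
151	modern,ancestral,modern		2	TRUE
41b	modern,modern,modern	W47L;R49F;H53M;L55W;W56N;V58H;T60F;Q61T;P63I;D66W;R67D;S70Y;S73P;I77L;H80W;N84D;W88I;G90T;F93L;P95V;Y97I;R105T;L107F;R108S;C111F;D113L;E116Q;C127M;A130S;T136S	50	TRUE
m39b	modern,ancestral,modern	W47L;R49F;H53M;L55W;W56N;V58H;T60F;Q61T;P63I;D66W;R67D;S70Y;S73P;I77L;H80W;N84D;W88I;G90T	95	TRUE
m39	modern,ancestral,modern	W47L;R49F;H53M;L55W;W56N;V58H;T60F;Q61T;P63I;D66W;R67D;S70Y;S73P;H80W;N84D;W88I;G90T	2	TRUE
151y	modern,ancestral,modern	I77L	2	TRUE
m14	modern,modern,modern	D113L;E116Q;C127M;A130S;T136S	90	FALSE
m9	modern,modern,modern	C111F;D113L;E116Q;C127M;A130S;T136S	2	TRUE
R105T	modern,modern,modern	R105T	2	TRUE
L107F	modern,modern,modern	L107F	3	TRUE
R108S	modern,modern,modern	R108S	2	TRUE
C111F	modern,modern,modern	C111F	3	TRUE
m28c	modern,ancestral,modern	F9K;F14R;P27S;N33P	2	FALSE
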