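parameter,male,female
GNa,1.0,1.0
GNaL,1.0,1.0
Gto,1.0,0.64
PCa,1.0,1.0
GKr,1.0,0.80
GKs,1.0,0.80
GK1,1.0,0.85
Gncx,1.0,1.10
Pnak,1.0,1.0
GKb,1.0,1.0
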