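family	description
CH	Calponin homology domain
VHP	Villin headpiece domain
Gelsolin	Gelsolin repeat domain
Cofilin_ADF	Cofilin/actin-depolymerizing factor homology domain
WH2	Wiskott-Aldrich homology 2 actin-monomer-binding motif
Profilin	Profilin
FH2	Formin homology 2 domain
Myosin_head	Myosin motor domain
Calponin	Calponin family repeat
Tropomyosin	Tropomyosin
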